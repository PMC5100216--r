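# Orchestration: CSV I/O for long-format observation tables, the full
# validity battery, and deterministic report files.

obs_cols <- c("patient_id", "session_day", "phase", "conscious", "vas",
              item_cols)

scale_cols <- c(bps = "bps_total", cpot = "cpot_total", combined = "combined")

#' Read a long-format observation table
#'
#' Expects an RFC-4180 CSV with header columns `patient_id`, `session_day`,
#' `phase` (`before`/`during`/`after`), `conscious` (0/1), `vas` (0-10,
#' empty when missing) and the seven item columns `bps_facial`,
#' `bps_upper_limb`, `bps_ventilator`, `cpot_facial`, `cpot_body`,
#' `cpot_tension`, `cpot_ventilator`. Rows failing validation are rejected
#' with row-numbered messages. VAS must be missing on unconscious rows;
#' with `strict_vas = TRUE`, conscious rows must carry a VAS.
#'
#' @param path CSV file path.
#' @param strict_vas Require a VAS value on every conscious row.
#' @return A validated observation tibble (`conscious` as logical).
#' @seealso [write_observations()], [simulate_cohort()]
#' @export
read_observations <- function(path, strict_vas = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      phase = readr::col_character(),
      .default = readr::col_integer()
    ),
    show_col_types = FALSE
  )
  missing_cols <- setdiff(obs_cols, names(df))
  extra_cols <- setdiff(names(df), obs_cols)
  if (length(missing_cols) || length(extra_cols)) {
    stop("malformed header: ",
         if (length(missing_cols)) paste0("missing column(s) ",
                                          paste(missing_cols, collapse = ", ")),
         if (length(missing_cols) && length(extra_cols)) "; ",
         if (length(extra_cols)) paste0("unexpected column(s) ",
                                        paste(extra_cols, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[obs_cols]
  if (nrow(df) == 0L) {
    warning("empty observation table (header only)", call. = FALSE)
    df$conscious <- as.logical(df$conscious)
    return(tibble::as_tibble(df))
  }
  validate_observations(df, strict_vas = strict_vas)
}

validate_observations <- function(df, strict_vas = FALSE) {
  fail_rows <- function(bad, what) {
    if (length(bad)) {
      shown <- utils::head(bad, 5L)
      stop(sprintf("invalid observations: %s at row%s %s%s", what,
                   if (length(bad) > 1L) "s" else "",
                   paste(shown, collapse = ", "),
                   if (length(bad) > 5L) sprintf(" (and %d more)",
                                                 length(bad) - 5L) else ""),
           call. = FALSE)
    }
  }
  fail_rows(which(is.na(df$patient_id) | df$patient_id == ""),
            "missing patient_id")
  fail_rows(which(is.na(df$session_day) | df$session_day < 1L),
            "session_day must be a positive integer")
  fail_rows(which(!(df$phase %in% phase_names)),
            "phase must be one of before/during/after")
  fail_rows(which(!(df$conscious %in% c(0L, 1L, NA)) | is.na(df$conscious)),
            "conscious must be 0 or 1")
  for (col in item_cols) {
    rng <- item_range(col)
    fail_rows(which(is.na(df[[col]]) | df[[col]] < rng[1] | df[[col]] > rng[2]),
              sprintf("%s outside [%d, %d]", col, rng[1], rng[2]))
  }
  fail_rows(which(!is.na(df$vas) & (df$vas < 0L | df$vas > 10L)),
            "vas outside [0, 10]")
  fail_rows(which(!is.na(df$vas) & df$conscious == 0L),
            "vas present on unconscious row")
  if (strict_vas) {
    fail_rows(which(is.na(df$vas) & df$conscious == 1L),
              "vas missing on conscious row (strict mode)")
  }
  df$conscious <- df$conscious == 1L
  tibble::as_tibble(df)
}

#' Write an observation table to CSV
#'
#' Inverse of [read_observations()]: `conscious` is written as 0/1 and
#' missing VAS as an empty field.
#'
#' @param records Observation tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_observations <- function(records, path) {
  out <- records[obs_cols]
  out$conscious <- as.integer(out$conscious)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# attach totals and severity categories to validated records
score_records <- function(records) {
  records$bps_total <- score_bps(records$bps_facial, records$bps_upper_limb,
                                 records$bps_ventilator)
  records$cpot_total <- score_cpot(records$cpot_facial, records$cpot_body,
                                   records$cpot_tension,
                                   records$cpot_ventilator)
  records$combined <- combine_scores(records$bps_total, records$cpot_total)
  records$bps_severity <- categorize_bps(records$bps_total)
  records$cpot_severity <- categorize_cpot(records$cpot_total)
  records
}

#' Run the full validity battery on an observation table
#'
#' Produces five sections:
#' \describe{
#'   \item{discriminant}{Paired Wilcoxon signed-rank tests of each scale
#'     total across the three phase contrasts (before-vs-during,
#'     during-vs-after, before-vs-after), overall and per consciousness
#'     stratum. Pairs are matched by patient and session-day; the Z sign
#'     follows `first phase - second phase`, so pain rising during nursing
#'     gives a negative before-vs-during Z.}
#'   \item{criterion}{Spearman correlation of each scale total with VAS
#'     across all rows carrying a VAS.}
#'   \item{performance}{Per scale and phase (plus `overall`, pooling all
#'     phases into a single ROC): the empirical ROC against the VAS >= 3
#'     pain label, the Youden-optimal cutoff, and sensitivity,
#'     specificity, AUC and prevalence-weighted accuracy at that cutoff.
#'     Only rows with a VAS contribute.}
#'   \item{agreement}{Quadratic-weighted kappa between BPS and CPOT
#'     severity categories (absence/moderate/severe), per phase and
#'     overall, on all rows.}
#'   \item{item_importance}{Before-vs-during Cohen's d per item (unpaired,
#'     pooled SD) with magnitude bands, on all rows.}
#' }
#'
#' Stages hitting degenerate inputs (a missing phase, single-class labels,
#' constant scores) are skipped with a warning rather than aborting the
#' run.
#'
#' @param records Observation tibble from [read_observations()] or
#'   [simulate_cohort()].
#' @param vas_cutoff VAS positivity threshold for the pain label
#'   (default 3).
#' @return An object of class `pain_report`: a list of tibbles
#'   `discriminant`, `criterion`, `performance`, `agreement`,
#'   `item_importance`, plus `meta`.
#' @export
run_analysis <- function(records, vas_cutoff = 3) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("empty records", call. = FALSE)
  }
  d <- score_records(records)
  skipped <- character(0)
  note_skip <- function(what, why) {
    skipped <<- c(skipped, sprintf("%s (%s)", what, conditionMessage(why)))
  }

  ## discriminant validity
  contrasts <- list(before_vs_during = c("before", "during"),
                    during_vs_after = c("during", "after"),
                    before_vs_after = c("before", "after"))
  strata <- list(overall = rep(TRUE, nrow(d)), conscious = d$conscious,
                 unconscious = !d$conscious)
  disc <- list()
  for (sc in names(scale_cols)) {
    col <- scale_cols[[sc]]
    for (st in names(strata)) {
      dd <- d[strata[[st]], c("patient_id", "session_day", "phase", col)]
      for (ct in names(contrasts)) {
        ph <- contrasts[[ct]]
        aa <- dd[dd$phase == ph[1], c("patient_id", "session_day", col)]
        bb <- dd[dd$phase == ph[2], c("patient_id", "session_day", col)]
        m <- merge(aa, bb, by = c("patient_id", "session_day"),
                   suffixes = c("_a", "_b"))
        res <- tryCatch(
          wilcoxon_signed_rank(m[[paste0(col, "_a")]],
                               m[[paste0(col, "_b")]]),
          error = function(e) {
            note_skip(sprintf("discriminant %s/%s/%s", sc, st, ct), e)
            NULL
          })
        if (!is.null(res)) {
          disc[[length(disc) + 1L]] <- tibble::tibble(
            scale = sc, stratum = st, contrast = ct, n_pairs = nrow(m),
            z = res$statistic, p = res$p.value)
        }
      }
    }
  }
  disc <- if (length(disc)) dplyr::bind_rows(disc) else
    tibble::tibble(scale = character(), stratum = character(),
                   contrast = character(), n_pairs = integer(),
                   z = numeric(), p = numeric())

  ## criterion validity
  vas_rows <- d[!is.na(d$vas), ]
  crit <- list()
  for (sc in names(scale_cols)) {
    res <- tryCatch(
      spearman_rank_correlation(vas_rows[[scale_cols[[sc]]]], vas_rows$vas),
      error = function(e) { note_skip(sprintf("criterion %s", sc), e); NULL })
    if (!is.null(res)) {
      crit[[length(crit) + 1L]] <- tibble::tibble(
        scale = sc, n = res$n, rs = res$estimate, p = res$p.value)
    }
  }
  crit <- if (length(crit)) dplyr::bind_rows(crit) else
    tibble::tibble(scale = character(), n = integer(), rs = numeric(),
                   p = numeric())

  ## diagnostic performance vs the VAS pain label
  perf <- list()
  if (nrow(vas_rows)) {
    labels <- dichotomize_vas(vas_rows$vas, cutoff = vas_cutoff)
    for (sc in names(scale_cols)) {
      for (ph in c(phase_names, "overall")) {
        sel <- if (ph == "overall") rep(TRUE, nrow(vas_rows)) else
          vas_rows$phase == ph
        res <- tryCatch({
          curve <- roc_curve(vas_rows[[scale_cols[[sc]]]][sel], labels[sel])
          op <- best_cutoff_youden(curve)
          list(curve = curve, op = op)
        }, error = function(e) {
          note_skip(sprintf("performance %s/%s", sc, ph), e)
          NULL
        })
        if (!is.null(res)) {
          perf[[length(perf) + 1L]] <- tibble::tibble(
            scale = sc, phase = ph, cutoff = res$op$cutoff,
            sensitivity = res$op$sensitivity,
            specificity = res$op$specificity,
            auc = res$curve$auc, accuracy = res$op$accuracy,
            sensitivity_pct = round_half_up(100 * res$op$sensitivity, 2),
            specificity_pct = round_half_up(100 * res$op$specificity, 2),
            accuracy_pct = round_half_up(100 * res$op$accuracy, 2),
            n_pos = res$curve$n_pos, n_neg = res$curve$n_neg)
        }
      }
    }
  } else {
    skipped <- c(skipped, "performance (no rows with VAS)")
  }
  perf <- if (length(perf)) dplyr::bind_rows(perf) else
    tibble::tibble(scale = character(), phase = character(),
                   cutoff = numeric(), sensitivity = numeric(),
                   specificity = numeric(), auc = numeric(),
                   accuracy = numeric(), sensitivity_pct = numeric(),
                   specificity_pct = numeric(), accuracy_pct = numeric(),
                   n_pos = integer(), n_neg = integer())

  ## BPS-CPOT agreement on severity categories
  agree <- list()
  for (ph in c(phase_names, "overall")) {
    sel <- if (ph == "overall") rep(TRUE, nrow(d)) else d$phase == ph
    if (!any(sel)) next
    res <- tryCatch(
      quadratic_weighted_kappa(d$bps_severity[sel], d$cpot_severity[sel],
                               categories = severity_levels),
      error = function(e) { note_skip(sprintf("agreement %s", ph), e); NULL })
    if (!is.null(res)) {
      agree[[length(agree) + 1L]] <- tibble::tibble(
        phase = ph, n = res$n, kappa = res$kappa)
    }
  }
  agree <- if (length(agree)) dplyr::bind_rows(agree) else
    tibble::tibble(phase = character(), n = integer(), kappa = numeric())

  ## item importance (before vs during)
  bef <- d[d$phase == "before", ]
  dur <- d[d$phase == "during", ]
  items <- list()
  for (it in item_cols) {
    res <- tryCatch(cohens_d(bef[[it]], dur[[it]]), error = function(e) {
      note_skip(sprintf("item_importance %s", it), e)
      NULL
    })
    if (!is.null(res)) {
      items[[length(items) + 1L]] <- tibble::tibble(
        item = it, d = res$d, magnitude = res$magnitude)
    }
  }
  items <- if (length(items)) dplyr::bind_rows(items) else
    tibble::tibble(item = character(), d = numeric(), magnitude = character())
  if (nrow(items)) items$rank <- rank(-abs(items$d), ties.method = "first")

  if (length(skipped)) {
    warning("skipped degenerate stage(s): ", paste(skipped, collapse = "; "),
            call. = FALSE)
  }

  structure(
    list(discriminant = disc, criterion = crit, performance = perf,
         agreement = agree, item_importance = items,
         meta = list(n_rows = nrow(d), n_patients = length(unique(d$patient_id)),
                     n_vas_rows = nrow(vas_rows), vas_cutoff = vas_cutoff,
                     skipped = skipped)),
    class = "pain_report"
  )
}

#' @export
print.pain_report <- function(x, ...) {
  cat(sprintf("Pain-scale validity report: %d rows, %d patients, %d with VAS\n",
              x$meta$n_rows, x$meta$n_patients, x$meta$n_vas_rows))
  cat(sprintf("  discriminant: %d tests | criterion: %d scales | performance: %d cells | agreement: %d phases | items: %d\n",
              nrow(x$discriminant), nrow(x$criterion), nrow(x$performance),
              nrow(x$agreement), nrow(x$item_importance)))
  if (length(x$meta$skipped)) {
    cat("  skipped:", paste(x$meta$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}

fmt_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", round_half_up(p, 4)))
}

#' Write a validity report to CSV files and a text summary
#'
#' Writes one CSV per report section plus `summary.txt` into `out_dir`.
#' The performance table is laid out with one row per scale x metric
#' (sensitivity, specificity, AUC, accuracy, cutoff) and one column per
#' phase (before/during/after/overall); sensitivity, specificity and
#' accuracy are printed as half-up-rounded 2-decimal percentages. Output
#' is deterministic: identical reports give byte-identical files.
#'
#' @param report A `pain_report` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!inherits(report, "pain_report")) {
    stop("'report' must be a pain_report object", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p, na = "")
    paths <<- c(paths, p)
  }

  disc <- report$discriminant
  if (nrow(disc)) {
    disc$z <- sprintf("%.2f", round_half_up(disc$z, 2))
    disc$p <- fmt_p(disc$p)
  }
  emit(disc, "discriminant.csv")

  crit <- report$criterion
  if (nrow(crit)) {
    crit$rs <- sprintf("%.2f", round_half_up(crit$rs, 2))
    crit$p <- fmt_p(crit$p)
  }
  emit(crit, "criterion.csv")

  perf_wide <- performance_table(report$performance)
  emit(perf_wide, "performance.csv")

  agree <- report$agreement
  if (nrow(agree)) agree$kappa <- sprintf("%.2f", round_half_up(agree$kappa, 2))
  emit(agree, "agreement.csv")

  items <- report$item_importance
  if (nrow(items)) items$d <- sprintf("%.2f", round_half_up(items$d, 2))
  emit(items, "item_importance.csv")

  writeLines(summary_lines(report), file.path(out_dir, "summary.txt"))
  paths <- c(paths, file.path(out_dir, "summary.txt"))
  invisible(paths)
}

# wide performance layout: 3 scales x 5 metrics rows, 4 phase columns
performance_table <- function(perf) {
  metrics <- c("sensitivity", "specificity", "auc", "accuracy", "cutoff")
  phases <- c(phase_names, "overall")
  out <- expand.grid(metric = metrics, scale = names(scale_cols),
                     stringsAsFactors = FALSE)[, c("scale", "metric")]
  out <- tibble::as_tibble(out)
  cell <- function(sc, met, ph) {
    row <- perf[perf$scale == sc & perf$phase == ph, ]
    if (nrow(row) == 0L) return(NA_character_)
    switch(met,
           sensitivity = sprintf("%.2f", row$sensitivity_pct),
           specificity = sprintf("%.2f", row$specificity_pct),
           accuracy = sprintf("%.2f", row$accuracy_pct),
           auc = sprintf("%.2f", round_half_up(row$auc, 2)),
           cutoff = sprintf("%g", row$cutoff))
  }
  for (ph in phases) {
    out[[ph]] <- mapply(cell, out$scale, out$metric, MoreArgs = list(ph = ph))
  }
  out
}

summary_lines <- function(report) {
  lines <- c(
    "Pain-scale validity report",
    sprintf("rows: %d  patients: %d  rows with VAS: %d  VAS cutoff: >=%g",
            report$meta$n_rows, report$meta$n_patients,
            report$meta$n_vas_rows, report$meta$vas_cutoff))
  perf <- report$performance
  dur <- perf[perf$phase == "during", ]
  if (nrow(dur)) {
    lines <- c(lines, "during-nursing performance (sens% / spec% / AUC / accuracy%):")
    for (i in seq_len(nrow(dur))) {
      lines <- c(lines, sprintf("  %-8s %6.2f / %6.2f / %.2f / %6.2f (cutoff >= %g)",
                                dur$scale[i], dur$sensitivity_pct[i],
                                dur$specificity_pct[i],
                                round_half_up(dur$auc[i], 2),
                                dur$accuracy_pct[i], dur$cutoff[i]))
    }
  }
  agree <- report$agreement
  if (nrow(agree)) {
    lines <- c(lines, sprintf("BPS-CPOT severity agreement (quadratic kappa): %s",
                              paste(sprintf("%s %.2f", agree$phase,
                                            round_half_up(agree$kappa, 2)),
                                    collapse = ", ")))
  }
  items <- report$item_importance
  if (nrow(items)) {
    top <- items[items$rank == 1L, ]
    lines <- c(lines, sprintf("most discriminating item: %s (d = %.2f, %s)",
                              top$item[1], round_half_up(top$d[1], 2),
                              top$magnitude[1]))
  }
  if (length(report$meta$skipped)) {
    lines <- c(lines, paste("skipped stages:",
                            paste(report$meta$skipped, collapse = "; ")))
  }
  lines
}
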