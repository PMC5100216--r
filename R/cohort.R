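# Seeded synthetic ICU cohort generator. A latent pain trajectory on the
# VAS-anchored 0-10 scale drives ordinal behavior levels per domain through
# a cumulative-threshold readout; levels map to concordant BPS/CPOT items,
# with optional discordance noise; conscious patients additionally report a
# noisy VAS.

phase_names <- c("before", "during", "after")

item_cols <- c("bps_facial", "bps_upper_limb", "bps_ventilator",
               "cpot_facial", "cpot_body", "cpot_tension", "cpot_ventilator")

item_range <- function(item) {
  if (startsWith(item, "bps_")) c(1L, 4L) else c(0L, 2L)
}

#' Configuration of the synthetic ICU cohort
#'
#' Defaults reproduce the emulated study design: 101 mechanically
#' ventilated patients (41 conscious, 60 unconscious), each observed on 3
#' session-days at 3 nursing phases (1 min before, during, 20 min after
#' the procedure) -- 303 observation sessions, 909 phase rows. Latent pain
#' sits on a VAS-like 0-10 scale; the nursing procedure raises its mean
#' from 1.5 to 4.5 and it relaxes back to 2 afterwards. Facial expression
#' carries the highest discrimination, making it the most informative item.
#'
#' @param n_conscious,n_unconscious Patients per consciousness stratum.
#' @param sessions_per_patient Observation days per patient.
#' @param phase_means Named numeric vector (`before`, `during`, `after`):
#'   latent pain mean per nursing phase on the 0-10 scale. The `during`
#'   mean must be at least the `before` mean.
#' @param latent_sd Standard deviation of both the patient random effect
#'   and the per-row session noise; the marginal latent SD is
#'   `latent_sd * sqrt(2)`.
#' @param anchor Latent pain value at which behavior starts to escalate
#'   (the first threshold sits at the anchor when `thresholds[1] = 0`).
#' @param thresholds Two increasing values on the discrimination-scaled
#'   latent axis separating the three behavior levels of every domain.
#' @param item_discrimination Named slopes (`facial`, `movement`,
#'   `ventilator`) linking latent pain to the domain's behavior level;
#'   larger slopes concentrate the level transitions near the anchor.
#' @param sub_intensity_prob Probability that the upper BPS value is taken
#'   where a crosswalk row spans two scores ("3 or 4").
#' @param discordance_rate Probability, independent per item, that an item
#'   deviates one level from the concordant crosswalk (clipped to the item
#'   range).
#' @param vas_noise_sd SD of the readout noise added to latent pain before
#'   rounding to the reported VAS (conscious patients only).
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return A validated list of class `cohort_config`.
#' @seealso [simulate_cohort()], [expected_item_effects()]
#' @export
cohort_config <- function(n_conscious = 41L,
                          n_unconscious = 60L,
                          sessions_per_patient = 3L,
                          phase_means = c(before = 1.5, during = 4.5,
                                          after = 2.0),
                          latent_sd = 1.2,
                          anchor = 2.5,
                          thresholds = c(1.0, 3.0),
                          item_discrimination = c(facial = 1.10,
                                                  movement = 0.35,
                                                  ventilator = 0.45),
                          sub_intensity_prob = 0.5,
                          discordance_rate = 0.05,
                          vas_noise_sd = 2.5,
                          seed = 1L) {
  cfg <- list(
    n_conscious = as.integer(n_conscious),
    n_unconscious = as.integer(n_unconscious),
    sessions_per_patient = as.integer(sessions_per_patient),
    phase_means = phase_means,
    latent_sd = latent_sd,
    anchor = anchor,
    thresholds = thresholds,
    item_discrimination = item_discrimination,
    sub_intensity_prob = sub_intensity_prob,
    discordance_rate = discordance_rate,
    vas_noise_sd = vas_noise_sd,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid cohort config: ", msg, call. = FALSE)
  if (is.na(cfg$n_conscious) || cfg$n_conscious < 1L ||
      is.na(cfg$n_unconscious) || cfg$n_unconscious < 0L) {
    stop_cfg("stratum sizes must be positive counts")
  }
  if (is.na(cfg$sessions_per_patient) || cfg$sessions_per_patient < 1L) {
    stop_cfg("sessions_per_patient must be a positive count")
  }
  pm <- cfg$phase_means
  if (!is.numeric(pm) || length(pm) != 3L ||
      !setequal(names(pm), phase_names)) {
    stop_cfg("phase_means must be named numeric (before, during, after)")
  }
  if (pm[["during"]] < pm[["before"]]) {
    stop_cfg("phase_means['during'] must be >= phase_means['before']")
  }
  if (!is.numeric(cfg$latent_sd) || cfg$latent_sd <= 0) {
    stop_cfg("latent_sd must be positive")
  }
  if (!is.numeric(cfg$thresholds) || length(cfg$thresholds) != 2L ||
      diff(cfg$thresholds) <= 0) {
    stop_cfg("thresholds must be two increasing values")
  }
  disc <- cfg$item_discrimination
  if (!is.numeric(disc) || length(disc) != 3L ||
      !setequal(names(disc), c("facial", "movement", "ventilator")) ||
      any(disc <= 0)) {
    stop_cfg("item_discrimination must be positive and named (facial, movement, ventilator)")
  }
  if (cfg$discordance_rate < 0 || cfg$discordance_rate > 1) {
    stop_cfg("discordance_rate must be in [0, 1]")
  }
  if (cfg$sub_intensity_prob < 0 || cfg$sub_intensity_prob > 1) {
    stop_cfg("sub_intensity_prob must be in [0, 1]")
  }
  if (!is.numeric(cfg$vas_noise_sd) || cfg$vas_noise_sd < 0) {
    stop_cfg("vas_noise_sd must be non-negative")
  }
  if (is.na(cfg$seed)) stop_cfg("seed must be an integer")
  invisible(cfg)
}

#' Read a cohort configuration from a YAML file
#'
#' Keys mirror the arguments of [cohort_config()]; unspecified keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("phase_means", "item_discrimination")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  if (!is.null(raw$thresholds)) raw$thresholds <- as.numeric(unlist(raw$thresholds))
  do.call(cohort_config, raw)
}

# behavior level (1..3) from latent pain via the cumulative-threshold readout
latent_to_level <- function(theta, lambda, anchor, thresholds) {
  s <- lambda * (theta - anchor)
  1L + (s >= thresholds[1]) + (s >= thresholds[2])
}

#' Simulate a synthetic ICU observation table
#'
#' For each patient and session-day, latent pain at each nursing phase is
#' `phase_mean + patient effect + session noise`, clipped to `[0, 10]`.
#' Each behavioral domain maps latent pain through two ordinal thresholds
#' to a behavior level, then to concordant BPS/CPOT items (with a random
#' sub-intensity flag where a crosswalk row spans two BPS values);
#' discordance noise perturbs items by one level independently with
#' probability `discordance_rate`. Conscious patients report
#' `round(clip(latent + noise, 0, 10))` as VAS; unconscious patients share
#' the identical behavioral model and differ only in VAS missingness.
#'
#' Draws come from a single stream seeded by `config$seed` in fixed order
#' (patients, then sessions, then phases, then domains), so the output is
#' fully reproducible.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with one row per patient x session-day x phase and
#'   columns `patient_id`, `session_day`, `phase`, `conscious` (logical),
#'   `vas` (integer, `NA` when unconscious), and the seven item columns
#'   `bps_facial`, `bps_upper_limb`, `bps_ventilator`, `cpot_facial`,
#'   `cpot_body`, `cpot_tension`, `cpot_ventilator`.
#' @examples
#' obs <- simulate_cohort(cohort_config(seed = 42))
#' nrow(obs)  # 909
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  validate_cohort_config(config)
  set.seed(config$seed)

  n_pat <- config$n_conscious + config$n_unconscious
  conscious <- rep(c(TRUE, FALSE), c(config$n_conscious, config$n_unconscious))
  ids <- sprintf("P%03d", seq_len(n_pat))
  lam <- config$item_discrimination
  n_rows <- n_pat * config$sessions_per_patient * 3L

  rows <- vector("list", n_rows)
  k <- 0L
  for (p in seq_len(n_pat)) {
    b_p <- stats::rnorm(1, 0, config$latent_sd)
    for (s in seq_len(config$sessions_per_patient)) {
      for (ph in phase_names) {
        theta <- clip(config$phase_means[[ph]] + b_p +
                        stats::rnorm(1, 0, config$latent_sd), 0, 10)
        levs <- c(
          facial = latent_to_level(theta, lam[["facial"]], config$anchor,
                                   config$thresholds),
          movement = latent_to_level(theta, lam[["movement"]], config$anchor,
                                     config$thresholds),
          ventilator = latent_to_level(theta, lam[["ventilator"]],
                                       config$anchor, config$thresholds)
        )
        hi <- stats::runif(3) < config$sub_intensity_prob
        items <- items_from_levels(levs[["facial"]], levs[["movement"]],
                                   levs[["ventilator"]],
                                   hi_facial = hi[1], hi_movement = hi[2],
                                   hi_ventilator = hi[3])
        vals <- as.integer(items[1, item_cols])
        # discordance: one draw for the event and one for the direction per
        # item, always consumed, so the stream layout is fixed
        u <- stats::runif(7)
        dir <- sample(c(-1L, 1L), 7L, replace = TRUE)
        flip <- u < config$discordance_rate
        for (j in which(flip)) {
          rng <- item_range(item_cols[j])
          vals[j] <- clip(vals[j] + dir[j], rng[1], rng[2])
        }
        vas <- NA_integer_
        if (conscious[p]) {
          vas <- as.integer(round(clip(theta +
                                         stats::rnorm(1, 0, config$vas_noise_sd),
                                       0, 10)))
        }
        k <- k + 1L
        rows[[k]] <- c(list(patient_id = ids[p], session_day = s, phase = ph,
                            conscious = conscious[p], vas = vas),
                       stats::setNames(as.list(vals), item_cols))
      }
    }
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  names(out) <- c("patient_id", "session_day", "phase", "conscious", "vas",
                  item_cols)
  out
}

# pmf of one item's score under the generator, by numeric normal integrals --
# used for analytic calibration and parameter-recovery checks
item_pmf <- function(config, item, phase) {
  domain <- switch(item,
                   bps_facial = "facial", cpot_facial = "facial",
                   bps_upper_limb = "movement", cpot_body = "movement",
                   cpot_tension = "movement",
                   bps_ventilator = "ventilator", cpot_ventilator = "ventilator",
                   stop("unknown item: ", item, call. = FALSE))
  lam <- config$item_discrimination[[domain]]
  mu <- config$phase_means[[phase]]
  sigma <- config$latent_sd * sqrt(2)
  # P(clipped latent >= x); clipping to [0,10] only moves mass onto the
  # boundaries, so interior thresholds see the unclipped normal
  p_ge <- function(x) {
    if (x <= 0) 1 else if (x > 10) 0 else stats::pnorm(x, mu, sigma,
                                                       lower.tail = FALSE)
  }
  x1 <- config$anchor + config$thresholds[1] / lam
  x2 <- config$anchor + config$thresholds[2] / lam
  p3 <- p_ge(x2)
  p2 <- p_ge(x1) - p3
  p1 <- 1 - p2 - p3
  if (startsWith(item, "bps_")) {
    q <- config$sub_intensity_prob
    pmf <- c(p1, p2, p3 * (1 - q), p3 * q)   # values 1..4
  } else {
    pmf <- c(p1, p2, p3)                     # values 0..2
  }
  r <- config$discordance_rate
  kk <- length(pmf)
  up <- c(0, pmf[-kk]); up[kk] <- up[kk] + pmf[kk]
  dn <- c(pmf[-1], 0); dn[1] <- dn[1] + pmf[1]
  (1 - r) * pmf + r * 0.5 * (up + dn)
}

#' Expected per-item effect sizes implied by a cohort configuration
#'
#' Computes, analytically (normal integrals, no simulation), the
#' standardized mean difference of each item score between the `before`
#' and `during` phases under the generator's model. This is the
#' "configured shift" that [calibration_summary()] and the pipeline's
#' item-importance stage should recover from simulated data, up to Monte
#' Carlo error.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with columns `item` and `expected_d`.
#' @export
expected_item_effects <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  d_one <- function(item) {
    stat <- function(phase) {
      pmf <- item_pmf(config, item, phase)
      vals <- if (startsWith(item, "bps_")) 1:4 else 0:2
      m <- sum(vals * pmf)
      c(m = m, v = sum(vals^2 * pmf) - m^2)
    }
    bef <- stat("before")
    dur <- stat("during")
    (dur[["m"]] - bef[["m"]]) / sqrt((bef[["v"]] + dur[["v"]]) / 2)
  }
  tibble::tibble(item = item_cols,
                 expected_d = vapply(item_cols, d_one, numeric(1)))
}

#' Calibration summary of a generated (or observed) cohort
#'
#' Computes the quantities used to check that a synthetic cohort carries
#' the intended statistical structure: per-item before-vs-during Cohen
#' effect sizes, Spearman correlation of each scale total (BPS, CPOT,
#' combined) with VAS on conscious rows, and per-phase mean totals.
#'
#' @param records An observation tibble as produced by [simulate_cohort()].
#' @return A list with tibbles `item_effects` (item, d, magnitude),
#'   `criterion` (scale, n, rs, p) and `phase_means` (phase, bps, cpot,
#'   combined).
#' @export
calibration_summary <- function(records) {
  if (nrow(records) == 0L) stop("empty records", call. = FALSE)
  scored <- score_records(records)

  bef <- scored[scored$phase == "before", ]
  dur <- scored[scored$phase == "during", ]
  eff <- lapply(item_cols, function(it) {
    res <- cohens_d(bef[[it]], dur[[it]])
    tibble::tibble(item = it, d = res$d, magnitude = res$magnitude)
  })

  vas_rows <- scored[!is.na(scored$vas), ]
  crit <- lapply(c(bps = "bps_total", cpot = "cpot_total",
                   combined = "combined"), function(col) {
    res <- spearman_rank_correlation(vas_rows[[col]], vas_rows$vas)
    tibble::tibble(n = res$n, rs = res$estimate, p = res$p.value)
  })
  crit <- dplyr::bind_rows(crit, .id = "scale")

  phase_mean <- function(col) {
    vapply(phase_names, function(p) mean(scored[[col]][scored$phase == p]),
           numeric(1))
  }
  pm <- tibble::tibble(phase = phase_names, bps = phase_mean("bps_total"),
                       cpot = phase_mean("cpot_total"),
                       combined = phase_mean("combined"))

  list(item_effects = dplyr::bind_rows(eff), criterion = crit,
       phase_means = pm)
}
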