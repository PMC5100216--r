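# Behavioral Pain Scale (BPS) and Critical-Care Pain Observation Tool (CPOT):
# item structure, totals, the combined 3-20 score, severity bands, and the
# concordant behavior-level -> item crosswalk used by the cohort generator.

severity_levels <- c("absence", "moderate", "severe")

behavior_levels <- list(
  facial     = c("relaxed", "tense", "grimacing"),
  movement   = c("still", "protective", "agitated"),
  ventilator = c("tolerating", "coughing", "fighting")
)

#' Score the Behavioral Pain Scale
#'
#' The BPS rates three behavioral indicators in mechanically ventilated
#' patients -- facial expression, upper-limb movement, and compliance with
#' the ventilator -- each on an ordinal 1-4 scale. The total is the plain
#' sum, ranging 3 (fully relaxed) to 12 (maximal behavioral pain response).
#'
#' @param facial,upper_limb,ventilator Integer item scores, each in 1-4.
#'   Vectors are scored element-wise.
#' @return Integer vector of totals in `[3, 12]`.
#' @examples
#' score_bps(1, 1, 1)  # 3, no behavioral pain response
#' score_bps(4, 4, 4)  # 12, maximal response
#' @seealso [score_cpot()], [combine_scores()], [categorize_bps()]
#' @export
score_bps <- function(facial, upper_limb, ventilator) {
  facial <- check_item(facial, "facial", 1L, 4L)
  upper_limb <- check_item(upper_limb, "upper_limb", 1L, 4L)
  ventilator <- check_item(ventilator, "ventilator", 1L, 4L)
  check_equal_lengths(facial, upper_limb, ventilator)
  facial + upper_limb + ventilator
}

#' Score the Critical-Care Pain Observation Tool
#'
#' The CPOT rates four behavioral indicators -- facial expression, body
#' movements, muscle tension, and compliance with the ventilator -- each on
#' an ordinal 0-2 scale. The total is the plain sum, ranging 0 to 8.
#'
#' @param facial,body_movement,muscle_tension,ventilator Integer item
#'   scores, each in 0-2. Vectors are scored element-wise.
#' @return Integer vector of totals in `[0, 8]`.
#' @examples
#' score_cpot(0, 0, 0, 0)  # 0
#' score_cpot(2, 2, 2, 2)  # 8
#' @seealso [score_bps()], [combine_scores()], [categorize_cpot()]
#' @export
score_cpot <- function(facial, body_movement, muscle_tension, ventilator) {
  facial <- check_item(facial, "facial", 0L, 2L)
  body_movement <- check_item(body_movement, "body_movement", 0L, 2L)
  muscle_tension <- check_item(muscle_tension, "muscle_tension", 0L, 2L)
  ventilator <- check_item(ventilator, "ventilator", 0L, 2L)
  check_equal_lengths(facial, body_movement, muscle_tension, ventilator)
  facial + body_movement + muscle_tension + ventilator
}

#' Combine BPS and CPOT totals into the fused 3-20 score
#'
#' The combination score is the arithmetic sum of the two scale totals.
#' Because the BPS total spans 3-12 and the CPOT total spans 0-8, the
#' combined score spans 3-20; no rescaling is applied (only the plain sum
#' reproduces that range).
#'
#' @param bps_total Integer BPS totals in 3-12.
#' @param cpot_total Integer CPOT totals in 0-8.
#' @return Integer vector of combined scores in `[3, 20]`.
#' @examples
#' combine_scores(3, 0)   # 3
#' combine_scores(12, 8)  # 20
#' @export
combine_scores <- function(bps_total, cpot_total) {
  bps_total <- check_item(bps_total, "bps_total", 3L, 12L)
  cpot_total <- check_item(cpot_total, "cpot_total", 0L, 8L)
  check_equal_lengths(bps_total, cpot_total)
  bps_total + cpot_total
}

#' Severity category of a BPS total
#'
#' Totals 3-4 indicate absence of pain, 5-7 moderate pain, and 8-12 severe
#' pain.
#'
#' @param bps_total Integer BPS totals in 3-12.
#' @return Ordered factor with levels `absence < moderate < severe`.
#' @examples
#' categorize_bps(c(4, 6, 9))
#' @export
categorize_bps <- function(bps_total) {
  bps_total <- check_item(bps_total, "bps_total", 3L, 12L)
  out <- ifelse(bps_total <= 4L, "absence",
                ifelse(bps_total <= 7L, "moderate", "severe"))
  factor(out, levels = severity_levels, ordered = TRUE)
}

#' Severity category of a CPOT total
#'
#' Totals 0-2 indicate absence of pain, 3-4 moderate pain, and 5-8 severe
#' pain.
#'
#' @param cpot_total Integer CPOT totals in 0-8.
#' @return Ordered factor with levels `absence < moderate < severe`.
#' @examples
#' categorize_cpot(c(1, 3, 8))
#' @export
categorize_cpot <- function(cpot_total) {
  cpot_total <- check_item(cpot_total, "cpot_total", 0L, 8L)
  out <- ifelse(cpot_total <= 2L, "absence",
                ifelse(cpot_total <= 4L, "moderate", "severe"))
  factor(out, levels = severity_levels, ordered = TRUE)
}

# vectorized crosswalk from 1-3 behavior levels to item scores; `hi_*`
# selects the upper BPS value where a crosswalk row spans two scores
items_from_levels <- function(facial_lev, movement_lev, ventilator_lev,
                              hi_facial = FALSE, hi_movement = FALSE,
                              hi_ventilator = FALSE) {
  bps_from <- function(lev, hi) {
    ifelse(lev == 3L, 3L + as.integer(hi), lev)
  }
  tibble::tibble(
    bps_facial      = bps_from(facial_lev, hi_facial),
    bps_upper_limb  = bps_from(movement_lev, hi_movement),
    bps_ventilator  = bps_from(ventilator_lev, hi_ventilator),
    cpot_facial     = facial_lev - 1L,
    cpot_body       = movement_lev - 1L,
    cpot_tension    = movement_lev - 1L,
    cpot_ventilator = ventilator_lev - 1L
  )
}

#' Map observed behavior levels to concordant BPS and CPOT item scores
#'
#' Each behavioral domain (facial expression, movement, ventilator
#' compliance) is rated at one of three levels; this returns the BPS and
#' CPOT item scores that sit on the same row of the instruments'
#' correspondence table. The CPOT carries two movement-related items (body
#' movements and muscle tension) against the BPS's single upper-limb item;
#' both CPOT items follow the movement level, with the `protective` level
#' fixed at body movement 1 / muscle tension 1.
#'
#' Where a row spans two BPS values ("3 or 4"), the `bps_sub_intensity`
#' flag for that domain selects the upper value, keeping the mapping
#' deterministic; [simulate_cohort()] supplies the flag stochastically.
#'
#' @param facial One of `"relaxed"`, `"tense"`, `"grimacing"`.
#' @param movement One of `"still"`, `"protective"`, `"agitated"`.
#' @param ventilator One of `"tolerating"`, `"coughing"`, `"fighting"`.
#' @param bps_sub_intensity Named logical vector with elements `facial`,
#'   `movement`, `ventilator`; `TRUE` takes the upper BPS value (4 rather
#'   than 3) at the highest behavior level of that domain. Ignored at the
#'   two lower levels, which map to a single BPS value.
#' @return A list with integer vectors `bps` (facial, upper_limb,
#'   ventilator) and `cpot` (facial, body, tension, ventilator).
#' @examples
#' behavior_to_items("relaxed", "still", "tolerating")
#' behavior_to_items("tense", "still", "coughing")
#' @export
behavior_to_items <- function(facial, movement, ventilator,
                              bps_sub_intensity = c(facial = FALSE,
                                                    movement = FALSE,
                                                    ventilator = FALSE)) {
  facial <- match.arg(facial, behavior_levels$facial)
  movement <- match.arg(movement, behavior_levels$movement)
  ventilator <- match.arg(ventilator, behavior_levels$ventilator)
  hi <- c(facial = FALSE, movement = FALSE, ventilator = FALSE)
  if (is.null(names(bps_sub_intensity))) {
    if (length(bps_sub_intensity) == 1L) {
      bps_sub_intensity <- rep(bps_sub_intensity, 3L)
    }
    if (length(bps_sub_intensity) != 3L) {
      stop("'bps_sub_intensity' must be length 1 or 3, or named", call. = FALSE)
    }
    names(bps_sub_intensity) <- names(hi)
  }
  if (!all(names(bps_sub_intensity) %in% names(hi))) {
    stop("'bps_sub_intensity' names must be among facial, movement, ventilator",
         call. = FALSE)
  }
  hi[names(bps_sub_intensity)] <- as.logical(bps_sub_intensity)
  if (anyNA(hi)) stop("'bps_sub_intensity' must be logical", call. = FALSE)

  items <- items_from_levels(
    match(facial, behavior_levels$facial),
    match(movement, behavior_levels$movement),
    match(ventilator, behavior_levels$ventilator),
    hi_facial = hi[["facial"]],
    hi_movement = hi[["movement"]],
    hi_ventilator = hi[["ventilator"]]
  )
  list(
    bps = c(facial = items$bps_facial, upper_limb = items$bps_upper_limb,
            ventilator = items$bps_ventilator),
    cpot = c(facial = items$cpot_facial, body = items$cpot_body,
             tension = items$cpot_tension, ventilator = items$cpot_ventilator)
  )
}
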