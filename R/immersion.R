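# Wet/dry immersion classification: raw logger blocks -> daily daytime
# activity budgets (proportion flying, resting, foraging).

#' Classify an immersion block as flight, rest or foraging
#'
#' A block is classed by its wet fraction: essentially dry blocks are
#' flight, essentially wet blocks are resting on the water, and
#' intermediate wet/dry mixing is the foraging signature.
#'
#' @param wet_fraction Numeric vector in \[0, 1\].
#' @param thresholds `c(dry_max, wet_min)`: wet fractions `<= dry_max`
#'   are FLY, `>= wet_min` are REST, anything between is FORAGE.  The
#'   defaults (0.05, 0.95) tolerate brief splashes and dry shakes.
#' @return Factor with levels FLY, REST, FORAGE.
#' @export
classify_block <- function(wet_fraction, thresholds = c(0.05, 0.95)) {
  dry_max <- thresholds[1]
  wet_min <- thresholds[2]
  if (!(dry_max >= 0 && dry_max < wet_min && wet_min <= 1)) {
    stop("thresholds must satisfy 0 <= dry_max < wet_min <= 1")
  }
  stopifnot_prob(wet_fraction, "wet_fraction")
  out <- ifelse(wet_fraction <= dry_max, "FLY",
                ifelse(wet_fraction >= wet_min, "REST", "FORAGE"))
  factor(out, levels = c("FLY", "REST", "FORAGE"))
}

#' Daily daytime activity budgets from an immersion series
#'
#' Classifies every block and, per bird and calendar date (dates bounded
#' by midnight in the logger's own clock; no timezone conversion),
#' reports the proportion of daytime blocks spent flying, resting and
#' foraging.  Dates without daytime blocks are omitted.
#'
#' @param series Immersion data.frame with columns `bird_id`,
#'   `timestamp` (POSIXct), `wet_fraction`, `is_daytime`.
#' @param thresholds Passed to [classify_block()].
#' @param include_night If `TRUE`, night blocks enter the budget too
#'   (exploratory; the analysis proper is daytime-only).
#' @return data.frame with `bird_id`, `date`, `p_fly`, `p_rest`,
#'   `p_forage`, `n_daytime_blocks`.
#' @export
daily_profiles <- function(series, thresholds = c(0.05, 0.95),
                           include_night = FALSE) {
  if (nrow(series) == 0L) stop("empty immersion series")
  keep <- if (include_night) rep(TRUE, nrow(series)) else series$is_daytime
  dt <- data.table::data.table(
    bird_id = series$bird_id[keep],
    date = as.Date(series$timestamp[keep], tz = "UTC"),
    act = classify_block(series$wet_fraction[keep], thresholds))
  agg <- dt[, list(p_fly = mean(act == "FLY"),
                   p_rest = mean(act == "REST"),
                   p_forage = mean(act == "FORAGE"),
                   n_daytime_blocks = .N),
            by = c("bird_id", "date")]
  data.table::setorderv(agg, c("bird_id", "date"))
  as.data.frame(agg)
}
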