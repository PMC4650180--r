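# Synthetic-data generators: encounter histories, phenology tables and
# immersion-logger series with the group structure the analysis assumes.

#' Simulate multi-year encounter histories
#'
#' Each bird follows a latent state path over `n_occasions` annual
#' breeding seasons: it survives with probability `phi(state, sex)`,
#' moves between SUCCESS/FAIL/SKIP with the row-stochastic `psi` of its
#' mixture class, and is otherwise absorbed in DEAD.  Observation is
#' imperfect: alive birds are detected with probability `p_detect`
#' (optionally with a state-unknown emission), dead birds are never seen.
#' All birds are released (first encountered, state recorded) at the
#' first occasion; the release event is the true state.
#'
#' @param config A [sim_config()].
#' @return A list with `histories` (an `encounter_histories` object:
#'   event matrix, sex, ids, first occasions) and `truth` (latent state
#'   matrix, mixture class per bird, and the generating parameters).
#' @export
simulate_encounter_histories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_occasions < 2) stop("n_occasions must be at least 2")
  if (!is.null(config$seed)) set.seed(stage_seed(config$seed, "simulate"))

  n <- config$n_birds_logger + config$n_birds_history_only
  T <- config$n_occasions
  C <- length(config$mixture_weights)
  sex <- ifelse(stats::runif(n) < config$prop_female, "F", "M")
  cls <- sample.int(C, n, replace = TRUE, prob = config$mixture_weights)

  phi_of <- function(c) (config$phi_classes[[c]] %||% config$phi)
  psi_of <- function(c) (config$psi_classes[[c]] %||% config$psi)

  init_prob <- config$rp_category_counts / sum(config$rp_category_counts)
  states <- matrix(NA_integer_, n, T)
  states[, 1] <- sample.int(3L, n, replace = TRUE, prob = init_prob)

  for (i in seq_len(n)) {
    phi_i <- phi_of(cls[i])[, sex[i]]
    psi_i <- psi_of(cls[i])[[sex[i]]]
    for (t in 2:T) {
      s <- states[i, t - 1]
      if (s == 4L) { states[i, t] <- 4L; next }
      if (stats::runif(1) > phi_i[s]) {
        states[i, t] <- 4L
      } else {
        states[i, t] <- sample.int(3L, 1L, prob = psi_i[s, ])
      }
    }
  }

  events <- matrix(EVENT_CODES[1L], n, T)
  events[, 1] <- EVENT_CODES[1L + states[, 1]]
  p <- config$p_detect
  u <- config$p_state_unknown
  for (t in 2:T) {
    alive <- states[, t] != 4L
    det <- alive & stats::runif(n) < p[sex]
    unk <- det & stats::runif(n) < u
    events[det, t] <- EVENT_CODES[1L + states[det, t]]
    events[unk, t] <- "SEEN_UNKNOWN"
  }

  bird_id <- sprintf("B%03d", seq_len(n))
  rownames(events) <- bird_id
  histories <- new_encounter_histories(events, sex, bird_id,
                                       first_occasion = rep(1L, n))
  truth <- list(states = states, class = cls, sex = sex,
                phi = config$phi, psi = config$psi,
                p_detect = config$p_detect,
                mixture_weights = config$mixture_weights,
                psi_classes = config$psi_classes,
                phi_classes = config$phi_classes)
  list(histories = histories, truth = truth)
}

# Constructor + validator for the encounter-histories container.
new_encounter_histories <- function(events, sex, bird_id, first_occasion) {
  stopifnot(is.matrix(events))
  bad <- !(events %in% EVENT_CODES)
  if (any(bad)) stop("unknown event code: ", events[bad][1L])
  n <- nrow(events)
  first_ev <- events[cbind(seq_len(n), first_occasion)]
  if (any(first_ev == "NOT_SEEN")) {
    stop("event at first_occasion must not be NOT_SEEN (bird ",
         bird_id[which(first_ev == "NOT_SEEN")[1L]], ")")
  }
  if (any(!sex %in% SEXES)) stop("sex must be 'F' or 'M'")
  structure(list(events = events, sex = sex, bird_id = bird_id,
                 first_occasion = as.integer(first_occasion)),
            class = "encounter_histories")
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat("Encounter histories:", nrow(x$events), "birds x",
      ncol(x$events), "occasions\n")
  cat("  events:", paste(names(table(x$events)), table(x$events),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate per-bird-winter phenology records
#'
#' Draws every annual-cycle event date from its group-specific Gaussian
#' (rounded to whole days, as day offsets from the season anchor) and
#' enforces the biological ordering lay < hatch < fledge < colony
#' departure < WG arrival < WG departure < colony arrival by rejection
#' sampling (at most 1000 attempts per bird).
#'
#' @param config A [sim_config()].
#' @return A `data.frame` (class `phenology_records`) with `bird_id`,
#'   `season_year`, `sex`, one column per registered feature, and the RP
#'   `label`.
#' @export
simulate_phenology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(stage_seed(config$seed, "simulate") + 1L)
  feats <- phenology_features()
  ordered_feats <- c("prior_lay_date", "prior_hatch_date", "prior_fledge_date",
                     "colony_departure", "wg_arrival", "wg_departure",
                     "colony_arrival")
  rows <- vector("list", sum(config$rp_category_counts))
  k <- 0L
  for (g in RP_STATES) {
    ph <- config$phenology[[g]]
    if (is.null(ph)) stop("phenology distribution missing for group ", g)
    if (!all(feats %in% names(ph$mean))) {
      stop("phenology means missing features for group ", g)
    }
    for (b in seq_len(config$rp_category_counts[[g]])) {
      dates <- NULL
      for (attempt in seq_len(1000L)) {
        cand <- round(stats::rnorm(length(feats), ph$mean[feats], ph$sd[feats]))
        names(cand) <- feats
        oc <- cand[ordered_feats]
        if (all(diff(oc) > 0)) { dates <- cand; break }
      }
      if (is.null(dates)) {
        stop("could not draw ordered event dates for group ", g,
             " within 1000 attempts")
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        bird_id = sprintf("L%03d", k),
        season_year = config$base_year + ((k - 1L) %% 5L),
        sex = ifelse(stats::runif(1) < config$prop_female, "F", "M"),
        t(dates), label = g, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phenology_records", "data.frame")
  out
}

# Piecewise-linear activity proportions for one group over winter days,
# with per-day Gaussian noise; rows renormalised to the simplex.
activity_proportions <- function(act, days, noise = TRUE) {
  interp <- function(v) stats::approx(act$breaks, v, xout = days, rule = 2)$y
  p <- cbind(fly = interp(act$fly), rest = interp(act$rest),
             forage = interp(act$forage))
  if (noise && act$noise_sd > 0) {
    p <- p + matrix(stats::rnorm(length(p), 0, act$noise_sd), nrow(p))
  }
  p[p < 0] <- 0
  zero <- rowSums(p) == 0
  p[zero, ] <- 1 / 3
  p / rowSums(p)
}

#' Simulate saltwater-immersion logger series
#'
#' For every phenology record, emits one wet-fraction value per
#' `block_minutes` block from colony departure to colony arrival.  Within
#' the daytime mask each block's behaviour is drawn from the bird's
#' group- and day-specific (fly, rest, forage) proportions; flight emits
#' a dry block (0), resting on water a wet block (1) and foraging an
#' intermediate wet fraction uniform on `forage_band`.  Night blocks are
#' emitted wet with the daytime flag off.
#'
#' @param config A [sim_config()].
#' @param phenology Records from [simulate_phenology()].
#' @return A `data.frame` with `bird_id`, `timestamp` (POSIXct, UTC),
#'   `wet_fraction` and `is_daytime`; block length is recorded in the
#'   `block_minutes` attribute.
#' @export
simulate_immersion <- function(config, phenology) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(stage_seed(config$seed, "simulate") + 2L)
  bm <- config$block_minutes
  blocks_per_day <- 1440L %/% bm
  hour_of_block <- (seq_len(blocks_per_day) - 1L) * bm / 60
  day_mask <- hour_of_block >= config$day_start_hour &
    hour_of_block < config$day_end_hour

  per_bird <- vector("list", nrow(phenology))
  for (i in seq_len(nrow(phenology))) {
    rec <- phenology[i, ]
    n_days <- rec$colony_arrival - rec$colony_departure
    if (n_days < 1) {
      stop("empty winter window for bird ", rec$bird_id)
    }
    act <- config$activity[[rec$label]]
    props <- activity_proportions(act, seq_len(n_days) - 1L)

    anchor <- as.POSIXct(paste0(rec$season_year, config$season_anchor),
                         tz = "UTC")
    t0 <- anchor + as.numeric(rec$colony_departure) * 86400
    ts <- t0 + (seq_len(n_days * blocks_per_day) - 1L) * bm * 60
    daytime <- rep(day_mask, n_days)
    day_ix <- rep(seq_len(n_days), each = blocks_per_day)

    wet <- rep(1, length(ts))            # night: on the water
    day_rows <- which(daytime)
    pfly <- props[day_ix[day_rows], "fly"]
    pforage <- props[day_ix[day_rows], "forage"]
    u <- stats::runif(length(day_rows))
    isfly <- u < pfly
    isforage <- !isfly & u < pfly + pforage
    wet[day_rows] <- 1                   # rest by default
    wet[day_rows[isfly]] <- 0
    wet[day_rows[isforage]] <- stats::runif(sum(isforage),
                                            config$forage_band[1],
                                            config$forage_band[2])

    per_bird[[i]] <- data.frame(bird_id = rec$bird_id, timestamp = ts,
                                wet_fraction = wet, is_daytime = daytime,
                                stringsAsFactors = FALSE)
  }
  out <- data.table::rbindlist(per_bird)
  out <- as.data.frame(out)
  attr(out, "block_minutes") <- bm
  out
}
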