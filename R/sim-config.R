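# Simulation configuration: the statistical structure of the synthetic
# colony (group sizes, survival/transition/detection parameters,
# phenology distributions and winter activity budgets).

#' Default year-to-year breeding-state transition matrix
#'
#' Row-stochastic 3x3 matrix of transition probabilities between
#' reproductive-performance states, conditional on survival.  Rows are the
#' current state, columns the next-year state.  The default encodes the
#' headline pattern that skipping birds have the highest next-year chance
#' of breeding successfully (0.79), failed birds an intermediate one
#' (0.61) and successful birds the lowest (0.57).
#'
#' @return 3x3 numeric matrix with dimnames over `rp_states()`.
#' @export
default_psi <- function() {
  m <- rbind(
    SUCCESS = c(0.57, 0.33, 0.10),
    FAIL    = c(0.61, 0.29, 0.10),
    SKIP    = c(0.79, 0.11, 0.10)
  )
  colnames(m) <- RP_STATES
  m
}

#' Default per-group phenology distributions
#'
#' Mean and SD (days, relative to the 1 March season anchor) of each
#' annual-cycle event, per reproductive-performance group.  Successful
#' birds are earliest throughout the prior season; skipping birds latest.
#'
#' @return Named list (one entry per RP group) of lists with numeric
#'   vectors `mean` and `sd` over the phenology feature registry.
#' @export
default_phenology <- function() {
  feats <- phenology_features()
  mk <- function(shift) {
    mean <- c(prior_lay_date = 68, prior_hatch_date = 119,
              prior_fledge_date = 189, colony_departure = 196,
              wg_arrival = 226, wg_departure = 345,
              colony_arrival = 375) + shift
    sd <- c(prior_lay_date = 6, prior_hatch_date = 6, prior_fledge_date = 6,
            colony_departure = 6, wg_arrival = 8, wg_departure = 8,
            colony_arrival = 8)
    list(mean = mean[feats], sd = sd[feats])
  }
  list(SUCCESS = mk(0), FAIL = mk(5), SKIP = mk(10))
}

#' Phenology feature registry
#'
#' Annual-cycle event dates used as classifier features: prior-season
#' breeding events (lay, hatch, fledge), colony departure/arrival and
#' wintering-ground (WG) arrival/departure.  All are integer day offsets
#' from the season anchor (1 March).
#'
#' @return Character vector of feature names.
#' @export
phenology_features <- function() {
  c("prior_lay_date", "prior_hatch_date", "prior_fledge_date",
    "colony_departure", "wg_arrival", "wg_departure", "colony_arrival")
}

#' Default winter activity budgets per RP group
#'
#' Daytime (fly, rest, forage) proportions as piecewise-linear functions
#' of winter day, specified by node positions (`breaks`, days since
#' colony departure) and node values, plus Gaussian day-to-day noise.
#' The skip group is hyperactive: more flight, much more foraging, less
#' resting than breeders; successful birds show the lowest foraging.
#' All groups share a breakpoint at winter day 60 after which flight
#' activity ramps up towards the spring return.
#'
#' @return Named list per RP group: `breaks`, `fly`, `rest`, `forage`
#'   (node values, each row of nodes summing to 1) and `noise_sd`.
#' @export
default_activity <- function() {
  list(
    SUCCESS = list(breaks = c(0, 60, 180),
                   fly = c(0.12, 0.12, 0.30),
                   rest = c(0.68, 0.66, 0.50),
                   forage = c(0.20, 0.22, 0.20),
                   noise_sd = 0.03),
    FAIL = list(breaks = c(0, 60, 180),
                fly = c(0.15, 0.15, 0.33),
                rest = c(0.55, 0.53, 0.37),
                forage = c(0.30, 0.32, 0.30),
                noise_sd = 0.03),
    SKIP = list(breaks = c(0, 60, 180),
                fly = c(0.20, 0.20, 0.38),
                rest = c(0.35, 0.32, 0.16),
                forage = c(0.45, 0.48, 0.46),
                noise_sd = 0.03)
  )
}

#' Build and validate a simulation configuration
#'
#' Collects every parameter of the synthetic colony: sample sizes,
#' survival (`phi`), transitions (`psi`), detection (`p_detect`),
#' optional finite-mixture heterogeneity, per-group phenology
#' distributions and winter activity budgets, and the immersion-logger
#' sampling scheme.
#'
#' @param n_birds_logger Number of logger bird-winters (defaults to the
#'   111 implied by `rp_category_counts`).
#' @param n_birds_history_only Additional birds monitored for breeding
#'   only (default 88).
#' @param n_occasions Number of annual breeding occasions (default 6).
#' @param rp_category_counts Named counts of logger bird-winters per RP
#'   group (default 64/29/18).
#' @param prop_female Probability a simulated bird is female.
#' @param phi Survival probability: scalar, per-state named vector, or
#'   3x2 matrix (state x sex `F`,`M`).
#' @param psi 3x3 row-stochastic transition matrix, or a list
#'   `list(F = , M = )` of such matrices for sex-specific transitions.
#' @param p_detect Detection probability: scalar or named `c(F=, M=)`.
#' @param p_state_unknown Probability a detection carries no state
#'   information (emits `SEEN_UNKNOWN`).
#' @param mixture_weights Finite-mixture class weights (sum to 1); a
#'   single 1 means a homogeneous population.
#' @param psi_classes Optional list (length = number of classes) of
#'   class-specific `psi` values; `NULL` means all classes share `psi`.
#' @param phi_classes Optional list of class-specific `phi` values.
#' @param phenology Per-group event-date means/SDs; see
#'   [default_phenology()].
#' @param activity Per-group piecewise-linear activity budgets; see
#'   [default_activity()].
#' @param forage_band Range of the uniform wet-fraction emitted by a
#'   foraging block.
#' @param block_minutes Immersion-logger aggregation block length in
#'   minutes; must divide 1440.
#' @param day_start_hour,day_end_hour Daytime mask bounds (hours,
#'   half-open interval).
#' @param season_anchor Month-day anchor of the season clock
#'   (`"-03-01"` = 1 March; all event dates are day offsets from it).
#' @param base_year First calendar season year.
#' @param seed Optional RNG seed stored with the config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_birds_logger = NULL,
                       n_birds_history_only = 88,
                       n_occasions = 6,
                       rp_category_counts = c(SUCCESS = 64, FAIL = 29,
                                              SKIP = 18),
                       prop_female = 0.5,
                       phi = 0.90,
                       psi = default_psi(),
                       p_detect = 0.85,
                       p_state_unknown = 0,
                       mixture_weights = 1,
                       psi_classes = NULL,
                       phi_classes = NULL,
                       phenology = default_phenology(),
                       activity = default_activity(),
                       forage_band = c(0.2, 0.8),
                       block_minutes = 10,
                       day_start_hour = 7,
                       day_end_hour = 19,
                       season_anchor = "-03-01",
                       base_year = 2009,
                       seed = NULL) {
  rp_category_counts <- rp_category_counts[RP_STATES]
  if (any(is.na(rp_category_counts)) || any(rp_category_counts < 0)) {
    stop("rp_category_counts must be non-negative and named over ",
         paste(RP_STATES, collapse = "/"))
  }
  if (is.null(n_birds_logger)) n_birds_logger <- sum(rp_category_counts)
  if (n_birds_logger != sum(rp_category_counts)) {
    stop("n_birds_logger must equal sum(rp_category_counts)")
  }
  if (n_birds_history_only < 0) stop("n_birds_history_only must be >= 0")
  if (n_occasions < 2) stop("n_occasions must be at least 2")
  stopifnot_prob(prop_female, "prop_female")
  stopifnot_prob(p_detect, "p_detect")
  stopifnot_prob(p_state_unknown, "p_state_unknown")

  phi <- expand_phi(phi)
  psi <- expand_psi(psi)
  C <- length(mixture_weights)
  if (abs(sum(mixture_weights) - 1) > 1e-12 || any(mixture_weights < 0)) {
    stop("mixture_weights must be non-negative and sum to 1")
  }
  if (!is.null(psi_classes)) {
    if (length(psi_classes) != C) stop("psi_classes must have one entry per mixture class")
    psi_classes <- lapply(psi_classes, expand_psi)
  }
  if (!is.null(phi_classes)) {
    if (length(phi_classes) != C) stop("phi_classes must have one entry per mixture class")
    phi_classes <- lapply(phi_classes, expand_phi)
  }
  if (length(p_detect) == 1L) p_detect <- c(F = unname(p_detect), M = unname(p_detect))
  p_detect <- p_detect[SEXES]

  for (g in names(phenology)) {
    ph <- phenology[[g]]
    if (any(ph$sd < 0)) stop("phenology SDs must be >= 0 (group ", g, ")")
  }
  for (g in names(activity)) {
    a <- activity[[g]]
    len <- length(a$breaks)
    if (length(a$fly) != len || length(a$rest) != len || length(a$forage) != len) {
      stop("activity nodes for group ", g, " must share the length of breaks")
    }
    props <- cbind(a$fly, a$rest, a$forage)
    stopifnot_prob(props, paste0("activity proportions (", g, ")"))
    if (any(abs(rowSums(props) - 1) > 1e-8)) {
      stop("activity proportions for group ", g, " must sum to 1 at every node")
    }
    if (is.null(a$noise_sd) || a$noise_sd < 0) {
      stop("activity noise_sd must be >= 0 (group ", g, ")")
    }
  }
  if (1440 %% block_minutes != 0) stop("block_minutes must divide 1440")
  if (!(day_start_hour < day_end_hour)) stop("daytime window is empty")
  if (forage_band[1] < 0 || forage_band[2] > 1 || forage_band[1] > forage_band[2]) {
    stop("forage_band must be an interval inside [0, 1]")
  }

  structure(list(
    n_birds_logger = as.integer(n_birds_logger),
    n_birds_history_only = as.integer(n_birds_history_only),
    n_occasions = as.integer(n_occasions),
    rp_category_counts = rp_category_counts,
    prop_female = prop_female,
    phi = phi, psi = psi, p_detect = p_detect,
    p_state_unknown = p_state_unknown,
    mixture_weights = mixture_weights,
    psi_classes = psi_classes, phi_classes = phi_classes,
    phenology = phenology, activity = activity,
    forage_band = forage_band,
    block_minutes = as.integer(block_minutes),
    day_start_hour = day_start_hour, day_end_hour = day_end_hour,
    season_anchor = season_anchor, base_year = as.integer(base_year),
    seed = seed
  ), class = "sim_config")
}

# phi -> 3x2 matrix (state x sex), validated.
expand_phi <- function(phi) {
  if (is.matrix(phi)) {
    m <- phi
  } else if (length(phi) == 1L) {
    m <- matrix(phi, 3, 2)
  } else if (length(phi) == 3L) {
    phi <- if (is.null(names(phi))) stats::setNames(phi, RP_STATES) else phi[RP_STATES]
    m <- cbind(phi, phi)
  } else {
    stop("phi must be a scalar, per-state vector or 3x2 matrix")
  }
  dimnames(m) <- list(RP_STATES, SEXES)
  stopifnot_prob(m, "phi")
  m
}

# psi -> list(F = 3x3, M = 3x3), rows validated stochastic.
expand_psi <- function(psi) {
  if (is.matrix(psi)) psi <- list(F = psi, M = psi)
  psi <- psi[SEXES]
  for (s in SEXES) {
    m <- psi[[s]]
    if (!is.matrix(m) || !all(dim(m) == c(3, 3))) {
      stop("psi must be (a list per sex of) a 3x3 matrix")
    }
    check_simplex_rows(m, paste0("psi[", s, "]"))
    dimnames(psi[[s]]) <- list(RP_STATES, RP_STATES)
  }
  psi
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic colony configuration\n")
  cat("  logger bird-winters :", x$n_birds_logger,
      sprintf("(%s)", paste(x$rp_category_counts, collapse = "/")), "\n")
  cat("  history-only birds  :", x$n_birds_history_only, "\n")
  cat("  occasions           :", x$n_occasions, "\n")
  cat("  mixture classes     :", length(x$mixture_weights), "\n")
  invisible(x)
}
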