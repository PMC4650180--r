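# Multi-event capture-mark-recapture model: a hidden-Markov likelihood
# over encounter histories.  Latent states are the breeding states
# SUCCESS/FAIL/SKIP plus absorbing DEAD; observable events are the five
# codes of event_codes().  Survival phi may depend on state and sex,
# transitions psi on departure state, sex and year, detection p on sex;
# finite-mixture classes give individual heterogeneity in psi or phi.

#' Specify the structure of a multi-event CMR model
#'
#' Toggles which effects each parameter block carries.  Probabilities
#' are estimated on the logit scale; each transition row on the
#' multinomial-logit scale with SUCCESS as baseline.
#'
#' @param phi_by_state,phi_by_sex Survival effects.
#' @param psi_by_state `TRUE` for state-dependent transitions (rows of
#'   psi differ by departure state); `FALSE` forces all rows equal.
#' @param psi_by_sex,psi_by_year Sex- and occasion-specific transition
#'   effects (year = fixed occasion effects).
#' @param p_by_sex Sex-specific detection.
#' @param n_mixture_classes Number of finite-mixture classes (1 = none).
#' @param mixture_on Which block the classes act on: `"psi"` or `"phi"`.
#' @param p_state_unknown Fixed probability that a detection of an alive
#'   bird carries no state information (`SEEN_UNKNOWN` emission).
#' @return Object of class `mecmr_spec`.
#' @export
mecmr_spec <- function(phi_by_state = FALSE, phi_by_sex = FALSE,
                       psi_by_state = TRUE, psi_by_sex = FALSE,
                       psi_by_year = FALSE, p_by_sex = FALSE,
                       n_mixture_classes = 1,
                       mixture_on = c("psi", "phi"),
                       p_state_unknown = 0) {
  mixture_on <- match.arg(mixture_on)
  stopifnot_prob(p_state_unknown, "p_state_unknown")
  if (n_mixture_classes < 1) stop("n_mixture_classes must be >= 1")
  structure(list(phi_by_state = phi_by_state, phi_by_sex = phi_by_sex,
                 psi_by_state = psi_by_state, psi_by_sex = psi_by_sex,
                 psi_by_year = psi_by_year, p_by_sex = p_by_sex,
                 n_mixture_classes = as.integer(n_mixture_classes),
                 mixture_on = mixture_on,
                 p_state_unknown = p_state_unknown),
            class = "mecmr_spec")
}

#' @export
print.mecmr_spec <- function(x, ...) {
  eff <- function(flag, nm) if (flag) nm else NULL
  cat("MECMR model structure\n")
  cat("  phi:", paste(c("~1", eff(x$phi_by_state, "state"),
                        eff(x$phi_by_sex, "sex")), collapse = " + "), "\n")
  cat("  psi:", paste(c(if (x$psi_by_state) "state" else "~1",
                        eff(x$psi_by_sex, "sex"),
                        eff(x$psi_by_year, "year")), collapse = " + "), "\n")
  cat("  p  :", if (x$p_by_sex) "sex" else "~1", "\n")
  if (x$n_mixture_classes > 1) {
    cat("  mixture:", x$n_mixture_classes, "classes on", x$mixture_on, "\n")
  }
  invisible(x)
}

# Parameter layout: names and block indices for a spec and occasion count.
mecmr_layout <- function(spec, n_occasions) {
  C <- spec$n_mixture_classes
  phi_states <- if (spec$phi_by_state) RP_STATES else "all"
  phi_sexes <- if (spec$phi_by_sex) SEXES else "all"
  phi_classes <- if (spec$mixture_on == "phi") seq_len(C) else 1L
  phi_names <- as.vector(outer(
    as.vector(outer(phi_states, phi_sexes,
                    function(a, b) paste0("phi[", a, ",", b))),
    phi_classes, function(ab, c) paste0(ab, ",c", c, "]")))

  p_names <- if (spec$p_by_sex) paste0("p[", SEXES, "]") else "p"

  psi_rows <- if (spec$psi_by_state) RP_STATES else "all"
  psi_sexes <- if (spec$psi_by_sex) SEXES else "all"
  psi_years <- if (spec$psi_by_year) seq_len(n_occasions - 1L) else 1L
  psi_classes <- if (spec$mixture_on == "psi") seq_len(C) else 1L
  psi_names <- character(0)
  for (c in psi_classes) for (yr in psi_years) for (s in psi_sexes)
    for (r in psi_rows) for (to in c("FAIL", "SKIP")) {
      psi_names <- c(psi_names,
                     paste0("psi[", r, "->", to, ",", s, ",y", yr,
                            ",c", c, "]"))
    }

  pi_names <- if (C > 1) paste0("pi[", 2:C, "]") else character(0)
  names <- c(phi_names, p_names, psi_names, pi_names)
  list(names = names, n = length(names),
       phi = seq_along(phi_names),
       p = length(phi_names) + seq_along(p_names),
       psi = length(phi_names) + length(p_names) + seq_along(psi_names),
       pi = length(phi_names) + length(p_names) + length(psi_names) +
         seq_along(pi_names),
       psi_dims = c(rows = length(psi_rows), sexes = length(psi_sexes),
                    years = length(psi_years), classes = length(psi_classes)))
}

# Link-scale parameter vector -> natural-scale arrays:
#   phi [3 states, 2 sexes, C], p [2 sexes], psi [3, 3, 2, Y, C], pi [C].
mecmr_natural <- function(spec, par, n_occasions) {
  lay <- mecmr_layout(spec, n_occasions)
  stopifnot(length(par) == lay$n)
  C <- spec$n_mixture_classes
  Y <- if (spec$psi_by_year) n_occasions - 1L else 1L

  phi_raw <- stats::plogis(par[lay$phi])
  nst <- if (spec$phi_by_state) 3L else 1L
  nsx <- if (spec$phi_by_sex) 2L else 1L
  ncl <- if (spec$mixture_on == "phi") C else 1L
  phi_small <- array(phi_raw, dim = c(nst, nsx, ncl))
  phi <- array(0, dim = c(3, 2, C),
               dimnames = list(RP_STATES, SEXES, NULL))
  for (c in seq_len(C)) for (s in 1:2) for (st in 1:3) {
    phi[st, s, c] <- phi_small[min(st, nst), min(s, nsx), min(c, ncl)]
  }

  p_raw <- stats::plogis(par[lay$p])
  p <- if (spec$p_by_sex) p_raw else rep(p_raw, 2)
  names(p) <- SEXES

  d <- lay$psi_dims
  eta <- array(par[lay$psi],
               dim = c(2, d["rows"], d["sexes"], d["years"], d["classes"]))
  psi <- array(0, dim = c(3, 3, 2, Y, C),
               dimnames = list(RP_STATES, RP_STATES, SEXES, NULL, NULL))
  for (c in seq_len(C)) for (yr in seq_len(Y)) for (s in 1:2)
    for (r in 1:3) {
      e <- eta[, min(r, d["rows"]), min(s, d["sexes"]),
               min(yr, d["years"]), min(c, d["classes"])]
      num <- c(1, exp(e))
      psi[r, , s, yr, c] <- num / sum(num)
    }

  if (C > 1) {
    z <- c(0, par[lay$pi])
    pi_w <- exp(z - max(z)); pi_w <- pi_w / sum(pi_w)
  } else {
    pi_w <- 1
  }
  list(phi = phi, p = p, psi = psi, pi = pi_w, Y = Y, C = C,
       u = spec$p_state_unknown)
}

# Natural-scale parameter list (as accepted by history_loglik) -> the
# array form used by the forward engine.
natural_arrays <- function(params, n_occasions) {
  C <- length(params$mixture_weights %||% 1)
  phi_list <- params$phi_classes %||% NULL
  psi_list <- params$psi_classes %||% NULL
  phi <- array(0, c(3, 2, C), dimnames = list(RP_STATES, SEXES, NULL))
  psi <- array(0, c(3, 3, 2, 1, C),
               dimnames = list(RP_STATES, RP_STATES, SEXES, NULL, NULL))
  for (c in seq_len(C)) {
    ph <- expand_phi(if (is.null(phi_list)) params$phi else phi_list[[c]])
    ps <- expand_psi(if (is.null(psi_list)) params$psi else psi_list[[c]])
    phi[, , c] <- ph
    psi[, , 1, 1, c] <- ps$F
    psi[, , 2, 1, c] <- ps$M
  }
  p <- params$p
  if (length(p) == 1L) p <- c(F = unname(p), M = unname(p))
  stopifnot_prob(p, "p")
  stopifnot_prob(phi, "phi")
  pi_w <- params$mixture_weights %||% 1
  if (abs(sum(pi_w) - 1) > 1e-12 || any(pi_w < 0)) {
    stop("mixture weights must form a simplex")
  }
  list(phi = phi, p = p[SEXES], psi = psi, pi = pi_w, Y = 1L, C = C,
       u = params$p_state_unknown %||% 0)
}

# 4x4 survival-transition matrix for (sex s, year yr, class c).
transition_matrix <- function(nat, s, yr, c) {
  yr <- min(yr, nat$Y)
  M <- matrix(0, 4, 4)
  for (i in 1:3) {
    M[i, 1:3] <- nat$phi[i, s, c] * nat$psi[i, , s, yr, c]
    M[i, 4] <- 1 - nat$phi[i, s, c]
  }
  M[4, 4] <- 1
  M
}

# 5x4 event-probability matrix (event x state) for sex s.
event_matrix <- function(nat, s) {
  p <- nat$p[s]; u <- nat$u
  D <- matrix(0, 5, 4)
  D[1, ] <- c(rep(1 - p, 3), 1)            # NOT_SEEN; certain if dead
  for (k in 1:3) D[1 + k, k] <- p * (1 - u)
  D[5, 1:3] <- p * u                       # SEEN_UNKNOWN
  D
}

# Scaled forward recursion over all histories at once.  events_int is an
# n x T integer matrix (1..5), sex_int in {1, 2}.  Returns the per-bird
# log-likelihood vector for one mixture class.
forward_class <- function(events_int, sex_int, first_occ, nat, c) {
  n <- nrow(events_int); T <- ncol(events_int)
  logL <- numeric(n)
  A <- matrix(0, n, 4)
  D <- list(event_matrix(nat, 1), event_matrix(nat, 2))
  for (t in seq_len(T)) {
    entering <- which(first_occ == t)
    if (length(entering)) {
      ev <- events_int[entering, t]
      for (i in seq_along(entering)) {
        A[entering[i], ] <- if (ev[i] == 5L) c(1 / 3, 1 / 3, 1 / 3, 0)
        else { v <- numeric(4); v[ev[i] - 1L] <- 1; v }
      }
    }
    if (t > 1L) {
      for (s in 1:2) {
        rows <- which(first_occ < t & sex_int == s)
        if (!length(rows)) next
        M <- transition_matrix(nat, s, t - 1L, c)
        A[rows, ] <- (A[rows, , drop = FALSE] %*% M) *
          D[[s]][events_int[rows, t], , drop = FALSE]
      }
      active <- which(first_occ < t)
      sa <- rowSums(A[active, , drop = FALSE])
      zero <- sa <= 0
      logL[active] <- logL[active] + ifelse(zero, -Inf, log(pmax(sa, 1e-300)))
      sa[zero] <- 1
      A[active, ] <- A[active, , drop = FALSE] / sa
    }
  }
  logL
}

# Total log-likelihood over all histories, mixing classes on the log
# scale: log L_i = logsumexp_c(log pi_c + log L_{i,c}).
mecmr_loglik_engine <- function(events_int, sex_int, first_occ, nat) {
  C <- nat$C
  if (C == 1L) {
    return(forward_class(events_int, sex_int, first_occ, nat, 1L))
  }
  ll <- matrix(vapply(seq_len(C), function(c) {
    forward_class(events_int, sex_int, first_occ, nat, c)
  }, numeric(nrow(events_int))), nrow = nrow(events_int))
  logsumexp_rows(sweep(ll, 2, log(nat$pi), "+"))
}

events_to_int <- function(events) {
  m <- match(events, EVENT_CODES)
  if (any(is.na(m))) stop("unknown event code: ", events[is.na(m)][1L])
  matrix(m, nrow(events), ncol(events))
}

#' Log-likelihood contribution of one encounter history
#'
#' Forward (hidden-Markov) recursion conditional on the first encounter:
#' the release event fixes the initial state (uniform over alive states
#' for a state-unknown release); at each later occasion the state
#' distribution is propagated through survival and transition and then
#' weighted by the event probability (`NOT_SEEN` contributes `1 - p` for
#' alive states and 1 for DEAD).  Mixture classes are combined as
#' `sum_c pi_c L_c` before taking the log.
#'
#' @param events Character vector of event codes, one per occasion.
#' @param params Natural-scale parameter list: `phi`, `psi`, `p`, and
#'   optionally `mixture_weights`, `psi_classes`, `phi_classes`,
#'   `p_state_unknown` (formats as in [sim_config()]).
#' @param sex `"F"` or `"M"`.
#' @param first_occasion Occasion of first encounter (default 1).
#' @return The log-likelihood (`-Inf` for an impossible history).
#' @export
history_loglik <- function(events, params, sex = "F", first_occasion = 1) {
  if (events[first_occasion] == "NOT_SEEN") {
    stop("history must start with an observed event at first_occasion")
  }
  nat <- natural_arrays(params, n_occasions = length(events))
  ev <- events_to_int(matrix(events, nrow = 1))
  mecmr_loglik_engine(ev, match(sex, SEXES), as.integer(first_occasion),
                      nat)[1L]
}

#' Fit a multi-event CMR model by maximum likelihood
#'
#' Maximises the joint forward log-likelihood on the link scale with
#' BFGS from `n_starts` jittered initialisations, keeping the best.
#' Standard errors come from the numerically differentiated Hessian at
#' the optimum; a non-positive-definite Hessian leaves them `NA` with a
#' flag.  Link-scale estimates beyond +-9 are flagged as boundary
#' estimates (the natural-scale MLE sits at 0 or 1).
#'
#' @param histories An `encounter_histories` object.
#' @param spec An [mecmr_spec()].
#' @param n_starts Number of optimisation starts (default 10).
#' @param seed Optional RNG seed for the start jitter.
#' @return Object of class `mecmr_fit`: `spec`, `par` (link scale,
#'   named), `natural` (phi/p/psi/pi arrays), `loglik`, `n_params`,
#'   `aic`, `se`, `vcov`, `converged`, `boundary`, `n_starts`,
#'   `data_info`.
#' @export
fit_mecmr <- function(histories, spec = mecmr_spec(), n_starts = 10,
                      seed = NULL) {
  stopifnot(inherits(histories, "encounter_histories"))
  if (!is.null(seed)) set.seed(seed)
  ev <- events_to_int(histories$events)
  sx <- match(histories$sex, SEXES)
  fo <- histories$first_occasion
  T <- ncol(ev)
  lay <- mecmr_layout(spec, T)
  df_data <- sum(ev != 1L) - nrow(ev)       # post-release observations
  if (lay$n >= df_data) {
    warning("parameter count (", lay$n, ") >= data degrees of freedom (",
            df_data, "); the model may not be identifiable")
  }

  negll <- function(par) {
    nat <- mecmr_natural(spec, par, T)
    v <- -sum(mecmr_loglik_engine(ev, sx, fo, nat))
    if (!is.finite(v)) 1e10 else v
  }

  base <- numeric(lay$n)
  base[lay$phi] <- stats::qlogis(0.85)
  base[lay$p] <- stats::qlogis(0.8)
  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    start <- if (s == 1) base else base + stats::rnorm(lay$n, 0, 0.5)
    opt <- tryCatch(
      stats::optim(start, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("no start reached a finite likelihood after ", n_starts, " starts")
  }

  par <- best$par
  names(par) <- lay$names
  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  se <- rep(NA_real_, lay$n)
  vcov <- NULL
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      vcov <- vc
      se <- sqrt(diag(vc))
    }
  }
  names(se) <- lay$names
  ll <- -best$value
  fit <- structure(list(
    spec = spec, par = par, natural = mecmr_natural(spec, par, T),
    loglik = ll, n_params = lay$n, aic = 2 * lay$n - 2 * ll,
    se = se, vcov = vcov, converged = best$convergence == 0,
    boundary = abs(par) > 9, n_starts = n_starts,
    n_occasions = T,
    data_info = list(n = nrow(ev), T = T,
                     event_counts = tabulate(ev, 5L))
  ), class = "mecmr_fit")
  fit
}

#' @export
print.mecmr_fit <- function(x, ...) {
  cat("MECMR fit: logLik =", format(x$loglik, digits = 8),
      " AIC =", format(x$aic, digits = 8),
      " (", x$n_params, "parameters )\n")
  est <- cbind(estimate = x$par, se = x$se)
  print(round(est, 4))
  if (any(x$boundary)) {
    cat("boundary estimate(s):",
        paste(names(x$par)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' AIC comparison table across fitted models
#'
#' @param fits Named list of `mecmr_fit` objects on identical data.
#' @return data.frame sorted by AIC with `delta_aic` relative to the
#'   best model and a `nested_in_best` flag (parameter-name subset
#'   heuristic).
#' @export
model_table <- function(fits) {
  if (inherits(fits, "mecmr_fit")) fits <- list(fit = fits)
  infos <- lapply(fits, function(f) f$data_info)
  if (length(unique(vapply(infos, function(i)
    paste(i$n, i$T, paste(i$event_counts, collapse = ","), collapse = "|"),
    character(1)))) != 1L) {
    stop("all fits must be on identical data")
  }
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  tab <- data.frame(
    model = nm,
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  best_names <- names(fits[[match(tab$model[1], nm)]]$par)
  tab$nested_in_best <- vapply(tab$model, function(m) {
    all(names(fits[[match(m, nm)]]$par) %in% best_names)
  }, logical(1))
  rownames(tab) <- NULL
  tab
}

#' Long-run probability of breeding success per current state
#'
#' In `next_year` mode, the probability of being a successful breeder
#' next season given the current state: the SUCCESS column of psi.  In
#' `stationary` mode, the equilibrium frequency of SUCCESS under the
#' transition matrix conditioned on survival (the left eigenvector of
#' psi for eigenvalue 1), identical from every starting state.
#' Confidence intervals are percentile intervals from a parametric
#' bootstrap of the MLE sampling distribution (multivariate normal on
#' the link scale).
#'
#' @param fit A converged `mecmr_fit` with an available `vcov`.
#' @param mode `"next_year"` (default) or `"stationary"`.
#' @param n_boot Bootstrap draws for the intervals (default 1000).
#' @param seed Optional RNG seed.
#' @param sex,year,class Which transition matrix to use when the fit has
#'   sex, year or mixture structure.
#' @param level Confidence level (default 0.95).
#' @return data.frame with `state`, `estimate`, `lower`, `upper`.
#' @export
longrun_success <- function(fit, mode = c("next_year", "stationary"),
                            n_boot = 1000, seed = NULL, sex = "F",
                            year = 1, class = 1, level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "mecmr_fit"))
  if (!is.null(seed)) set.seed(seed)
  s <- match(sex, SEXES)

  quantity <- function(nat) {
    psi <- nat$psi[, , s, min(year, nat$Y), min(class, nat$C)]
    if (mode == "next_year") {
      psi[, "SUCCESS"]
    } else {
      rep(stationary_distribution(psi)[["SUCCESS"]], 3)
    }
  }

  est <- quantity(fit$natural)
  lower <- upper <- rep(NA_real_, 3)
  if (!is.null(fit$vcov) && n_boot > 0) {
    draws <- MASS::mvrnorm(n_boot, fit$par, fit$vcov)
    qs <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      nat_b <- mecmr_natural(fit$spec, draws[b, ], fit$n_occasions)
      qs[b, ] <- tryCatch(quantity(nat_b), error = function(e) rep(NA, 3))
    }
    a <- (1 - level) / 2
    lower <- apply(qs, 2, stats::quantile, probs = a, na.rm = TRUE)
    upper <- apply(qs, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  } else if (n_boot > 0) {
    warning("no variance-covariance matrix available; intervals are NA")
  }
  data.frame(state = RP_STATES, estimate = unname(est),
             lower = unname(lower), upper = unname(upper))
}

#' Stationary distribution of a breeding-state transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1,
#' normalised to sum to 1.  Errors if the chain is reducible or
#' periodic (no unique positive stationary distribution).
#'
#' @param psi 3x3 row-stochastic matrix.
#' @return Named probability vector over `rp_states()`.
#' @export
stationary_distribution <- function(psi) {
  check_simplex_rows(psi, "psi")
  reach <- psi + diag(3) * 0
  acc <- psi
  for (k in 1:3) acc <- acc + acc %*% psi
  if (any(acc <= 1e-14)) {
    stop("psi is reducible: some state cannot reach another")
  }
  e <- eigen(t(psi))
  vals <- e$values
  one <- which(abs(vals - 1) < 1e-8)
  if (!length(one)) stop("psi has no unit eigenvalue")
  if (sum(abs(Mod(vals) - 1) < 1e-8) > 1L) {
    stop("psi is periodic: the unit-modulus eigenvalue is not unique")
  }
  v <- Re(e$vectors[, one[1]])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("psi admits no positive stationary vector")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), RP_STATES)
}

#' Empirical year-to-year transition frequencies
#'
#' Counts consecutive observed state pairs (adjacent occasions only) and
#' normalises rows.  Pairs of observations separated by a NOT_SEEN or
#' state-unknown gap are excluded and reported separately.
#'
#' @param histories An `encounter_histories` object.
#' @return List with `matrix` (row-normalised 3x3), `counts` (raw 3x3)
#'   and `n_gap_pairs` (observed pairs spanning a gap, excluded).
#' @export
empirical_transition_matrix <- function(histories) {
  stopifnot(inherits(histories, "encounter_histories"))
  ev <- histories$events
  state <- matrix(match(ev, EVENT_CODES[2:4]), nrow(ev), ncol(ev))
  counts <- matrix(0L, 3, 3, dimnames = list(RP_STATES, RP_STATES))
  gaps <- 0L
  for (i in seq_len(nrow(state))) {
    obs <- which(!is.na(state[i, ]))
    if (length(obs) < 2) next
    for (j in seq_len(length(obs) - 1L)) {
      a <- obs[j]; b <- obs[j + 1L]
      if (b == a + 1L) {
        counts[state[i, a], state[i, b]] <- counts[state[i, a], state[i, b]] + 1L
      } else {
        gaps <- gaps + 1L
      }
    }
  }
  if (sum(counts) == 0L) stop("no usable consecutive observed-state pairs")
  P <- counts / pmax(rowSums(counts), 1L)
  list(matrix = P, counts = counts, n_gap_pairs = gaps)
}
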