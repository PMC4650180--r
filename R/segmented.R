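# Segmented (piecewise linear) regression of daily flight proportion
# against winter day: iterative linearization for the breakpoint
# positions, with bootstrap restarting to escape local optima, and
# information-criterion selection of the number of breakpoints.

# Design matrix of a broken-line model with hinge terms (x - tau)_+.
hinge_design <- function(x, tau) {
  X <- cbind(1, x)
  for (t in tau) X <- cbind(X, pmax(x - t, 0))
  X
}

# RSS of the broken-line model at fixed breakpoints (fast path).
segmented_rss <- function(x, y, tau) {
  fit <- stats::lm.fit(hinge_design(x, tau), y)
  sum(fit$residuals^2)
}

# Coordinate-wise polish of a breakpoint vector: each tau_j is refined
# by golden-section search over the interval bounded by its neighbours.
# The linearized update converges to a fixed point of the working model,
# which can sit a fraction of a grid step away from the RSS minimum.
polish_breakpoints <- function(x, y, tau, lo, hi, sweeps = 2L) {
  k <- length(tau)
  for (s in seq_len(sweeps)) {
    for (j in seq_len(k)) {
      bounds <- c(if (j == 1) lo else tau[j - 1] + 1e-8,
                  if (j == k) hi else tau[j + 1] - 1e-8)
      opt <- stats::optimize(function(t) {
        segmented_rss(x, y, sort(replace(tau, j, t)))
      }, interval = bounds, tol = 1e-7)
      if (opt$objective < segmented_rss(x, y, tau)) {
        tau[j] <- opt$minimum
      }
    }
  }
  sort(tau)
}

# One run of the iterative-linearization algorithm from a given
# breakpoint initialisation.  The working model augments the hinge terms
# with step indicators -1(x > tau); each breakpoint is updated by the
# ratio of its indicator coefficient to its hinge coefficient.
iterate_breakpoints <- function(x, y, tau, lo, hi, tol = 1e-6,
                                max_iter = 50L) {
  k <- length(tau)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    X <- cbind(1, x)
    for (t in tau) X <- cbind(X, pmax(x - t, 0))
    for (t in tau) X <- cbind(X, -as.numeric(x > t))
    fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit)) break
    beta <- fit$coefficients[2L + seq_len(k)]
    gamma <- fit$coefficients[2L + k + seq_len(k)]
    step <- gamma / beta
    step[!is.finite(step)] <- 0
    new_tau <- sort(pmin(pmax(tau + step, lo), hi))
    # keep breakpoints distinct: a merged pair would drop the model rank
    if (any(diff(new_tau) < (hi - lo) * 1e-9)) {
      new_tau <- new_tau + seq_len(k) * (hi - lo) * 1e-6
      new_tau <- pmin(pmax(new_tau, lo), hi)
    }
    delta <- max(abs(new_tau - tau))
    tau <- new_tau
    if (delta < tol) { converged <- TRUE; break }
  }
  list(tau = tau, converged = converged)
}

#' Fit a piecewise linear (segmented) regression
#'
#' Estimates `n_breakpoints` breakpoint positions by iterative
#' linearization, restarted from nonparametric-bootstrap refits: each
#' restart re-estimates the breakpoints on a case-resampled copy of the
#' data and uses the result to re-initialise the fit on the original
#' data; the best-RSS solution is kept.  Breakpoints are constrained to
#' the interior of the observed range (between the 3rd and the (n-2)th
#' order statistic).
#'
#' @param x Sorted, distinct predictor values (winter day).
#' @param y Response (daily flight proportion).
#' @param n_breakpoints Number of breakpoints to fit (0 = straight line).
#' @param n_restarts Bootstrap restarts (default 10).
#' @param seed Optional RNG seed.
#' @return An object of class `breakpoint_fit`: `n_breakpoints`, `tau`
#'   (positions), `tau_se` (delta-method standard errors), `coefs`
#'   (intercept, first slope and slope changes), `segment_slopes`, `rss`,
#'   `converged`, `n_restarts_used`, `selection_scores` (filled by
#'   [select_n_breakpoints()]).
#' @export
fit_segmented <- function(x, y, n_breakpoints = 1, n_restarts = 10,
                          seed = NULL) {
  n <- length(x)
  k <- as.integer(n_breakpoints)
  if (length(y) != n) stop("x and y lengths differ")
  if (is.unsorted(x, strictly = TRUE)) stop("x must be sorted and distinct")
  if (n < 2 * (k + 2)) stop("too few points for ", k, " breakpoint(s)")
  if (stats::var(y) == 0) stop("degenerate fit: y is constant")
  if (!is.null(seed)) set.seed(seed)

  if (k == 0L) {
    fit <- stats::lm.fit(cbind(1, x), y)
    rss <- sum(fit$residuals^2)
    return(new_breakpoint_fit(0L, numeric(0), numeric(0),
                              fit$coefficients, rss, TRUE, 0L, x, y))
  }

  lo <- x[3L]
  hi <- x[n - 2L]
  # several deterministic quantile-spread initialisations guard against
  # convergence to a secondary basin before the bootstrap restarts run
  interior <- x[x >= lo & x <= hi]
  qgrid <- stats::quantile(interior, probs = seq(0.1, 0.9, by = 0.2))
  inits <- list(as.numeric(stats::quantile(interior,
                                           probs = seq_len(k) / (k + 1))))
  if (k <= 2 && length(qgrid) >= k) {
    cmb <- utils::combn(as.numeric(qgrid), k)
    for (j in seq_len(ncol(cmb))) inits[[length(inits) + 1L]] <- cmb[, j]
  }
  best <- NULL
  best_rss <- Inf
  for (init in inits) {
    cand <- iterate_breakpoints(x, y, sort(init), lo, hi)
    cand$tau <- polish_breakpoints(x, y, cand$tau, lo, hi)
    rss <- segmented_rss(x, y, cand$tau)
    if (rss < best_rss) { best <- cand; best_rss <- rss }
  }

  used <- 0L
  if (n_restarts > 0) {
    for (r in seq_len(n_restarts)) {
      idx <- sort(sample.int(n, n, replace = TRUE))
      xb <- x[idx]; yb <- y[idx]
      ub <- !duplicated(xb)
      if (sum(ub) < 2 * (k + 2)) next
      boot <- tryCatch(
        iterate_breakpoints(xb[ub], yb[ub], best$tau, lo, hi),
        error = function(e) NULL)
      if (is.null(boot)) next
      cand <- iterate_breakpoints(x, y, boot$tau, lo, hi)
      cand$tau <- polish_breakpoints(x, y, cand$tau, lo, hi, sweeps = 1L)
      cand_rss <- segmented_rss(x, y, cand$tau)
      used <- used + 1L
      if (cand_rss < best_rss - 1e-12) {
        best <- cand
        best_rss <- cand_rss
      }
    }
  }

  finalize_breakpoint_fit(x, y, best$tau, best$converged, used)
}

# Refit at the final breakpoints with lm() for coefficients and
# delta-method breakpoint standard errors.
finalize_breakpoint_fit <- function(x, y, tau, converged, used) {
  k <- length(tau)
  df <- data.frame(y = y, x = x)
  X <- hinge_design(x, tau)[, -1, drop = FALSE]
  colnames(X) <- c("x", if (k) paste0("h", seq_len(k)))
  fit <- stats::lm(y ~ ., data = cbind(df["y"], as.data.frame(X)))
  rss <- sum(stats::residuals(fit)^2)

  # se(tau_j) ~ se(gamma_j)/|beta_j| from the working (hinge + step) model
  tau_se <- rep(NA_real_, k)
  W <- cbind(X, vapply(tau, function(t) -as.numeric(x > t), numeric(length(x))))
  colnames(W) <- c(colnames(X), if (k) paste0("v", seq_len(k)))
  wfit <- tryCatch(
    stats::lm(y ~ ., data = cbind(df["y"], as.data.frame(W))),
    error = function(e) NULL)
  if (!is.null(wfit)) {
    sm <- tryCatch(suppressWarnings(summary(wfit)$coefficients),
                   error = function(e) NULL)
    if (!is.null(sm)) {
      for (j in seq_len(k)) {
        b <- stats::coef(fit)[[paste0("h", j)]]
        vrow <- paste0("v", j)
        if (vrow %in% rownames(sm) && is.finite(b) && abs(b) > 0) {
          tau_se[j] <- sm[vrow, "Std. Error"] / abs(b)
        }
      }
    }
  }
  new_breakpoint_fit(k, tau, tau_se, stats::coef(fit), rss, converged,
                     used, x, y)
}

new_breakpoint_fit <- function(k, tau, tau_se, coefs, rss, converged,
                               n_restarts_used, x, y) {
  slopes <- cumsum(coefs[-1])   # first slope then slope per segment
  structure(list(
    n_breakpoints = k, tau = unname(tau), tau_se = unname(tau_se),
    coefs = coefs, segment_slopes = unname(slopes),
    rss = max(rss, 0), converged = converged,
    n_restarts_used = n_restarts_used,
    selection_scores = NULL, n = length(x),
    x_range = range(x)
  ), class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Segmented fit:", x$n_breakpoints, "breakpoint(s)")
  if (x$n_breakpoints > 0) {
    cat(" at", paste(signif(x$tau, 5), collapse = ", "))
  }
  cat("\n  RSS =", signif(x$rss, 6),
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' Select the number of breakpoints by information criterion
#'
#' Fits 0..`max_k` breakpoints and returns the fit minimising BIC (or
#' AIC), with the criterion values recorded in `selection_scores`.  A fit
#' with k+1 breakpoints is additionally warm-started from the best
#' k-breakpoint solution so the residual sum of squares is
#' non-increasing in k.  Ties are broken towards fewer breakpoints.
#'
#' @param x,y As in [fit_segmented()].
#' @param max_k Largest breakpoint count to consider.
#' @param criterion `"BIC"` (default) or `"AIC"`; the Gaussian criterion
#'   uses 2 + 2k regression parameters plus the error variance.
#' @param n_restarts,seed Passed to [fit_segmented()].
#' @return The selected `breakpoint_fit`.
#' @export
select_n_breakpoints <- function(x, y, max_k = 2, criterion = c("BIC", "AIC"),
                                 n_restarts = 10, seed = NULL) {
  criterion <- match.arg(criterion)
  if (max_k < 0) stop("max_k must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  fits <- vector("list", max_k + 1L)
  for (k in 0:max_k) {
    if (n < 2 * (k + 2)) break
    f <- fit_segmented(x, y, n_breakpoints = k, n_restarts = n_restarts)
    if (k > 0 && !is.null(fits[[k]]) && fits[[k]]$rss < f$rss) {
      # warm start: previous breakpoints plus one in the widest gap;
      # the extra regressor can only reduce the RSS
      prev <- fits[[k]]$tau
      lo <- x[3L]; hi <- x[n - 2L]
      gaps <- diff(c(lo, sort(prev), hi))
      g <- which.max(gaps)
      extra <- (c(lo, sort(prev), hi)[g] + c(lo, sort(prev), hi)[g + 1]) / 2
      warm <- iterate_breakpoints(x, y, sort(c(prev, extra)), lo, hi)
      warm$tau <- polish_breakpoints(x, y, warm$tau, lo, hi, sweeps = 1L)
      cand <- list(warm$tau, sort(c(prev, extra)))
      for (tau_c in cand) {
        if (segmented_rss(x, y, tau_c) < f$rss) {
          f <- finalize_breakpoint_fit(x, y, tau_c, TRUE, f$n_restarts_used)
        }
      }
    }
    fits[[k + 1L]] <- f
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  npar <- vapply(fits, function(f) 2 + 2 * f$n_breakpoints + 1, numeric(1))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  # floor an (effectively) perfect fit so noiseless data cannot reward
  # extra breakpoints through rounding noise in a zero RSS
  rss <- pmax(rss, 1e-12 * sum((y - mean(y))^2))
  ll <- -n / 2 * (log(2 * pi) + log(pmax(rss, 1e-300) / n) + 1)
  score <- if (criterion == "BIC") -2 * ll + npar * log(n) else
    -2 * ll + 2 * npar
  best <- which(score <= min(score) + 1e-9)[1L]   # ties -> smaller k
  out <- fits[[best]]
  out$selection_scores <- stats::setNames(score,
                                          paste0("k", seq_along(score) - 1L))
  out$criterion <- criterion
  out
}
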