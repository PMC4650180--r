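# Shared fixtures, built in code.

# A small colony configuration that keeps simulation cheap.
tiny_sim_config <- function(seed = 101, ...) {
  sim_config(rp_category_counts = c(SUCCESS = 4, FAIL = 3, SKIP = 2),
             n_birds_history_only = 5, n_occasions = 4, seed = seed, ...)
}

# Linearly separable three-class records: one informative feature.
separable_records <- function(n_per_class = 8, noise_features = 2,
                              seed = 1) {
  set.seed(seed)
  lab <- rep(rp_states(), each = n_per_class)
  f1 <- rep(c(0, 10, 20), each = n_per_class) +
    stats::runif(length(lab), -1, 1)
  out <- data.frame(prior_lay_date = f1, label = lab,
                    sex = rep_len(c("F", "M"), length(lab)))
  for (j in seq_len(noise_features)) {
    out[[paste0("noise", j)]] <- stats::rnorm(length(lab))
  }
  out
}

# Pure-noise records: labels carry no feature information.
noise_records <- function(n_per_class = 200, n_features = 4, seed = 1) {
  set.seed(seed)
  lab <- rep(rp_states(), each = n_per_class)
  out <- data.frame(label = lab, sex = rep_len(c("F", "M"), length(lab)))
  for (j in seq_len(n_features)) {
    out[[paste0("f", j)]] <- stats::rnorm(length(lab))
  }
  out
}

# Random row-stochastic 3x3 transition matrix.
random_psi <- function() {
  m <- matrix(stats::rexp(9) + 0.05, 3)
  m / rowSums(m)
}

# Piecewise-linear response with given slopes joined at breakpoints.
piecewise_y <- function(x, intercept, slopes, taus) {
  y <- intercept + slopes[1] * x
  for (j in seq_along(taus)) {
    y <- y + (slopes[j + 1] - slopes[j]) * pmax(x - taus[j], 0)
  }
  y
}

# Exhaustive grid search for segmented regression: breakpoints restricted
# to observed interior x values; independent of the iterative estimator.
grid_search_breaks <- function(x, y, k) {
  n <- length(x)
  cand <- x[3:(n - 2)]
  best <- list(rss = Inf, tau = NULL)
  eval_rss <- function(tau) {
    X <- cbind(1, x)
    for (t in tau) X <- cbind(X, pmax(x - t, 0))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  if (k == 1) {
    for (t in cand) {
      r <- eval_rss(t)
      if (r < best$rss) best <- list(rss = r, tau = t)
    }
  } else if (k == 2) {
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (cand[j] <= cand[i]) next
        r <- eval_rss(c(cand[i], cand[j]))
        if (r < best$rss) best <- list(rss = r, tau = c(cand[i], cand[j]))
      }
    }
  }
  best
}

# Recover per-k RSS differences from a selection fit's criterion scores
# (inverts the Gaussian profile-likelihood form of the criterion).
diff_rss_from_scores <- function(f, x, y) {
  n <- length(x)
  sc <- f$selection_scores
  npar <- 2 + 2 * (seq_along(sc) - 1) + 1
  pen <- if (identical(f$criterion, "AIC")) 2 * npar else npar * log(n)
  m2ll <- sc - pen
  rss <- n * exp((m2ll / n) - log(2 * pi) - 1)
  diff(rss)
}

# Brute-force multi-event likelihood: sum over all latent state paths.
# Kept independent of the package's forward recursion.
enumerate_history_lik <- function(events, phi, p, psi, u = 0,
                                  mixture_weights = 1, psi_classes = NULL) {
  states <- 1:4   # SUCCESS FAIL SKIP DEAD
  T <- length(events)
  ev <- match(events, event_codes())
  lik_class <- function(psi_c) {
    init <- if (ev[1] == 5L) c(1, 1, 1, 0) / 3 else {
      v <- numeric(4); v[ev[1] - 1L] <- 1; v
    }
    trans <- function(a, b) {
      if (a == 4) return(as.numeric(b == 4))
      if (b == 4) return(1 - phi)
      phi * psi_c[a, b]
    }
    emit <- function(s, e) {
      if (s == 4) return(as.numeric(e == 1L))
      if (e == 1L) return(1 - p)
      if (e == 5L) return(p * u)
      as.numeric(e - 1L == s) * p * (1 - u)
    }
    total <- 0
    paths <- as.matrix(expand.grid(rep(list(states), T)))
    for (r in seq_len(nrow(paths))) {
      pth <- paths[r, ]
      pr <- init[pth[1]]
      if (pr == 0) next
      for (t in 2:T) {
        pr <- pr * trans(pth[t - 1], pth[t])
        if (pr == 0) break
        pr <- pr * emit(pth[t], ev[t])
        if (pr == 0) break
      }
      total <- total + pr
    }
    total
  }
  if (is.null(psi_classes)) psi_classes <- list(psi)
  sum(mixture_weights * vapply(psi_classes, lik_class, numeric(1)))
}

# Exact two-sample KS p-value by full enumeration of group assignments.
enumerate_ks_pvalue <- function(a, b) {
  n <- length(a); m <- length(b)
  comb <- utils::combn(n + m, n)
  vals <- c(a, b)
  ord <- order(vals)
  D_of <- function(idx) {
    z <- rep(0, n + m)
    z[idx] <- 1
    z <- z[ord]
    max(abs(cumsum(z) / n - cumsum(1 - z) / m))
  }
  D_obs <- D_of(seq_len(n))
  count <- 0L
  for (j in seq_len(ncol(comb))) {
    if (D_of(comb[, j]) >= D_obs - 1e-12) count <- count + 1L
  }
  count / ncol(comb)
}
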