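# Winter activity trends: additive time-series decomposition of daily
# budgets, group-averaged trends by reproductive performance, ECDF
# summaries and Bonferroni-corrected Kolmogorov-Smirnov contrasts.

#' Additive decomposition of a daily series
#'
#' `observed = trend + seasonal + remainder`.  The trend is a centred
#' moving average of window `period` (for even periods, the standard
#' 2xMA); at the edges, where the moving average is undefined, the
#' nearest defined trend value is carried outward (flagged in `edge`).
#' The seasonal component is the period-position mean of the detrended
#' series, centred to zero mean; the remainder is the residual, so the
#' reconstruction identity holds exactly at every point.  `period = 0`
#' requests a trend-only decomposition (zero seasonal term, window 7).
#'
#' @param values Numeric series at daily resolution.
#' @param period Observations per seasonal cycle (default 7).
#' @return Object of class `additive_decomposition`: `observed`,
#'   `trend`, `seasonal`, `remainder`, `period`, `edge` (logical flags).
#' @export
decompose_additive <- function(values, period = 7) {
  n <- length(values)
  window <- if (period == 0) 7L else as.integer(period)
  if (period != 0 && period < 2) stop("period must be >= 2 (or 0)")
  if (n < 2 * window) stop("series too short for the decomposition window")

  if (window %% 2 == 1) {
    w <- rep(1 / window, window)
  } else {
    w <- c(0.5, rep(1, window - 1), 0.5) / window
  }
  trend <- as.numeric(stats::filter(values, w, sides = 2))
  edge <- is.na(trend)
  if (all(edge)) stop("series too short for the decomposition window")
  # carry the nearest defined trend value outward at the edges
  defined <- which(!edge)
  trend[seq_len(defined[1] - 1)] <- trend[defined[1]]
  last <- defined[length(defined)]
  if (last < n) trend[(last + 1):n] <- trend[last]

  if (period == 0) {
    seasonal <- rep(0, n)
  } else {
    # period-position means of the detrended series, using only points
    # with a genuine (non-extrapolated) trend so the edge carry-over
    # cannot leak into the seasonal component
    detrended <- values - trend
    pos <- ((seq_len(n) - 1L) %% period) + 1L
    means <- rep(0, period)
    got <- tapply(detrended[!edge], pos[!edge], mean)
    means[as.integer(names(got))] <- got
    means <- means - mean(means)
    seasonal <- means[pos]
  }
  remainder <- values - trend - seasonal
  structure(list(observed = values, trend = trend, seasonal = seasonal,
                 remainder = remainder, period = period, edge = edge),
            class = "additive_decomposition")
}

#' @export
print.additive_decomposition <- function(x, ...) {
  cat("Additive decomposition: n =", length(x$observed),
      "period =", x$period, "\n")
  invisible(x)
}

# Per-bird trend components of one activity column, aligned on days
# since each bird's first profile day (= colony departure for logger
# series that start at departure).
bird_trends <- function(profiles, activity = c("FLY", "REST", "FORAGE"),
                        period = 7) {
  activity <- match.arg(activity)
  col <- switch(activity, FLY = "p_fly", REST = "p_rest",
                FORAGE = "p_forage")
  out <- list()
  for (b in unique(profiles$bird_id)) {
    rows <- profiles[profiles$bird_id == b, ]
    rows <- rows[order(rows$date), ]
    if (nrow(rows) < 2 * max(period, 7)) next
    dec <- decompose_additive(rows[[col]], period = period)
    out[[b]] <- dec$trend
  }
  out
}

#' Group-mean activity trend over aligned winter days
#'
#' Decomposes each bird's daily series for one activity, aligns winters
#' on days since colony departure (day of the bird's first profile),
#' truncates to the span common to all usable birds, and averages the
#' trend components pointwise within each RP group.
#'
#' @param profiles Daily profiles from [daily_profiles()].
#' @param labels Named character vector mapping `bird_id` to RP group.
#' @param activity One of `"FLY"`, `"REST"`, `"FORAGE"`.
#' @param period Seasonal period for the decomposition.
#' @return List with `mean_trend` (data.frame: group, day, mean, n) and
#'   `bird_trends` (per-bird trend vectors over the common span, by
#'   group).
#' @export
group_mean_trend <- function(profiles, labels,
                             activity = c("FLY", "REST", "FORAGE"),
                             period = 7) {
  activity <- match.arg(activity)
  tr <- bird_trends(profiles, activity, period)
  if (!length(tr)) stop("no bird has a long enough series")
  grp <- labels[names(tr)]
  keep <- !is.na(grp)
  tr <- tr[keep]; grp <- grp[keep]
  span <- min(lengths(tr))
  tr <- lapply(tr, function(v) v[seq_len(span)])

  groups <- unique(grp)
  rows <- list()
  by_group <- list()
  for (g in groups) {
    members <- tr[grp == g]
    if (!length(members)) {
      warning("group ", g, " has no usable bird; omitted")
      next
    }
    m <- do.call(rbind, members)
    rows[[g]] <- data.frame(group = g, day = seq_len(span) - 1L,
                            mean = colMeans(m), n = nrow(m))
    by_group[[g]] <- members
  }
  list(mean_trend = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       bird_trends = by_group, span = span)
}

#' Empirical cumulative distribution per group
#'
#' @param values_by_group Named list of numeric vectors.
#' @return Named list of right-continuous step functions (class `ecdf`).
#' @export
ecdf_by_group <- function(values_by_group) {
  if (!length(values_by_group)) stop("no groups supplied")
  lapply(values_by_group, function(v) {
    if (!length(v)) stop("empty group sample")
    stats::ecdf(v)
  })
}

#' Pairwise Kolmogorov-Smirnov contrasts with Bonferroni correction
#'
#' Runs a two-sample KS test for every unordered pair of groups within
#' every activity, and declares significance against
#' `alpha / (n_pairs * n_activities)` (Bonferroni across the whole
#' family) when `correct = TRUE`, or against raw `alpha` otherwise (the
#' convention used for the sex contrasts).  Identical constant samples
#' are reported as D = 0, p = 1.
#'
#' @param values Named list: activity -> named list of group samples.
#'   A plain named list of samples is treated as one unnamed activity.
#' @param alpha Family significance level (default 0.01).
#' @param correct Apply the Bonferroni correction (default TRUE).
#' @param exact Passed to [stats::ks.test()] (`NULL` = automatic).
#' @return data.frame with `activity`, `group1`, `group2`,
#'   `ks_statistic`, `p_value`, `bonferroni_alpha`, `significant`.
#' @export
compare_groups <- function(values, alpha = 0.01, correct = TRUE,
                           exact = NULL) {
  if (!is.list(values[[1]])) values <- list(all = values)
  n_act <- length(values)
  groups <- names(values[[1]])
  if (length(groups) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(groups, 2)
  m <- if (correct) ncol(pairs) * n_act else 1L
  thr <- alpha / m

  rows <- list()
  for (a in names(values)) {
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      v1 <- values[[a]][[g1]]; v2 <- values[[a]][[g2]]
      if (length(v1) < 2 || length(v2) < 2) {
        stop("each group needs at least 2 values (", g1, " vs ", g2, ")")
      }
      if (stats::var(v1) == 0 && stats::var(v2) == 0 &&
          v1[1] == v2[1]) {
        D <- 0; p <- 1
      } else {
        kt <- suppressWarnings(stats::ks.test(v1, v2, exact = exact))
        D <- unname(kt$statistic); p <- kt$p.value
        if (is.na(p)) {
          # extreme scaled statistics can overflow the asymptotic code;
          # fall back to the Kolmogorov series directly
          lam <- sqrt(length(v1) * length(v2) /
                        (length(v1) + length(v2))) * D
          ks <- seq_len(50)
          p <- min(1, max(0, 2 * sum((-1)^(ks - 1) * exp(-2 * ks^2 * lam^2))))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        activity = a, group1 = g1, group2 = g2,
        ks_statistic = D, p_value = p, bonferroni_alpha = thr,
        significant = p < thr)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Plot group ECDFs for one activity
#'
#' Base-graphics rendering of the per-group empirical cumulative
#' distributions of winter trend values.
#'
#' @param values_by_group Named list of numeric vectors.
#' @param main Plot title.
#' @param xlab X-axis label.
#' @param col Colours per group.
#' @export
plot_group_ecdf <- function(values_by_group, main = "", xlab = "trend value",
                            col = c("blue", "red", "black")) {
  fs <- ecdf_by_group(values_by_group)
  xs <- range(unlist(values_by_group))
  graphics::plot(NULL, xlim = xs, ylim = c(0, 1), main = main,
                 xlab = xlab, ylab = "F(x)")
  for (i in seq_along(fs)) {
    graphics::plot(fs[[i]], add = TRUE, col = col[(i - 1) %% length(col) + 1],
                   do.points = FALSE, verticals = TRUE)
  }
  graphics::legend("bottomright", legend = names(fs),
                   col = col[seq_along(fs)], lty = 1, bty = "n")
}
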