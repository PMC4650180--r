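# Shared constants and small helpers.

# data.table syntax is used internally without attaching the package
.datatable.aware <- TRUE

# Breeding (reproductive-performance) states and the absorbing death state.
RP_STATES <- c("SUCCESS", "FAIL", "SKIP")
ALL_STATES <- c(RP_STATES, "DEAD")

# Encounter-history event codes.  SEEN_UNKNOWN marks a capture whose
# breeding state could not be ascertained.
EVENT_CODES <- c("NOT_SEEN", "SEEN_SUCCESS", "SEEN_FAIL", "SEEN_SKIP",
                 "SEEN_UNKNOWN")

SEXES <- c("F", "M")

#' Reproductive-performance state labels
#'
#' @return Character vector `c("SUCCESS", "FAIL", "SKIP")`.
#' @export
rp_states <- function() RP_STATES

#' Encounter-history event codes
#'
#' @return Character vector of the five recognised event codes.
#' @export
event_codes <- function() EVENT_CODES

# log(sum(exp(x))) along rows of a matrix, numerically safe.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  fin <- is.finite(mx)
  out <- mx
  if (any(fin)) {
    out[fin] <- mx[fin] + log(rowSums(exp(m[fin, , drop = FALSE] - mx[fin])))
  }
  out
}

# Deterministic per-stage child seeds derived from one global seed.
# Kept below 2^31 so they are valid R integer seeds.
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "activity", "breakpoints", "boost", "trends",
              "mecmr", "acceptance")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Robust ISO-8601 timestamp parsing.  Parses element-wise across the
# accepted formats (a single as.POSIXct call would lock onto the format
# of the first element and silently truncate the rest).
parse_timestamps <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- tz
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = tz), tz = tz)
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M:%OS",
                                     tz = tz), tz = tz)
  }
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d", tz = tz),
                            tz = tz)
  }
  out
}

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# Row-stochasticity check used by the simulator and the CMR spec.
check_simplex_rows <- function(m, name, tol = 1e-12) {
  if (any(m < -tol)) stop(name, " has negative entries", call. = FALSE)
  bad <- abs(rowSums(m) - 1) > tol
  if (any(bad)) {
    stop(name, " rows must sum to 1 (row ", which(bad)[1L], " sums to ",
         format(rowSums(m)[bad][1L], digits = 15), ")", call. = FALSE)
  }
  invisible(m)
}
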