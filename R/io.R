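# CSV interchange: writers with a one-line provenance header, matching
# readers, and schema validation of the three input dialects.

# Write a data.frame with a leading "# key=value ..." provenance line.
write_csv_prov <- function(df, path, seed = NA, stage = NA) {
  header <- sprintf("# package=shearwaterCOE version=%s stage=%s seed=%s",
                    as.character(utils::packageVersion("shearwaterCOE")),
                    stage, seed)
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE,
                     dateTimeAs = "ISO")
  invisible(path)
}

# Read a CSV written by write_csv_prov (or a plain CSV).
read_csv_prov <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  as.data.frame(data.table::fread(path, skip = skip))
}

#' Read an immersion-series CSV
#'
#' Columns: `bird_id`, `timestamp` (ISO-8601), `wet_fraction`,
#' `is_daytime`.
#'
#' @param path File path.
#' @return data.frame with POSIXct timestamps (UTC).
#' @export
read_immersion_csv <- function(path) {
  df <- read_csv_prov(path)
  df$timestamp <- parse_timestamps(df$timestamp)
  df$is_daytime <- as.logical(df$is_daytime)
  df
}

#' Read a phenology-records CSV
#' @param path File path.
#' @return data.frame of phenology records.
#' @export
read_phenology_csv <- function(path) read_csv_prov(path)

#' Read an encounter-history CSV
#'
#' Long format: `bird_id`, `sex`, `occasion`, `event`.
#'
#' @param path File path.
#' @return An `encounter_histories` object.
#' @export
read_histories_csv <- function(path) {
  df <- read_csv_prov(path)
  long_to_histories(df)
}

# Long data.frame -> encounter_histories.
long_to_histories <- function(df) {
  ids <- unique(df$bird_id)
  occ <- sort(unique(df$occasion))
  ev <- matrix(EVENT_CODES[1L], length(ids), length(occ),
               dimnames = list(ids, NULL))
  ev[cbind(match(df$bird_id, ids), match(df$occasion, occ))] <- df$event
  sex <- df$sex[match(ids, df$bird_id)]
  first <- apply(ev != "NOT_SEEN", 1L, function(r) which(r)[1L])
  new_encounter_histories(ev, sex, ids, first)
}

# encounter_histories -> long data.frame.
histories_to_long <- function(histories) {
  n <- nrow(histories$events); T <- ncol(histories$events)
  data.frame(bird_id = rep(histories$bird_id, T),
             sex = rep(histories$sex, T),
             occasion = rep(seq_len(T), each = n),
             event = as.vector(histories$events))
}

#' Validate pipeline input files against their schemas
#'
#' Checks each supplied file and reports every violation found: bad or
#' non-increasing timestamps, wet fractions outside \[0, 1\], missing
#' columns, unknown event codes, histories starting with `NOT_SEEN`,
#' labels outside the RP set.  An empty report means every file is valid.
#'
#' @param immersion,phenology,histories Optional file paths.
#' @return data.frame with `file`, `row`, `column`, `problem` (zero rows
#'   when everything validates).
#' @export
validate_inputs <- function(immersion = NULL, phenology = NULL,
                            histories = NULL) {
  probs <- list()
  note <- function(file, row, column, problem) {
    probs[[length(probs) + 1L]] <<- data.frame(
      file = file, row = row, column = column, problem = problem)
  }

  if (!is.null(immersion)) {
    if (!file.exists(immersion)) stop("unreadable file: ", immersion)
    df <- read_csv_prov(immersion)
    need <- c("bird_id", "timestamp", "wet_fraction", "is_daytime")
    for (cn in setdiff(need, names(df))) {
      note(immersion, NA, cn, "missing column")
    }
    if (all(need %in% names(df))) {
      ts <- parse_timestamps(df$timestamp)
      bad_ts <- which(is.na(ts))
      for (r in bad_ts) note(immersion, r, "timestamp", "unparseable timestamp")
      bad_wf <- which(!is.finite(df$wet_fraction) | df$wet_fraction < 0 |
                        df$wet_fraction > 1)
      for (r in bad_wf) note(immersion, r, "wet_fraction",
                             "wet_fraction outside [0, 1]")
      if (!length(bad_ts)) {
        for (b in unique(df$bird_id)) {
          tb <- ts[df$bird_id == b]
          d <- diff(as.numeric(tb))
          if (any(d <= 0) || any(abs(d - d[1]) > 1e-6)) {
            note(immersion, which(df$bird_id == b)[1L], "timestamp",
                 paste0("timestamps of ", b,
                        " not strictly increasing with constant spacing"))
          }
        }
      }
    }
  }

  if (!is.null(phenology)) {
    if (!file.exists(phenology)) stop("unreadable file: ", phenology)
    df <- read_csv_prov(phenology)
    need <- c("bird_id", "sex", "label", phenology_features())
    for (cn in setdiff(need, names(df))) note(phenology, NA, cn,
                                              "missing column")
    if ("label" %in% names(df)) {
      bad <- which(!df$label %in% RP_STATES)
      for (r in bad) note(phenology, r, "label",
                          paste0("unknown RP label '", df$label[r], "'"))
    }
  }

  if (!is.null(histories)) {
    if (!file.exists(histories)) stop("unreadable file: ", histories)
    df <- read_csv_prov(histories)
    need <- c("bird_id", "sex", "occasion", "event")
    for (cn in setdiff(need, names(df))) note(histories, NA, cn,
                                              "missing column")
    if (all(need %in% names(df))) {
      bad <- which(!df$event %in% EVENT_CODES)
      for (r in bad) note(histories, r, "event",
                          paste0("unknown event code '", df$event[r], "'"))
      if (!length(bad)) {
        occ <- sort(unique(df$occasion))
        for (b in unique(df$bird_id)) {
          evb <- df$event[df$bird_id == b][order(df$occasion[df$bird_id == b])]
          seen <- which(evb != "NOT_SEEN")
          if (!length(seen)) {
            note(histories, which(df$bird_id == b)[1L], "event",
                 paste0("bird ", b, " is never seen"))
          }
        }
      }
    }
  }

  if (!length(probs)) {
    data.frame(file = character(0), row = integer(0),
               column = character(0), problem = character(0))
  } else {
    do.call(rbind, c(probs, list(make.row.names = FALSE)))
  }
}
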