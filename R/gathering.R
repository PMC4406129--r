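# From raw detection streams to gathering events (flocks) and the
# group-by-individual (GBI) matrix that underpins the gambit-of-the-group
# association analysis.

#' Detect gathering events in a detection stream
#'
#' Segments the time-stamped detections at each location-day into bursts of
#' activity and calls each burst a gathering event; every individual with at
#' least one detection in a burst is a member of that event. Two detectors
#' are provided:
#'
#' * `"gap"` (default): a new event starts whenever the gap between
#'   consecutive detections exceeds `max_gap_s`. Deterministic and fast.
#' * `"gmm"`: a one-dimensional Gaussian mixture over the day's timestamps
#'   with the number of components chosen by BIC over `1..k_max` (via
#'   \pkg{mclust}), hard assignment, and components whose means lie within
#'   `max_gap_s` merged. Emulates burst detection by mixture modelling.
#'
#' Location-days are processed independently (no event spans midnight).
#'
#' @param detections `data.frame` with `individual_id`, `location_id`,
#'   `timestamp` (POSIXct), sorted by location then timestamp (see
#'   [sort_detections()]); unsorted input is an error.
#' @param method `"gap"` or `"gmm"`.
#' @param max_gap_s burst-separation threshold in seconds.
#' @param k_max maximum number of mixture components per location-day
#'   (`"gmm"` only).
#' @return `data.frame` of class `gathering_events` with columns `event_id`,
#'   `location_id`, `start`, `end`, `n_members` and a list-column `members`
#'   of individual identifiers.
#' @export
detect_events <- function(detections, method = c("gap", "gmm"),
                          max_gap_s = 600, k_max = 15) {
  method <- match.arg(method)
  cols <- c("individual_id", "location_id", "timestamp")
  stopifnot(all(cols %in% names(detections)))
  if (nrow(detections) == 0) return(empty_events())
  if (any(!nzchar(detections$individual_id)) ||
      any(!nzchar(detections$location_id)))
    stop("identifiers must be non-empty")
  o <- order(detections$location_id, detections$timestamp)
  if (!identical(o, seq_len(nrow(detections))))
    stop("detections must be sorted by (location_id, timestamp); ",
         "see sort_detections()")

  day <- as.Date(detections$timestamp, tz = "UTC")
  chunks <- split(seq_len(nrow(detections)),
                  list(detections$location_id, day), drop = TRUE)
  out <- lapply(chunks, function(idx) {
    d <- detections[idx, ]
    ts <- as.numeric(d$timestamp)
    grp <- switch(method,
                  gap = cumsum(c(TRUE, diff(ts) > max_gap_s)),
                  gmm = gmm_segment(ts, max_gap_s, k_max))
    lapply(split(seq_along(ts), grp), function(j) {
      list(location_id = d$location_id[1],
           start = d$timestamp[j[1]],
           end = d$timestamp[j[length(j)]],
           members = sort(unique(d$individual_id[j])))
    })
  })
  evs <- unlist(out, recursive = FALSE, use.names = FALSE)
  # stable chronological order across locations
  ord <- order(vapply(evs, function(e) as.numeric(e$start), 0),
               vapply(evs, function(e) e$location_id, ""))
  evs <- evs[ord]
  res <- data.frame(
    event_id = sprintf("ev%06d", seq_along(evs)),
    location_id = vapply(evs, function(e) e$location_id, ""),
    start = as.POSIXct(vapply(evs, function(e) as.numeric(e$start), 0),
                       origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(vapply(evs, function(e) as.numeric(e$end), 0),
                     origin = "1970-01-01", tz = "UTC"),
    n_members = vapply(evs, function(e) length(e$members), 0L),
    stringsAsFactors = FALSE
  )
  res$members <- lapply(evs, function(e) e$members)
  class(res) <- c("gathering_events", class(res))
  res
}

empty_events <- function() {
  res <- data.frame(event_id = character(), location_id = character(),
                    start = as.POSIXct(character(), tz = "UTC"),
                    end = as.POSIXct(character(), tz = "UTC"),
                    n_members = integer(), stringsAsFactors = FALSE)
  res$members <- list()
  class(res) <- c("gathering_events", class(res))
  res
}

# 1-D Gaussian mixture segmentation of one location-day's timestamps;
# returns an integer group label per detection
gmm_segment <- function(ts, max_gap_s, k_max) {
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("method = \"gmm\" requires the mclust package")
  if (length(unique(ts)) < 3) return(rep(1L, length(ts)))
  k_max <- min(k_max, length(unique(ts)) - 1)
  ts <- ts - ts[1]                      # seconds since first read of the day
  # Mclust resolves helpers in the caller frame, so evaluate the call inside
  # the mclust namespace
  fit <- suppressWarnings(eval(
    as.call(list(quote(Mclust), ts, G = seq_len(k_max),
                 modelNames = c("E", "V"), verbose = FALSE)),
    envir = asNamespace("mclust")))
  if (is.null(fit)) return(cumsum(c(TRUE, diff(ts) > max_gap_s)))
  cl <- fit$classification
  # merge components whose means are closer than max_gap_s
  mu <- sort(tapply(ts, cl, mean))
  merged <- cumsum(c(TRUE, diff(mu) >= max_gap_s))
  relabel <- merged[match(as.character(cl), names(mu))]
  # events must be contiguous in time: label runs along the sorted stream
  cumsum(c(TRUE, diff(relabel) != 0))
}

#' Sort a detection stream
#'
#' Orders detections by location then timestamp, the order [detect_events()]
#' requires.
#'
#' @param detections detection `data.frame`.
#' @return sorted `data.frame`.
#' @export
sort_detections <- function(detections) {
  out <- detections[order(detections$location_id, detections$timestamp), ]
  rownames(out) <- NULL
  out
}

#' Build the group-by-individual matrix
#'
#' Binary matrix with one row per gathering event and one column per
#' individual in `roster`; entry 1 marks membership. Row sums equal event
#' sizes and column sums equal each individual's number of observations.
#'
#' @param events a `gathering_events` table ([detect_events()]) or any
#'   `data.frame` with `event_id` and a `members` list-column, or a
#'   two-column `data.frame` of (`event_id`, `individual_id`) incidences.
#' @param roster character vector of individual identifiers (column order).
#' @param sparse return a `Matrix::sparseMatrix` instead of a dense base
#'   matrix (useful at the scale of tens of thousands of events).
#' @return binary matrix, `dimnames = list(event_id, individual_id)`.
#' @export
build_gbi <- function(events, roster, sparse = FALSE) {
  stopifnot(!anyDuplicated(roster))
  if (!is.null(events$members)) {
    eid <- rep(events$event_id, lengths(events$members))
    iid <- unlist(events$members, use.names = FALSE)
  } else {
    stopifnot(all(c("event_id", "individual_id") %in% names(events)))
    eid <- events$event_id
    iid <- events$individual_id
  }
  if (length(eid) == 0) {
    m <- matrix(0L, 0, length(roster),
                dimnames = list(character(), roster))
    return(m)
  }
  col <- match(iid, roster)
  if (anyNA(col))
    stop("member(s) not in roster: ",
         paste(unique(iid[is.na(col)]), collapse = ", "))
  ue <- unique(eid)
  row <- match(eid, ue)
  if (sparse) {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("sparse = TRUE requires the Matrix package")
    return(Matrix::sparseMatrix(i = row, j = col, x = 1,
                                dims = c(length(ue), length(roster)),
                                dimnames = list(ue, roster)))
  }
  m <- matrix(0L, length(ue), length(roster),
              dimnames = list(ue, roster))
  m[cbind(row, col)] <- 1L
  m
}

#' First-detection week per individual
#'
#' The sampling-week index of each individual's earliest detection, the
#' operational definition of arrival time (week 1 = detected in the first
#' sampling week). Individuals with no detections are simply absent from the
#' output.
#'
#' @param detections detection `data.frame`.
#' @param calendar `data.frame` mapping `date` to `week` (see
#'   [week_calendar()]); every detection date must be covered.
#' @return named integer vector of arrival weeks.
#' @export
first_detection_week <- function(detections, calendar) {
  if (nrow(detections) == 0) return(setNames(integer(), character()))
  d <- as.Date(detections$timestamp, tz = "UTC")
  wk <- calendar$week[match(d, calendar$date)]
  if (anyNA(wk))
    stop("detection date(s) outside the sampling calendar: ",
         paste(unique(d[is.na(wk)]), collapse = ", "))
  out <- tapply(wk, detections$individual_id, min)
  setNames(as.integer(out), names(out))
}
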