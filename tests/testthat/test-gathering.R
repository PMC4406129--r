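# event detection, GBI construction and first-detection weeks

toy_stream <- function(times, ids, loc = "F1",
                       day = as.POSIXct("2011-12-05 08:00:00", tz = "UTC")) {
  sort_detections(data.frame(individual_id = ids,
                             location_id = rep_len(loc, length(ids)),
                             timestamp = day + times,
                             stringsAsFactors = FALSE))
}

test_that("gap detector splits well-separated bursts and keeps singletons", {
  d <- toy_stream(c(0, 30, 90, 7200, 7260), c("A", "B", "A", "C", "A"))
  ev <- detect_events(d, max_gap_s = 600)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$members[[1]], c("A", "B"))
  expect_equal(ev$members[[2]], c("A", "C"))
  expect_equal(ev$n_members, c(2L, 2L))

  single <- detect_events(toy_stream(0, "A"))
  expect_equal(nrow(single), 1)
  expect_equal(single$members[[1]], "A")

  empty <- detect_events(toy_stream(numeric(), character()))
  expect_equal(nrow(empty), 0)
})

test_that("event detection requires sorted input and is order-independent
           after sorting", {
  d <- toy_stream(c(0, 30, 7200), c("A", "B", "C"))
  shuffled <- d[c(3, 1, 2), ]
  expect_error(detect_events(shuffled), "sorted")
  resorted <- detect_events(sort_detections(shuffled))
  expect_equal(resorted$members, detect_events(d)$members)
  # idempotence: re-detecting on the same stream gives the same events
  expect_identical(detect_events(d), detect_events(d))
})

test_that("events never span locations or midnight", {
  d1 <- toy_stream(c(0, 10), c("A", "B"), loc = "F1")
  d2 <- toy_stream(c(0, 10), c("C", "D"), loc = "F2")
  ev <- detect_events(sort_detections(rbind(d1, d2)))
  expect_equal(nrow(ev), 2)
  expect_equal(sort(vapply(ev$members, paste, "", collapse = "")),
               c("AB", "CD"))
  across <- toy_stream(c(-60, 60),  # 23:59 and 00:01 next day
                       c("A", "B"),
                       day = as.POSIXct("2011-12-06 00:00:00", tz = "UTC"))
  expect_equal(nrow(detect_events(across)), 2)
})

test_that("gmm detector recovers two bursts via BIC model choice", {
  skip_if_not_installed("mclust")
  set.seed(1)
  d <- toy_stream(c(rnorm(25, 0, 40), rnorm(25, 7200, 40)),
                  sample(LETTERS[1:6], 50, replace = TRUE))
  ev <- detect_events(d, method = "gmm", max_gap_s = 600)
  expect_equal(nrow(ev), 2)
  expect_lt(max(as.numeric(ev$end[1]) - as.numeric(ev$start[1])), 600)
})

test_that("detected events recover the generator's true flocks", {
  skip_if_not_installed("mclust")          # for adjustedRandIndex
  w <- small_winter(seed = 11)
  truth_part <- setNames(w$sim$truth$event_id, NULL)
  # partitions compared over detections (each detection belongs to exactly
  # one true and one detected event); rebuild the detected assignment
  d <- w$sim$detections
  key_truth <- w$sim$truth
  det_labels <- rep(NA_character_, nrow(d))
  for (i in seq_len(nrow(w$events))) {
    in_ev <- d$location_id == w$events$location_id[i] &
      d$timestamp >= w$events$start[i] & d$timestamp <= w$events$end[i]
    det_labels[in_ev] <- w$events$event_id[i]
  }
  # true label per detection: match on (individual, nearest true event time)
  truth_of <- split(key_truth$event_id, key_truth$individual_id)
  ev_time <- setNames(as.numeric(w$sim$events$time), w$sim$events$event_id)
  true_labels <- vapply(seq_len(nrow(d)), function(i) {
    cand <- truth_of[[d$individual_id[i]]]
    cand[which.min(abs(ev_time[cand] - as.numeric(d$timestamp[i])))]
  }, "")
  ari <- mclust::adjustedRandIndex(det_labels, true_labels)
  expect_gte(ari, 0.9)
})

test_that("GBI layout matches membership and rejects unknown individuals", {
  ev <- data.frame(event_id = "e1", stringsAsFactors = FALSE)
  ev$members <- list(c("A", "B"))
  g <- build_gbi(ev, c("A", "B", "C"))
  expect_equal(unname(g["e1", ]), c(1L, 1L, 0L))

  g0 <- build_gbi(ev[0, ], c("A", "B"))
  expect_equal(dim(g0), c(0L, 2L))

  expect_error(build_gbi(ev, c("A", "C")), "B")
})

test_that("large sparse GBI builds within a minute at field scale", {
  # year-1 field magnitude: 73 737 events over 1053 individuals
  skip_if_not_installed("Matrix")
  set.seed(2)
  n_ev <- 73737; n_id <- 1053
  sizes <- pmax(1 + rpois(n_ev, 7), 1)
  inc <- data.frame(
    event_id = rep(sprintf("e%06d", seq_len(n_ev)), sizes),
    individual_id = sprintf("i%04d", sample.int(n_id, sum(sizes),
                                                replace = TRUE)))
  inc <- inc[!duplicated(inc), ]
  roster <- sprintf("i%04d", seq_len(n_id))
  t0 <- Sys.time()
  g <- build_gbi(inc, roster, sparse = TRUE)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_equal(dim(g), c(n_ev, n_id))
  expect_equal(sum(g), nrow(inc))
})

test_that("first-detection week is the minimum over an individual's record", {
  cal <- week_calendar(as.Date("2011-12-05"), 6)
  day_of <- function(wk) cal$date[match(wk, cal$week)]
  d <- data.frame(
    individual_id = c("A", "A", "A", "B"),
    location_id = "F1",
    timestamp = as.POSIXct(paste(day_of(c(3, 5, 3, 1)), "09:00:00"),
                           tz = "UTC"))
  out <- first_detection_week(sort_detections(d), cal)
  expect_equal(out[["A"]], 3L)
  expect_equal(out[["B"]], 1L)           # first sampling day -> week 1
  expect_false("C" %in% names(out))      # no record -> omitted
  expect_equal(length(first_detection_week(d[0, ], cal)), 0L)
})
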