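# synthetic-data generator: arrival mixture, settlement, detections,
# fitness and breeding locations

test_that("arrival mixture honours the configured waves", {
  # degenerate mixture: everyone present at the start
  cfg <- small_config(frac_early = 1, brood_var_frac = 0, year_var_frac = 0)
  expect_true(all(generate_arrivals(cfg)$arrival_week == 1L))

  # Monte-Carlo check of the late-wave mean under the field defaults
  # (year effect off to isolate the marginal late-arrival distribution)
  cfg <- sim_config(n_individuals = 10000, n_broods = 833,
                    year_var_frac = 0, seed = 3)
  pop <- generate_arrivals(cfg)
  expect_equal(mean(pop$arrival_week == 1), 0.628, tolerance = 0.03)
  late <- pop$arrival_week[pop$arrival_week > 1]
  expect_lt(abs(mean(late) - 7.2), 0.2)
  expect_true(all(pop$arrival_week >= 1 & pop$arrival_week <= 14))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_config(seed = 9)
  expect_identical(generate_arrivals(cfg), generate_arrivals(cfg))
  pop <- generate_arrivals(cfg)
  s1 <- generate_detections(pop, cfg)
  s2 <- generate_detections(pop, cfg)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$truth, s2$truth)
})

test_that("config and arrival validation reject impossible parameters", {
  expect_error(sim_config(frac_early = 1.2), "frac_early")
  expect_error(sim_config(brood_var_frac = 0.6, year_var_frac = 0.5),
               "must be < 1")
  expect_error(generate_arrivals(small_config(late_arrival_mean = 12)),
               "late_arrival_mean")
  expect_error(generate_detections(generate_arrivals(small_config())[0, ],
                                   small_config()),
               "empty population")
})

test_that("brood and year fractions are realized on the arrival-week scale", {
  # large single factor-level design, checked with a one-way between/within
  # decomposition of the simulated weeks (no model fitting involved)
  cfg <- sim_config(n_individuals = 20000, n_broods = 1000,
                    year_var_frac = 0, seed = 21)
  pop <- generate_arrivals(cfg)
  juv <- pop[pop$age_class == "juvenile", ]
  gm <- tapply(juv$arrival_week, juv$brood_id, mean)
  k <- mean(table(juv$brood_id))
  msb <- var(gm) * k                     # balanced one-way moments
  msw <- mean(tapply(juv$arrival_week, juv$brood_id, var))
  sigma_b <- (msb - msw) / k
  frac <- sigma_b / (sigma_b + msw)
  expect_equal(frac, 0.12, tolerance = 0.25)
})

test_that("no bird is detected before its arrival week", {
  w <- small_winter(seed = 4)
  arr <- setNames(w$pop$arrival_week, w$pop$individual_id)
  first <- first_detection_week(w$sim$detections, w$sim$calendar)
  expect_true(all(first >= arr[names(first)]))
  # and in particular a week-5 arriver has nothing in weeks 1-4
  late_ids <- names(arr)[arr == max(arr)]
  if (length(late_ids) > 0) {
    d <- w$sim$detections
    wk <- w$sim$calendar$week[match(as.Date(d$timestamp, tz = "UTC"),
                                    w$sim$calendar$date)]
    expect_true(all(wk[d$individual_id %in% late_ids] >= max(arr)))
  }
})

test_that("truth-label GBI has event sizes as row sums and observation
           counts as column sums", {
  w <- small_winter(seed = 5)
  tg <- build_gbi(w$sim$truth, sort(unique(w$sim$truth$individual_id)))
  sizes <- table(w$sim$truth$event_id)
  expect_equal(unname(rowSums(tg)), as.vector(sizes[rownames(tg)]))
  counts <- table(w$sim$truth$individual_id)
  expect_equal(unname(colSums(tg)), as.vector(counts[colnames(tg)]))
})

test_that("settlement is independent of arrival phenotype only when the
           avoidance strength is zero", {
  feeder_arrival_cor <- function(strength, seed) {
    cfg <- sim_config(n_individuals = 500, n_feeders = 16, n_weeks = 8,
                      late_arrival_mean = 5, late_arrival_sd = 2,
                      spatial_assortment_strength = strength,
                      n_broods = 80, seed = seed)
    pop <- generate_arrivals(cfg)
    set.seed(seed)
    pop <- socsel:::settle_population(pop, feeder_grid(cfg), cfg)
    # mean arrival of the OTHER birds at an individual's feeder
    fsum <- tapply(pop$arrival_week, pop$home_feeder, sum)
    fn <- tapply(pop$arrival_week, pop$home_feeder, length)
    other <- (fsum[pop$home_feeder] - pop$arrival_week) /
      (fn[pop$home_feeder] - 1)
    cor(pop$arrival_week, other, use = "complete.obs")
  }
  null_cor <- sapply(1:20, function(s) feeder_arrival_cor(0, s))
  strong_cor <- sapply(1:20, function(s) feeder_arrival_cor(3, s))
  expect_lt(abs(mean(null_cor)), 0.05)
  expect_gt(mean(strong_cor), 0.2)
})

test_that("fitness generation follows the logistic model and flags isolates", {
  cfg <- small_config(n_individuals = 4000, beta_N = 0, beta_S = 0,
                      alpha = 0, seed = 6)
  pop <- generate_arrivals(cfg)
  z <- rnorm(nrow(pop)); zbar <- rnorm(nrow(pop))
  zbar[1:5] <- NA                        # isolates
  out <- generate_fitness(pop, z, zbar, cfg)
  expect_equal(mean(out$bred, na.rm = TRUE), 0.5, tolerance = 0.05)
  expect_equal(attr(out, "n_excluded"), 5)
  expect_true(all(is.na(out$bred[1:5])))

  # saturation: strongly negative intercept -> nobody breeds
  cfg2 <- small_config(alpha = -30, beta_N = 0, beta_S = 0, seed = 6)
  out2 <- generate_fitness(pop, z, zbar, cfg2)
  expect_true(all(out2$bred[!is.na(out2$bred)] == 0))
})

test_that("breeding-location assignment respects distance, occupancy and
           capacity", {
  cfg <- small_config(seed = 8)
  feeders <- feeder_grid(cfg)
  pop <- generate_arrivals(cfg)[1:2, ]
  pop$home_feeder <- feeders$feeder_id[1]
  pop$bred <- c(1L, 0L)
  boxes <- data.frame(box_id = "N1", x = feeders$x[1] + 5, y = feeders$y[1])
  one <- generate_breeding_locations(pop, feeders, boxes)
  expect_equal(one$breeding_box, c("N1", NA))

  # two breeders sharing a home feeder take distinct boxes
  pop$bred <- c(1L, 1L)
  boxes2 <- rbind(boxes, data.frame(box_id = "N2", x = feeders$x[1],
                                    y = feeders$y[1] + 9))
  two <- generate_breeding_locations(pop, feeders, boxes2)
  expect_setequal(two$breeding_box, c("N1", "N2"))

  expect_error(generate_breeding_locations(pop, feeders, boxes),
               "more breeders")
})

test_that("a run directory round-trips config and detections", {
  dir <- tempfile("socselrun")
  w <- small_winter(seed = 2)
  write_simulation(w$sim, w$cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("detections.csv", "truth.csv", "population.csv",
           "feeders.csv", "config.yaml", "manifest.json")))))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$seed, w$cfg$seed)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, w$cfg$seed)
  unlink(dir, recursive = TRUE)
})
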