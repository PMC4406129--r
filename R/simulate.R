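# Synthetic winter populations, detection streams and breeding outcomes with
# known ground truth. The generator emulates the structure the analysis
# assumes: a two-wave arrival process (a resident pool present when sampling
# starts plus late arrivals centred in mid-winter), spatial assortment of
# arrival phenotype across a feeder grid, bursty flock visitation, and binary
# territory acquisition from a logistic model with chosen nonsocial and
# social gradients.

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' Defaults describe one winter of a large woodland great tit population
#' monitored by a stratified grid of automated feeders: ~63% of birds present
#' when sampling starts, late arrivals centred near week 7, 65 feeders at
#' 250 m spacing opened two days per week for 14 weeks.
#'
#' @param n_individuals number of birds in the winter population.
#' @param n_feeders number of feeding stations (laid out on a square grid).
#' @param grid_spacing feeder grid spacing in metres.
#' @param n_weeks number of sampling weeks (arrival weeks run 1..n_weeks).
#' @param sampling_days_per_week days per week on which feeders open.
#' @param frac_early fraction of birds present in week 1 (the first wave).
#' @param late_arrival_mean mean arrival week of late (second-wave) birds.
#' @param late_arrival_sd standard deviation of late arrival week.
#' @param spatial_assortment_strength density-avoidance strength of settling
#'   birds; 0 = settlement independent of arrival time (no assortment).
#' @param beta_N true nonsocial selection gradient on the logit scale.
#' @param beta_S true social selection gradient on the logit scale.
#' @param alpha logit-scale intercept of the territory-acquisition model.
#' @param n_broods number of natal broods among juveniles.
#' @param brood_var_frac fraction of arrival-week variance attributable to
#'   natal brood (observed scale; see Details).
#' @param year_var_frac fraction of arrival-week variance attributable to
#'   year.
#' @param mean_flock_size mean number of birds per gathering event.
#' @param flocks_per_feeder_day expected gathering events per feeder per
#'   sampling day.
#' @param seed integer seed; all generator stages derive child seeds from it.
#'
#' @details A single latent standard-normal arrival propensity per bird
#' drives both wave membership (threshold at `qnorm(frac_early)`) and the
#' timing of late arrival. `brood_var_frac` and `year_var_frac` are specified
#' on the observed arrival-week scale; the generator calibrates the latent
#' brood/year variance shares by closed-form truncated-normal moment matching
#' so that the realized week-scale fractions equal the configured ones.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 1053, n_feeders = 65,
                       grid_spacing = 250, n_weeks = 14,
                       sampling_days_per_week = 2, frac_early = 0.628,
                       late_arrival_mean = 7.2, late_arrival_sd = 3,
                       spatial_assortment_strength = 1, beta_N = -0.8,
                       beta_S = 1.1, alpha = -0.62, n_broods = 200,
                       brood_var_frac = 0.12, year_var_frac = 0.027,
                       mean_flock_size = 8, flocks_per_feeder_day = 40,
                       seed = 1L) {
  cfg <- list(n_individuals = n_individuals, n_feeders = n_feeders,
              grid_spacing = grid_spacing, n_weeks = n_weeks,
              sampling_days_per_week = sampling_days_per_week,
              frac_early = frac_early, late_arrival_mean = late_arrival_mean,
              late_arrival_sd = late_arrival_sd,
              spatial_assortment_strength = spatial_assortment_strength,
              beta_N = beta_N, beta_S = beta_S, alpha = alpha,
              n_broods = n_broods, brood_var_frac = brood_var_frac,
              year_var_frac = year_var_frac,
              mean_flock_size = mean_flock_size,
              flocks_per_feeder_day = flocks_per_feeder_day,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_individuals > 0, n_feeders > 0, n_weeks > 0, n_broods > 0,
              grid_spacing > 0, sampling_days_per_week >= 1,
              frac_early >= 0, frac_early <= 1,
              late_arrival_sd > 0, mean_flock_size >= 1,
              flocks_per_feeder_day > 0,
              spatial_assortment_strength >= 0,
              brood_var_frac >= 0, year_var_frac >= 0)
    if (brood_var_frac + year_var_frac >= 1)
      stop("brood_var_frac + year_var_frac must be < 1")
  })
  class(cfg) <- "sim_config"
  cfg
}

# ---- latent arrival-propensity machinery ----------------------------------

# Mapping from latent propensity g ~ N(0,1) to arrival week:
#   week = 1                          if g <= t  (t = qnorm(frac_early))
#   week = round(A + B * g), clipped  otherwise
# with A, B chosen so late weeks have mean late_arrival_mean and sd
# late_arrival_sd before rounding. Returns the pieces needed both for
# generation and for the moment-matching calibration.
week_map <- function(config) {
  t <- qnorm(config$frac_early)
  if (is.finite(t)) {
    m_t <- dnorm(t) / (1 - pnorm(t))      # mean of N(0,1) truncated above t
    s_t <- sqrt(1 + t * m_t - m_t^2)
  } else {                                # frac_early = 0: no truncation
    m_t <- 0
    s_t <- 1
  }
  B <- config$late_arrival_sd / s_t
  A <- config$late_arrival_mean - B * m_t
  list(t = t, A = A, B = B)
}

# E[h(g)] and E[h(g)^2] for g ~ N(mu, sig^2), h the week map above
# (rounding/clipping ignored; both are vectorised over mu)
week_map_moments <- function(mu, sig, map) {
  t <- map$t; A <- map$A; B <- map$B
  if (is.finite(t)) {
    al <- (t - mu) / sig
    Q <- 1 - pnorm(al)                    # P(g > t)
    pE <- pnorm(al)
    E1 <- mu * Q + sig * dnorm(al)        # E[g; g > t]
    E2 <- (mu^2 + sig^2) * Q + sig * (t + mu) * dnorm(al)
  } else {
    Q <- 1; pE <- 0; E1 <- mu; E2 <- mu^2 + sig^2
  }
  list(m1 = pE + A * Q + B * E1,
       m2 = pE + A^2 * Q + 2 * A * B * E1 + B^2 * E2,
       p_late = Q)
}

# Latent variance share `a` such that the between-group variance of the
# arrival week equals `target` as a fraction of its total variance.
solve_latent_share <- function(target, config, map) {
  if (target == 0) return(0)
  if (config$frac_early >= 1)
    stop("variance fractions > 0 are unattainable when frac_early = 1 ",
         "(all arrival weeks equal 1)")
  mm0 <- week_map_moments(0, 1, map)
  v_total <- mm0$m2 - mm0$m1^2 + mm0$p_late / 12   # + rounding variance
  between_var <- function(a) {
    f <- function(b)
      (week_map_moments(sqrt(a) * b, sqrt(1 - a), map)$m1 - mm0$m1)^2 *
        dnorm(b)
    stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
  }
  fr <- function(a) between_var(a) / v_total - target
  if (fr(0.995) < 0)
    stop("requested variance fraction ", target,
         " is unattainable on the arrival-week scale under this config")
  uniroot(fr, c(1e-9, 0.995), tol = 1e-9)$root
}

latent_shares <- function(config, map) {
  a <- solve_latent_share(config$brood_var_frac, config, map)
  c_ <- solve_latent_share(config$year_var_frac, config, map)
  if (a + c_ >= 1)
    stop("calibrated latent brood + year shares reach ", round(a + c_, 3),
         "; lower brood_var_frac/year_var_frac")
  c(brood = a, year = c_)
}

# ---- arrivals --------------------------------------------------------------

#' Generate a winter population with arrival weeks
#'
#' Draws a population of adults and first-year juveniles and assigns each
#' bird an arrival week: a fraction `frac_early` is already present in week 1
#' (the first wave) and the remainder arrive later, on a discretised normal
#' centred at `late_arrival_mean`. A shared latent propensity ties natal
#' brood and year to both wave membership and late timing, so that brood and
#' year explain the configured fractions of arrival-week variance.
#'
#' @param config a [sim_config()].
#' @param year cohort index; changes the derived seed, the year random
#'   intercept, and identifier prefixes so multi-year tables can be stacked.
#' @return a `data.frame` (one row per bird) with columns `individual_id`,
#'   `age_class` ("juvenile"/"adult"), `brood_id` (NA for adults),
#'   `home_feeder` (filled by [generate_detections()]), `arrival_week`,
#'   `bred`, `breeding_box`, `year`.
#' @export
generate_arrivals <- function(config, year = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$late_arrival_mean < 2 || config$late_arrival_mean > config$n_weeks)
    stop("late_arrival_mean must lie in [2, n_weeks]")
  set.seed(stage_seed(config$seed, 10L + year))
  n <- config$n_individuals
  n_juv <- round(n / 2)
  map <- week_map(config)
  shares <- latent_shares(config, map)
  a <- shares["brood"]; cy <- shares["year"]

  brood_of <- sort(rep_len(seq_len(config$n_broods), n_juv))
  b_eff <- rnorm(config$n_broods)
  u_year <- rnorm(1)
  age <- c(rep("juvenile", n_juv), rep("adult", n - n_juv))
  g <- numeric(n)
  g[seq_len(n_juv)] <- sqrt(a) * b_eff[brood_of] + sqrt(cy) * u_year +
    sqrt(1 - a - cy) * rnorm(n_juv)
  if (n > n_juv)
    g[(n_juv + 1):n] <- sqrt(cy) * u_year + sqrt(1 - cy) * rnorm(n - n_juv)

  week <- rep(1L, n)
  if (config$frac_early < 1) {
    late <- g > map$t
    wl <- round(map$A + map$B * g[late])
    week[late] <- as.integer(pmin(pmax(wl, 2), config$n_weeks))
  }
  data.frame(
    individual_id = sprintf("y%d_i%05d", year, seq_len(n)),
    age_class = age,
    brood_id = c(sprintf("y%d_b%04d", year, brood_of), rep(NA, n - n_juv)),
    home_feeder = NA_character_,
    arrival_week = week,
    bred = NA_integer_,
    breeding_box = NA_character_,
    year = as.integer(year),
    stringsAsFactors = FALSE
  )
}

#' Generate several annual cohorts at once
#'
#' Stacks [generate_arrivals()] tables for `n_years` winters; each year has
#' its own broods, identifiers, and year random intercept.
#'
#' @inheritParams generate_arrivals
#' @param n_years number of winters.
#' @return row-bound population `data.frame`.
#' @export
generate_cohorts <- function(config, n_years = 3L) {
  do.call(rbind, lapply(seq_len(n_years),
                        function(y) generate_arrivals(config, year = y)))
}

# ---- feeder grid and settlement -------------------------------------------

#' Square feeder grid
#'
#' Lays `n_feeders` feeding stations on a square grid at `grid_spacing`
#' metres (an idealisation of a stratified field grid).
#'
#' @param config a [sim_config()].
#' @return `data.frame` with `feeder_id`, `x`, `y` (metres).
#' @export
feeder_grid <- function(config) {
  side <- ceiling(sqrt(config$n_feeders))
  idx <- seq_len(config$n_feeders) - 1L
  data.frame(
    feeder_id = sprintf("F%03d", seq_len(config$n_feeders)),
    x = (idx %% side) * config$grid_spacing,
    y = (idx %/% side) * config$grid_spacing,
    stringsAsFactors = FALSE
  )
}

# Sequential settlement in order of arrival. Each feeder has a lognormal
# baseline attractiveness; the resident first wave (week 1) settles by
# attractiveness alone, while newcomers (arrival week > 1) additionally
# avoid feeders in proportion to current occupancy,
# exp(-strength * relative occupancy). With strength = 0 settlement is
# independent of arrival time (no spatial assortment of phenotype); with
# strong avoidance, late birds are pushed into the low-density areas the
# first wave left empty, spatially assorting arrival phenotype.
settle_population <- function(population, feeders, config) {
  n <- nrow(population)
  nf <- nrow(feeders)
  attract <- stats::rlnorm(nf, 0, 0.75)
  occupancy <- numeric(nf)
  expected_per_feeder <- n / nf
  ord <- order(population$arrival_week, runif(n))
  home <- character(n)
  lambda <- config$spatial_assortment_strength
  for (i in ord) {
    w <- if (population$arrival_week[i] > 1)
      attract * exp(-lambda * occupancy / expected_per_feeder)
    else attract
    f <- sample.int(nf, 1, prob = w)
    occupancy[f] <- occupancy[f] + 1
    home[i] <- feeders$feeder_id[f]
  }
  population$home_feeder <- home
  population
}

# ---- detection streams -----------------------------------------------------

#' Generate a detection stream with true gathering-event labels
#'
#' Settles the population on the feeder grid, then simulates bursty flock
#' visitation: on each feeder-day a Poisson number of gathering events occurs
#' at well-separated times through the day; each event draws members from the
#' feeder's local pool (birds homed at that feeder or an adjacent one, and
#' already arrived); each member yields one RFID detection at the event time
#' plus short Gaussian jitter. No bird is detected before its arrival week.
#'
#' @param population output of [generate_arrivals()] (a single cohort).
#' @param config a [sim_config()].
#' @param start_date first sampling day (a `Date`); sampling days within each
#'   week are offset 0, 3, 1, 4, ... days from the week start.
#' @return a list with elements `detections` (`individual_id`, `location_id`,
#'   `timestamp` POSIXct UTC, sorted by location then time), `truth`
#'   (`event_id`, `individual_id` membership of the true events), `events`
#'   (`event_id`, `location_id`, `time`), `population` (with `home_feeder`
#'   filled), `feeders`, and `calendar` (date to week map, see
#'   [week_calendar()]).
#' @export
generate_detections <- function(population, config,
                                start_date = as.Date("2011-12-05")) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(population) == 0) stop("empty population")
  year <- population$year[1]
  set.seed(stage_seed(config$seed, 200L + year))
  feeders <- feeder_grid(config)
  population <- settle_population(population, feeders, config)

  # local pools: home feeder (weight 1) plus adjacent feeders (weight 0.15)
  fxy <- as.matrix(feeders[, c("x", "y")])
  dmat <- cross_dist(fxy, fxy)
  adjacent <- dmat > 0 & dmat <= 1.5 * config$grid_spacing
  home_idx <- match(population$home_feeder, feeders$feeder_id)
  pool_ids <- vector("list", nrow(feeders))
  pool_wts <- vector("list", nrow(feeders))
  for (f in seq_len(nrow(feeders))) {
    at_home <- which(home_idx == f)
    nearby <- which(adjacent[f, ][home_idx])
    pool_ids[[f]] <- c(at_home, nearby)
    pool_wts[[f]] <- c(rep(1, length(at_home)), rep(0.15, length(nearby)))
  }

  calendar <- week_calendar(start_date, config$n_weeks,
                            config$sampling_days_per_week)
  day_len <- 36000                       # feeders open 10 h, 07:00-17:00 UTC
  day_open <- 7 * 3600
  det <- list(); truth <- list(); ev <- list()
  counter <- 0L
  for (d in seq_len(nrow(calendar))) {
    wk <- calendar$week[d]
    day0 <- as.POSIXct(paste(calendar$date[d], "00:00:00"), tz = "UTC")
    for (f in seq_len(nrow(feeders))) {
      present <- population$arrival_week[pool_ids[[f]]] <= wk
      ids <- pool_ids[[f]][present]
      if (length(ids) == 0) next
      wts <- pool_wts[[f]][present]
      n_ev <- rpois(1, config$flocks_per_feeder_day)
      if (n_ev == 0) next
      # near-regular slots with jitter keep events temporally separated
      times <- day_open + (seq_len(n_ev) - 0.5 + runif(n_ev, -0.1, 0.1)) /
        n_ev * day_len
      for (e in seq_len(n_ev)) {
        size <- min(1 + rpois(1, config$mean_flock_size - 1), length(ids))
        mem <- if (length(ids) == 1) ids else
          ids[sample.int(length(ids), size, prob = wts)]
        counter <- counter + 1L
        eid <- sprintf("E%07d", counter)
        stamp <- day0 + times[e] + rnorm(length(mem), 0, 20)
        det[[counter]] <- data.frame(
          individual_id = population$individual_id[mem],
          location_id = feeders$feeder_id[f],
          timestamp = stamp, stringsAsFactors = FALSE)
        truth[[counter]] <- data.frame(
          event_id = eid, individual_id = population$individual_id[mem],
          stringsAsFactors = FALSE)
        ev[[counter]] <- data.frame(
          event_id = eid, location_id = feeders$feeder_id[f],
          time = day0 + times[e], stringsAsFactors = FALSE)
      }
    }
  }
  detections <- do.call(rbind, det)
  detections <- detections[order(detections$location_id,
                                 detections$timestamp), ]
  rownames(detections) <- NULL
  list(detections = detections,
       truth = do.call(rbind, truth),
       events = do.call(rbind, ev),
       population = population,
       feeders = feeders,
       calendar = calendar)
}

#' Sampling-week calendar
#'
#' Maps sampling dates to week indices starting at 1.
#'
#' @param start_date first sampling day (`Date`).
#' @param n_weeks number of weeks.
#' @param days_per_week sampling days per week (offsets 0, 3, 1, 4, ... from
#'   each week's start).
#' @return `data.frame` with `date` and `week`.
#' @export
week_calendar <- function(start_date, n_weeks, days_per_week = 2) {
  offsets <- c(0, 3, 1, 4, 2, 5, 6)[seq_len(min(days_per_week, 7))]
  do.call(rbind, lapply(seq_len(n_weeks), function(w) {
    data.frame(date = start_date + (w - 1) * 7 + sort(offsets),
               week = as.integer(w))
  }))
}

# ---- fitness and breeding locations ---------------------------------------

#' Generate territory-acquisition outcomes from a logistic model
#'
#' Draws `bred` for every bird with a defined social environment from
#' `Bernoulli(plogis(alpha + beta_N * z + beta_S * zbar))`. Birds with an
#' undefined social environment (network isolates, `zbar` = NA) are excluded
#' (`bred` = NA) and counted.
#'
#' @param population population `data.frame`.
#' @param z standardized own-trait values aligned with `population` rows.
#' @param zbar weighted mean associate trait aligned with `population` rows;
#'   NA marks isolates.
#' @param config a [sim_config()]; supplies `alpha`, `beta_N`, `beta_S` and
#'   the seed.
#' @return `population` with `bred` filled; attributes `truth` (named vector
#'   of the generating coefficients) and `n_excluded` (isolates).
#' @export
generate_fitness <- function(population, z, zbar, config) {
  stopifnot(inherits(config, "sim_config"),
            length(z) == nrow(population), length(zbar) == nrow(population))
  set.seed(stage_seed(config$seed, 300L + population$year[1]))
  ok <- !is.na(zbar) & !is.na(z)
  eta <- config$alpha + config$beta_N * z[ok] + config$beta_S * zbar[ok]
  bred <- rep(NA_integer_, nrow(population))
  bred[ok] <- rbinom(sum(ok), 1, plogis(eta))
  population$bred <- bred
  attr(population, "truth") <- c(alpha = config$alpha,
                                 beta_N = config$beta_N,
                                 beta_S = config$beta_S)
  attr(population, "n_excluded") <- sum(!ok)
  population
}

#' Scatter nest boxes over the study plane
#'
#' Places `n_boxes` boxes uniformly over the feeder-grid extent (plus half a
#' grid spacing of margin), mirroring a woodland where boxes considerably
#' outnumber feeders.
#'
#' @param config a [sim_config()].
#' @param n_boxes number of boxes; the default keeps the field ratio of
#'   roughly 16.6 boxes per feeder.
#' @return `data.frame` with `box_id`, `x`, `y`.
#' @export
make_nestboxes <- function(config, n_boxes = round(16.6 * config$n_feeders)) {
  set.seed(stage_seed(config$seed, 400L))
  f <- feeder_grid(config)
  m <- config$grid_spacing / 2
  data.frame(
    box_id = sprintf("N%05d", seq_len(n_boxes)),
    x = runif(n_boxes, min(f$x) - m, max(f$x) + m),
    y = runif(n_boxes, min(f$y) - m, max(f$y) + m),
    stringsAsFactors = FALSE
  )
}

#' Assign breeding boxes to successful breeders
#'
#' Every bird with `bred` = 1 takes the nearest unoccupied nest box to its
#' home feeder (ties broken by lowest box identifier); boxes hold at most one
#' brood. Breeders are processed in order of arrival week (earlier arrivals
#' choose first), then identifier.
#'
#' @param population population with `bred` and `home_feeder` filled.
#' @param feeders feeder coordinate table (from [generate_detections()]).
#' @param boxes nest-box coordinate table (see [make_nestboxes()]).
#' @return `population` with `breeding_box` filled for breeders.
#' @export
generate_breeding_locations <- function(population, feeders, boxes) {
  breeders <- which(!is.na(population$bred) & population$bred == 1L)
  if (length(breeders) > nrow(boxes))
    stop("more breeders (", length(breeders), ") than boxes (",
         nrow(boxes), ")")
  if (length(breeders) == 0) return(population)
  fxy <- as.matrix(feeders[, c("x", "y")])
  bxy <- as.matrix(boxes[, c("x", "y")])
  dfb <- cross_dist(fxy, bxy)            # feeder x box distances
  # per feeder: boxes ranked by distance, lowest box_id breaking ties
  rank_of <- lapply(seq_len(nrow(feeders)),
                    function(f) order(dfb[f, ], boxes$box_id))
  ord <- breeders[order(population$arrival_week[breeders],
                        population$individual_id[breeders])]
  taken <- logical(nrow(boxes))
  fidx <- match(population$home_feeder, feeders$feeder_id)
  for (i in ord) {
    pref <- rank_of[[fidx[i]]]
    b <- pref[!taken[pref]][1]
    taken[b] <- TRUE
    population$breeding_box[i] <- boxes$box_id[b]
  }
  population
}

# ---- run directory export --------------------------------------------------

#' Write a simulation run to disk
#'
#' Exports the detection stream, true event memberships, population table,
#' feeder coordinates and configuration under one directory, together with a
#' manifest recording the seed and a parameter digest.
#'
#' @param sim output of [generate_detections()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- sim$detections
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  write.csv(d, file.path(dir, "detections.csv"), row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(sim$population, file.path(dir, "population.csv"),
            row.names = FALSE)
  write.csv(sim$feeders, file.path(dir, "feeders.csv"), row.names = FALSE)
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  manifest <- list(
    seed = config$seed,
    config_digest = fnv1a32(paste(names(cfg), unlist(cfg), collapse = ";")),
    files = c("detections.csv", "truth.csv", "population.csv",
              "feeders.csv", "config.yaml"),
    package_version = as.character(utils::packageVersion("socsel"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
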