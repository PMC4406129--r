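# shared fixtures: small seeded configurations and simulated objects

# compact winter: 4 feeders, 6 weeks, ~80 birds; cheap enough to simulate
# end-to-end many times
small_config <- function(seed = 1, ...) {
  args <- list(n_individuals = 80, n_feeders = 4, n_weeks = 6,
               late_arrival_mean = 4, late_arrival_sd = 1.5,
               flocks_per_feeder_day = 6, mean_flock_size = 6,
               n_broods = 15, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# simulate one winter and derive events / GBI / network / standardized trait
small_winter <- function(seed = 1, ...) {
  cfg <- small_config(seed = seed, ...)
  pop <- generate_arrivals(cfg)
  sim <- generate_detections(pop, cfg)
  ev <- detect_events(sim$detections)
  roster <- sort(unique(sim$detections$individual_id))
  gbi <- build_gbi(ev, roster)
  z <- standardize(first_detection_week(sim$detections, sim$calendar)[roster])
  names(z) <- roster
  list(cfg = cfg, pop = sim$population, sim = sim, events = ev,
       roster = roster, gbi = gbi, net = simple_ratio_index(gbi), z = z)
}

# random symmetric weight matrix with named roster and a random trait
random_network <- function(n, seed, density = 0.3) {
  set.seed(seed)
  ids <- sprintf("i%02d", seq_len(n))
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < density, runif(sum(ut)), 0)
  w[ut] <- vals
  w <- w + t(w)
  list(net = as_association_network(w),
       trait = setNames(rnorm(n), ids))
}

# sparse assortative partner network for the large-n gradient-recovery
# experiment: partners accepted with probability decaying in trait distance,
# zbar computed by direct edge-list aggregation (the same arithmetic as
# social_environment(), which is oracle-tested separately)
simulate_social_environment <- function(z, seed, mean_degree = 8,
                                        preference = 1.5) {
  set.seed(seed)
  n <- length(z)
  k <- 1 + rpois(n, mean_degree)
  ia <- rep(seq_len(n), k)
  cand <- sample.int(n, length(ia), replace = TRUE)
  keep <- cand != ia
  ia <- ia[keep]; cand <- cand[keep]
  acc <- runif(length(ia)) < exp(-preference * abs(z[ia] - z[cand]))
  ia <- ia[acc]; ib <- cand[acc]
  w <- runif(length(ia), 0.05, 0.6)
  sw <- rowsum(c(w * z[ib], w * z[ia]), c(ia, ib))
  sww <- rowsum(c(w, w), c(ia, ib))
  zbar <- rep(NA_real_, n)
  zbar[as.integer(rownames(sw))] <- sw / sww
  zbar
}

# brute-force weighted assortativity over the directed edge list: plain
# loops, no shared code with the package implementation
brute_force_assortativity <- function(net, trait) {
  w <- net$weights
  z <- trait[net$roster]
  js <- ks <- ws <- numeric(0)
  n <- length(net$roster)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a != b && w[a, b] > 0) {         # both orientations appear
      js <- c(js, z[a]); ks <- c(ks, z[b]); ws <- c(ws, w[a, b])
    }
  }
  W <- sum(ws)
  mj <- sum(ws * js) / W
  mk <- sum(ws * ks) / W
  num <- sum(ws * js * ks) / W - mj * mk
  den <- sqrt((sum(ws * js^2) / W - mj^2) * (sum(ws * ks^2) / W - mk^2))
  num / den
}
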