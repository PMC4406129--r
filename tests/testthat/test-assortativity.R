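# weighted assortativity, jackknife SE, and the permutation engine

two_component_network <- function(traits = c(1, 1, 2, 2)) {
  ids <- sprintf("i%d", seq_along(traits))
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  w["i1", "i2"] <- w["i2", "i1"] <- 0.5
  w["i3", "i4"] <- w["i4", "i3"] <- 0.2
  list(net = as_association_network(w), trait = setNames(traits, ids))
}

test_that("perfectly assorted and disassorted networks hit the bounds", {
  tc <- two_component_network()
  expect_equal(weighted_assortativity(tc$net, tc$trait)$r_hat, 1)

  w <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  w["a", "b"] <- w["b", "a"] <- 0.7
  r <- weighted_assortativity(as_association_network(w),
                              c(a = 0, b = 1))$r_hat
  expect_equal(r, -1)
})

test_that("assortativity matches a brute-force oracle on random networks", {
  for (s in 1:20) {
    rn <- random_network(30, seed = 100 + s)
    r <- weighted_assortativity(rn$net, rn$trait)$r_hat
    expect_equal(r, brute_force_assortativity(rn$net, rn$trait),
                 tolerance = 1e-12)
    expect_true(r >= -1 - 1e-12 && r <= 1 + 1e-12)
  }
})

test_that("assortativity is invariant to trait affine maps and weight
           rescaling", {
  rn <- random_network(25, seed = 33)
  r0 <- weighted_assortativity(rn$net, rn$trait)$r_hat
  expect_equal(weighted_assortativity(rn$net, 3 * rn$trait - 7)$r_hat, r0)
  scaled <- rn$net; scaled$weights <- scaled$weights * 0.25
  expect_equal(weighted_assortativity(scaled, rn$trait)$r_hat, r0)
})

test_that("degenerate networks raise explicit errors", {
  ids <- c("a", "b")
  w0 <- matrix(0, 2, 2, dimnames = list(ids, ids))
  expect_error(weighted_assortativity(as_association_network(w0),
                                      c(a = 1, b = 2)), "no edges")
  w1 <- w0; w1["a", "b"] <- w1["b", "a"] <- 0.4
  expect_error(weighted_assortativity(as_association_network(w1),
                                      c(a = 2, b = 2)), "variance")
})

test_that("jackknife SE equals an explicit leave-one-edge-out loop", {
  rn <- random_network(12, seed = 55, density = 0.35)
  se <- assortativity_se(rn$net, rn$trait)
  w <- rn$net$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  loo <- vapply(seq_len(nrow(idx)), function(i) {
    wd <- w
    wd[idx[i, 1], idx[i, 2]] <- wd[idx[i, 2], idx[i, 1]] <- 0
    brute_force_assortativity(
      as_association_network(wd), rn$trait)
  }, 0)
  n <- length(loo)
  expect_equal(se, sqrt((n - 1) / n * sum((loo - mean(loo))^2)),
               tolerance = 1e-10)
})

test_that("jackknife SE vanishes under edge duplication and perfect
           assortment", {
  # triangles keep every leave-one-out network trait-heterogeneous
  ids <- sprintf("i%d", 1:6)
  w <- matrix(0, 6, 6, dimnames = list(ids, ids))
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    w[p[1], p[2]] <- w[p[2], p[1]] <- 0.4
  tr <- setNames(c(1, 1, 1, 5, 5, 5), ids)
  expect_equal(assortativity_se(as_association_network(w), tr), 0)

  # replicating an edge structure shrinks the jackknife SE
  rep_net <- function(k) {
    n <- 4 * k
    ids <- sprintf("r%02d", seq_len(n))
    w <- matrix(0, n, n, dimnames = list(ids, ids))
    tr <- setNames(numeric(n), ids)
    for (j in seq_len(k)) {
      a <- 4 * (j - 1)
      w[a + 1, a + 2] <- w[a + 2, a + 1] <- 0.5
      w[a + 3, a + 4] <- w[a + 4, a + 3] <- 0.5
      tr[a + 1:4] <- c(0, 1, 1, 0.2)
    }
    assortativity_se(as_association_network(w), tr)
  }
  expect_lt(rep_net(16), rep_net(2))
})

test_that("checkerboard swaps conserve row and column sums and respect
           strata", {
  set.seed(77)
  g <- matrix(rbinom(200, 1, 0.3), 20, 10,
              dimnames = list(sprintf("e%d", 1:20), sprintf("i%d", 1:10)))
  g[1, ] <- 1L                           # guarantee no empty row
  rs <- rowSums(g); cs <- colSums(g)
  p <- permute_gbi(g, n_accept = 500, seed = 1)
  expect_equal(rowSums(p), rs)
  expect_equal(colSums(p), cs)
  expect_false(identical(unname(p), unname(g)))

  # strata with disjoint memberships never mix
  g2 <- rbind(cbind(matrix(rbinom(40, 1, 0.5), 10, 4), matrix(0L, 10, 4)),
              cbind(matrix(0L, 10, 4), matrix(rbinom(40, 1, 0.5), 10, 4)))
  dimnames(g2) <- list(sprintf("e%d", 1:20), sprintf("i%d", 1:8))
  g2[1, 1] <- 1L; g2[11, 5] <- 1L
  p2 <- permute_gbi(g2, n_accept = 300, strata = rep(c("s1", "s2"), each = 10),
                    seed = 2)
  expect_true(all(p2[1:10, 5:8] == 0L))
  expect_true(all(p2[11:20, 1:4] == 0L))
})

test_that("a GBI with no legal swap is reported as degenerate", {
  g <- matrix(1L, 3, 3, dimnames = list(sprintf("e%d", 1:3), c("a", "b", "c")))
  expect_error(permute_gbi(g, n_accept = 1), "degenerate")
})

test_that("the null p-value carries the add-one correction", {
  set.seed(3)
  g <- matrix(rbinom(300, 1, 0.3), 30, 10,
              dimnames = list(sprintf("e%d", 1:30), sprintf("i%d", 1:10)))
  g[rowSums(g) == 0, 1] <- 1L
  # a statistic conserved by construction: every permutation ties the
  # observed value, so the upper-tail p must be exactly 1
  pn <- permute_datastream(g, statistic = function(x) sum(x), n_perm = 19,
                           seed = 4)
  expect_equal(pn$p_value, 1)
  expect_length(pn$statistic_values, 19)
})

test_that("strong spatial assortment is detected against the day-stratified
           permutation null", {
  cfg <- sim_config(n_individuals = 150, n_feeders = 6, n_weeks = 8,
                    late_arrival_mean = 5, late_arrival_sd = 2,
                    spatial_assortment_strength = 3,
                    flocks_per_feeder_day = 6, mean_flock_size = 6,
                    n_broods = 25, seed = 42)
  pop <- generate_arrivals(cfg)
  sim <- generate_detections(pop, cfg)
  ev <- detect_events(sim$detections)
  roster <- sort(unique(sim$detections$individual_id))
  gbi <- build_gbi(ev, roster)
  z <- standardize(first_detection_week(sim$detections, sim$calendar)[roster])
  names(z) <- roster
  stat <- function(g) weighted_assortativity(simple_ratio_index(g), z)$r_hat
  pn <- permute_datastream(gbi, stat, n_perm = 1000, n_swaps = 5,
                           strata = as.character(as.Date(ev$start,
                                                         tz = "UTC")),
                           burn_in = 10 * sum(gbi), seed = 9)
  expect_lt(pn$p_value, 0.001)
  expect_gt(pn$observed, 0.2)
})
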