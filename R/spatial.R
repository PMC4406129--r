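# Linking winter associations to breeding geography: dyadic distance tests,
# the edge-weight--distance slope with nestbox randomization, and the
# per-individual breeding-competition index.

#' Map nest boxes to their nearest feeder
#'
#' Assigns every nest box to the nearest feeder by Euclidean distance
#' (lowest feeder identifier breaks exact ties).
#'
#' @param feeders `data.frame` with `feeder_id`, `x`, `y` (metres, planar).
#' @param boxes `data.frame` with `box_id`, `x`, `y`.
#' @return object of class `site_map`: list with `feeders`, `boxes`, and
#'   `box_to_feeder` (named character vector, box -> feeder).
#' @export
site_map <- function(feeders, boxes) {
  stopifnot(!anyDuplicated(feeders$feeder_id), !anyDuplicated(boxes$box_id))
  d <- cross_dist(as.matrix(boxes[, c("x", "y")]),
                  as.matrix(feeders[, c("x", "y")]))
  ord <- order(feeders$feeder_id)
  nearest <- apply(d[, ord, drop = FALSE], 1, which.min)  # ties -> lowest id
  structure(list(feeders = feeders, boxes = boxes,
                 box_to_feeder = setNames(feeders$feeder_id[ord][nearest],
                                          boxes$box_id)),
            class = "site_map")
}

# all unordered dyads of breeders present in the network: endpoint indices
# (into ids), breeding distance and edge weight per dyad
breeding_dyads <- function(network, breeding_xy, exclude_same_box = TRUE) {
  stopifnot(all(c("individual_id", "x", "y") %in% names(breeding_xy)))
  ids <- intersect(network$roster, breeding_xy$individual_id)
  if (length(ids) < 2) stop("fewer than 2 breeders present in the network")
  xy <- breeding_xy[match(ids, breeding_xy$individual_id), ]
  d <- cross_dist(as.matrix(xy[, c("x", "y")]), as.matrix(xy[, c("x", "y")]))
  w <- network$weights[ids, ids]
  ut <- which(upper.tri(d), arr.ind = TRUE)
  keep <- rep(TRUE, nrow(ut))
  if (exclude_same_box) {
    if (!is.null(breeding_xy$box)) {
      bx <- breeding_xy$box[match(ids, breeding_xy$individual_id)]
      keep <- bx[ut[, 1]] != bx[ut[, 2]]
    } else {
      keep <- d[ut] != 0                  # coordinate identity as proxy
    }
  }
  list(ids = ids, xy = xy,
       ia = ut[keep, 1], ib = ut[keep, 2],
       distance = d[ut][keep], weight = w[ut][keep])
}

#' Do connected dyads breed closer together?
#'
#' Compares the Euclidean distance between breeding locations of dyads with
#' a network connection (edge weight > 0) to dyads never observed together,
#' over all unordered pairs of breeders, with a two-sample t-test
#' (Welch by default). Same-box dyads (mated pairs, distance 0) are excluded
#' by default.
#'
#' @param network an `association_network`.
#' @param breeding_xy `data.frame` with `individual_id`, `x`, `y` (and
#'   optionally `box`) for breeders.
#' @param exclude_same_box drop dyads breeding in the same box?
#' @param var_equal use the pooled-variance (Student) t-test instead of
#'   Welch.
#' @return list with `mean_connected`, `mean_nonconnected`, `t`, `df`, `p`,
#'   `n_connected`, `n_nonconnected`.
#' @export
dyad_distance_test <- function(network, breeding_xy,
                               exclude_same_box = TRUE, var_equal = FALSE) {
  dy <- breeding_dyads(network, breeding_xy, exclude_same_box)
  conn <- dy$weight > 0
  if (all(conn) || !any(conn))
    stop("all breeding dyads are ", if (all(conn)) "connected"
         else "non-connected", "; the comparison is undefined")
  ht <- t.test(dy$distance[conn], dy$distance[!conn], var.equal = var_equal)
  list(mean_connected = mean(dy$distance[conn]),
       mean_nonconnected = mean(dy$distance[!conn]),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       n_connected = sum(conn), n_nonconnected = sum(!conn))
}

#' Edge-weight--distance slope with nestbox randomization
#'
#' Over connected breeding dyads, fits the ordinary least-squares regression
#' of breeding distance (metres) on edge weight. A negative slope means
#' stronger associates breed closer together. Significance is assessed
#' against `n_rand` null data sets in which each breeder is independently
#' reassigned a uniformly random box from the full box list (the same model
#' refitted each time); the lower-tail p-value
#' `(#(null slope <= observed) + 1) / (n_rand + 1)` asks whether the
#' observed slope is more negative than expected given box geography.
#'
#' @inheritParams dyad_distance_test
#' @param boxes `data.frame` of all nest boxes (`box_id`, `x`, `y`).
#' @param n_rand number of randomized data sets.
#' @param exclusive reassign boxes without replacement (at most one breeder
#'   per box) instead of the default independent draws.
#' @param seed optional integer seed.
#' @return list with `slope`, `se`, `t`, `p_rand`, `n_dyads`, `null_slopes`.
#' @export
weight_distance_slope <- function(network, breeding_xy, boxes,
                                  n_rand = 1000, exclude_same_box = TRUE,
                                  exclusive = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dy <- breeding_dyads(network, breeding_xy, exclude_same_box)
  conn <- which(dy$weight > 0)
  if (length(conn) < 2) stop("fewer than 2 connected breeding dyads")
  wgt <- dy$weight[conn]
  if (sd(wgt) == 0) stop("edge weights are constant over breeding dyads")
  fit <- lm(dy$distance[conn] ~ wgt)
  sm <- summary(fit)$coefficients
  slope <- sm["wgt", "Estimate"]

  ia <- dy$ia[conn]
  ib <- dy$ib[conn]
  n <- length(dy$ids)
  bxy <- as.matrix(boxes[, c("x", "y")])
  null_slopes <- vapply(seq_len(n_rand), function(r) {
    bi <- if (exclusive) sample.int(nrow(bxy), n)
          else sample.int(nrow(bxy), n, replace = TRUE)
    dx <- bxy[bi[ia], 1] - bxy[bi[ib], 1]
    dyv <- bxy[bi[ia], 2] - bxy[bi[ib], 2]
    dd <- sqrt(dx^2 + dyv^2)
    cov(dd, wgt) / var(wgt)               # OLS slope, closed form
  }, 0)
  list(slope = slope, se = sm["wgt", "Std. Error"], t = sm["wgt", "t value"],
       p_rand = (sum(null_slopes <= slope) + 1) / (n_rand + 1),
       n_dyads = length(conn), null_slopes = null_slopes)
}

#' Per-individual breeding-competition index
#'
#' Local population size at each feeder is the sum over individuals of the
#' proportion of time they spend there; local competition divides this by
#' the number of used nest boxes assigned to that feeder; each individual's
#' competition index is the time-weighted average of local competition over
#' the feeders it uses. In the degenerate single-feeder case this reduces to
#' (number of birds) / (number of boxes) for every individual.
#'
#' @param time_proportions either a numeric matrix of time proportions
#'   (rows = individuals, columns = feeders, each row summing to 1) or a
#'   detection `data.frame` (`individual_id`, `location_id`), in which case
#'   the proportion of an individual's detections at each feeder is used.
#' @param sitemap a [site_map()]; its `box_to_feeder` assignment determines
#'   how many boxes each feeder serves.
#' @param boxes_used character vector of box identifiers with a breeding
#'   attempt (the denominator counts only these); defaults to all boxes in
#'   the site map.
#' @return object of class `competition_index`: list with `local_population`
#'   and `local_competition` (per feeder) and `individual_competition`
#'   (named per-individual vector).
#' @export
competition_index <- function(time_proportions, sitemap,
                              boxes_used = NULL) {
  stopifnot(inherits(sitemap, "site_map"))
  feeders <- sitemap$feeders$feeder_id
  if (is.data.frame(time_proportions)) {
    tab <- table(time_proportions$individual_id,
                 time_proportions$location_id)
    p <- matrix(0, nrow(tab), length(feeders),
                dimnames = list(rownames(tab), feeders))
    p[, colnames(tab)] <- tab
    p <- p / rowSums(p)
  } else {
    p <- as.matrix(time_proportions)
    stopifnot(identical(sort(colnames(p)), sort(feeders)))
    p <- p[, feeders, drop = FALSE]
    if (max(abs(rowSums(p) - 1)) > 1e-8)
      stop("time proportions must sum to 1 for every individual")
  }
  if (is.null(boxes_used)) boxes_used <- sitemap$boxes$box_id
  stopifnot(all(boxes_used %in% sitemap$boxes$box_id))
  nbox <- table(factor(sitemap$box_to_feeder[boxes_used], levels = feeders))
  local_pop <- colSums(p)
  bad <- local_pop > 0 & nbox == 0
  if (any(bad))
    stop("feeder(s) with population but no used boxes: ",
         paste(feeders[bad], collapse = ", "))
  local_comp <- ifelse(nbox > 0, local_pop / as.numeric(nbox), 0)
  structure(list(
    local_population = setNames(as.numeric(local_pop), feeders),
    local_competition = setNames(as.numeric(local_comp), feeders),
    individual_competition = setNames(as.numeric(p %*% local_comp),
                                      rownames(p))),
    class = "competition_index")
}

#' @export
print.competition_index <- function(x, ...) {
  cat("Competition index over", length(x$local_population), "feeders and",
      length(x$individual_competition), "individuals\n",
      "mean individual competition:",
      format(mean(x$individual_competition), digits = 3), "\n")
  invisible(x)
}
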