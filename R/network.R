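# Weighted association network (simple ratio index) and per-individual
# social-environment covariates.

#' Simple ratio index association network
#'
#' Edge weight between A and B is `x / (x + y)`: `x` = number of gathering
#' events containing both, `y` = number containing exactly one. Weights
#' estimate the probability that the two individuals are in the same flock,
#' ranging from 0 (never observed together) to 1 (always observed together).
#' Pairs never observed at all (`x + y = 0`) get weight 0. No thresholding is
#' applied.
#'
#' @param gbi binary group-by-individual matrix (rows = events, columns =
#'   individuals; see [build_gbi()]); dense or `Matrix` sparse.
#' @return object of class `association_network`: list with `weights` (a
#'   symmetric dense matrix, zero diagonal) and `roster`.
#' @export
simple_ratio_index <- function(gbi) {
  stopifnot(!is.null(colnames(gbi)))
  x <- as.matrix(crossprod(gbi))         # co-occurrence counts
  n_obs <- diag(x)                       # per-individual observation counts
  denom <- outer(n_obs, n_obs, "+") - x  # events with at least one of the pair
  w <- x / denom
  w[denom == 0] <- 0
  diag(w) <- 0
  structure(list(weights = w, roster = colnames(gbi)),
            class = "association_network")
}

#' Construct an association network from a weight matrix
#'
#' Validates and wraps an existing symmetric weight matrix (e.g. read from an
#' edge list) as an `association_network`.
#'
#' @param weights symmetric numeric matrix, entries in \[0, 1\], zero
#'   diagonal, with dimnames.
#' @return `association_network`.
#' @export
as_association_network <- function(weights) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights),
            !is.null(rownames(weights)),
            identical(rownames(weights), colnames(weights)))
  if (max(abs(weights - t(weights))) > 1e-12) stop("weights must be symmetric")
  if (any(weights < 0) || any(weights > 1)) stop("weights must lie in [0, 1]")
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  structure(list(weights = w, roster = rownames(weights)),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  w <- x$weights
  ut <- w[upper.tri(w)]
  cat("Association network:", length(x$roster), "individuals,",
      sum(ut > 0), "edges, density",
      round(mean(ut > 0), 3), "\n")
  invisible(x)
}

#' Edge list of an association network
#'
#' @param network an `association_network`.
#' @param keep_zero keep unconnected pairs (weight 0)?
#' @return `data.frame` with `id_a`, `id_b`, `weight` (each unordered pair
#'   once).
#' @export
network_edges <- function(network, keep_zero = FALSE) {
  w <- network$weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  out <- data.frame(id_a = network$roster[ut[, 1]],
                    id_b = network$roster[ut[, 2]],
                    weight = w[ut], stringsAsFactors = FALSE)
  if (!keep_zero) out <- out[out$weight > 0, ]
  rownames(out) <- NULL
  out
}

#' Social environment: weighted mean associate trait
#'
#' For each individual i, `zbar_i = sum_k w_ik * z_k / sum_k w_ik` over all
#' other individuals k, i.e. the edge-weighted mean trait of its associates,
#' together with the weighted degree `C_i = sum_k w_ik`. Isolates (weighted
#' degree 0) have an undefined social environment and get `zbar` = NA.
#'
#' @param network an `association_network`.
#' @param trait named numeric vector of trait values; must be defined for
#'   every individual connected to anyone.
#' @return `data.frame` with `individual_id`, `zbar`, `weighted_degree`.
#' @export
social_environment <- function(network, trait) {
  w <- network$weights
  z <- trait[network$roster]
  deg <- rowSums(w)
  needed <- colSums(w) > 0
  if (anyNA(z[needed]))
    stop("trait missing for networked individual(s): ",
         paste(network$roster[needed & is.na(z)], collapse = ", "))
  z0 <- ifelse(is.na(z), 0, z)           # isolates' own NA can't propagate
  zbar <- as.vector(w %*% z0) / deg
  zbar[deg == 0] <- NA_real_
  data.frame(individual_id = network$roster, zbar = zbar,
             weighted_degree = deg, stringsAsFactors = FALSE)
}
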