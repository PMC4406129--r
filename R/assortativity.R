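# Weighted continuous assortativity (the interaction covariance C^I), its
# jackknife uncertainty, and the data-stream permutation null model.

# directed edge list: each undirected positive edge contributes both
# orientations, so the j and k marginals coincide and the coefficient is
# symmetric; returns per-undirected-edge endpoint traits and weights
directed_edge_terms <- function(network, trait) {
  w <- network$weights
  z <- trait[network$roster]
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("undefined assortativity: network has no edges")
  za <- z[idx[, 1]]; zb <- z[idx[, 2]]
  if (anyNA(za) || anyNA(zb))
    stop("trait missing for edge endpoint(s)")
  list(w = w[idx], za = za, zb = zb)
}

# r over the directed edge list from per-undirected-edge sufficient sums;
# all arguments may be vectors of leave-one-out totals
r_from_sums <- function(W2, Sj, Sjj, Sjk) {
  mj <- Sj / W2
  num <- Sjk / W2 - mj^2
  den <- Sjj / W2 - mj^2
  num / den
}

#' Weighted assortativity of a continuous trait
#'
#' The weighted Pearson correlation between the trait values at the two ends
#' of network edges: over the directed edge list (each undirected edge taken
#' in both orientations, with weight `w_i`),
#' `r = (E_w[jk] - E_w[j] E_w[k]) / sqrt(Var_w(j) Var_w(k))`,
#' where `j_i` and `k_i` are the traits of the individuals edge i leads into
#' and out of and expectations are weighted by `w_i / W` (`W` = total
#' weight). Positive values mean like associates with like; the denominator
#' scales the coefficient to \[-1, 1\]. With equal weights this reduces to
#' Newman's continuous assortativity coefficient. When applied to a
#' standardized trait, the coefficient is the interaction covariance `C^I`
#' of the selection decomposition.
#'
#' @param network an `association_network`.
#' @param trait named numeric vector of trait values.
#' @param se also compute the delete-one-edge jackknife standard error?
#' @return object of class `assortativity_result`: list with `r_hat`, `se`
#'   (NA unless requested), `n_edges` (undirected positive edges).
#' @export
weighted_assortativity <- function(network, trait, se = FALSE) {
  e <- directed_edge_terms(network, trait)
  W2 <- 2 * sum(e$w)                        # directed total weight
  Sj <- sum(e$w * (e$za + e$zb))            # = directed sum w*j = sum w*k
  Sjj <- sum(e$w * (e$za^2 + e$zb^2))
  Sjk <- sum(2 * e$w * e$za * e$zb)
  den <- Sjj / W2 - (Sj / W2)^2
  if (den <= 0)
    stop("undefined assortativity: zero trait variance over edge endpoints")
  r <- r_from_sums(W2, Sj, Sjj, Sjk)
  out <- structure(list(r_hat = r, se = NA_real_, n_edges = length(e$w)),
                   class = "assortativity_result")
  if (se) out$se <- assortativity_se(network, trait)
  out
}

#' @export
print.assortativity_result <- function(x, ...) {
  cat("Weighted assortativity r =", format(x$r_hat, digits = 4))
  if (!is.na(x$se)) cat(" +/-", format(x$se, digits = 3), "(jackknife SE)")
  cat(" over", x$n_edges, "edges\n")
  invisible(x)
}

#' Jackknife standard error of the assortativity coefficient
#'
#' Delete-one-edge jackknife: the coefficient is recomputed with each
#' undirected edge (both orientations) removed in turn, and
#' `se = sqrt((n-1)/n * sum((r_(-i) - mean(r_(-)))^2))`.
#'
#' @inheritParams weighted_assortativity
#' @return numeric standard error.
#' @export
assortativity_se <- function(network, trait) {
  e <- directed_edge_terms(network, trait)
  n <- length(e$w)
  if (n < 2) stop("jackknife SE needs at least 2 edges")
  W2 <- 2 * sum(e$w)
  Sj <- sum(e$w * (e$za + e$zb))
  Sjj <- sum(e$w * (e$za^2 + e$zb^2))
  Sjk <- sum(2 * e$w * e$za * e$zb)
  loo <- r_from_sums(W2 - 2 * e$w,
                     Sj - e$w * (e$za + e$zb),
                     Sjj - e$w * (e$za^2 + e$zb^2),
                     Sjk - 2 * e$w * e$za * e$zb)
  if (anyNA(loo) || any(!is.finite(loo))) {
    warning("assortativity undefined after deleting some edge(s); ",
            "they are dropped from the jackknife")
    loo <- loo[is.finite(loo)]
    n <- length(loo)
    if (n < 2) stop("too few informative edges for a jackknife SE")
  }
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Data-stream permutation null for GBI statistics
#'
#' Serial Markov chain of checkerboard swaps on the group-by-individual
#' matrix: repeatedly pick two events and two individuals such that each
#' individual occurs in exactly one of the two events, and exchange them.
#' Every swap preserves all group sizes (row sums) and every individual's
#' number of observations (column sums); if `strata` are given, swaps only
#' occur between events in the same stratum (e.g. same location and sampling
#' day), preserving spatiotemporal structure. After a burn-in, the statistic
#' is recorded every `n_swaps` accepted swaps; the upper-tail p-value uses
#' the add-one correction `(#(null >= observed) + 1) / (n_perm + 1)`.
#'
#' @param gbi binary group-by-individual matrix.
#' @param statistic function taking a GBI matrix and returning a scalar
#'   (e.g. the assortativity of the simple-ratio network it implies).
#' @param n_perm number of recorded permutations.
#' @param n_swaps accepted swaps between recorded permutations.
#' @param strata optional vector of stratum labels, one per GBI row.
#' @param burn_in accepted swaps discarded before recording starts.
#' @param seed optional integer seed.
#' @return object of class `permutation_null`: list with `observed`,
#'   `statistic_values`, `n_perm`, `n_swaps_per_perm`, `p_value`.
#' @export
permute_datastream <- function(gbi, statistic, n_perm = 1000, n_swaps = 1,
                               strata = NULL, burn_in = 1000, seed = NULL) {
  stopifnot(is.function(statistic), n_perm >= 1, n_swaps >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- gbi_int_matrix(gbi)
  strata_code <- encode_strata(strata, nrow(g))
  observed <- statistic(g)
  g <- swap_chain(g, strata_code, burn_in)
  vals <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    g <- swap_chain(g, strata_code, n_swaps)
    vals[i] <- statistic(g)
  }
  structure(list(observed = observed, statistic_values = vals,
                 n_perm = n_perm, n_swaps_per_perm = n_swaps,
                 p_value = (sum(vals >= observed) + 1) / (n_perm + 1)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Data-stream permutation null:", x$n_perm, "permutations\n",
      "observed =", format(x$observed, digits = 4),
      " null mean =", format(mean(x$statistic_values), digits = 4),
      " P (upper tail) =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Advance the swap chain by a number of accepted swaps
#'
#' Low-level access to the permutation engine, mostly useful for verifying
#' the conservation properties of individual swaps.
#'
#' @inheritParams permute_datastream
#' @param n_accept number of accepted checkerboard swaps to perform.
#' @return the permuted GBI matrix.
#' @export
permute_gbi <- function(gbi, n_accept = 1, strata = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  swap_chain(gbi_int_matrix(gbi), encode_strata(strata, nrow(gbi)), n_accept)
}

gbi_int_matrix <- function(gbi) {
  g <- as.matrix(gbi)
  storage.mode(g) <- "integer"
  if (nrow(g) < 2 || ncol(g) < 2)
    stop("degenerate GBI: need at least 2 events and 2 individuals")
  if (any(g != 0L & g != 1L)) stop("GBI entries must be 0/1")
  g
}

encode_strata <- function(strata, n_events) {
  if (is.null(strata)) return(integer(0))
  stopifnot(length(strata) == n_events)
  as.integer(factor(strata)) - 1L
}

swap_chain <- function(g, strata_code, n_accept) {
  gbi_swap_chain_cpp(g, strata_code, as.integer(n_accept))
}
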