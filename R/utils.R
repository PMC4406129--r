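# small shared helpers

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a hash of a character scalar, returned as hex; used for
# config/file digests in run manifests (dependency-free, not cryptographic)
#' @keywords internal
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (h %% 2^32 + 2^32) %% 2^32          # back to [0, 2^32)
    h <- (h * 16777619) %% 2^32
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# derive a per-stage child seed from a global seed; keeps values in 32-bit
# integer range so set.seed() accepts them
#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 1000003 * stage) %% 2147483647)
}

# Euclidean distances between rows of two (x, y) matrices
#' @keywords internal
cross_dist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

#' Juvenile percentage as reported in cohort summary tables
#'
#' Percentage of a cohort made up of first-year (juvenile) birds, rounded to
#' one decimal place as printed in population summary tables.
#'
#' @param n_juveniles number of juveniles.
#' @param n_total total number of individuals.
#' @return numeric percentage in \[0, 100\], one decimal place.
#' @examples
#' juvenile_percentage(520, 1053)
#' @export
juvenile_percentage <- function(n_juveniles, n_total) {
  stopifnot(n_total > 0, n_juveniles >= 0, n_juveniles <= n_total)
  round(100 * n_juveniles / n_total, 1)
}
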