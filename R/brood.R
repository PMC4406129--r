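# Variance partitioning of arrival time among natal brood, year and residual
# via a Gaussian intercept-only model with crossed random intercepts, fitted
# by maximum likelihood with an EM algorithm.

#' Brood and year variance components of arrival time
#'
#' Fits `arrival ~ mu + b_brood + u_year + e` with independent Gaussian
#' random intercepts for natal brood and year (crossed), by an EM algorithm
#' on the Gaussian likelihood. Reports the three variance components and the
#' fractions of total variance explained by brood and year. Individuals with
#' unknown brood are excluded and counted.
#'
#' @param arrival numeric arrival weeks (or any trait on an interval scale).
#' @param brood_id natal brood identifier per individual (NA = unknown).
#' @param year_id year identifier per individual.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @return object of class `variance_components`: list with `var_brood`,
#'   `var_year`, `var_resid`, `frac_brood`, `frac_year`, `mu`, `loglik`,
#'   `n_used`, `n_excluded`, `n_iter`.
#' @export
variance_components <- function(arrival, brood_id, year_id,
                                tol = 1e-8, max_iter = 500) {
  stopifnot(length(arrival) == length(brood_id),
            length(arrival) == length(year_id))
  ok <- !is.na(arrival) & !is.na(brood_id) & !is.na(year_id)
  n_excluded <- sum(!ok)
  y <- as.numeric(arrival[ok])
  fb <- factor(brood_id[ok])
  fy <- factor(year_id[ok])
  n <- length(y)
  q1 <- nlevels(fb); q2 <- nlevels(fy)
  if (q1 < 2) stop("need at least 2 broods")
  if (max(table(fb)) == 1)
    warning("every brood has a single individual: brood variance is ",
            "confounded with the residual (non-identifiable design)")

  # sparse-free crossed design: Z = [Z_brood | Z_year], q = q1 + q2 columns
  indmat <- function(f) {
    m <- matrix(0, length(f), nlevels(f))
    m[cbind(seq_along(f), as.integer(f))] <- 1
    m
  }
  Z <- cbind(indmat(fb), indmat(fy))
  q <- q1 + q2
  ZtZ <- crossprod(Z)
  i1 <- seq_len(q1); i2 <- q1 + seq_len(q2)

  v_tot <- var(y)
  s_b <- 0.2 * v_tot; s_y <- 0.1 * v_tot; s_e <- 0.7 * v_tot
  mu <- mean(y)
  floorv <- 1e-10 * v_tot
  ll_old <- -Inf
  trace <- numeric(0)
  # parameter-expanded EM (PX-EM): the M-step also maximises over scale
  # factors alpha_k on each random-effect block, which greatly accelerates
  # convergence when a component is weakly identified (e.g. few year levels)
  for (it in seq_len(max_iter)) {
    dinv <- c(rep(1 / s_b, q1), rep(1 / s_y, q2))
    M <- ZtZ / s_e
    diag(M) <- diag(M) + dinv
    R <- chol(M)
    Zty <- crossprod(Z, y - mu)
    bhat <- backsolve(R, forwardsolve(t(R), Zty / s_e))
    C <- chol2inv(R)                     # conditional covariance of (b, u)
    # log-likelihood of y ~ N(mu, s_e I + Z D Z') via the Woodbury identity
    quad <- sum((y - mu)^2) / s_e - as.numeric(crossprod(Zty / s_e, bhat))
    logdet <- n * log(s_e) + 2 * sum(log(diag(R))) - sum(log(dinv))
    ll <- -0.5 * (n * log(2 * pi) + logdet + quad)
    trace <- c(trace, ll)

    # E-step moments: E[b_k' (Z'Z)_kl b_l] and E[b_k' Z_k'(y - mu)]
    EbZZb <- function(k, l)
      as.numeric(crossprod(bhat[k],
                           ZtZ[k, l, drop = FALSE] %*% bhat[l])) +
        sum(ZtZ[k, l, drop = FALSE] * C[k, l, drop = FALSE])
    A <- matrix(c(EbZZb(i1, i1), EbZZb(i1, i2),
                  EbZZb(i2, i1), EbZZb(i2, i2)), 2, 2)
    v <- c(as.numeric(crossprod(bhat[i1], Zty[i1])),
           as.numeric(crossprod(bhat[i2], Zty[i2])))
    alpha <- tryCatch(solve(A, v), error = function(e) c(1, 1))
    # PX M-step: usual component updates rescaled by the expansion factors
    s_b_star <- (sum(bhat[i1]^2) + sum(diag(C)[i1])) / q1
    s_y_star <- (sum(bhat[i2]^2) + sum(diag(C)[i2])) / q2
    s_b <- max(alpha[1]^2 * s_b_star, floorv)
    s_y <- max(alpha[2]^2 * s_y_star, floorv)
    s_e <- max((sum((y - mu)^2) - 2 * sum(alpha * v) +
                  as.numeric(crossprod(alpha, A %*% alpha))) / n, floorv)
    mu <- mean(y - Z[, i1, drop = FALSE] %*% (alpha[1] * bhat[i1]) -
                 Z[, i2, drop = FALSE] %*% (alpha[2] * bhat[i2]))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      ll_old <- ll
      break
    }
    ll_old <- ll
    if (it == max_iter)
      stop("EM did not converge in ", max_iter, " iterations; ",
           "last log-likelihood changes: ",
           paste(format(tail(diff(tail(trace, 6)), 5), digits = 3),
                 collapse = ", "))
  }
  s_b <- if (s_b <= 2 * floorv) 0 else s_b
  s_y <- if (s_y <= 2 * floorv) 0 else s_y
  tot <- s_b + s_y + s_e
  structure(list(var_brood = s_b, var_year = s_y, var_resid = s_e,
                 frac_brood = s_b / tot, frac_year = s_y / tot,
                 mu = mu, loglik = ll_old, n_used = n,
                 n_excluded = n_excluded, n_iter = it),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Crossed random-intercept variance components (EM, ", x$n_iter,
      " iterations, n = ", x$n_used, ")\n", sep = "")
  tab <- data.frame(
    variance = c(x$var_brood, x$var_year, x$var_resid),
    fraction = c(x$frac_brood, x$frac_year,
                 1 - x$frac_brood - x$frac_year),
    row.names = c("brood", "year", "residual"))
  print(round(tab, 4))
  invisible(x)
}
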