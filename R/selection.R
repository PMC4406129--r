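# Trait standardization, nonsocial/social selection gradient estimation, and
# the decomposition of total selection.

#' Standardize a trait to zero mean and unit variance
#'
#' Uses the population (divide-by-n) standard deviation so that the
#' phenotypic variance P of the standardized trait is exactly 1.
#'
#' @param values numeric vector (at least two distinct values); names are
#'   preserved.
#' @return standardized numeric vector with attribute `P = 1`.
#' @export
standardize <- function(values) {
  x <- as.numeric(values)
  n <- sum(!is.na(x))
  if (n < 2) stop("need at least 2 values to standardize")
  mu <- mean(x, na.rm = TRUE)
  s <- sqrt(sum((x - mu)^2, na.rm = TRUE) / n)
  if (s == 0) stop("cannot standardize a constant trait")
  z <- (x - mu) / s
  names(z) <- names(values)
  attr(z, "P") <- 1
  z
}

#' Estimate nonsocial and social selection gradients
#'
#' Fits `fitness ~ alpha + beta_N * z + beta_S * zbar`, where `z` is the
#' individual's own (standardized) trait and `zbar` the weighted mean trait
#' of its associates ([social_environment()]). With binary fitness
#' (territory acquired or not) a binomial error distribution with logit link
#' is used; the gaussian option regresses relative fitness (w / mean(w))
#' with an identity link, the classical linear selection-gradient model.
#' Individuals with undefined `zbar` (network isolates) are excluded and
#' counted.
#'
#' @param fitness numeric vector; 0/1 under `family = "binomial"`.
#' @param z standardized own-trait values.
#' @param zbar weighted mean associate trait (NA = isolate).
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @return object of class `selection_gradients`: list with `beta_N`,
#'   `beta_S`, `alpha`, `se_N`, `se_S`, `p_N`, `p_S`, `n_used`,
#'   `n_excluded`, `family`, `converged`, `separation` and the underlying
#'   `fit`.
#' @export
fit_gradients <- function(fitness, z, zbar,
                          family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  stopifnot(length(fitness) == length(z), length(z) == length(zbar))
  ok <- !is.na(fitness) & !is.na(z) & !is.na(zbar)
  n_excluded <- sum(!ok)
  w <- fitness[ok]; zi <- z[ok]; zb <- zbar[ok]
  if (length(w) < 3) stop("fewer than 3 usable individuals")
  if (family == "binomial" && !all(w %in% c(0, 1)))
    stop("binomial family requires binary (0/1) fitness")
  if (sd(zi) == 0 || sd(zb) == 0 || abs(cor(zi, zb)) > 0.999)
    stop("own trait and associate trait are (nearly) collinear")
  dat <- data.frame(w = w, z = zi, zbar = zb)
  separation <- FALSE
  if (family == "binomial") {
    fit <- glm(w ~ z + zbar, family = binomial(), data = dat,
               control = glm.control(epsilon = 1e-8, maxit = 100))
    mu <- fitted(fit)
    separation <- any(mu < 1e-8 | mu > 1 - 1e-8)
    if (separation)
      warning("fitted probabilities of 0 or 1: possible complete separation")
  } else {
    dat$w <- dat$w / mean(dat$w)        # relative fitness
    fit <- glm(w ~ z + zbar, family = gaussian(), data = dat)
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  pz <- 2 * pnorm(-abs(est / se))
  structure(list(beta_N = unname(est["z"]), beta_S = unname(est["zbar"]),
                 alpha = unname(est["(Intercept)"]),
                 se_N = unname(se["z"]), se_S = unname(se["zbar"]),
                 p_N = unname(pz["z"]), p_S = unname(pz["zbar"]),
                 n_used = length(w), n_excluded = n_excluded,
                 family = family, converged = fit$converged %||% TRUE,
                 separation = separation, fit = fit),
            class = "selection_gradients")
}

#' @export
print.selection_gradients <- function(x, ...) {
  cat("Selection gradients (", x$family, " fit, n = ", x$n_used, ", ",
      x$n_excluded, " isolate(s) excluded)\n", sep = "")
  tab <- data.frame(
    estimate = c(x$beta_N, x$beta_S),
    SE = c(x$se_N, x$se_S),
    p = c(x$p_N, x$p_S),
    row.names = c("beta_N (own trait)", "beta_S (associates)"))
  print(round(tab, 4))
  invisible(x)
}

#' Decompose total selection into nonsocial and social terms
#'
#' For a single standardized trait, total selection is
#' `s = P * beta_N + C^I * beta_S`, where `P` is the phenotypic variance
#' (1 after standardization), `C^I` the covariance of interacting phenotypes
#' (the network assortativity coefficient), and `beta_N`, `beta_S` the
#' nonsocial and social selection gradients. The social term shows how much
#' phenotypic assortment amplifies or offsets selection on the individual's
#' own trait.
#'
#' @param P phenotypic variance of the trait (1 when standardized).
#' @param C_I interaction covariance (assortativity coefficient).
#' @param beta_N nonsocial selection gradient.
#' @param beta_S social selection gradient.
#' @return object of class `selection_decomposition`: list with `P`, `C_I`,
#'   `beta_N`, `beta_S`, `term_nonsocial` (= P * beta_N), `term_social`
#'   (= C^I * beta_S) and `s_total` (their sum).
#' @export
decompose_selection <- function(P, C_I, beta_N, beta_S) {
  stopifnot(is.finite(P), is.finite(C_I), is.finite(beta_N),
            is.finite(beta_S))
  term_n <- P * beta_N
  term_s <- C_I * beta_S
  structure(list(P = P, C_I = C_I, beta_N = beta_N, beta_S = beta_S,
                 term_nonsocial = term_n, term_social = term_s,
                 s_total = term_n + term_s),
            class = "selection_decomposition")
}

#' @export
print.selection_decomposition <- function(x, ...) {
  cat("Selection decomposition  s = P*beta_N + C^I*beta_S\n",
      sprintf("  nonsocial  P*beta_N  = %.3f * %.3f = %.3f\n",
              x$P, x$beta_N, x$term_nonsocial),
      sprintf("  social     C^I*beta_S = %.3f * %.3f = %.3f\n",
              x$C_I, x$beta_S, x$term_social),
      sprintf("  total      s         = %.3f\n", x$s_total), sep = "")
  invisible(x)
}
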