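# Count-family probability machinery shared by the residual and simulation
# code.  All families are built from one base distribution g(y):
# negative binomial with mean mu and inverse dispersion theta
# (variance mu + mu^2/theta), or its Poisson limit theta = Inf.
# Probabilities are evaluated in log space and exponentiated at the
# interface so that large counts (10^5) and large means (10^4) stay finite.

check_count_params <- function(mu, theta) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("'mu' must be positive and finite", call. = FALSE)
  if (any(is.na(theta)) || any(theta <= 0))
    stop("'theta' must be positive (Inf gives the Poisson limit)", call. = FALSE)
  invisible(TRUE)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(TRUE)
}

check_counts <- function(y) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    stop("'y' must contain nonnegative integers", call. = FALSE)
  invisible(TRUE)
}

#' Base count distribution: PMF and CDF
#'
#' The base distribution \eqn{g(y)} underlying all six model families:
#' negative binomial with mean \eqn{\mu} and inverse dispersion
#' \eqn{\theta} (so that \eqn{V(y) = \mu + \mu^2/\theta}), or Poisson
#' with mean \eqn{\mu} when \code{theta = Inf}.
#'
#' @param y Vector of nonnegative integer counts.
#' @param q Vector of quantiles; values below 0 give probability 0.
#' @param mu Positive mean(s) of the base distribution.
#' @param theta Positive inverse dispersion; \code{Inf} selects the
#'   Poisson limit.  As \eqn{\theta \to \infty} the negative binomial
#'   converges to the Poisson.
#' @param log Return log probabilities?
#' @return `count_pmf`: probabilities \eqn{g(y)}; `count_cdf`:
#'   cumulative probabilities \eqn{G(q) = \sum_{j \le q} g(j)}.
#' @examples
#' count_pmf(0, mu = 2, theta = 3)     # (3/5)^3 = 0.216
#' count_cdf(-1, mu = 2, theta = 3)    # 0
#' @export
count_pmf <- function(y, mu, theta = Inf, log = FALSE) {
  check_counts(y)
  check_count_params(mu, theta)
  n <- max(length(y), length(mu), length(theta))
  y <- rep_len(y, n); mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  lp <- numeric(n)
  pois <- is.infinite(theta)
  lp[pois] <- stats::dpois(y[pois], lambda = mu[pois], log = TRUE)
  lp[!pois] <- stats::dnbinom(y[!pois], size = theta[!pois], mu = mu[!pois],
                              log = TRUE)
  if (log) lp else exp(lp)
}

#' @rdname count_pmf
#' @export
count_cdf <- function(q, mu, theta = Inf) {
  check_count_params(mu, theta)
  n <- max(length(q), length(mu), length(theta))
  q <- rep_len(q, n); mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  out <- numeric(n)
  pois <- is.infinite(theta)
  out[pois] <- stats::ppois(q[pois], lambda = mu[pois])
  out[!pois] <- stats::pnbinom(q[!pois], size = theta[!pois], mu = mu[!pois])
  out[q < 0] <- 0
  out
}

# log(1 - g(0)) computed on the log scale (stable for tiny and large mu)
log1m_g0 <- function(mu, theta) {
  n <- max(length(mu), length(theta))
  mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  out <- numeric(n)
  pois <- is.infinite(theta)
  out[pois] <- stats::ppois(0, lambda = mu[pois], lower.tail = FALSE,
                            log.p = TRUE)
  out[!pois] <- stats::pnbinom(0, size = theta[!pois], mu = mu[!pois],
                               lower.tail = FALSE, log.p = TRUE)
  out
}

#' Zero-inflated count distribution: PMF and CDF
#'
#' Mixture of a point mass at zero (structural zeros, mixture proportion
#' \code{p}) and the base count distribution \eqn{g} (which can itself
#' produce sampling zeros):
#' \deqn{f(y) = p\,I(y = 0) + (1 - p)\,g(y),}
#' \deqn{F(J) = p\,F_0(J) + (1 - p)\,G(J),}
#' where \eqn{F_0} is the CDF of the point mass at zero.
#'
#' @inheritParams count_pmf
#' @param p Structural-zero mixture proportion(s) in \eqn{[0, 1]}.
#' @return Probabilities.
#' @examples
#' zi_pmf(0, p = 0.3, mu = 2, theta = 3)   # 0.3 + 0.7 * 0.216
#' @export
zi_pmf <- function(y, p, mu, theta = Inf, log = FALSE) {
  check_prob(p, "p")
  g <- count_pmf(y, mu, theta)
  n <- length(g)
  p <- rep_len(p, n); y <- rep_len(y, n)
  out <- (1 - p) * g + p * (y == 0)
  if (log) base::log(out) else out
}

#' @rdname zi_pmf
#' @export
zi_cdf <- function(q, p, mu, theta = Inf) {
  check_prob(p, "p")
  G <- count_cdf(q, mu, theta)
  n <- length(G)
  p <- rep_len(p, n); q <- rep_len(q, n)
  p * (q >= 0) + (1 - p) * G
}

#' Zero-modified (hurdle) count distribution: PMF and CDF
#'
#' Two-part distribution in which the zero probability \eqn{\pi} is
#' modelled directly and positive counts follow the zero-truncated base
#' distribution:
#' \deqn{f(0) = \pi, \qquad f(y) = (1 - \pi)\,\frac{g(y)}{1 - g(0)}
#'   \quad (y > 0),}
#' \deqn{F(J) = \pi\,F_0(J) + (1 - \pi)\,\frac{G(J) - g(0)}{1 - g(0)}\,
#'   I(J > 0).}
#'
#' @inheritParams count_pmf
#' @param pi Zero probability(ies) in \eqn{[0, 1]}.
#' @return Probabilities.
#' @examples
#' zm_cdf(0, pi = 0.4, mu = 2, theta = 3)  # exactly pi
#' @export
zm_pmf <- function(y, pi, mu, theta = Inf, log = FALSE) {
  check_prob(pi, "pi")
  check_counts(y)
  check_count_params(mu, theta)
  n <- max(length(y), length(pi), length(mu), length(theta))
  y <- rep_len(y, n); pi <- rep_len(pi, n)
  mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  l1mg0 <- log1m_g0(mu, theta)
  if (any(l1mg0 == -Inf))
    stop("base distribution is degenerate at zero (g(0) is numerically 1)",
         call. = FALSE)
  ltrunc <- count_pmf(y, mu, theta, log = TRUE) - l1mg0
  out <- ifelse(y == 0, pi, (1 - pi) * exp(ltrunc))
  if (log) base::log(out) else out
}

#' @rdname zm_pmf
#' @export
zm_cdf <- function(q, pi, mu, theta = Inf) {
  check_prob(pi, "pi")
  check_count_params(mu, theta)
  n <- max(length(q), length(pi), length(mu), length(theta))
  q <- rep_len(q, n); pi <- rep_len(pi, n)
  mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  l1mg0 <- log1m_g0(mu, theta)
  if (any(l1mg0 == -Inf))
    stop("base distribution is degenerate at zero (g(0) is numerically 1)",
         call. = FALSE)
  G <- count_cdf(q, mu, theta)
  g0 <- count_pmf(0L, mu, theta)
  tail_part <- pmax(G - g0, 0) / exp(l1mg0)
  pi * (q >= 0) + (1 - pi) * tail_part * (q > 0)
}

#' Mean and variance of a fitted count family
#'
#' Per-observation mean and variance of the Poisson/negative-binomial
#' base distribution, optionally with zero inflation or zero
#' modification, as needed for Pearson residuals
#' \eqn{r_i = (y_i - \hat\mu_i)/\sqrt{\hat V(y_i)}}.
#'
#' Moments follow from the base moments \eqn{E_g = \mu},
#' \eqn{E_g[y^2] = V_g + \mu^2} with \eqn{V_g = \mu + \mu^2/\theta}
#' (\eqn{\mu^2/\theta = 0} in the Poisson limit):
#' zero inflation multiplies both raw moments by \eqn{1 - p};
#' zero modification multiplies them by \eqn{(1-\pi)/(1-g(0))} since the
#' zero cell contributes nothing to either raw moment.
#'
#' @inheritParams count_pmf
#' @param zero_prob Mixture proportion \eqn{p} (inflated) or zero
#'   probability \eqn{\pi} (modified); ignored for `zero_mode = "none"`.
#' @param zero_mode One of `"none"`, `"inflated"`, `"modified"`.
#' @return A list with numeric vectors `mean` and `var`.
#' @examples
#' dist_mean_var(mu = 4, theta = 2)  # mean 4, var 4 + 16/2 = 12
#' @export
dist_mean_var <- function(mu, theta = Inf, zero_prob = NULL,
                          zero_mode = c("none", "inflated", "modified")) {
  zero_mode <- match.arg(zero_mode)
  check_count_params(mu, theta)
  vb <- mu + mu^2 / theta   # mu^2/Inf = 0: the Poisson limit
  e2b <- vb + mu^2
  if (zero_mode == "none")
    return(list(mean = mu + numeric(length(mu)), var = vb))
  if (is.null(zero_prob))
    stop("'zero_prob' is required for zero-inflated/modified families",
         call. = FALSE)
  check_prob(zero_prob, "zero_prob")
  w <- if (zero_mode == "inflated") 1 - zero_prob
       else (1 - zero_prob) / exp(log1m_g0(mu, theta))
  m <- w * mu
  list(mean = m, var = w * e2b - m^2)
}
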