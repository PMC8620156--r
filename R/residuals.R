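# Randomized quantile residuals (Dunn-Smyth residuals) and Pearson
# residuals for fitted count mixed models.  For a discrete response the
# CDF tail probability is randomized uniformly across the probability
# step at the observed count,
#   F*(y_i) = F(y_i - 1) + u_i p(y_i),   u_i ~ U[0, 1],
# and mapped through the standard normal quantile function,
#   q_i = Phi^{-1}(F*(y_i)).
# Under the true model with the true parameters the q_i are exactly
# standard normal, so normality checks on them act as an overall
# goodness-of-fit test.  Residuals are conditional on the random-effect
# modes: mu_hat_i includes Z_i u_hat and the offset.

family_cdf <- function(q, mu, theta, zero, zero_mode) {
  switch(zero_mode,
         none = count_cdf(q, mu, theta),
         inflated = zi_cdf(q, zero, mu, theta),
         modified = zm_cdf(q, zero, mu, theta))
}

family_pmf <- function(y, mu, theta, zero, zero_mode) {
  switch(zero_mode,
         none = count_pmf(y, mu, theta),
         inflated = zi_pmf(y, zero, mu, theta),
         modified = zm_pmf(y, zero, mu, theta))
}

#' Randomized tail probability for a discrete count family
#'
#' \eqn{F^*(y) = F(y - 1) + u\,p(y)} with \eqn{F(-1) = 0}, using the
#' family-appropriate CDF/PMF (zero-inflated, zero-modified, or the
#' base distribution).  Non-decreasing in `u`, with
#' \eqn{F^*(y) \in [F(y-1), F(y)]}.
#'
#' @param y Nonnegative integer count(s).
#' @param u Uniform randomization value(s) in \eqn{[0, 1]}.
#' @param mu Base-distribution mean(s).
#' @param theta Inverse dispersion (`Inf` = Poisson).
#' @param zero_prob \eqn{p} (inflated) or \eqn{\pi} (modified).
#' @param zero_mode `"none"`, `"inflated"` or `"modified"`.
#' @return Tail probabilities in \eqn{[0, 1]}.
#' @export
randomized_tail_prob <- function(y, u, mu, theta = Inf, zero_prob = NULL,
                                 zero_mode = c("none", "inflated", "modified")) {
  zero_mode <- match.arg(zero_mode)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("'u' must lie in [0, 1]", call. = FALSE)
  check_counts(y)
  if (zero_mode != "none" && is.null(zero_prob))
    stop("'zero_prob' is required for zero-inflated/modified families",
         call. = FALSE)
  a <- family_cdf(y - 1, mu, theta, zero_prob, zero_mode)
  p <- family_pmf(y, mu, theta, zero_prob, zero_mode)
  pmin(a + u * p, 1)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Randomized quantile residuals of a fitted model
#'
#' Draws independent \eqn{u_i \sim U[0,1]}, computes the randomized
#' tail probabilities at the fitted \eqn{(\hat\mu_i, \hat
#' p_i/\hat\pi_i, \hat\theta)}, clips them to
#' \eqn{[10^{-10}, 1 - 10^{-10}]} and returns
#' \eqn{q_i = \Phi^{-1}(F^*_i)}.  The same fit and seed give a
#' bit-identical result; the number of clipped values is recorded.
#'
#' @param fit A converged `rqr_fit` (see [fit_model()]).
#' @param seed Integer seed for the randomization draws (kept separate
#'   from any simulation stream), or `NULL` to use the current RNG
#'   state.
#' @param clip Clipping bound applied to \eqn{F^*} before the normal
#'   quantile transform.
#' @return An object of class `rqr_resid`: list with `values`, `kind
#'   = "rqr"`, the `u` draws, `seed` and `n_clipped`.
#' @export
rqr <- function(fit, seed = NULL, clip = 1e-10) {
  stopifnot(inherits(fit, "rqr_fit"))
  if (!isTRUE(fit$converged))
    stop("refusing to compute residuals for a non-converged fit",
         call. = FALSE)
  n <- length(fit$y)
  u <- with_seed(seed, stats::runif(n))
  fs <- randomized_tail_prob(fit$y, u, fit$mu_hat, fit$theta,
                             fit$zero_hat, fit$spec$zero_mode)
  clipped <- fs < clip | fs > 1 - clip
  fs <- pmin(pmax(fs, clip), 1 - clip)
  structure(list(values = stats::qnorm(fs), kind = "rqr", u = u,
                 seed = seed, n_clipped = sum(clipped)),
            class = "rqr_resid")
}

#' Pearson residuals of a fitted model
#'
#' \eqn{r_i = (y_i - \hat m_i)/\sqrt{\hat V(y_i)}} where \eqn{\hat m_i}
#' and \eqn{\hat V(y_i)} are the mean and variance of the observation's
#' fitted distribution (accounting for zero inflation/modification; see
#' [dist_mean_var()]).  Deterministic.  Included as the conventional
#' comparator: for count data Pearson residuals are not normal even
#' under the true model, so normality tests on them are uninformative.
#'
#' @inheritParams rqr
#' @return An object of class `rqr_resid` with `kind = "pearson"`.
#' @export
pearson_residuals <- function(fit) {
  stopifnot(inherits(fit, "rqr_fit"))
  if (!isTRUE(fit$converged))
    stop("refusing to compute residuals for a non-converged fit",
         call. = FALSE)
  # extreme zero-part linear predictors can push the fitted zero
  # probability to 1 within machine precision, collapsing the variance;
  # nudge it off the boundary so the residual stays defined (and huge,
  # which is the honest signal)
  zp <- pmin(pmax(fit$zero_hat, 1e-12), 1 - 1e-12)
  mv <- dist_mean_var(fit$mu_hat, fit$theta, zp, fit$spec$zero_mode)
  if (any(mv$var <= 0))
    stop("zero fitted variance: Pearson residual undefined", call. = FALSE)
  structure(list(values = (fit$y - mv$mean) / sqrt(mv$var),
                 kind = "pearson", seed = NULL),
            class = "rqr_resid")
}

#' @export
print.rqr_resid <- function(x, ...) {
  cat(sprintf("<rqr_resid> %s residuals, n = %d\n", x$kind,
              length(x$values)))
  print(summary(x$values))
  invisible(x)
}

#' Export residuals as a two-column data.frame
#'
#' @param x An `rqr_resid`.
#' @param ... Unused.
#' @return data.frame with columns `observation` and `residual`.
#' @export
as.data.frame.rqr_resid <- function(x, ...) {
  data.frame(observation = seq_along(x$values), residual = x$values)
}
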