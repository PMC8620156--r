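# Overall goodness-of-fit testing on residual vectors.  The working
# test is Shapiro-Wilk normality: randomized quantile residuals of an
# adequate model are standard normal, so SW p-values are uniform under
# the true model and small under misspecification.

#' Shapiro-Wilk normality test on a residual vector
#'
#' @param values Numeric vector, \eqn{3 \le n \le 5000}, all finite.
#' @param kind Label for the residual kind tested (metadata only).
#' @return A `gof_result`: list with `W`, `p_value`, `n`, `kind`.
#' @export
sw_test <- function(values, kind = "rqr") {
  if (inherits(values, "rqr_resid")) {
    kind <- values$kind
    values <- values$values
  }
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (any(!is.finite(values)))
    stop("residual vector contains non-finite values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant residual vector: test degenerate", call. = FALSE)
  sw <- stats::shapiro.test(values)
  structure(list(W = unname(sw$statistic), p_value = sw$p.value,
                 n = n, kind = kind),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> Shapiro-Wilk on %s residuals: W = %.4f, p = %.4g (n = %d)\n",
              x$kind, x$W, x$p_value, x$n))
  invisible(x)
}

#' Mean Shapiro-Wilk p-value over replicated RQR draws
#'
#' Randomized quantile residuals carry randomization noise; for applied
#' model checking the SW p-value is therefore averaged over independent
#' replications of the residual draw (default 100).
#'
#' @param fit A converged `rqr_fit`.
#' @param reps Number of independent RQR replications.
#' @param seed Integer seed governing all replications (replication
#'   `k` uses a sub-seed derived from it), or `NULL`.
#' @return The mean p-value (scalar) with attribute `"p_values"`.
#' @export
replicated_sw_p <- function(fit, reps = 100, seed = NULL) {
  stopifnot(reps >= 1)
  seeds <- if (is.null(seed)) vector("list", reps)
           else as.list((seed + seq_len(reps) * 7919L) %% .Machine$integer.max)
  p <- vapply(seeds, function(s) sw_test(rqr(fit, seed = s))$p_value,
              numeric(1))
  structure(mean(p), p_values = p)
}

#' Rejection rate of a set of p-values
#'
#' Fraction of p-values strictly below `alpha`.  Applied to SW p-values
#' of the true model this estimates the type-I error of the GOF test;
#' applied to a misspecified model it estimates power.
#'
#' @param p_values Numeric vector of p-values in \eqn{[0, 1]};
#'   `NA` entries (non-converged fits) are dropped.
#' @param alpha Significance level.
#' @return List with `rejection_rate`, `n_converged`, `alpha`.
#' @export
rejection_rate <- function(p_values, alpha = 0.05) {
  p <- p_values[!is.na(p_values)]
  if (!length(p))
    stop("no p-values (no converged fits?)", call. = FALSE)
  check_prob(p, "p_values")
  list(rejection_rate = mean(p < alpha), n_converged = length(p),
       alpha = alpha)
}
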