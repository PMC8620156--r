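# Maximum-likelihood fitting of the six mixed-effects count models:
# Poisson, NB, and their zero-inflated (ZIP, ZINB) and zero-modified /
# hurdle (ZMP, ZMNB) versions, with a log link for the count mean
# (plus a log total-reads offset) and a logit link for the zero part.
# Random effects are Gaussian with an independent variance per grouping
# factor per model part, integrated out by the Laplace approximation.
# Estimation is delegated to glmmTMB; the surrounding code normalises
# the model specification, extracts per-observation fitted components
# and applies the convergence filter used by the study runner.

#' Specify a count mixed model
#'
#' @param family `"poisson"` or `"nbinom"` (negative binomial with
#'   inverse dispersion \eqn{\theta}).
#' @param zero_mode `"none"` (plain count model), `"inflated"`
#'   (mixture of a structural-zero point mass with proportion
#'   \eqn{p_i} and the full count distribution) or `"modified"`
#'   (hurdle: zero probability \eqn{\pi_i} modelled directly, positive
#'   counts zero-truncated).
#' @param zi_random Include the grouping factors as random effects in
#'   the zero part as well as the count part?  The zero part always
#'   shares the fixed-effect covariates of the count part.
#' @param use_offset Include `log(total reads)` as an offset in the
#'   count linear predictor?
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("poisson", "nbinom"),
                       zero_mode = c("none", "inflated", "modified"),
                       zi_random = TRUE, use_offset = TRUE) {
  structure(list(family = match.arg(family), zero_mode = match.arg(zero_mode),
                 zi_random = isTRUE(zi_random), use_offset = isTRUE(use_offset)),
            class = "model_spec")
}

#' @rdname model_spec
#' @param name Canonical model name: one of `"Poisson"`, `"NB"`,
#'   `"ZIP"`, `"ZINB"`, `"ZMP"`, `"ZMNB"` (case-insensitive).
#' @param ... Passed on to [model_spec()].
#' @export
model_spec_by_name <- function(name, ...) {
  key <- toupper(name)
  tab <- list(POISSON = c("poisson", "none"), NB   = c("nbinom", "none"),
              ZIP     = c("poisson", "inflated"), ZINB = c("nbinom", "inflated"),
              ZMP     = c("poisson", "modified"), ZMNB = c("nbinom", "modified"))
  if (is.null(tab[[key]]))
    stop("unknown model name: ", name, call. = FALSE)
  spec <- model_spec(tab[[key]][1], tab[[key]][2], ...)
  spec$name <- key
  spec
}

spec_label <- function(spec) {
  if (!is.null(spec$name)) return(spec$name)
  paste0(switch(spec$zero_mode, none = "", inflated = "ZI", modified = "ZM"),
         if (spec$family == "poisson") "P" else "NB")
}

model_formulas <- function(table, spec) {
  roles <- ot_roles(table)
  fixed_terms <- if (length(roles$fixed)) roles$fixed else "1"
  rand_terms <- sprintf("(1 | %s)", roles$random)
  rhs <- paste(c(fixed_terms, rand_terms), collapse = " + ")
  if (spec$use_offset && !is.null(roles$offset))
    rhs <- paste0(rhs, sprintf(" + offset(log(%s))", roles$offset))
  count_formula <- stats::as.formula(paste(roles$count, "~", rhs))
  zi_formula <- if (spec$zero_mode == "none") ~0 else {
    zi_rhs <- paste(c(fixed_terms, if (spec$zi_random) rand_terms),
                    collapse = " + ")
    stats::as.formula(paste("~", zi_rhs))
  }
  list(count = count_formula, zi = zi_formula)
}

#' Fit a count mixed model by maximum likelihood
#'
#' Fits the model described by `spec` to an [observation_table()] using
#' the Laplace approximation for the Gaussian random effects (via
#' \pkg{glmmTMB}), then extracts the per-observation fitted components
#' needed for residual diagnostics: \eqn{\hat\mu_i}, the mean of the
#' base count distribution including the offset and the conditional
#' modes of the random effects, and \eqn{\hat p_i} (zero-inflated) or
#' \eqn{\hat\pi_i} (hurdle).
#'
#' A fit is flagged as converged only when the optimizer reports
#' success, the Hessian for the top-level parameters is positive
#' definite, the log-likelihood is finite and, for negative-binomial
#' families, \eqn{|\log\hat\theta| \le 15}.  The \eqn{\theta} bound
#' flags fits that are running off to the Poisson limit — the familiar
#' failure mode when an NB model is fitted to equidispersed data — and
#' non-converged fits are excluded from downstream rejection-rate
#' denominators.
#'
#' @param table An [observation_table()].
#' @param spec A [model_spec()].
#' @param theta_bound Convergence bound on \eqn{|\log\hat\theta|}.
#' @return An object of class `rqr_fit` with elements `y`, `mu_hat`,
#'   `zero_hat`, `theta`, `beta`, `beta_zero`, `re_sd`, `re_modes`,
#'   `loglik`, `aic`, `n_params`, `converged`, `spec` and the
#'   underlying glmmTMB `fit`.
#' @export
fit_model <- function(table, spec, theta_bound = 15) {
  stopifnot(inherits(spec, "model_spec"))
  if (!inherits(table, "observation_table"))
    stop("'table' must be an observation_table", call. = FALSE)
  roles <- ot_roles(table)
  y <- table[[roles$count]]
  if (all(y == 0) && spec$zero_mode == "none")
    stop("all counts are zero: a plain count model is degenerate",
         call. = FALSE)
  fam <- switch(paste(spec$family, spec$zero_mode),
                "poisson none" = stats::poisson(),
                "poisson inflated" = stats::poisson(),
                "poisson modified" = glmmTMB::truncated_poisson(),
                "nbinom none" = glmmTMB::nbinom2(),
                "nbinom inflated" = glmmTMB::nbinom2(),
                "nbinom modified" = glmmTMB::truncated_nbinom2())
  fml <- model_formulas(table, spec)
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch(
      glmmTMB::glmmTMB(fml$count, ziformula = fml$zi, family = fam,
                       data = as.data.frame(table)),
      error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  out <- list(spec = spec, table = table, messages = msgs,
              converged = FALSE, fit = NULL)
  class(out) <- "rqr_fit"
  if (inherits(fit, "error")) {
    out$messages <- c(out$messages, conditionMessage(fit))
    return(out)
  }
  out$fit <- fit
  out$y <- y
  ll <- tryCatch(as.numeric(stats::logLik(fit)), error = function(e) NA_real_)
  out$loglik <- ll
  out$n_params <- tryCatch(attr(stats::logLik(fit), "df"),
                           error = function(e) NA_integer_)
  out$aic <- -2 * ll + 2 * out$n_params
  out$theta <- if (spec$family == "nbinom")
    tryCatch(stats::sigma(fit), error = function(e) NA_real_) else Inf
  mu <- tryCatch(exp(stats::predict(fit, type = "link")),
                 error = function(e) rep(NA_real_, length(y)))
  zh <- if (spec$zero_mode == "none") rep(0, length(y)) else
    tryCatch(stats::predict(fit, type = "zprob"),
             error = function(e) rep(NA_real_, length(y)))
  out$mu_hat <- mu
  out$zero_hat <- zh
  out$beta <- glmmTMB::fixef(fit)$cond
  out$beta_zero <- glmmTMB::fixef(fit)$zi
  vc <- glmmTMB::VarCorr(fit)
  out$re_sd <- lapply(vc, function(part)
    vapply(part, function(m) attr(m, "stddev"), numeric(1)))
  out$re_modes <- tryCatch(suppressWarnings(glmmTMB::ranef(fit)),
                           error = function(e) NULL)
  opt_ok <- isTRUE(fit$fit$convergence == 0)
  pd_ok <- isTRUE(fit$sdr$pdHess)
  theta_ok <- spec$family == "poisson" ||
    (is.finite(out$theta) && abs(log(out$theta)) <= theta_bound)
  out$converged <- opt_ok && pd_ok && theta_ok && is.finite(ll) &&
    all(is.finite(mu)) && all(is.finite(zh))
  out
}

#' @export
print.rqr_fit <- function(x, ...) {
  cat(sprintf("<rqr_fit> %s model, n = %d, converged: %s\n",
              spec_label(x$spec),
              if (is.null(x$y)) nrow(x$table) else length(x$y),
              x$converged))
  if (!is.null(x$loglik) && is.finite(x$loglik))
    cat(sprintf("  logLik = %.3f, AIC = %.3f (%d parameters)\n",
                x$loglik, x$aic, x$n_params))
  if (is.finite(x$theta)) cat(sprintf("  theta = %.4f\n", x$theta))
  if (length(x$messages))
    cat("  notes:", paste(unique(x$messages), collapse = "; "), "\n")
  invisible(x)
}

#' Recompute fitted components from a fit
#'
#' Returns the per-observation mean of the base count distribution
#' \eqn{\hat\mu_i = \exp(\mathrm{offset}_i + X_i\hat\beta + Z_i\hat u)}
#' (conditional on the random-effect modes) and the fitted zero
#' probability \eqn{\hat p_i} / \eqn{\hat\pi_i}, recomputed from the
#' stored model object.
#'
#' @param fit A converged `rqr_fit`.
#' @return A list with `mu` and `zero`.
#' @export
predict_components <- function(fit) {
  stopifnot(inherits(fit, "rqr_fit"))
  if (is.null(fit$fit)) stop("fit failed; no components", call. = FALSE)
  mu <- exp(stats::predict(fit$fit, type = "link"))
  zero <- if (fit$spec$zero_mode == "none") rep(0, length(mu)) else
    stats::predict(fit$fit, type = "zprob")
  list(mu = mu, zero = zero)
}
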