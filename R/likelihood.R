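# Explicit likelihood machinery for the six model families.  fit_model()
# estimates via glmmTMB/TMB; the functions here give an independent,
# transparent route to the same objective — a joint negative
# log-likelihood over (parameters, random effects), its Laplace-
# approximate marginal, and an adaptive Gauss-Hermite marginal for the
# one-grouping-factor case — used for verification and for inspecting
# fitted objectives.

#' Build fixed- and random-effect design matrices
#'
#' Dummy-codes the fixed-effect factors (treatment contrasts, reference
#' level = lexicographically first level) with an intercept, and builds
#' one 0/1 indicator matrix per grouping factor.  The column-to-level
#' mapping is recorded so coefficients are comparable across runs.
#'
#' @param table An [observation_table()].
#' @param spec A [model_spec()].
#' @return A list with response `y`, fixed design `X` (shared by count
#'   and zero parts), indicator matrices `Z` (count part) and `Zz`
#'   (zero part; empty when `zi_random = FALSE`), `offset` (log total
#'   reads, or zeros) and `levels` (the level mapping).
#' @export
build_design <- function(table, spec) {
  roles <- ot_roles(table)
  for (f in roles$random)
    if (nlevels(factor(table[[f]])) < 2)
      stop(sprintf("grouping factor '%s' has a single level", f),
           call. = FALSE)
  fml <- if (length(roles$fixed))
    stats::as.formula(paste("~", paste(roles$fixed, collapse = " + ")))
  else ~1
  X <- stats::model.matrix(fml, data = as.data.frame(table))
  Z <- lapply(roles$random, function(f) {
    g <- factor(table[[f]])
    m <- stats::model.matrix(~ 0 + g)
    colnames(m) <- levels(g)
    m
  })
  names(Z) <- roles$random
  off <- if (spec$use_offset && !is.null(roles$offset))
    log(table[[roles$offset]]) else numeric(nrow(table))
  list(y = table[[roles$count]], X = X, Z = Z,
       Zz = if (spec$zero_mode != "none" && spec$zi_random) Z else
         stats::setNames(list(), character()),
       offset = off,
       levels = lapply(as.data.frame(table)[c(roles$fixed, roles$random)],
                       function(col) levels(factor(col))))
}

observation_loglik <- function(y, mu, zero, spec, log_theta = NULL) {
  theta <- if (spec$family == "nbinom") exp(log_theta) else Inf
  switch(spec$zero_mode,
         none = count_pmf(y, mu, theta, log = TRUE),
         inflated = zi_pmf(y, zero, mu, theta, log = TRUE),
         modified = zm_pmf(y, zero, mu, theta, log = TRUE))
}

linear_predictors <- function(params, re_values, design, spec) {
  eta <- design$offset + drop(design$X %*% params$beta)
  for (f in names(design$Z))
    eta <- eta + drop(design$Z[[f]] %*% re_values$count[[f]])
  etaz <- NULL
  if (spec$zero_mode != "none") {
    etaz <- drop(design$X %*% params$beta_zero)
    for (f in names(design$Zz))
      etaz <- etaz + drop(design$Zz[[f]] %*% re_values$zero[[f]])
  }
  list(mu = exp(eta), zero = if (is.null(etaz)) NULL else stats::plogis(etaz))
}

#' Joint negative log-likelihood of data and random effects
#'
#' \eqn{-\sum_i \log f(y_i \mid u, \tilde u) - \log N(u; 0, \Sigma)
#' - \log N(\tilde u; 0, \tilde\Sigma)} with diagonal \eqn{\Sigma}:
#' one variance per grouping factor per model part.
#'
#' @param params List with `beta` (count fixed effects, intercept
#'   first), `beta_zero` (zero-part fixed effects; required unless
#'   `zero_mode = "none"`), `log_theta` (NB only), `log_sd` and
#'   `log_sd_zero` (named per grouping factor).
#' @param re_values List with `count` and `zero`, each a named list of
#'   per-level random-effect values per grouping factor.
#' @param design Output of [build_design()].
#' @param spec A [model_spec()].
#' @return The joint negative log-likelihood (a scalar).
#' @export
joint_nll <- function(params, re_values, design, spec) {
  lp <- linear_predictors(params, re_values, design, spec)
  if (any(!is.finite(lp$mu)))
    stop("non-finite linear predictor", call. = FALSE)
  ll <- sum(observation_loglik(design$y, lp$mu, lp$zero, spec,
                               params$log_theta))
  prior <- 0
  for (f in names(design$Z))
    prior <- prior + sum(stats::dnorm(re_values$count[[f]], 0,
                                      exp(params$log_sd[[f]]), log = TRUE))
  for (f in names(design$Zz))
    prior <- prior + sum(stats::dnorm(re_values$zero[[f]], 0,
                                      exp(params$log_sd_zero[[f]]), log = TRUE))
  -(ll + prior)
}

re_template <- function(design, spec) {
  list(count = lapply(design$Z, function(m) numeric(ncol(m))),
       zero = lapply(design$Zz, function(m) numeric(ncol(m))))
}

re_unflatten <- function(v, template) {
  out <- template
  i <- 0
  for (part in c("count", "zero")) for (f in names(template[[part]])) {
    k <- length(template[[part]][[f]])
    out[[part]][[f]] <- v[i + seq_len(k)]
    i <- i + k
  }
  out
}

re_length <- function(template)
  sum(lengths(template$count)) + sum(lengths(template$zero))

#' Laplace-approximate marginal negative log-likelihood
#'
#' Optimizes the joint negative log-likelihood over the random effects
#' (inner Newton-type optimization) and applies the Laplace correction
#' \eqn{\mathrm{nll}(\hat u) + \tfrac12 \log\det H - \tfrac q2
#' \log 2\pi}, where \eqn{H} is the inner Hessian at the mode and
#' \eqn{q} the number of random effects.  Deterministic given `params`.
#'
#' @inheritParams joint_nll
#' @param max_iter Inner optimization iteration cap.
#' @return The marginal negative log-likelihood (a scalar), with
#'   attribute `"inner_converged"`.
#' @export
laplace_marginal_nll <- function(params, design, spec, max_iter = 200) {
  template <- re_template(design, spec)
  q <- re_length(template)
  obj <- function(v) joint_nll(params, re_unflatten(v, template), design, spec)
  if (q == 0) return(structure(obj(numeric(0)), inner_converged = TRUE))
  inner <- stats::nlminb(numeric(q), obj,
                         control = list(iter.max = max_iter))
  H <- stats::optimHess(inner$par, obj)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ok <- inner$convergence == 0 && all(ev > 0)
  val <- inner$objective + 0.5 * sum(log(ev)) - 0.5 * q * log(2 * pi)
  structure(val, inner_converged = ok)
}

gauss_hermite <- function(k) {
  # Golub-Welsch: nodes/weights for integr. against exp(-x^2)
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Adaptive Gauss-Hermite marginal negative log-likelihood
#'
#' Quadrature-based marginal likelihood for models with exactly one
#' grouping factor (count part; plus the same factor in the zero part
#' if present with `zi_random = TRUE`).  Because groups are
#' independent, the marginal likelihood factorizes over levels and each
#' level needs only a low-dimensional integral: 1-d for
#' `zero_mode = "none"` or `zi_random = FALSE`, 2-d otherwise.  Each
#' integral is centred and scaled at its own mode (adaptive rule).
#' Used as a high-accuracy check of [laplace_marginal_nll()].
#'
#' @inheritParams joint_nll
#' @param k Number of quadrature points per dimension.
#' @return The marginal negative log-likelihood (a scalar).
#' @export
aghq_marginal_nll <- function(params, design, spec, k = 20) {
  if (length(design$Z) != 1)
    stop("quadrature oracle supports exactly one grouping factor",
         call. = FALSE)
  gh <- gauss_hermite(k)
  fac <- names(design$Z)
  lev <- colnames(design$Z[[fac]])
  has_zi_re <- length(design$Zz) > 0
  total <- 0
  for (l in seq_along(lev)) {
    idx <- design$Z[[fac]][, l] == 1
    sub <- list(y = design$y[idx], X = design$X[idx, , drop = FALSE],
                offset = design$offset[idx])
    dim_l <- if (has_zi_re) 2L else 1L
    nll_l <- function(v) {
      eta <- sub$offset + drop(sub$X %*% params$beta) + v[1]
      mu <- exp(eta)
      zero <- NULL
      if (spec$zero_mode != "none") {
        etaz <- drop(sub$X %*% params$beta_zero) + if (has_zi_re) v[2] else 0
        zero <- stats::plogis(etaz)
      }
      -(sum(observation_loglik(sub$y, mu, zero, spec, params$log_theta)) +
          stats::dnorm(v[1], 0, exp(params$log_sd[[fac]]), log = TRUE) +
          (if (has_zi_re)
            stats::dnorm(v[2], 0, exp(params$log_sd_zero[[fac]]), log = TRUE)
           else 0))
    }
    opt <- stats::nlminb(numeric(dim_l), nll_l)
    H <- stats::optimHess(opt$par, nll_l)
    if (dim_l == 1L) {
      s <- sqrt(1 / H[1, 1])
      x <- opt$par + sqrt(2) * s * gh$nodes
      lw <- log(gh$weights) + gh$nodes^2 + log(sqrt(2) * s)
      lv <- vapply(seq_along(x), function(j) -nll_l(x[j]), numeric(1)) + lw
    } else {
      # product rule over the 2-d grid, scaled by the mode's Cholesky
      L <- t(chol(solve(H)))
      grid <- as.matrix(expand.grid(a = gh$nodes, b = gh$nodes))
      pts <- t(opt$par + sqrt(2) * L %*% t(grid))
      lw <- log(outer(gh$weights, gh$weights))[cbind(
        match(grid[, 1], gh$nodes), match(grid[, 2], gh$nodes))] +
        rowSums(grid^2) + log(2 * det(L))
      lv <- vapply(seq_len(nrow(pts)), function(j) -nll_l(pts[j, ]),
                   numeric(1)) + lw
    }
    m <- max(lv)
    total <- total + (m + log(sum(exp(lv - m))))
  }
  -total
}
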