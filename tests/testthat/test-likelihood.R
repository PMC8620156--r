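# Design construction and the explicit likelihood route: reductions to
# known objectives, the hurdle factorization, and agreement between the
# Laplace marginal, adaptive Gauss-Hermite quadrature, and glmmTMB.

test_that("build_design dummy-codes fixed factors and indicators for groups", {
  tab <- toy_table()
  spec <- model_spec("poisson", "none")
  d <- build_design(tab, spec)
  expect_equal(ncol(d$X), 3)              # intercept + 2 dummies
  expect_equal(colnames(d$X)[1], "(Intercept)")
  Z <- d$Z$G1
  expect_equal(ncol(Z), 3)
  expect_true(all(rowSums(Z) == 1))
  # level mapping reconstructs the factor
  expect_equal(levels(factor(tab$G1)), d$levels$G1)
  expect_equal(colnames(Z)[apply(Z, 1, which.max)], as.character(tab$G1))
  # degenerate grouping factor refused
  bad <- tab
  bad$G1 <- factor("only")
  expect_error(build_design(observation_table(as.data.frame(bad),
                                              fixed = "F1", random = "G1"),
                            spec),
               "single level")
})

test_that("joint nll with zero random effects reduces to the fixed-effects nll", {
  tab <- toy_table(p_zero = 0)
  spec <- model_spec("poisson", "none")
  d <- build_design(tab, spec)
  par <- toy_params()
  re0 <- list(count = list(G1 = numeric(3)), zero = list())
  mu <- exp(d$offset + drop(d$X %*% par$beta))
  oracle <- -sum(dpois(d$y, mu, log = TRUE)) -
    sum(dnorm(numeric(3), 0, exp(par$log_sd$G1), log = TRUE))
  expect_equal(joint_nll(par, re0, d, spec), oracle)
})

test_that("hurdle joint nll factorizes into logistic and truncated-count parts", {
  tab <- toy_table()
  spec <- model_spec("nbinom", "modified")
  d <- build_design(tab, spec)
  par <- toy_params()
  re <- list(count = list(G1 = c(0.2, -0.1, 0.3)),
             zero = list(G1 = c(-0.3, 0.1, 0.2)))
  # oracle: two independent parts plus the two Gaussian priors
  eta <- d$offset + drop(d$X %*% par$beta) + drop(d$Z$G1 %*% re$count$G1)
  etaz <- drop(d$X %*% par$beta_zero) + drop(d$Z$G1 %*% re$zero$G1)
  pi <- plogis(etaz)
  mu <- exp(eta)
  th <- exp(par$log_theta)
  is0 <- d$y == 0
  nll_bin <- -sum(log(ifelse(is0, pi, 1 - pi)))
  ltrunc <- dnbinom(d$y[!is0], size = th, mu = mu[!is0], log = TRUE) -
    pnbinom(0, size = th, mu = mu[!is0], lower.tail = FALSE, log.p = TRUE)
  nll_count <- -sum(ltrunc)
  nll_prior <- -sum(dnorm(re$count$G1, 0, exp(par$log_sd$G1), log = TRUE)) -
    sum(dnorm(re$zero$G1, 0, exp(par$log_sd_zero$G1), log = TRUE))
  expect_equal(joint_nll(par, re, d, spec), nll_bin + nll_count + nll_prior,
               tolerance = 1e-10)
})

test_that("perturbing a coefficient moves the joint nll like a finite difference", {
  tab <- toy_table()
  spec <- model_spec("nbinom", "inflated")
  d <- build_design(tab, spec)
  par <- toy_params()
  re <- list(count = list(G1 = c(0.2, -0.1, 0.3)),
             zero = list(G1 = c(-0.3, 0.1, 0.2)))
  delta <- 1e-5
  for (j in 1:3) {
    up <- par; up$beta[j] <- up$beta[j] + delta
    dn <- par; dn$beta[j] <- dn$beta[j] - delta
    grad_fd <- (joint_nll(up, re, d, spec) - joint_nll(dn, re, d, spec)) /
      (2 * delta)
    # central difference at half the step agrees to O(delta^2)
    up2 <- par; up2$beta[j] <- up2$beta[j] + delta / 2
    dn2 <- par; dn2$beta[j] <- dn2$beta[j] - delta / 2
    grad_fd2 <- (joint_nll(up2, re, d, spec) - joint_nll(dn2, re, d, spec)) /
      delta
    expect_equal(grad_fd, grad_fd2, tolerance = 1e-4)
  }
})

test_that("Laplace marginal nll approaches the fixed-effects nll as re_sd -> 0", {
  tab <- toy_table(p_zero = 0)
  spec <- model_spec("poisson", "none")
  d <- build_design(tab, spec)
  par <- toy_params()
  par$log_sd$G1 <- log(1e-5)
  mu <- exp(d$offset + drop(d$X %*% par$beta))
  fixed_nll <- -sum(dpois(d$y, mu, log = TRUE))
  lap <- laplace_marginal_nll(par, d, spec)
  expect_lt(abs(as.numeric(lap) - fixed_nll), 1e-3)
})

test_that("Laplace marginal agrees with 20-point adaptive quadrature", {
  tab <- toy_table(p_zero = 0)
  par <- toy_params()
  spec <- model_spec("poisson", "none")
  d <- build_design(tab, spec)
  lap <- laplace_marginal_nll(par, d, spec)
  agh <- aghq_marginal_nll(par, d, spec, k = 20)
  expect_lt(abs(as.numeric(lap) - agh), 1e-3)
  # and for a zero-inflated model with random effects in both parts
  # (2-d integrals per level); the zero part carries limited information
  # per observation, so its RE scale is kept small for the comparison
  tab2 <- toy_table(n = 300, seed = 12, p_zero = 0.3)
  spec2 <- model_spec("poisson", "inflated")
  d2 <- build_design(tab2, spec2)
  par2 <- toy_params(); par2$log_sd_zero$G1 <- log(0.1)
  lap2 <- laplace_marginal_nll(par2, d2, spec2)
  agh2 <- aghq_marginal_nll(par2, d2, spec2, k = 20)
  expect_lt(abs(as.numeric(lap2) - agh2), 1e-3)
})

test_that("in-package Laplace marginal matches glmmTMB's marginal likelihood", {
  f <- shared_fit()   # converged ZMNB fit
  spec <- f$spec
  tab <- f$table
  d <- build_design(tab, spec)
  vc_sd <- f$re_sd
  par <- list(beta = unname(f$beta), beta_zero = unname(f$beta_zero),
              log_theta = log(f$theta),
              log_sd = as.list(log(pmax(vc_sd$cond, 1e-8))),
              log_sd_zero = as.list(log(pmax(vc_sd$zi, 1e-8))))
  names(par$log_sd) <- names(d$Z)
  names(par$log_sd_zero) <- names(d$Z)
  lap <- laplace_marginal_nll(par, d, spec)
  expect_lt(abs(as.numeric(lap) - (-f$loglik)), 1e-2)
})

test_that("marginal nll at the MLE is no worse than at the truth", {
  f <- shared_fit()
  tab <- f$table
  truth <- attr(tab, "truth")
  spec <- f$spec
  d <- build_design(tab, spec)
  # truth on the design scale: intercept absorbs reference-level coefs
  coefs <- truth$coefs
  to_design <- function(part) {
    b0 <- part$beta0 + sum(vapply(part$fixed, `[`, numeric(1), 1))
    contrasts <- unlist(lapply(part$fixed, function(b) b[-1] - b[1]))
    c(b0, contrasts)
  }
  par_true <- list(beta = to_design(coefs$count),
                   beta_zero = to_design(coefs$zero),
                   log_theta = log(coefs$theta),
                   log_sd = stats::setNames(
                     lapply(coefs$count$random, function(u) log(2)),
                     names(d$Z)),
                   log_sd_zero = stats::setNames(
                     lapply(coefs$zero$random, function(u) log(2)),
                     names(d$Z)))
  par_mle <- list(beta = unname(f$beta), beta_zero = unname(f$beta_zero),
                  log_theta = log(f$theta),
                  log_sd = stats::setNames(
                    as.list(log(pmax(f$re_sd$cond, 1e-8))), names(d$Z)),
                  log_sd_zero = stats::setNames(
                    as.list(log(pmax(f$re_sd$zi, 1e-8))), names(d$Z)))
  expect_gte(as.numeric(laplace_marginal_nll(par_true, d, spec)) + 1e-6,
             as.numeric(laplace_marginal_nll(par_mle, d, spec)))
})
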