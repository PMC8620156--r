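# The data generator: scenario definitions, coefficient draws,
# dataset structure, truncation contract, summaries and the study
# runner's bookkeeping.

test_that("scenario intercepts follow the four-scenario design", {
  expect_equal(simulation_scenario(1, "nbinom")$beta0_zero, 3.5)
  expect_equal(simulation_scenario(3, "nbinom")$beta0_zero, -5.5)
  expect_equal(simulation_scenario(1, "nbinom")$beta0_count, -5.5)
  expect_equal(simulation_scenario(1, "poisson")$beta0_count, -5.7)
  expect_equal(simulation_scenario(2, "nbinom")$beta0_count, -7.8)
  expect_equal(simulation_scenario(4, "poisson")$beta0_count, -8)
  scn <- simulation_scenario(1)
  expect_equal(scn$n_fixed, 3L); expect_equal(scn$levels_fixed, 3L)
  expect_equal(scn$n_random, 2L); expect_equal(scn$levels_random, 2L)
  expect_error(simulation_scenario(5), "scenario")
})

test_that("coefficient draws have the stated spread and are reproducible", {
  scn <- simulation_scenario(1, "nbinom")
  set.seed(10); c1 <- draw_coefficients(scn)
  set.seed(10); c2 <- draw_coefficients(scn)
  expect_identical(c1, c2)
  expect_length(c1$count$fixed, 3)
  expect_length(c1$count$fixed[[1]], 3)
  expect_length(c1$zero$random, 2)
  expect_length(c1$zero$random[[1]], 2)
  set.seed(4)
  fx <- replicate(4000, draw_coefficients(scn)$count$fixed[[1]][1])
  expect_gt(sd(fx), 0.095); expect_lt(sd(fx), 0.105)
  th <- replicate(500, draw_coefficients(scn)$theta)
  expect_true(all(th > 2 & th < 3))
  expect_true(is.infinite(draw_coefficients(simulation_scenario(1, "poisson"))$theta))
})

test_that("simulated datasets honour the generating contracts", {
  scn <- simulation_scenario(1, "nbinom", "modified", n = 300)
  tab <- simulate_dataset(scn, seed = 5)
  expect_s3_class(tab, "observation_table")
  expect_named(as.data.frame(tab), c("y", "total_reads", "F1", "F2", "F3",
                                     "G1", "G2"))
  truth <- attr(tab, "truth")
  # hurdle truth: every count with H = 1 is >= 1, every H = 0 is exactly 0
  expect_true(all(tab$y[truth$H == 1] >= 1))
  expect_true(all(tab$y[truth$H == 0] == 0))
  # same seed, same dataset
  expect_identical(as.data.frame(simulate_dataset(scn, seed = 5)),
                   as.data.frame(tab))
  # total reads near the stated sequencing depth
  expect_lt(abs(mean(tab$total_reads) / 3e5 - 1), 0.01)
})

test_that("structural-zero probability follows the logistic model", {
  scn <- simulation_scenario(1, "nbinom", "inflated", n = 2000)
  coefs <- draw_coefficients(scn)
  # force all zero-part terms except the intercept to zero
  coefs$zero$fixed <- lapply(coefs$zero$fixed, function(b) b * 0)
  coefs$zero$random <- lapply(coefs$zero$random, function(u) u * 0)
  tab <- simulate_dataset(scn, coefs = coefs, seed = 17)
  truth <- attr(tab, "truth")
  expect_equal(unique(truth$p), plogis(3.5))
  # empirical structural-zero fraction close to logistic(3.5) ~ 0.9707
  expect_lt(abs(mean(truth$H == 0) - plogis(3.5)), 0.02)
})

test_that("scenario ordering: high-ZP scenarios have more zeros", {
  zp <- function(scenario) {
    scn <- simulation_scenario(scenario, "nbinom", "modified", n = 200)
    mean(vapply(1:25, function(s)
      mean(simulate_dataset(scn, seed = 600 + s)$y == 0), numeric(1)))
  }
  expect_gt(zp(1), zp(3) + 0.2)
})

test_that("replicate summaries average ZP and non-zero quantiles", {
  t1 <- data.frame(y = c(0, 0, 1, 5, 10))
  t2 <- data.frame(y = 1:100)
  s <- summarize_replicates(list(t1, t2))
  expect_equal(s$zp, mean(c(2 / 5, 0)))
  expect_equal(s$q50, mean(c(5, 50.5)))
  expect_equal(s$n_replicates, 2)
  # order invariance
  s2 <- summarize_replicates(list(t2, t1))
  expect_equal(s[c("zp", "q05", "q50", "q95")],
               s2[c("zp", "q05", "q50", "q95")])
  expect_equal(summarize_replicates(t2)$zp, 0)
  expect_error(summarize_replicates(data.frame(y = c(0, 0))), "no non-zero")
})

test_that("the study runner is deterministic and books cells correctly", {
  scn <- simulation_scenario(3, "nbinom", "modified", n = 100)
  r1 <- run_study(scn, models = c("ZMNB", "Poisson"), n_replicates = 4,
                  seed = 12, pearson = TRUE)
  r2 <- run_study(scn, models = c("ZMNB", "Poisson"), n_replicates = 4,
                  seed = 12, pearson = TRUE)
  expect_identical(r1$p_values, r2$p_values)
  expect_identical(r1$rates, r2$rates)
  expect_equal(nrow(r1$rates), 2)
  expect_true(all(r1$rates$n_converged <= 4))
  # denominator = converged fits only
  expect_equal(r1$rates$n_converged,
               colSums(!is.na(r1$p_values))[r1$rates$model], ignore_attr = TRUE)
  # single-replicate studies yield 0/1 cells
  r3 <- run_study(scn, models = "Poisson", n_replicates = 1, seed = 2)
  expect_true(r3$rates$rejection_rate %in% c(0, 1, NA))
})

test_that("checkpointed studies resume to identical results", {
  scn <- simulation_scenario(3, "nbinom", "modified", n = 100)
  dir <- withr::local_tempdir()
  r1 <- run_study(scn, models = "Poisson", n_replicates = 3, seed = 8,
                  checkpoint_dir = dir)
  expect_length(list.files(dir, pattern = "^rep-"), 3)
  # re-run reads the checkpoints and reproduces the result
  r2 <- run_study(scn, models = "Poisson", n_replicates = 3, seed = 8,
                  checkpoint_dir = dir)
  expect_identical(r1$p_values, r2$p_values)
})
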