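# Shared fixtures and a per-session cache so expensive Monte-Carlo
# studies are computed once and examined by several tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# small deterministic table for design/likelihood tests: one fixed
# 3-level factor, one 3-level grouping factor, modest counts
toy_table <- function(n = 60, seed = 11, p_zero = 0.25) {
  set.seed(seed)
  df <- data.frame(
    F1 = sample(c("a", "b", "c"), n, replace = TRUE),
    G1 = sample(c("g1", "g2", "g3"), n, replace = TRUE),
    total_reads = rpois(n, 500))
  mu <- exp(log(df$total_reads) - 3.5 +
              c(0, 0.3, -0.2)[match(df$F1, c("a", "b", "c"))] +
              c(0.4, -0.4, 0.1)[match(df$G1, c("g1", "g2", "g3"))])
  df$y <- ifelse(rbinom(n, 1, p_zero) == 1, 0L,
                 rnbinom(n, size = 3, mu = mu))
  observation_table(df, count = "y", offset = "total_reads",
                    fixed = "F1", random = "G1")
}

toy_params <- function(zero_mode = "none", family = "poisson") {
  list(beta = c(-3.5, 0.3, -0.2),
       beta_zero = c(-1, 0.2, -0.1),
       log_theta = log(3),
       log_sd = list(G1 = log(0.5)),
       log_sd_zero = list(G1 = log(0.4)))
}

# a converged fit on a simulated dataset, shared across residual/gof tests
shared_fit <- function() cached("shared_fit", {
  scn <- simulation_scenario(3, family = "nbinom", zero_mode = "modified",
                             n = 200)
  for (s in 1:10) {
    tab <- simulate_dataset(scn, seed = 100 + s)
    f <- fit_model(tab, model_spec_by_name("ZMNB"))
    if (f$converged) return(f)
  }
  stop("no converged fixture fit found")
})
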