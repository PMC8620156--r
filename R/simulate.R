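# Synthetic microbiome-like count data generator and Monte-Carlo study
# runner.  Each dataset mimics one taxon's per-observation read counts:
# a structural-zero indicator H_i with
#   logit P(H_i = 0) = b0_zero + sum_m b_zero[F_m(i)] + sum_k u_zero[G_k(i)]
# and, when H_i = 1, a count from a Poisson/NB (zero-inflated truth) or
# zero-truncated Poisson/NB (hurdle truth) distribution with
#   log mu_i = log T_i + b0_count + sum_m b_count[F_m(i)] + sum_k u_count[G_k(i)],
# where T_i ~ Poisson(300000) is the sequencing depth, the three fixed
# factors F_m have three levels, the two grouping factors G_k have two
# levels, fixed-effect level coefficients are N(0, 0.1^2), random-effect
# level coefficients are N(0, 2^2), and theta ~ unif(2, 3) for NB truth.

#' Define a simulation scenario
#'
#' The four scenarios cross high/low zero proportion (zero-part
#' intercept `3.5` vs `-5.5`) with high/low counts (count-part
#' intercept `-5.5` / `-7.8` for NB truth, `-5.7` / `-8` for Poisson
#' truth).
#'
#' @param scenario Integer 1..4.  1: high ZP, high counts; 2: high ZP,
#'   low counts; 3: low ZP, high counts; 4: low ZP, low counts.
#' @param family Truth count family, `"nbinom"` or `"poisson"`.
#' @param zero_mode Truth zero handling, `"inflated"` or `"modified"`.
#' @param n Observations per dataset.
#' @return A `sim_scenario` object holding all generator settings.
#' @export
simulation_scenario <- function(scenario = 1,
                                family = c("nbinom", "poisson"),
                                zero_mode = c("modified", "inflated"),
                                n = 100) {
  family <- match.arg(family)
  zero_mode <- match.arg(zero_mode)
  stopifnot(scenario %in% 1:4, n >= 1)
  beta0_zero <- c(3.5, 3.5, -5.5, -5.5)[scenario]
  beta0_count <- if (family == "nbinom")
    c(-5.5, -7.8, -5.5, -7.8)[scenario]
  else
    c(-5.7, -8, -5.7, -8)[scenario]
  structure(list(scenario = scenario, family = family,
                 zero_mode = zero_mode, n = as.integer(n),
                 beta0_zero = beta0_zero, beta0_count = beta0_count,
                 n_fixed = 3L, levels_fixed = 3L,
                 n_random = 2L, levels_random = 2L,
                 sd_fixed = 0.1, sd_random = 2,
                 total_reads_mean = 3e5, theta_range = c(2, 3)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario %d> truth %s%s, n = %d, b0_zero = %.1f, b0_count = %.1f\n",
              x$scenario,
              if (x$zero_mode == "inflated") "ZI" else "ZM",
              if (x$family == "poisson") "P" else "NB",
              x$n, x$beta0_zero, x$beta0_count))
  invisible(x)
}

#' Draw one coefficient set for a scenario
#'
#' One coefficient per level of each fixed factor
#' (\eqn{N(0, 0.1^2)}) and of each random factor (\eqn{N(0, 2^2)}),
#' drawn independently for the zero part and the count part, plus
#' \eqn{\theta \sim \mathrm{unif}(2, 3)} for NB truth.  Uses the
#' current RNG stream.
#'
#' @param scn A [simulation_scenario()].
#' @return List with `zero` and `count` parts (each: `beta0`, `fixed`,
#'   `random`) and `theta`.
#' @export
draw_coefficients <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  part <- function(beta0) list(
    beta0 = beta0,
    fixed = replicate(scn$n_fixed,
                      stats::rnorm(scn$levels_fixed, 0, scn$sd_fixed),
                      simplify = FALSE),
    random = replicate(scn$n_random,
                       stats::rnorm(scn$levels_random, 0, scn$sd_random),
                       simplify = FALSE))
  list(zero = part(scn$beta0_zero), count = part(scn$beta0_count),
       theta = if (scn$family == "nbinom")
         stats::runif(1, scn$theta_range[1], scn$theta_range[2]) else Inf)
}

# zero-truncated sampling from the base distribution: vectorized
# rejection, with an inverse-CDF fallback for observations whose g(0)
# exceeds 0.99 (rejection would be wasteful there)
rtrunc_count <- function(mu, theta) {
  n <- length(mu)
  y <- integer(n)
  g0 <- count_pmf(0L, mu, theta)
  hard <- g0 > 0.99
  todo <- which(!hard)
  for (round in 1:50) {
    if (!length(todo)) break
    draw <- if (is.infinite(theta[1]))
      stats::rpois(length(todo), mu[todo])
    else stats::rnbinom(length(todo), size = theta[todo], mu = mu[todo])
    y[todo] <- draw
    todo <- todo[draw == 0]
  }
  hard_idx <- c(which(hard), todo)
  if (length(hard_idx)) {
    u <- stats::runif(length(hard_idx), g0[hard_idx], 1)
    y[hard_idx] <- if (is.infinite(theta[1]))
      stats::qpois(u, mu[hard_idx])
    else stats::qnbinom(u, size = theta[hard_idx], mu = mu[hard_idx])
    y[hard_idx] <- pmax(y[hard_idx], 1L)
  }
  y
}

#' Simulate one dataset from a scenario
#'
#' Assigns each observation uniformly at random to one level of each
#' factor, draws sequencing depths \eqn{T_i \sim}
#' Poisson(`total_reads_mean`), computes the structural-zero
#' probability \eqn{p_i} and base mean \eqn{\mu_i} from the (re)drawn
#' coefficient set, draws \eqn{H_i} and the counts.  Coefficients are
#' redrawn for every dataset so replicates are exchangeable.
#'
#' @param scn A [simulation_scenario()].
#' @param coefs Optional coefficient set from [draw_coefficients()];
#'   drawn fresh when `NULL`.
#' @param seed Optional integer seed (isolated from the caller's RNG
#'   state).
#' @return An [observation_table()] with columns `y`, `total_reads`,
#'   `F1..F3`, `G1..G2`, and attribute `"truth"` (coefficients, theta,
#'   per-observation `p`, `mu`, and `H`).
#' @export
simulate_dataset <- function(scn, coefs = NULL, seed = NULL) {
  stopifnot(inherits(scn, "sim_scenario"))
  with_seed(seed, {
    if (is.null(coefs)) coefs <- draw_coefficients(scn)
    n <- scn$n
    Fm <- replicate(scn$n_fixed,
                    sample.int(scn$levels_fixed, n, replace = TRUE),
                    simplify = FALSE)
    Gk <- replicate(scn$n_random,
                    sample.int(scn$levels_random, n, replace = TRUE),
                    simplify = FALSE)
    total_reads <- stats::rpois(n, scn$total_reads_mean)
    lin <- function(part, base) {
      eta <- rep(part$beta0, n) + base
      for (m in seq_len(scn$n_fixed)) eta <- eta + part$fixed[[m]][Fm[[m]]]
      for (k in seq_len(scn$n_random)) eta <- eta + part$random[[k]][Gk[[k]]]
      eta
    }
    p <- stats::plogis(lin(coefs$zero, 0))
    mu <- exp(lin(coefs$count, log(total_reads)))
    H <- stats::rbinom(n, 1L, 1 - p)   # P(H = 0) = p: structural zero
    y <- integer(n)
    pos <- H == 1L
    if (any(pos)) {
      mu_p <- mu[pos]
      th_p <- rep_len(coefs$theta, sum(pos))
      y[pos] <- if (scn$zero_mode == "modified")
        rtrunc_count(mu_p, th_p)
      else if (scn$family == "poisson") stats::rpois(sum(pos), mu_p)
      else stats::rnbinom(sum(pos), size = th_p, mu = mu_p)
    }
    df <- data.frame(y = y, total_reads = total_reads)
    for (m in seq_len(scn$n_fixed))
      df[[paste0("F", m)]] <- factor(letters[Fm[[m]]])
    for (k in seq_len(scn$n_random))
      df[[paste0("G", k)]] <- factor(letters[Gk[[k]]])
    out <- observation_table(df, count = "y", offset = "total_reads",
                             fixed = paste0("F", seq_len(scn$n_fixed)),
                             random = paste0("G", seq_len(scn$n_random)))
    attr(out, "truth") <- list(coefs = coefs, p = p, mu = mu, H = H,
                               scenario = scn)
    out
  })
}

#' Summarize replicate datasets
#'
#' Mean zero proportion (ZP) and mean 5%/50%/95% quantiles of the
#' non-zero counts across replicate datasets (the descriptive columns
#' of a study summary).
#'
#' @param tables List of data.frames (or a single data.frame) with a
#'   `y` column.
#' @param drop_empty All-zero replicates have undefined non-zero
#'   quantiles; by default they raise an error, with `drop_empty =
#'   TRUE` they still contribute to ZP but are skipped in the quantile
#'   averages (high-zero-proportion scenarios do produce them).
#' @return List with `zp`, `q05`, `q50`, `q95`, `n_replicates`.
#' @export
summarize_replicates <- function(tables, drop_empty = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  per <- vapply(tables, function(tb) {
    y <- tb$y
    nz <- y[y > 0]
    if (!length(nz)) {
      if (!drop_empty)
        stop("replicate with no non-zero counts: quantiles undefined",
             call. = FALSE)
      return(c(mean(y == 0), NA_real_, NA_real_, NA_real_))
    }
    c(mean(y == 0), stats::quantile(nz, c(0.05, 0.5, 0.95), names = FALSE))
  }, numeric(4))
  m <- rowMeans(per, na.rm = TRUE)
  list(zp = m[1], q05 = m[2], q50 = m[3], q95 = m[4],
       n_replicates = length(tables))
}

study_seed <- function(seed, k, offset = 0L)
  as.integer((as.numeric(seed) * 1009 + k * 7 + offset) %% 2147483647L)

#' Run a Monte-Carlo rejection-rate study
#'
#' For each replicate: simulate a dataset from the truth scenario, fit
#' each candidate model, compute one RQR draw per converged fit
#' (using a randomization stream independent of the simulation
#' stream), Shapiro-Wilk-test it, and optionally also SW-test the
#' Pearson residuals.  Rejection rates are aggregated over converged
#' fits only; each cell reports its own denominator `N`.
#'
#' @param scn Truth [simulation_scenario()].
#' @param models Character vector of models to fit (see
#'   [model_spec_by_name()]), e.g. `c("ZMNB", "ZINB", "ZMP", "ZIP",
#'   "NB", "Poisson")`.
#' @param n_replicates Number of replicate datasets.
#' @param alpha GOF significance level.
#' @param seed Integer master seed; all simulation and randomization
#'   sub-seeds derive from it.
#' @param pearson Also SW-test Pearson residuals of each converged fit?
#' @param checkpoint_dir Optional directory; per-replicate results are
#'   saved there and reused on re-run, so interrupted studies resume.
#' @param progress Print a progress line every 25 replicates?
#' @return A `study_result`: list with `rates` (data.frame: model,
#'   rejection_rate, n_converged, and pearson_rejection_rate if
#'   requested), `summary` (from [summarize_replicates()]), the
#'   p-value matrices, `alpha`, `seed` and the scenario.
#' @export
run_study <- function(scn, models = c("ZMNB", "ZINB", "ZMP", "ZIP", "NB", "Poisson"),
                      n_replicates = 200, alpha = 0.05, seed = 1,
                      pearson = FALSE, checkpoint_dir = NULL,
                      progress = FALSE) {
  stopifnot(inherits(scn, "sim_scenario"), length(models) >= 1,
            n_replicates >= 1)
  specs <- lapply(models, model_spec_by_name)
  names(specs) <- vapply(specs, spec_label, character(1))
  pv <- matrix(NA_real_, n_replicates, length(specs),
               dimnames = list(NULL, names(specs)))
  pv_pearson <- if (pearson) pv else NULL
  summaries <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("rep-%05d.rds", k)) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      rep_res <- readRDS(ck)
    } else {
      tab <- simulate_dataset(scn, seed = study_seed(seed, k))
      rep_res <- list(y = tab$y,
                      p = rep(NA_real_, length(specs)),
                      pp = rep(NA_real_, length(specs)))
      for (j in seq_along(specs)) {
        # degenerate datasets (e.g. all-zero under extreme zero
        # proportions) count as failed fits, not study failures
        f <- tryCatch(fit_model(tab, specs[[j]]), error = function(e) NULL)
        if (is.null(f) || !isTRUE(f$converged)) next
        rep_res$p[j] <- tryCatch({
          r <- rqr(f, seed = study_seed(seed, k, offset = 1000000L + j))
          sw_test(r)$p_value
        }, error = function(e) NA_real_)
        if (pearson)
          rep_res$pp[j] <- tryCatch(sw_test(pearson_residuals(f))$p_value,
                                    error = function(e) NA_real_)
      }
      if (!is.null(ck)) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(rep_res, ck)
      }
    }
    pv[k, ] <- rep_res$p
    if (pearson) pv_pearson[k, ] <- rep_res$pp
    summaries[[k]] <- data.frame(y = rep_res$y)
    if (progress && k %% 25 == 0)
      message(sprintf("replicate %d / %d", k, n_replicates))
  }
  rates <- do.call(rbind, lapply(names(specs), function(m) {
    cell <- tryCatch(rejection_rate(pv[, m], alpha), error = function(e)
      list(rejection_rate = NA_real_, n_converged = 0L, alpha = alpha))
    row <- data.frame(model = m, rejection_rate = cell$rejection_rate,
                      n_converged = cell$n_converged)
    if (pearson) {
      pc <- tryCatch(rejection_rate(pv_pearson[, m], alpha),
                     error = function(e) list(rejection_rate = NA_real_))
      row$pearson_rejection_rate <- pc$rejection_rate
    }
    row
  }))
  structure(list(rates = rates,
                 summary = summarize_replicates(summaries, drop_empty = TRUE),
                 p_values = pv, pearson_p_values = pv_pearson,
                 alpha = alpha, seed = seed, scenario = scn),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("<study_result> truth %s%s scenario %d, n = %d, %d replicates, alpha = %.2f\n",
              if (s$zero_mode == "inflated") "ZI" else "ZM",
              if (s$family == "poisson") "P" else "NB",
              s$scenario, s$n, nrow(x$p_values), x$alpha))
  cat(sprintf("  ZP = %.2f, Q05 = %.0f, Q50 = %.0f, Q95 = %.0f\n",
              x$summary$zp, x$summary$q05, x$summary$q50, x$summary$q95))
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Export a study result as a TSV summary
#'
#' Writes a one-row-per-model table (scenario descriptors, ZP and
#' non-zero count quantiles, rejection rate, N).
#'
#' @param result A `study_result`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_study_tsv <- function(result, path) {
  stopifnot(inherits(result, "study_result"))
  s <- result$scenario
  df <- cbind(data.frame(scenario = s$scenario,
                         truth = paste0(ifelse(s$zero_mode == "inflated", "ZI", "ZM"),
                                        ifelse(s$family == "poisson", "P", "NB")),
                         n = s$n,
                         zp = result$summary$zp, q05 = result$summary$q05,
                         q50 = result$summary$q50, q95 = result$summary$q95),
              result$rates)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
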