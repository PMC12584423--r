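test_that("sampling is bit-reproducible under the master seed", {
  tab <- small_table(k = 2, seed = 1)
  f1 <- dhgm(value ~ population * sex + context, tab, model = "M3",
             chains = 2, warmup = 50, samples = 50, seed = 11, diag_warn = FALSE)
  f2 <- dhgm(value ~ population * sex + context, tab, model = "M3",
             chains = 2, warmup = 50, samples = 50, seed = 11, diag_warn = FALSE)
  expect_identical(f1$samples$draws, f2$samples$draws)
  f3 <- dhgm(value ~ population * sex + context, tab, model = "M3",
             chains = 2, warmup = 50, samples = 50, seed = 12, diag_warn = FALSE)
  expect_false(identical(f1$samples$draws$beta, f3$samples$draws$beta))
})

test_that("with fixed SDs the beta posterior matches the conjugate closed form", {
  set.seed(9)
  n <- 400
  y <- rnorm(n, 2, 1)
  d <- bare_design(y)
  s <- fit_mcmc(y, d, prior = prior_config(beta_scale = 10), chains = 1,
                warmup = 50, samples = 1e5, seed = 2, compute_loglik = FALSE,
                diag_warn = FALSE, sigma_W_fixed = 1, sigma_A_fixed = 1)
  prec <- n / 1 + 1 / 100
  expect_equal(mean(s$draws$beta), sum(y) / prec, tolerance = 1e-3)
  expect_equal(sd(s$draws$beta), 1 / sqrt(prec), tolerance = 3e-3)
})

test_that("the residual-SD posterior is calibrated on iid Normal data", {
  # y ~ N(1, 2), intercept-only, no random effects: the 95% interval for
  # sigma_W should cover 2 in at least 90 of 100 seeded replicates
  covered <- vapply(1:100, function(r) {
    set.seed(1000 + r)
    y <- rnorm(200, 1, 2)
    s <- fit_mcmc(y, bare_design(y), chains = 1, warmup = 100, samples = 400,
                  seed = r, compute_loglik = FALSE, diag_warn = FALSE)
    ci <- quantile(s$draws$sigma_W, c(0.025, 0.975))
    ci[1] <= 2 && 2 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("with no observations the sampler reproduces the prior", {
  d0 <- bare_design(numeric(0))
  s <- fit_mcmc(numeric(0), d0, chains = 2, warmup = 200, samples = 8000,
                thin = 4, seed = 5, compute_loglik = FALSE, diag_warn = FALSE)
  # beta prior: Normal(0, 5)
  expect_equal(mean(s$draws$beta), 0, tolerance = 0.25)
  expect_equal(sd(s$draws$beta), 5, tolerance = 0.25)
  # sigma_W prior: half-t(3, 2.5); compare central quantiles
  for (p in c(0.25, 0.5, 0.75)) {
    expect_equal(unname(quantile(s$draws$sigma_W, p)),
                 2.5 * qt((1 + p) / 2, df = 3), tolerance = 0.12)
  }
})

test_that("split-R-hat flags degenerate and disjoint chains, passes iid ones", {
  expect_true(is.na(split_rhat(matrix(1, 1000, 2))))
  set.seed(21)
  expect_lt(split_rhat(matrix(rnorm(4000), ncol = 2)), 1.01)
  disjoint <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(split_rhat(disjoint), 1.1)
})

test_that("bulk-ESS is near the draw count for iid chains and sane for AR(1)", {
  set.seed(22)
  x <- matrix(rnorm(8000), ncol = 4)
  expect_gt(ess_bulk(x), 0.8 * 8000)
  expect_lt(ess_bulk(x), 1.25 * 8000)
  # AR(1) with rho = 0.9: theoretical ESS factor (1-rho)/(1+rho) = 1/19;
  # cross-check against coda's spectral estimator
  rho <- 0.9
  ar <- replicate(4, as.numeric(stats::arima.sim(list(ar = rho), 2000)))
  e <- ess_bulk(ar)
  expect_gt(e, 8000 / 19 * 0.5)
  expect_lt(e, 8000 / 19 * 2.0)
  if (requireNamespace("coda", quietly = TRUE)) {
    e_coda <- sum(apply(ar, 2, function(z) coda::effectiveSize(coda::mcmc(z))))
    expect_lt(abs(log(e / e_coda)), log(2))
  }
})

test_that("check_convergence reports per-parameter diagnostics and a pass flag", {
  tab <- small_table(k = 6, seed = 2)
  fit <- dhgm(value ~ population * sex + context, tab, model = "M1",
              chains = 2, warmup = 300, samples = 1500, seed = 3,
              diag_warn = FALSE)
  cc <- check_convergence(fit, rhat_max = 1.05, ess_min = 100)
  expect_s3_class(cc, "dhgm_convergence")
  core <- cc$table[!startsWith(cc$table$parameter, "a["), ]
  expect_true(all(c("rhat", "ess") %in% names(cc$table)))
  expect_true(all(is.finite(core$rhat)))
  # diagnostics cover every scalar parameter, including random intercepts
  expect_equal(nrow(cc$table),
               ncol(fit$samples$draws$beta) + length(fit$design$individuals) + 2)
  # never mutates draws
  before <- fit$samples$draws$beta
  invisible(check_convergence(fit, rhat_max = 1.05, ess_min = 100))
  expect_identical(fit$samples$draws$beta, before)
})

test_that("a single chain yields a warning about unavailable R-hat", {
  tab <- small_table(k = 2, seed = 3)
  fit <- dhgm(value ~ population * sex + context, tab, model = "M1",
              chains = 1, warmup = 50, samples = 60, seed = 4, diag_warn = FALSE)
  expect_warning(check_convergence(fit), "chains|R-hat")
})

test_that("group-specific residual SDs are recovered under the M3 scenario", {
  # sigma_W = (0.5, 1, 1, 1), 25 individuals/group x 3 trials: posterior
  # medians within +/-30% of truth in at least 80% of 50 seeded replicates
  sc <- study_scenario(group_sizes = c(PKF = 25, PKM = 25, PMF = 25, PMM = 25),
                       sigma_A = 0.6, sigma_W = c(0.5, 1, 1, 1), seed = 1)
  rep_ok <- recovery_experiment(sc, model = "M3", n_replicates = 50,
                                chains = 2, warmup = 250, samples = 250, seed = 100)
  sw <- rep_ok$params[grepl("^sigma_W", rep_ok$params$parameter), ]
  within30 <- abs(sw$post_median - sw$truth) / sw$truth <= 0.30
  rate_by_group <- tapply(within30, sw$parameter, mean)
  expect_true(all(rate_by_group >= 0.80))
})
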