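# minimal stand-in fit: hand-set draws wrapped in the classes the derived-
# quantity functions accept
fake_samples <- function(sigma_A, sigma_W, groups = c("PKF", "PKM", "PMF", "PMM")) {
  structure(list(
    draws = list(beta = matrix(0, nrow(as.matrix(sigma_A)), 1,
                               dimnames = list(NULL, "(Intercept)")),
                 a = matrix(numeric(0), nrow(as.matrix(sigma_A)), 0),
                 sigma_A = as.matrix(sigma_A), sigma_W = as.matrix(sigma_W)),
    chain = rep(1L, nrow(as.matrix(sigma_A))),
    loglik = NULL, diagnostics = NULL,
    spec = model_spec("M4"), groups = groups,
    n_obs = 0L, n_individuals = 0L,
    config = list(chains = 1L, warmup = 0L, samples = nrow(as.matrix(sigma_A)),
                  thin = 1L, seed = 1L)),
    class = "dhgm_samples")
}

test_that("repeatability follows its defining ratio and stays in [0, 1]", {
  expect_equal(repeatability(1, 1), 0.5)
  expect_equal(repeatability(0, 7), 0)
  expect_equal(repeatability(3, 1), 0.75)
  expect_error(repeatability(0, 0), "undefined")
  expect_error(repeatability(-1, 1), "non-negative")
  set.seed(51)
  va <- rexp(200); vw <- rexp(200)
  r <- repeatability(va, vw)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(r, va / (va + vw))
  # scale invariance
  expect_equal(repeatability(3.7 * va, 3.7 * vw), r, tolerance = 1e-14)
})

test_that("variance components square the SD draws and share draws under M1", {
  s <- fake_samples(sigma_A = matrix(1, 3, 1), sigma_W = matrix(1, 3, 1))
  s$spec <- model_spec("M1")
  vc <- variance_components(s)
  expect_equal(unname(vc$va[1, ]), rep(1, 4))
  expect_equal(unname(vc$r[1, ]), rep(0.5, 4))
  # all four groups identical draw-by-draw when components are shared
  set.seed(52)
  s2 <- fake_samples(sigma_A = matrix(rexp(50) + 0.1, 50, 1),
                     sigma_W = matrix(rexp(50) + 0.1, 50, 1))
  s2$spec <- model_spec("M1")
  vc2 <- variance_components(s2)
  for (g in 2:4) {
    expect_identical(vc2$va[, 1], vc2$va[, g])
    expect_identical(vc2$vw[, 1], vc2$vw[, g])
  }
  # draw-wise identities hold exactly
  expect_identical(vc2$r, vc2$va / (vc2$va + vc2$vw))
})

test_that("zero among-individual variance forces zero repeatability", {
  s <- fake_samples(sigma_A = matrix(0, 2, 1) + 1e-300,
                    sigma_W = matrix(2, 2, 1))
  s$draws$sigma_A <- matrix(0, 2, 1)
  vc <- variance_components(s)
  expect_equal(unname(vc$r[1, ]), rep(0, 4))
})

test_that("fixed-effect summaries match quantile oracles and antisymmetry", {
  tab <- small_table(k = 3, seed = 10)
  fit <- dhgm(value ~ population * sex + context, tab, model = "M1",
              chains = 1, warmup = 50, samples = 100, seed = 7, diag_warn = FALSE)
  # degenerate draws
  fit_deg <- fit
  fit_deg$samples$draws$beta[] <- 0.5
  fe <- fixed_effect_summary(fit_deg)
  expect_equal(fe$estimate, rep(0.5, 3))
  expect_equal(fe$lower95, rep(0.5, 3))
  expect_true(all(c("populationPM", "sexM", "populationPM:sexM") %in% fe$term))
  expect_false(any(grepl("context|Intercept", fe$term)))

  # iid Normal(0,1) draws: CI endpoints near +/- 1.96
  fit_n <- fit
  set.seed(53)
  fit_n$samples$draws$beta <- matrix(rnorm(10000 * 6), 10000, 6,
    dimnames = dimnames(matrix(0, 1, 6, dimnames = list(NULL, colnames(fit$samples$draws$beta)))))
  colnames(fit_n$samples$draws$beta) <- colnames(fit$samples$draws$beta)
  fe_n <- fixed_effect_summary(fit_n)
  expect_true(all(abs(fe_n$lower95 + 1.96) < 0.05))
  expect_true(all(abs(fe_n$upper95 - 1.96) < 0.05))

  # negating every draw negates the summary (CI endpoints swap)
  fit_neg <- fit_n
  fit_neg$samples$draws$beta <- -fit_n$samples$draws$beta
  fe_neg <- fixed_effect_summary(fit_neg)
  expect_equal(fe_neg$estimate, -fe_n$estimate)
  expect_equal(fe_neg$lower95, -fe_n$upper95)
  expect_equal(fe_neg$upper95, -fe_n$lower95)

  expect_error(fixed_effect_summary(fit, terms = "body_size"), "absent")
})

test_that("contrast tables come from paired draws and match a brute-force oracle", {
  set.seed(54)
  S <- 5000
  sa <- matrix(rexp(S * 4) + 0.2, S, 4)
  sw <- matrix(rexp(S * 4) + 0.2, S, 4)
  s <- fake_samples(sigma_A = sa, sigma_W = sw)
  vc <- variance_components(s)
  ct <- contrast_table(vc, "vw")
  groups <- c("PKF", "PKM", "PMF", "PMM")
  for (i in 1:4) for (j in 1:4) {
    row <- ct[ct$row == groups[i] & ct$col == groups[j], ]
    if (i == j) {
      expect_identical(row$mean, 0)
      expect_false(row$substantial)
    } else {
      d <- sw[, i]^2 - sw[, j]^2
      expect_equal(row$mean, mean(d), tolerance = 1e-12)
      expect_equal(row$lower95, unname(quantile(d, 0.025)), tolerance = 1e-12)
      expect_equal(row$upper95, unname(quantile(d, 0.975)), tolerance = 1e-12)
      expect_equal(row$substantial,
                   quantile(d, 0.025) > 0 || quantile(d, 0.975) < 0)
    }
  }
  # antisymmetry of means and CI endpoints
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rij <- ct[ct$row == groups[i] & ct$col == groups[j], ]
    rji <- ct[ct$row == groups[j] & ct$col == groups[i], ]
    expect_equal(rij$mean, -rji$mean, tolerance = 1e-12)
    expect_equal(rij$lower95, -rji$upper95, tolerance = 1e-12)
  }
})

test_that("constant draws produce exact substantial contrasts; equal groups none", {
  s_eq <- fake_samples(sigma_A = matrix(1, 100, 4), sigma_W = matrix(1, 100, 4))
  ct_eq <- contrast_table(s_eq, "vw")
  off <- ct_eq[ct_eq$row != ct_eq$col, ]
  expect_true(all(off$mean == 0))
  expect_false(any(off$substantial))

  sw <- cbind(rep(1, 100), rep(sqrt(0.8), 100), rep(1, 100), rep(1, 100))
  s_ab <- fake_samples(sigma_A = matrix(1, 100, 4), sigma_W = sw)
  ct <- contrast_table(s_ab, "vw")
  r <- ct[ct$row == "PKF" & ct$col == "PKM", ]
  expect_equal(r$mean, 0.2, tolerance = 1e-12)
  expect_equal(c(r$lower95, r$upper95), c(0.2, 0.2), tolerance = 1e-12)
  expect_true(r$substantial)
})

test_that("repeatability contrasts carry NA flags when Va overlaps zero", {
  set.seed(55)
  S <- 400
  sa <- cbind(abs(rnorm(S, 0, 0.02)), rexp(S) + 0.5, rexp(S) + 0.5, rexp(S) + 0.5)
  sw <- matrix(1, S, 4)
  s <- fake_samples(sigma_A = sa, sigma_W = sw)
  ct <- contrast_table(s, "r")
  flagged <- ct[ct$row == "PKF" & ct$col == "PKM", ]
  expect_true(flagged$na_flag)
  clean <- ct[ct$row == "PMF" & ct$col == "PKM", ]
  expect_false(clean$na_flag)
  # raw values retained alongside the flag
  expect_true(is.finite(flagged$mean))
  # formatted square table renders NA below diagonal, values above
  fm <- format_contrast_matrix(contrast_table(s, "vw"), ct)
  expect_equal(fm["PKM", "PKF"], "NA")
  expect_match(fm["PKF", "PKM"], "\\(")
})
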