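test_that("read_trials parses a complete table and honors a column map", {
  df <- toy_trials_df()
  names(df)[names(df) == "individual"] <- "lizard_id"
  path <- write_trials_csv(df)
  tab <- read_trials(path, column_map = c(individual = "lizard_id"))
  expect_s3_class(tab, "trial_table")
  expect_equal(nrow(tab), 9)
  expect_equal(length(unique(tab$individual)), 3)
  expect_equal(attr(tab, "drop_report"), 0)
})

test_that("read_trials rejects conflicting labels, duplicates, missing columns", {
  df <- toy_trials_df()
  df$sex[df$individual == "i1"] <- c("F", "M", "F")
  expect_error(read_trials(write_trials_csv(df)), "conflicting population/sex")

  df2 <- toy_trials_df()
  df2 <- rbind(df2, df2[1, ])
  expect_error(read_trials(write_trials_csv(df2)), "duplicate")

  df3 <- toy_trials_df()
  df3$value <- NULL
  expect_error(read_trials(write_trials_csv(df3)), "missing required column")
})

test_that("rows with missing values are dropped and counted", {
  df <- toy_trials_df()
  df$value[4] <- NA
  tab <- read_trials(write_trials_csv(df))
  expect_equal(nrow(tab), 8)
  expect_equal(attr(tab, "drop_report"), 1)
})

test_that("standardization gives mean 0 / sample SD 1 and is idempotent", {
  tab <- small_table(k = 2, seed = 3)
  tab$value <- rep(c(1, 2, 3), length.out = nrow(tab))[order(rep(1:3, length.out = nrow(tab)))]
  tab3 <- tab[1:3, ]
  tab3$value <- c(1, 2, 3)
  std <- standardize_trait(as_trial_table(as.data.frame(tab3)))
  expect_equal(std$table$value, c(-1, 0, 1))

  again <- standardize_trait(std$table)
  expect_equal(again$table$value, std$table$value, tolerance = 1e-10)
  expect_lt(abs(mean(std$table$value)), 1e-10)
  expect_lt(abs(sd(std$table$value) - 1), 1e-10)
})

test_that("constant trait columns raise a degenerate-data error", {
  tab <- small_table(k = 2, seed = 3)[1:3, ]
  tab$value <- c(5, 5, 5)
  expect_error(standardize_trait(as_trial_table(as.data.frame(tab))), "degenerate")
})

test_that("Yeo-Johnson MLE is near 1 for Gaussian data and matches a profile-likelihood oracle", {
  set.seed(11)
  tab <- small_table(k = 50, n_contexts = 1, seed = 11)
  tab$value <- rnorm(nrow(tab))
  g <- gaussianize_trait(tab)
  expect_equal(g$record$transform, "yeo_johnson")
  expect_lt(abs(g$record$lambda - 1), 0.3)
  # profile-likelihood oracle: fitted lambda beats a coarse grid
  grid <- seq(-1, 2.5, by = 0.05)
  prof <- vapply(grid, function(l) yj_profile_loglik(tab$value, l), 0)
  expect_lt(abs(g$record$lambda - grid[which.max(prof)]), 0.06)
  # data near-unchanged: correlation with the input essentially 1
  expect_gt(cor(g$table$value, tab$value), 0.999)
})

test_that("Yeo-Johnson pulls an exponential sample toward symmetry", {
  set.seed(12)
  tab <- small_table(k = 50, n_contexts = 1, seed = 12)
  tab$value <- rexp(nrow(tab))
  g <- gaussianize_trait(tab)
  expect_lt(g$record$lambda, 1)
  expect_lt(abs(sample_skewness(g$table$value)), abs(sample_skewness(tab$value)))
})

test_that("transform = 'none' is the exact identity", {
  tab <- small_table(k = 3, seed = 4)
  g <- gaussianize_trait(tab, transform = "none")
  expect_identical(g$table$value, tab$value)
  expect_equal(g$record$transform, "none")
})

test_that("context exemptions leave excluded rows untransformed", {
  set.seed(13)
  tab <- small_table(k = 20, seed = 13)
  tab$value <- rexp(nrow(tab))
  g <- gaussianize_trait(tab, exclude_context = "familiar_env")
  fam <- as.character(tab$context) == "familiar_env"
  expect_identical(g$table$value[fam], tab$value[fam])
  expect_false(isTRUE(all.equal(g$table$value[!fam], tab$value[!fam])))
})

test_that("preprocessing records round-trip raw values to 1e-8", {
  set.seed(14)
  tab <- small_table(k = 20, seed = 14)
  tab$value <- rexp(nrow(tab)) * 10
  raw <- tab$value
  g <- gaussianize_trait(tab, exclude_context = "familiar_env")
  s <- standardize_trait(g$table)
  recs <- list(g$record, s$record)
  forward <- apply_preprocess(raw, recs, context = tab$context)
  expect_equal(forward, s$table$value, tolerance = 1e-12)
  back <- invert_preprocess(s$table$value, recs, context = tab$context)
  expect_equal(back, raw, tolerance = 1e-8)
})

test_that("group assignment is a pure function of population and sex", {
  tab <- small_table(k = 3, seed = 5)
  perm <- sample(nrow(tab))
  tab_perm <- as_trial_table(as.data.frame(tab)[perm, ])
  g1 <- attr(tab, "group")
  g2 <- attr(tab_perm, "group")
  expect_identical(levels(g1), levels(g2))
  expect_identical(as.character(g1)[perm], as.character(g2))
})
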