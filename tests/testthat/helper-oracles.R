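# Shared fixtures and independent oracles. Everything is generated in code;
# oracle implementations are deliberately naive (loops, direct formulas) and
# never share code with the package internals they check.

# small synthetic study: k individuals in each of the 4 groups
small_table <- function(k = 2, n_contexts = 3, seed = 1, ...) {
  simulate_study(study_scenario(
    group_sizes = stats::setNames(rep(k, 4), c("PKF", "PKM", "PMF", "PMM")),
    n_contexts = n_contexts, seed = seed, ...))
}

# a bare design with no random effects (individual-free), intercept-only
bare_design <- function(y, groups_per_obs = rep(1L, length(y)), n_groups = 1L) {
  structure(list(
    X = matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
    y = y, indiv = integer(0), individuals = character(0),
    gi = integer(0), gk = groups_per_obs,
    groups = paste0("G", seq_len(n_groups)),
    spec = model_spec(if (n_groups > 1) "M3" else "M1"),
    row_order = seq_along(y), terms = 0L, term_labels = character(0)),
    class = "dhgm_design")
}

# direct WAIC evaluation (no shared code with the package)
oracle_waic <- function(ll) {
  n <- ncol(ll)
  lppd <- p <- numeric(n)
  for (k in seq_len(n)) {
    lppd[k] <- log(mean(exp(ll[, k] - max(ll[, k])))) + max(ll[, k])
    p[k] <- stats::var(ll[, k])
  }
  list(elpd = sum(lppd) - sum(p), p_waic = sum(p), pointwise = lppd - p)
}

# conjugate Normal-mean toy: y_i ~ N(mu, sd_y^2) with sd_y known,
# mu ~ N(0, sd_mu^2). Exact posterior, exact LOO predictive, exact draws.
conjugate_toy <- function(n = 20, sd_y = 1, sd_mu = 1, mu_true = 0.5, seed = 1) {
  set.seed(seed)
  y <- rnorm(n, mu_true, sd_y)
  post <- function(yy) {
    prec <- length(yy) / sd_y^2 + 1 / sd_mu^2
    c(mean = sum(yy) / sd_y^2 / prec, sd = sqrt(1 / prec))
  }
  # exact leave-one-out log predictive density per observation
  loo_exact <- vapply(seq_len(n), function(i) {
    p <- post(y[-i])
    stats::dnorm(y[i], p["mean"], sqrt(p["sd"]^2 + sd_y^2), log = TRUE)
  }, 0)
  list(y = y, post = post(y), loo_exact = loo_exact, sd_y = sd_y)
}

# pointwise log-likelihood matrix of the conjugate toy under S posterior draws
conjugate_loglik <- function(toy, S = 4000, seed = 2) {
  set.seed(seed)
  mu_draws <- rnorm(S, toy$post["mean"], toy$post["sd"])
  outer(mu_draws, toy$y, function(m, yy) stats::dnorm(yy, m, toy$sd_y, log = TRUE))
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# Yeo-Johnson profile log-likelihood at lambda (direct textbook formula)
yj_profile_loglik <- function(x, lambda) {
  z <- car::yjPower(x, lambda)
  n <- length(x)
  sig2 <- mean((z - mean(z))^2)
  -n / 2 * log(sig2) + (lambda - 1) * sum(sign(x) * log(abs(x) + 1))
}

write_trials_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# complete 3x3 toy trial data frame
toy_trials_df <- function() {
  expand.grid(individual = c("i1", "i2", "i3"),
              context = c("novel_env", "familiar_env", "novel_object"),
              stringsAsFactors = FALSE) |>
    transform(population = ifelse(individual == "i3", "PM", "PK"),
              sex = ifelse(individual == "i2", "M", "F"),
              trait = "distance_moved",
              value = seq(1, 1.8, by = 0.1))
}
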