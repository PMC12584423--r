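#' Weakly informative prior configuration
#'
#' Defaults mirror common weakly-informative practice for standardized
#' responses: Normal(0, `beta_scale`) on each fixed-effect coefficient and a
#' half-Student-t(`sd_df`, 0, `sd_scale`) on every standard-deviation
#' component (among-individual and residual).
#'
#' @param beta_scale SD of the Normal prior on fixed effects (default 5).
#' @param sd_df Degrees of freedom of the half-t prior on SDs (default 3).
#' @param sd_scale Scale of the half-t prior on SDs (default 2.5).
#' @return A `prior_config` object.
#' @export
prior_config <- function(beta_scale = 5, sd_df = 3, sd_scale = 2.5) {
  stopifnot(beta_scale > 0, sd_df >= 1, sd_scale > 0)
  structure(list(beta_scale = beta_scale, sd_df = sd_df, sd_scale = sd_scale),
            class = "prior_config")
}

check_params <- function(params, design) {
  G <- length(design$groups)
  spec <- design$spec
  stopifnot(length(params$beta) == ncol(design$X),
            length(params$a) == length(design$individuals))
  if (length(params$sigma_A) != n_sd_groups(spec$va_by_group, G))
    stop("sigma_A has length ", length(params$sigma_A),
         "; model ", spec$model_id, " expects ", n_sd_groups(spec$va_by_group, G))
  if (length(params$sigma_W) != n_sd_groups(spec$vw_by_group, G))
    stop("sigma_W has length ", length(params$sigma_W),
         "; model ", spec$model_id, " expects ", n_sd_groups(spec$vw_by_group, G))
  invisible(TRUE)
}

#' Pointwise conditional log-likelihood
#'
#' Evaluates, for each observation, the Gaussian log-density of the response
#' given the fixed effects and the individual's random intercept (the
#' conditional likelihood used for WAIC/LOO on posterior draws), with the
#' residual SD taken from the observation's population-by-sex group when the
#' model lets it vary.
#'
#' @param params List with `beta` (length p), `a` (one intercept per
#'   individual), `sigma_A` (length 1 or 4), `sigma_W` (length 1 or 4).
#' @param design A `dhgm_design` from [build_design()].
#' @param y Response vector (defaults to the one stored in the design).
#' @return Numeric vector of per-observation log-densities.
#' @export
log_likelihood_pointwise <- function(params, design, y = design$y) {
  check_params(params, design)
  if (any(params$sigma_W <= 0)) stop("non-positive residual SD")
  mu <- drop(design$X %*% params$beta) + params$a[design$indiv]
  stats::dnorm(y, mean = mu, sd = expand_sd(params$sigma_W, design$gk), log = TRUE)
}

#' Joint log-prior density
#'
#' Sum of independent log-prior terms: Normal(0, `beta_scale`) for each fixed
#' effect, half-Student-t for each SD component, and `Normal(0, sigma_A[g(i)])`
#' for each individual intercept given its group's among-individual SD.
#' Returns `-Inf` for non-positive SDs so samplers may propose invalid states.
#'
#' @inheritParams log_likelihood_pointwise
#' @param prior A [prior_config()].
#' @return A single log-density value.
#' @export
log_prior <- function(params, prior = prior_config(), design) {
  check_params(params, design)
  if (any(params$sigma_A <= 0) || any(params$sigma_W <= 0)) return(-Inf)
  lp <- sum(stats::dnorm(params$beta, 0, prior$beta_scale, log = TRUE))
  lp <- lp + sum(dhalft(params$sigma_A, prior$sd_df, prior$sd_scale, log = TRUE))
  lp <- lp + sum(dhalft(params$sigma_W, prior$sd_df, prior$sd_scale, log = TRUE))
  lp + sum(stats::dnorm(params$a, 0, expand_sd(params$sigma_A, design$gi), log = TRUE))
}

#' Simulate responses from the forward model
#'
#' Draws `y = X beta + Z a + eps` with `eps` drawn per observation from
#' `Normal(0, sigma_W[g])` — the generating process the hierarchical model
#' assumes, used for parameter-recovery and calibration experiments.
#'
#' @inheritParams log_likelihood_pointwise
#' @param seed Integer seed; the draw is reproducible.
#' @return Numeric response vector of length `nrow(design$X)`.
#' @export
simulate_responses <- function(params, design, seed = NULL) {
  check_params(params, design)
  if (!is.null(seed)) set.seed(seed)
  mu <- drop(design$X %*% params$beta) + params$a[design$indiv]
  mu + stats::rnorm(length(mu), 0, expand_sd(params$sigma_W, design$gk))
}
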