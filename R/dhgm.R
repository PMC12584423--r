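#' Fit a double-hierarchical Gaussian model to repeated behavioral trials
#'
#' The main fitting function of the package. It partitions the variance of a
#' repeatedly measured behavioral trait into an among-individual component
#' (\eqn{V_A}, consistent individual differences) and a within-individual
#' component (\eqn{V_W}, behavioral flexibility), either shared across
#' population-by-sex groups or group-specific depending on the candidate
#' model:
#'
#' \describe{
#'   \item{M1}{\eqn{V_A} and \eqn{V_W} constant across groups (null model).}
#'   \item{M2}{\eqn{V_A} varies by group, \eqn{V_W} constant.}
#'   \item{M3}{\eqn{V_W} varies by group, \eqn{V_A} constant.}
#'   \item{M4}{both vary by group.}
#' }
#'
#' The mean model has fixed effects for population, sex, their interaction and
#' context, and a random intercept per individual. The posterior is sampled by
#' a conjugate Gibbs sampler ([fit_mcmc()]).
#'
#' @param formula Fixed-effect formula, default
#'   `value ~ population * sex + context`. The response must name a numeric
#'   column of `data`.
#' @param data A `trial_table` (or data.frame with columns `individual`,
#'   `population`, `sex`, `context`, `value`). Values are used as-is; apply
#'   [standardize_trait()] / [gaussianize_trait()] first (or use
#'   [run_full_analysis()], which does).
#' @param model Candidate model id, `"M1"`–`"M4"` (default `"M3"`).
#' @param prior A [prior_config()].
#' @param chains,warmup,samples,thin,seed MCMC settings, see [fit_mcmc()].
#' @param ... Passed on to [fit_mcmc()].
#'
#' @return An object of class `"dhgm"` with components `samples`
#'   (`dhgm_samples`), `design`, `data`, `call`. Methods: `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `predict`, `simulate`, `plot`.
#'
#' @examples
#' tab <- simulate_study(study_scenario(seed = 42))
#' fit <- dhgm(value ~ population * sex + context, tab, model = "M3",
#'             chains = 2, warmup = 200, samples = 300, seed = 1)
#' fit
#' variance_components(fit)
#' @export
dhgm <- function(formula = value ~ population * sex + context, data,
                 model = "M3", prior = prior_config(), chains = 4,
                 warmup = 1000, samples = 2000, thin = 1, seed = 1, ...) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model, formula = formula)
  spec$formula <- formula
  table <- if (inherits(data, "trial_table")) data else as_trial_table(data)
  design <- build_design(table, spec)
  samples_out <- fit_mcmc(design$y, design, prior = prior, chains = chains,
                          warmup = warmup, samples = samples, thin = thin,
                          seed = seed, ...)
  structure(list(samples = samples_out, design = design, data = table,
                 prior = prior, call = match.call()),
            class = "dhgm")
}

#' @export
print.dhgm <- function(x, ...) {
  s <- x$samples
  cat("Double-hierarchical Gaussian model (", s$spec$model_id, ")\n", sep = "")
  cat("  ", s$n_obs, " trials, ", s$n_individuals, " individuals, groups: ",
      paste(s$groups, collapse = ", "), "\n", sep = "")
  cat("  ", s$config$chains, " chains x ", s$config$samples,
      " draws (warmup ", s$config$warmup, ", thin ", s$config$thin, ")\n", sep = "")
  core <- s$diagnostics[!startsWith(s$diagnostics$parameter, "a["), ]
  cat("  max split-R-hat ", signif(max(core$rhat, na.rm = TRUE), 4),
      ", min bulk-ESS ", round(min(core$ess, na.rm = TRUE)), "\n", sep = "")
  cat("\nPosterior means:\n")
  print(round(colMeans(s$draws$beta), 3))
  cat("sigma_A:", paste(round(colMeans(s$draws$sigma_A), 3), collapse = " "), "\n")
  cat("sigma_W:", paste(round(colMeans(s$draws$sigma_W), 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.dhgm <- function(object, probs = c(0.025, 0.25, 0.5, 0.75, 0.975), ...) {
  s <- object$samples
  mats <- cbind(s$draws$beta, s$draws$sigma_A, s$draws$sigma_W)
  qs <- t(apply(mats, 2, stats::quantile, probs = probs))
  tab <- data.frame(mean = colMeans(mats), sd = apply(mats, 2, stats::sd), qs,
                    check.names = FALSE)
  d <- s$diagnostics
  tab$rhat <- d$rhat[match(rownames(tab), d$parameter)]
  tab$ess <- d$ess[match(rownames(tab), d$parameter)]
  structure(list(model = s$spec$model_id, table = tab,
                 n_obs = s$n_obs, n_individuals = s$n_individuals,
                 config = s$config),
            class = "summary.dhgm")
}

#' @export
print.summary.dhgm <- function(x, digits = 3, ...) {
  cat("Model", x$model, "-", x$n_obs, "trials,", x$n_individuals, "individuals\n")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
coef.dhgm <- function(object, ...) colMeans(object$samples$draws$beta)

#' @export
fitted.dhgm <- function(object, ...) {
  d <- object$design
  mu <- colMeans(object$samples$draws$beta %*% t(d$X))
  if (length(d$individuals)) mu <- mu + colMeans(object$samples$draws$a)[d$indiv]
  to_input_order(unname(mu), d)
}

#' @export
residuals.dhgm <- function(object, ...) {
  d <- object$design
  to_input_order(d$y, d) - fitted(object)
}

# design rows are stored in canonical (individual, context) order; map a
# canonical-order vector back to the input table's row order
to_input_order <- function(v, design) {
  out <- v
  out[design$row_order] <- v
  out
}

#' Posterior-mean predictions for new trials
#'
#' @param object A fitted [dhgm()] model.
#' @param newdata Optional data.frame with the fixed-effect columns; known
#'   individuals contribute their posterior-mean random intercept, unknown
#'   (or `re.form = NA`) individuals predict at the population level.
#' @param re.form `NULL` (default, include known individuals' intercepts) or
#'   `NA` (population-level prediction).
#' @param ... Unused.
#' @return Numeric vector of posterior-mean predictions.
#' @export
predict.dhgm <- function(object, newdata = NULL, re.form = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  d <- object$design
  Xn <- stats::model.matrix(stats::delete.response(stats::terms(d$spec$formula)),
                            data = newdata)
  Xn <- Xn[, colnames(d$X), drop = FALSE]
  mu <- drop(Xn %*% coef(object))
  if (is.null(re.form) && "individual" %in% names(newdata)) {
    amean <- colMeans(object$samples$draws$a)
    ix <- match(as.character(newdata$individual), d$individuals)
    mu <- mu + ifelse(is.na(ix), 0, amean[ix])
  }
  unname(mu)
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws `nsim` replicate response vectors: for each replicate a retained
#' posterior draw is selected and new residuals are generated from
#' `Normal(0, sigma_W[g])` (individual intercepts are kept at their drawn
#' values, i.e. predictions for the same individuals).
#'
#' @param object A fitted [dhgm()] model.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns `sim_1 ...`.
#' @export
simulate.dhgm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$samples
  d <- object$design
  S <- nrow(s$draws$beta)
  take <- sample.int(S, nsim, replace = nsim > S)
  GW <- ncol(s$draws$sigma_W)
  out <- vapply(take, function(i) {
    mu <- drop(d$X %*% s$draws$beta[i, ]) +
      (if (length(d$individuals)) s$draws$a[i, d$indiv] else 0)
    sdv <- if (GW > 1) s$draws$sigma_W[i, d$gk] else s$draws$sigma_W[i, 1]
    to_input_order(mu + stats::rnorm(length(mu), 0, sdv), d)
  }, numeric(s$n_obs))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot per-group variance components of a fitted model
#'
#' Interval plot of the posterior of among-individual variance (Va),
#' within-individual variance (Vw) and repeatability (R) per
#' population-by-sex group: mean (circle), 25–75% interval (thick bar),
#' 95% interval (whisker).
#'
#' @param x A fitted [dhgm()] model.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [variance_components()] object plotted.
#' @export
plot.dhgm <- function(x, ...) {
  vc <- variance_components(x)
  sm <- vc$summary
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (qt in c("va", "vw", "r")) {
    rows <- sm[sm$quantity == qt, ]
    k <- nrow(rows)
    ylim <- range(rows$q2.5, rows$q97.5, 0)
    graphics::plot(seq_len(k), rows$mean, pch = 19, xaxt = "n",
                   xlab = "", ylab = toupper(qt), xlim = c(0.5, k + 0.5),
                   ylim = ylim, main = switch(qt, va = "Among-individual (Va)",
                                              vw = "Within-individual (Vw)",
                                              r = "Repeatability (R)"), ...)
    graphics::axis(1, at = seq_len(k), labels = rows$group, las = 2)
    graphics::segments(seq_len(k), rows$q2.5, seq_len(k), rows$q97.5)
    graphics::segments(seq_len(k), rows$q25, seq_len(k), rows$q75, lwd = 4)
    graphics::points(seq_len(k), rows$mean, pch = 21, bg = "white", cex = 1.2)
  }
  invisible(vc)
}
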