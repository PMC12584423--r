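#' Widely applicable information criterion (WAIC)
#'
#' Computes WAIC from a pointwise conditional log-likelihood matrix: per
#' observation, the log pointwise predictive density
#' `lppd_k = log mean_s exp(loglik_sk)` (numerically stabilized) and the
#' pointwise-variance penalty `p_k = var_s(loglik_sk)` (n - 1 convention,
#' the "p_waic2" form); `elpd = sum(lppd_k - p_k)`.
#'
#' @param x A draws-by-observations log-likelihood matrix, or a fitted
#'   [dhgm()] / `dhgm_samples` object (its stored matrix is used).
#' @param ... Unused.
#' @return A `dhgm_ic` object: `elpd`, `penalty`, `ic_value` (`-2 * elpd`,
#'   deviance scale), `se` (SE of elpd over observations), `pointwise`
#'   (per-observation elpd contributions), `n_obs`, `n_draws`,
#'   `criterion = "waic"`.
#' @seealso [psis_loo()], [compare_models()]
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @export
waic.default <- function(x, ...) {
  ll <- as.matrix(x)
  stopifnot(nrow(ll) >= 2)
  if (any(apply(ll, 2, function(col) all(col == -Inf)))) {
    stop("observation with zero likelihood under every draw")
  }
  lppd <- apply(ll, 2, log_mean_exp)
  p_waic <- apply(ll, 2, stats::var)
  pointwise <- lppd - p_waic
  new_ic(pointwise, penalty = sum(p_waic), criterion = "waic",
         n_draws = nrow(ll))
}

#' @export
waic.dhgm <- function(x, ...) waic(get_loglik(x), ...)
#' @export
waic.dhgm_samples <- function(x, ...) waic(get_loglik(x), ...)

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates each observation's leave-one-out log predictive density by
#' importance sampling over posterior draws, with the raw importance ratios
#' (proportional to `exp(-loglik)`) tail-smoothed: the largest
#' `M = min(0.2 S, 3 sqrt(S))` weights are replaced by quantiles of a
#' generalized Pareto distribution fitted to the exceedances (Zhang-Stephens
#' profile-posterior estimator with a weak prior on the shape), then truncated
#' at the raw-weight maximum and self-normalized. The fitted shape `pareto_k`
#' is reported per observation; values above 0.7 trigger a warning.
#'
#' @inheritParams waic
#' @param warn_k Shape threshold for the reliability warning (default 0.7).
#' @return A `dhgm_ic` object (see [waic()]) with `pareto_k` and
#'   `criterion = "loo"`; `penalty` is `p_loo = lppd - elpd_loo`.
#' @export
psis_loo <- function(x, ...) UseMethod("psis_loo")

#' @export
psis_loo.default <- function(x, warn_k = 0.7, ...) {
  ll <- as.matrix(x)
  S <- nrow(ll)
  if (S < 100) warning("fewer than 100 draws; PSIS-LOO may be unreliable", call. = FALSE)
  n <- ncol(ll)
  pointwise <- numeric(n)
  k_hat <- numeric(n)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  for (j in seq_len(n)) {
    lw <- -ll[, j]
    lw <- lw - max(lw)
    if (stats::sd(lw) == 0 || M < 5) {
      k_hat[j] <- -Inf
    } else {
      ord <- order(lw)
      tail_ids <- ord[(S - M + 1):S]
      cutoff <- lw[ord[S - M]]
      exceed <- exp(lw[tail_ids]) - exp(cutoff)
      if (all(exceed == 0)) {
        k_hat[j] <- -Inf
      } else {
        fit <- gpdfit(exceed)
        k_hat[j] <- fit$k
        pq <- (seq_len(M) - 0.5) / M
        smoothed <- qgpd(pq, fit$k, fit$sigma) + exp(cutoff)
        lw[tail_ids[order(lw[tail_ids])]] <- log(smoothed)
        lw <- pmin(lw, 0)  # truncate at the raw-weight maximum (max lw was 0)
      }
    }
    if (any(!is.finite(lw))) stop("non-finite smoothed weights for observation ", j)
    pointwise[j] <- logsumexp(lw + ll[, j]) - logsumexp(lw)
  }
  lppd <- sum(apply(ll, 2, log_mean_exp))
  bad <- sum(is.finite(k_hat) & k_hat > warn_k)
  if (bad) warning(bad, " observation(s) with pareto_k > ", warn_k,
                   "; PSIS-LOO estimate may be unreliable", call. = FALSE)
  new_ic(pointwise, penalty = lppd - sum(pointwise), criterion = "loo",
         n_draws = S, pareto_k = k_hat)
}

#' @export
psis_loo.dhgm <- function(x, ...) psis_loo(get_loglik(x), ...)
#' @export
psis_loo.dhgm_samples <- function(x, ...) psis_loo(get_loglik(x), ...)

get_loglik <- function(x) {
  s <- as_dhgm_samples(x)
  if (is.null(s$loglik)) stop("fit was run with compute_loglik = FALSE")
  s$loglik
}

new_ic <- function(pointwise, penalty, criterion, n_draws, pareto_k = NULL) {
  n <- length(pointwise)
  elpd <- sum(pointwise)
  structure(
    list(elpd = elpd, penalty = penalty, ic_value = -2 * elpd,
         se = sqrt(n * stats::var(pointwise)), pointwise = pointwise,
         pareto_k = pareto_k, criterion = criterion,
         n_obs = n, n_draws = n_draws),
    class = "dhgm_ic")
}

#' @export
print.dhgm_ic <- function(x, ...) {
  lab <- if (x$criterion == "waic") c("WAIC", "p_waic") else c("LOOIC", "p_loo")
  cat(lab[1], ": ", round(x$ic_value, 1), "  (elpd ", round(x$elpd, 1),
      " +/- ", round(x$se, 1), ", ", lab[2], " ", round(x$penalty, 1),
      ", n = ", x$n_obs, ")\n", sep = "")
  if (!is.null(x$pareto_k)) {
    nk <- sum(is.finite(x$pareto_k) & x$pareto_k > 0.7)
    cat("  pareto_k > 0.7: ", nk, " of ", x$n_obs, " observations\n", sep = "")
  }
  invisible(x)
}

# generalized Pareto fit (Zhang & Stephens 2009 profile estimator with the
# weak shape prior used by standard PSIS implementations)
gpdfit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  mm <- 30 + floor(sqrt(n))
  jj <- seq_len(mm)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(mm / (jj - 0.5))) / (prior_bs * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), 0)
  l_theta <- n * (log(theta / k_j) + k_j - 1)
  w <- exp(l_theta - logsumexp(l_theta))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)  # weak prior pulls k toward 0.5
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Compare candidate models by WAIC and PSIS-LOO
#'
#' Ranks fitted candidate models on both criteria and selects the best one,
#' with a parsimony tie-break: when the elpd difference between the top model
#' and a simpler model is smaller than half the SE of that difference, the
#' simpler model (order M1 < M2 < M3 < M4) is selected. Both WAIC-based and
#' LOO-based selections are reported and disagreement is flagged.
#'
#' @param ... Named fitted [dhgm()] models (or one named list of them); all
#'   must be fitted to the same observations.
#' @param criterion Criterion driving `selected_model`: `"waic"` (default)
#'   or `"loo"`.
#' @return A `dhgm_ranking`: `table` (per model: elpd and SE for both
#'   criteria, differences vs. best with difference SEs), `selected_model`,
#'   `selected_waic`, `selected_loo`, `disagreement`.
#' @export
compare_models <- function(..., criterion = c("waic", "loo")) {
  criterion <- match.arg(criterion)
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], c("dhgm", "dhgm_samples"))) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2) stop("need at least 2 models to compare")
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) as_dhgm_samples(f)$spec$model_id, "")
  }
  lls <- lapply(fits, get_loglik)
  ns <- vapply(lls, ncol, 1L)
  if (length(unique(ns)) > 1) stop("models fitted to different observation sets")
  w <- lapply(lls, waic)
  l <- lapply(lls, function(m) suppressWarnings(psis_loo(m)))
  tab <- data.frame(
    model = names(fits),
    elpd_waic = vapply(w, `[[`, 0, "elpd"),
    se_waic = vapply(w, `[[`, 0, "se"),
    p_waic = vapply(w, `[[`, 0, "penalty"),
    elpd_loo = vapply(l, `[[`, 0, "elpd"),
    se_loo = vapply(l, `[[`, 0, "se"),
    p_loo = vapply(l, `[[`, 0, "penalty"),
    stringsAsFactors = FALSE)
  sel_w <- select_by(w, names(fits))
  sel_l <- select_by(l, names(fits))
  best <- if (criterion == "waic") sel_w else sel_l
  pw <- lapply(if (criterion == "waic") w else l, `[[`, "pointwise")
  bestpw <- pw[[best]]
  tab$elpd_diff <- vapply(pw, function(z) sum(z - bestpw), 0)
  tab$se_diff <- vapply(pw, function(z) {
    d <- z - bestpw
    sqrt(length(d) * stats::var(d))
  }, 0)
  tab <- tab[order(-if (criterion == "waic") tab$elpd_waic else tab$elpd_loo), ]
  structure(
    list(table = tab, selected_model = best, selected_waic = sel_w,
         selected_loo = sel_l, disagreement = !identical(sel_w, sel_l),
         criterion = criterion, waic = w, loo = l),
    class = "dhgm_ranking")
}

# maximal-elpd selection with the parsimony tie-break (M1 < M2 < M3 < M4)
select_by <- function(ics, model_names) {
  elpd <- vapply(ics, `[[`, 0, "elpd")
  pw <- lapply(ics, `[[`, "pointwise")
  complexity <- match(model_names, c("M1", "M2", "M3", "M4"))
  complexity[is.na(complexity)] <- seq_along(model_names)[is.na(complexity)] + 4
  best <- which.max(elpd)
  candidates <- seq_along(ics)
  for (j in candidates[order(complexity)]) {
    if (j == best) break
    d <- pw[[best]] - pw[[j]]
    se_d <- sqrt(length(d) * stats::var(d))
    if (abs(sum(d)) <= 0.5 * se_d && complexity[j] < complexity[best]) {
      best <- j
      break
    }
  }
  model_names[best]
}

#' @export
print.dhgm_ranking <- function(x, ...) {
  cat("Model comparison (", length(x$waic), " models, n = ",
      x$waic[[1]]$n_obs, " observations)\n", sep = "")
  print(transform(x$table,
                  elpd_waic = round(elpd_waic, 1), se_waic = round(se_waic, 1),
                  p_waic = round(p_waic, 1), elpd_loo = round(elpd_loo, 1),
                  se_loo = round(se_loo, 1), p_loo = round(p_loo, 1),
                  elpd_diff = round(elpd_diff, 1), se_diff = round(se_diff, 1)),
        row.names = FALSE)
  cat("Selected (", x$criterion, "): ", x$selected_model, sep = "")
  if (x$disagreement) {
    cat("  [WAIC and LOO disagree: ", x$selected_waic, " vs ", x$selected_loo, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}
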