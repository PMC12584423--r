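#' Fit a double-hierarchical Gaussian model by Gibbs sampling
#'
#' Posterior sampler for the hierarchical model
#' \deqn{y_k = x_k' \beta + a_{i(k)} + \epsilon_k, \quad
#'       a_i \sim N(0, \sigma_{A,g(i)}^2), \quad
#'       \epsilon_k \sim N(0, \sigma_{W,g(k)}^2),}
#' where the among-individual SD \eqn{\sigma_A} and the residual
#' (within-individual) SD \eqn{\sigma_W} are shared or group-specific
#' according to the model specification carried by `design`.
#'
#' The sampler is a full conjugate Gibbs scheme: \eqn{(\beta, a)} are updated
#' jointly from their multivariate-normal full conditional given the SDs, and
#' each variance is updated from its inverse-gamma full conditional obtained
#' by writing the half-Student-t prior as an inverse-gamma scale mixture.
#' No step requires tuning, and warmup draws are always discarded.
#'
#' @param y Response vector (standardized trait values).
#' @param design A `dhgm_design` from [build_design()]; its `spec` determines
#'   which SDs are group-specific.
#' @param prior A [prior_config()].
#' @param chains Number of chains (default 4).
#' @param warmup Discarded iterations per chain (default 1000).
#' @param samples Retained post-warmup draws per chain before thinning
#'   (default 2000).
#' @param thin Thinning interval (default 1).
#' @param seed Master seed; chain c runs with the deterministic seed
#'   `(seed + 104729 * c) mod 2147483629`, so runs are bit-reproducible.
#' @param compute_loglik Store the pointwise conditional log-likelihood
#'   matrix (draws x observations) needed for WAIC/LOO (default `TRUE`).
#' @param diag_warn Warn when split-R-hat / bulk-ESS miss the default
#'   thresholds (1.01 / 400) on the model parameters (default `TRUE`).
#' @param sigma_A_fixed,sigma_W_fixed Optionally hold an SD component fixed
#'   at the given value(s) instead of sampling it (length 1 or one value per
#'   group). Intended for validation against closed-form conditional
#'   posteriors.
#'
#' @return A `dhgm_samples` object: `draws` (matrices `beta`, `a`, `sigma_A`,
#'   `sigma_W`, rows = retained draws), `chain` (chain index per draw),
#'   `loglik` (draws x n matrix or `NULL`), `diagnostics` (per-parameter
#'   split-R-hat and bulk-ESS), `spec`, `config`.
#' @seealso [dhgm()] for the formula front end, [check_convergence()].
#' @export
fit_mcmc <- function(y, design, prior = prior_config(), chains = 4,
                     warmup = 1000, samples = 2000, thin = 1, seed = 1,
                     compute_loglik = TRUE, diag_warn = TRUE,
                     sigma_A_fixed = NULL, sigma_W_fixed = NULL) {
  stopifnot(chains >= 1, warmup >= 0, samples >= 1, thin >= 1)
  spec <- design$spec
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  m <- length(design$individuals)
  G <- length(design$groups)
  GA <- n_sd_groups(spec$va_by_group, G)
  GW <- n_sd_groups(spec$vw_by_group, G)
  ga_ind <- if (GA > 1) design$gi else rep(1L, m)
  gw_obs <- if (GW > 1) design$gk else rep(1L, n)

  if (n > 0 && n < p + 2) stop("too few observations: n = ", n, ", p = ", p)
  if (m > 0) {
    Z <- matrix(0, n, m)
    if (n > 0) Z[cbind(seq_len(n), design$indiv)] <- 1
    W <- cbind(X, Z)
  } else {
    W <- X
  }
  q <- p + m

  # per residual-SD group: precomputed cross-products (the only data the
  # (beta, a) update needs each iteration)
  idx_w <- lapply(seq_len(GW), function(g) which(gw_obs == g))
  Cg <- lapply(idx_w, function(ix) if (length(ix)) crossprod(W[ix, , drop = FALSE]) else matrix(0, q, q))
  bg <- lapply(idx_w, function(ix) if (length(ix)) drop(crossprod(W[ix, , drop = FALSE], y[ix])) else numeric(q))
  ng <- vapply(idx_w, length, 1L)
  idx_a <- lapply(seq_len(GA), function(g) which(ga_ind == g))
  mg <- vapply(idx_a, length, 1L)

  nu <- prior$sd_df
  s2 <- prior$sd_scale^2
  beta_prec <- 1 / prior$beta_scale^2
  kept <- samples %/% thin
  total <- warmup + kept * thin

  out_beta <- matrix(NA_real_, chains * kept, p,
                     dimnames = list(NULL, colnames(X)))
  out_a <- matrix(NA_real_, chains * kept, m,
                  dimnames = list(NULL, if (m) paste0("a[", design$individuals, "]")))
  out_sa <- matrix(NA_real_, chains * kept, GA,
                   dimnames = list(NULL, paste0("sigma_A",
                     if (GA > 1) paste0("[", design$groups, "]") else "")))
  out_sw <- matrix(NA_real_, chains * kept, GW,
                   dimnames = list(NULL, paste0("sigma_W",
                     if (GW > 1) paste0("[", design$groups, "]") else "")))
  chain_id <- rep(seq_len(chains), each = kept)

  fixA <- !is.null(sigma_A_fixed)
  fixW <- !is.null(sigma_W_fixed)
  if (fixA) stopifnot(length(sigma_A_fixed) %in% c(1L, GA), all(sigma_A_fixed > 0))
  if (fixW) stopifnot(length(sigma_W_fixed) %in% c(1L, GW), all(sigma_W_fixed > 0))

  for (ch in seq_len(chains)) {
    set.seed(chain_seed(seed, ch))
    sig2A <- if (fixA) rep(sigma_A_fixed^2, length.out = GA) else rep(1, GA)
    sig2W <- if (fixW) rep(sigma_W_fixed^2, length.out = GW) else rep(1, GW)
    xiA <- rep(1, GA); xiW <- rep(1, GW)
    row0 <- (ch - 1L) * kept
    stored <- 0L
    for (it in seq_len(total)) {
      # --- joint (beta, a) block: MVN full conditional ---
      lam <- 1 / sig2W
      Q <- matrix(0, q, q)
      rhs <- numeric(q)
      for (g in seq_len(GW)) {
        if (ng[g]) {
          Q <- Q + lam[g] * Cg[[g]]
          rhs <- rhs + lam[g] * bg[[g]]
        }
      }
      dprior <- c(rep(beta_prec, p), if (m) 1 / sig2A[ga_ind])
      diag(Q) <- diag(Q) + dprior
      U <- tryCatch(chol(Q), error = function(e)
        stop("divergent state: non-PD precision in (beta,a) update (chain ",
             ch, ", iteration ", it, ")", call. = FALSE))
      mu <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
      theta <- mu + backsolve(U, stats::rnorm(q))
      if (any(!is.finite(theta))) {
        stop("divergent state: non-finite draw in (beta,a) update (chain ",
             ch, ", iteration ", it, "); sig2W = ",
             paste(signif(sig2W, 3), collapse = ","), call. = FALSE)
      }
      a <- if (m) theta[(p + 1):q] else numeric(0)

      # --- residual variances: inverse-gamma full conditionals ---
      if (!fixW) {
        r <- if (n) y - drop(W %*% theta) else numeric(0)
        for (g in seq_len(GW)) {
          ssr <- if (ng[g]) sum(r[idx_w[[g]]]^2) else 0
          sig2W[g] <- rinvgamma(1, (nu + ng[g]) / 2, nu / xiW[g] + ssr / 2)
          xiW[g] <- rinvgamma(1, (nu + 1) / 2, nu / sig2W[g] + 1 / s2)
        }
      }
      # --- among-individual variances ---
      if (!fixA) {
        for (g in seq_len(GA)) {
          ssa <- if (mg[g]) sum(a[idx_a[[g]]]^2) else 0
          sig2A[g] <- rinvgamma(1, (nu + mg[g]) / 2, nu / xiA[g] + ssa / 2)
          xiA[g] <- rinvgamma(1, (nu + 1) / 2, nu / sig2A[g] + 1 / s2)
        }
      }

      if (it > warmup && (it - warmup) %% thin == 0L) {
        stored <- stored + 1L
        out_beta[row0 + stored, ] <- theta[seq_len(p)]
        if (m) out_a[row0 + stored, ] <- a
        out_sa[row0 + stored, ] <- sqrt(sig2A)
        out_sw[row0 + stored, ] <- sqrt(sig2W)
      }
    }
  }

  draws <- list(beta = out_beta, a = out_a, sigma_A = out_sa, sigma_W = out_sw)
  loglik <- if (compute_loglik && n > 0) loglik_matrix_from_draws(draws, design) else NULL

  diagnostics <- mcmc_diagnostics(draws, chain_id, chains)
  res <- structure(
    list(draws = draws, chain = chain_id, loglik = loglik,
         diagnostics = diagnostics, spec = spec, groups = design$groups,
         n_obs = n, n_individuals = m,
         config = list(chains = chains, warmup = warmup, samples = samples,
                       thin = thin, seed = seed)),
    class = "dhgm_samples")
  if (diag_warn && chains > 1) {
    core <- diagnostics[!startsWith(diagnostics$parameter, "a["), ]
    bad <- core[!is.na(core$rhat) & (core$rhat > 1.01 | core$ess < 400), ]
    if (nrow(bad)) {
      warning("convergence diagnostics below default thresholds for: ",
              paste(bad$parameter, collapse = ", "),
              " (max R-hat ", signif(max(bad$rhat), 4), ", min ESS ",
              round(min(bad$ess)), "); consider longer chains", call. = FALSE)
    }
  }
  res
}

# pointwise conditional log-likelihood, draws x observations
loglik_matrix_from_draws <- function(draws, design) {
  mu <- draws$beta %*% t(design$X)
  if (length(design$individuals)) mu <- mu + draws$a[, design$indiv, drop = FALSE]
  GW <- ncol(draws$sigma_W)
  sdm <- if (GW > 1) draws$sigma_W[, design$gk, drop = FALSE]
         else matrix(draws$sigma_W[, 1], nrow(mu), ncol(mu))
  yk <- matrix(design$y, nrow(mu), ncol(mu), byrow = TRUE)
  -0.5 * log(2 * pi) - log(sdm) - 0.5 * ((yk - mu) / sdm)^2
}

mcmc_diagnostics <- function(draws, chain_id, chains) {
  mats <- do.call(cbind, draws[vapply(draws, ncol, 1L) > 0])
  params <- colnames(mats)
  rhat <- ess <- rep(NA_real_, length(params))
  for (j in seq_along(params)) {
    x <- matrix(mats[, j], ncol = chains)
    rhat[j] <- split_rhat(x)
    ess[j] <- ess_bulk(x)
  }
  data.frame(parameter = params, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}

#' Split-R-hat of a set of chains
#'
#' Potential-scale-reduction statistic computed after splitting each chain in
#' half, so within-chain trends inflate the statistic. Returns `NA` (with no
#' error) for a single chain of length < 4 or zero-variance draws.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return The split-R-hat value, or `NA` if undefined.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  ns <- nrow(x) %/% 2
  if (ns < 2) return(NA_real_)
  halves <- cbind(x[seq_len(ns), , drop = FALSE],
                  x[(nrow(x) - ns + 1):nrow(x), , drop = FALSE])
  W <- mean(apply(halves, 2, stats::var))
  B <- ns * stats::var(colMeans(halves))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((ns - 1) / ns * W + B / ns) / W)
}

#' Bulk effective sample size
#'
#' Rank-normalized, split-chain effective sample size: draws are mapped to
#' normal scores, chains split in half, and the multi-chain autocorrelation
#' sequence summed with Geyer's initial monotone truncation.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Estimated effective sample size (`NA` if undefined).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  ns <- nrow(x) %/% 2
  if (ns < 4) return(NA_real_)
  x <- cbind(x[seq_len(ns), , drop = FALSE],
             x[(nrow(x) - ns + 1):nrow(x), , drop = FALSE])
  if (stats::sd(x) == 0) return(NA_real_)
  # rank-normalize pooled draws
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
  x <- matrix(z, nrow = ns)
  M <- ncol(x)
  acov <- apply(x, 2, autocov_fft)
  if (is.null(dim(acov))) acov <- matrix(acov, nrow = ns)
  mean_var <- mean(acov[1, ]) * ns / (ns - 1)
  var_plus <- mean_var * (ns - 1) / ns
  if (M > 1) var_plus <- var_plus + stats::var(colMeans(x))
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  max_t <- ns - 1
  # Geyer initial positive sequence over pairs (lag 1,2), (3,4), ...
  tau <- rho[1]
  t <- 2
  pair_prev <- Inf
  while (t + 1 <= max_t + 1) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, pair_prev)  # initial monotone sequence
    tau <- tau + 2 * pair
    pair_prev <- pair
    t <- t + 2
  }
  ess <- M * ns / max(tau, 1e-12)
  min(ess, M * ns * log10(M * ns))  # cap as in rank-normalized ESS practice
}

# biased autocovariance via FFT (divides by n, as the ESS estimator expects)
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  MM <- stats::nextn(2 * n)
  f <- stats::fft(c(x, rep(0, MM - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (as.numeric(MM) * n)
}

#' Convergence report for a fitted model
#'
#' @param samples A `dhgm_samples` or fitted [dhgm()] object.
#' @param rhat_max Maximum acceptable split-R-hat (default 1.01).
#' @param ess_min Minimum acceptable bulk-ESS (default 400).
#' @param include_ranef Include the per-individual intercepts in the pass
#'   criterion (default `FALSE`; they are always listed in the table).
#' @return A `dhgm_convergence` list: `table` (parameter, rhat, ess, ok),
#'   `pass` (logical), `rhat_max`, `ess_min`. Never mutates the draws. With a
#'   single chain R-hat is unavailable and a warning is issued.
#' @export
check_convergence <- function(samples, rhat_max = 1.01, ess_min = 400,
                              include_ranef = FALSE) {
  samples <- as_dhgm_samples(samples)
  d <- samples$diagnostics
  if (samples$config$chains < 2) {
    warning("R-hat requires at least 2 chains; diagnostics incomplete", call. = FALSE)
  }
  d$ok <- !is.na(d$rhat) & d$rhat <= rhat_max & !is.na(d$ess) & d$ess >= ess_min
  scope <- if (include_ranef) d else d[!startsWith(d$parameter, "a["), ]
  degenerate <- any(is.na(scope$rhat))
  if (degenerate) {
    warning("R-hat undefined for some parameters (zero-variance or too-short chains)",
            call. = FALSE)
  }
  structure(list(table = d, pass = all(scope$ok) && !degenerate,
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "dhgm_convergence")
}

#' @export
print.dhgm_convergence <- function(x, ...) {
  core <- x$table[!startsWith(x$table$parameter, "a["), ]
  cat("Convergence check (R-hat <= ", x$rhat_max, ", ESS >= ", x$ess_min, "): ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  print(core, row.names = FALSE, digits = 4)
  invisible(x)
}

as_dhgm_samples <- function(x) {
  if (inherits(x, "dhgm")) x$samples
  else if (inherits(x, "dhgm_samples")) x
  else stop("expected a 'dhgm' fit or 'dhgm_samples' object")
}
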