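#' Repeatability (intraclass correlation) of a behavioral trait
#'
#' `R = Va / (Va + Vw)`: the fraction of phenotypic variance attributable to
#' consistent differences among individuals. Vectorized over its arguments.
#'
#' @param va Among-individual variance(s), `>= 0`.
#' @param vw Within-individual variance(s), `>= 0`.
#' @return Repeatability value(s) in `[0, 1]`.
#' @examples
#' repeatability(1, 1)   # 0.5
#' repeatability(3, 1)   # 0.75
#' @export
repeatability <- function(va, vw) {
  if (any(va < 0) || any(vw < 0)) stop("variances must be non-negative")
  tot <- va + vw
  if (any(tot == 0)) stop("undefined repeatability: va + vw = 0")
  va / tot
}

#' Per-group posterior variance components
#'
#' Expands the posterior draws of a fitted model into per-group draws of
#' among-individual variance (Va = sigma_A^2), within-individual variance
#' (Vw = sigma_W^2) and repeatability (R = Va/(Va+Vw), computed draw-wise).
#' For model specifications with a shared component, every group's draws are
#' the shared draws, so group contrasts of that component are exactly zero.
#'
#' @param samples A fitted [dhgm()] model or `dhgm_samples` object.
#' @return A `dhgm_varcomp`: `groups`, draw matrices `va`, `vw`, `r`
#'   (draws x groups), and `summary` (per group and quantity: mean and
#'   2.5/25/50/75/97.5% quantiles).
#' @export
variance_components <- function(samples) {
  s <- as_dhgm_samples(samples)
  G <- length(s$groups)
  sa <- s$draws$sigma_A
  sw <- s$draws$sigma_W
  va <- (if (ncol(sa) == 1) sa[, rep(1, G), drop = FALSE] else sa)^2
  vw <- (if (ncol(sw) == 1) sw[, rep(1, G), drop = FALSE] else sw)^2
  colnames(va) <- colnames(vw) <- s$groups
  r <- va / (va + vw)
  sm <- do.call(rbind, lapply(c(va = "va", vw = "vw", r = "r"), function(qt) {
    mat <- switch(qt, va = va, vw = vw, r = r)
    data.frame(group = s$groups, quantity = qt, mean = colMeans(mat),
               q2.5 = apply(mat, 2, stats::quantile, 0.025),
               q25 = apply(mat, 2, stats::quantile, 0.25),
               q50 = apply(mat, 2, stats::quantile, 0.50),
               q75 = apply(mat, 2, stats::quantile, 0.75),
               q97.5 = apply(mat, 2, stats::quantile, 0.975),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(sm) <- NULL
  structure(list(groups = s$groups, va = va, vw = vw, r = r,
                 model = s$spec$model_id, summary = sm),
            class = "dhgm_varcomp")
}

#' @export
print.dhgm_varcomp <- function(x, digits = 3, ...) {
  cat("Variance components (model ", x$model, ", ", nrow(x$va),
      " draws per group)\n", sep = "")
  sm <- x$summary
  sm[, -(1:2)] <- round(sm[, -(1:2)], digits)
  print(sm, row.names = FALSE)
  invisible(x)
}

#' Posterior summary of the population, sex and interaction effects
#'
#' Posterior mean and equal-tailed 95% credible interval for each
#' population, sex and population-by-sex coefficient of the mean model, on
#' the standardized-trait scale.
#'
#' @param samples A fitted [dhgm()] model (needs the design's term mapping).
#' @param terms Which fixed-effect terms to summarize; default all
#'   non-intercept, non-context terms (population, sex, interaction).
#' @return A data.frame with columns `term`, `estimate`, `lower95`, `upper95`.
#' @export
fixed_effect_summary <- function(samples, terms = NULL) {
  fit <- if (inherits(samples, "dhgm")) samples else stop("needs a fitted 'dhgm' object")
  d <- fit$design
  beta <- fit$samples$draws$beta
  assign_idx <- d$terms
  labels <- c("(Intercept)", d$term_labels)[assign_idx + 1]
  keep_terms <- terms %||% setdiff(unique(labels), c("(Intercept)", "context"))
  missing_terms <- setdiff(keep_terms, labels)
  if (length(missing_terms)) {
    stop("term(s) absent from the model: ", paste(missing_terms, collapse = ", "))
  }
  keep <- labels %in% keep_terms
  data.frame(
    term = colnames(beta)[keep],
    estimate = colMeans(beta[, keep, drop = FALSE]),
    lower95 = apply(beta[, keep, drop = FALSE], 2, stats::quantile, 0.025),
    upper95 = apply(beta[, keep, drop = FALSE], 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise posterior contrasts of variance components between groups
#'
#' Builds the pairwise contrast table of a per-group quantity (`vw`, `va` or
#' `r`): for every ordered group pair the contrast draws are computed
#' per-iteration (paired draws, never summary-of-summaries), then summarized
#' by the posterior mean and equal-tailed 95% credible interval. A contrast
#' is flagged `substantial` when its 95% interval excludes zero.
#'
#' For repeatability contrasts, pairs involving a group whose among-individual
#' variance is indistinguishable from zero are additionally flagged `na_flag`
#' (repeatability is not meaningful there); the raw value is retained. Since
#' posterior Va draws are strictly positive, "indistinguishable from zero" is
#' operationalized as the 2.5% quantile of Va falling below 1% of that
#' group's posterior-median total phenotypic variance (Va + Vw).
#'
#' @param vc A `dhgm_varcomp` from [variance_components()] (or a fitted
#'   [dhgm()] model).
#' @param quantity One of `"vw"`, `"r"`, `"va"`.
#' @return A `dhgm_contrasts` data.frame with one row per ordered pair
#'   (`row`, `col`): `mean`, `lower95`, `upper95`, `substantial`, `na_flag`.
#'   Entry (row, col) is value(row group) - value(col group); diagonal rows
#'   are exactly zero and never substantial.
#' @export
contrast_table <- function(vc, quantity = c("vw", "r", "va")) {
  quantity <- match.arg(quantity)
  if (inherits(vc, c("dhgm", "dhgm_samples"))) vc <- variance_components(vc)
  mat <- vc[[quantity]]
  groups <- vc$groups
  G <- length(groups)
  if (G < 2) stop("need at least 2 groups")
  va_includes_zero <- vapply(seq_len(G), function(g) {
    unname(stats::quantile(vc$va[, g], 0.025)) <
      0.01 * stats::median(vc$va[, g] + vc$vw[, g])
  }, logical(1))
  rows <- list()
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (i == j) {
        rows[[length(rows) + 1]] <- data.frame(
          row = groups[i], col = groups[j], mean = 0, lower95 = 0, upper95 = 0,
          substantial = FALSE, na_flag = FALSE, stringsAsFactors = FALSE)
      } else {
        d <- mat[, i] - mat[, j]
        ci <- stats::quantile(d, c(0.025, 0.975))
        rows[[length(rows) + 1]] <- data.frame(
          row = groups[i], col = groups[j], mean = mean(d),
          lower95 = ci[[1]], upper95 = ci[[2]],
          substantial = ci[[1]] > 0 || ci[[2]] < 0,
          na_flag = quantity == "r" && (va_includes_zero[i] || va_includes_zero[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "quantity") <- quantity
  attr(out, "groups") <- groups
  class(out) <- c("dhgm_contrasts", "data.frame")
  out
}

#' Format upper/lower-triangle contrast tables as one square matrix
#'
#' Renders two contrast tables in the square layout used for reporting:
#' `upper` (e.g. within-individual variance differences) above the diagonal
#' and `lower` (e.g. repeatability differences) below it, each cell showing
#' `mean (lower95, upper95)`, a `*` marker for substantial contrasts and
#' `NA` for flagged repeatability contrasts.
#'
#' @param upper,lower `dhgm_contrasts` tables over the same groups.
#' @param digits Digits for rounding (default 2).
#' @return A character matrix with group row/column names.
#' @export
format_contrast_matrix <- function(upper, lower, digits = 2) {
  groups <- attr(upper, "groups")
  stopifnot(identical(groups, attr(lower, "groups")))
  G <- length(groups)
  out <- matrix("-", G, G, dimnames = list(groups, groups))
  fmt <- function(tb, i, j) {
    r <- tb[tb$row == groups[i] & tb$col == groups[j], ]
    if (r$na_flag) return("NA")
    paste0(round(r$mean, digits), " (", round(r$lower95, digits), ", ",
           round(r$upper95, digits), ")", if (r$substantial) " *")
  }
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i < j) out[i, j] <- fmt(upper, i, j)
    if (i > j) out[i, j] <- fmt(lower, i, j)
  }
  out
}

#' @export
print.dhgm_contrasts <- function(x, digits = 3, ...) {
  cat("Pairwise group contrasts of ",
      switch(attr(x, "quantity"), vw = "within-individual variance (Vw)",
             va = "among-individual variance (Va)", r = "repeatability (R)"),
      "\n", sep = "")
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits)
  df$lower95 <- round(df$lower95, digits)
  df$upper95 <- round(df$upper95, digits)
  print(df[df$row != df$col, ], row.names = FALSE)
  invisible(x)
}
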