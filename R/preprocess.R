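#' Standardize a behavioral trait to mean 0, SD 1
#'
#' Centers and scales the `value` column of a trial table (optionally
#' restricted to one trait) so the analysed column has sample mean 0 and
#' sample standard deviation 1 (n - 1 convention). The transformation is
#' recorded so it can be inverted exactly.
#'
#' @param table A `trial_table` (or compatible data.frame).
#' @param trait Optional trait label; defaults to all rows (single-trait
#'   tables).
#' @return A list with elements `table` (standardized values) and `record`
#'   (a `preprocess_record` storing the centering mean and scaling SD).
#' @examples
#' tab <- simulate_study(study_scenario(seed = 1))
#' std <- standardize_trait(tab)
#' c(mean(std$table$value), stats::sd(std$table$value))
#' @export
standardize_trait <- function(table, trait = NULL) {
  idx <- trait_rows(table, trait)
  v <- table$value[idx]
  if (length(unique(v)) < 2) {
    stop("degenerate data: trait column is constant, cannot standardize", call. = FALSE)
  }
  m <- mean(v)
  s <- stats::sd(v)
  table$value[idx] <- (v - m) / s
  record <- structure(
    list(trait = trait %||% unique(as.character(table$trait[idx])),
         transform = "none", lambda = NA_real_,
         exclude_context = NULL,
         standardize_mean = m, standardize_sd = s),
    class = "preprocess_record")
  list(table = table, record = record)
}

#' Gaussianize a behavioral trait by a Yeo-Johnson power transform
#'
#' Applies a monotone Yeo-Johnson power transform with the parameter chosen by
#' maximum likelihood (profile likelihood over lambda), to pull a skewed trait
#' toward a Gaussian shape before model fitting. A subset of contexts can be
#' exempted from the transformation (their rows are passed through unchanged),
#' mirroring analyses in which one trait-context series is already
#' Gaussian-looking.
#'
#' @param table A `trial_table`.
#' @param trait Optional trait label (defaults to all rows).
#' @param exclude_context Character vector of context levels to leave
#'   untransformed; the lambda is estimated on the remaining rows only.
#' @param transform `"yeo_johnson"` (default) or `"none"` (identity).
#' @return A list with `table` (transformed values) and `record` (a
#'   `preprocess_record` storing the fitted lambda and exclusions).
#' @details If the likelihood optimization fails the function falls back to
#'   `transform = "none"` with a warning. The transform is applied before
#'   standardization in [run_full_analysis()].
#' @export
gaussianize_trait <- function(table, trait = NULL, exclude_context = NULL,
                              transform = c("yeo_johnson", "none")) {
  transform <- match.arg(transform)
  idx <- trait_rows(table, trait)
  use <- idx & !(as.character(table$context) %in% exclude_context)
  record <- structure(
    list(trait = trait %||% unique(as.character(table$trait[idx])),
         transform = "none", lambda = NA_real_,
         exclude_context = exclude_context,
         standardize_mean = 0, standardize_sd = 1),
    class = "preprocess_record")
  if (transform == "none" || !any(use)) {
    return(list(table = table, record = record))
  }
  lambda <- tryCatch({
    pt <- car::powerTransform(table$value[use], family = "yjPower")
    as.numeric(stats::coef(pt))
  }, error = function(e) {
    warning("Yeo-Johnson likelihood optimization failed (", conditionMessage(e),
            "); falling back to no transformation", call. = FALSE)
    NA_real_
  })
  if (is.na(lambda)) return(list(table = table, record = record))
  table$value[use] <- car::yjPower(table$value[use], lambda)
  record$transform <- "yeo_johnson"
  record$lambda <- lambda
  list(table = table, record = record)
}

trait_rows <- function(table, trait) {
  if (is.null(trait)) rep(TRUE, nrow(table)) else as.character(table$trait) == trait
}

#' Apply or invert a preprocessing record
#'
#' `apply_preprocess()` maps raw values to the analysis scale exactly as the
#' recorded steps did; `invert_preprocess()` is its exact inverse
#' (unstandardize, then invert the Yeo-Johnson transform analytically).
#'
#' @param values Numeric vector on the raw (`apply_preprocess`) or analysis
#'   (`invert_preprocess`) scale.
#' @param record A `preprocess_record`, or a list of them applied in order
#'   (e.g. `list(gaussianize_record, standardize_record)`).
#' @param context Optional character vector of contexts (same length as
#'   `values`) so context exclusions recorded in the transform are honored.
#' @return Numeric vector of the same length.
#' @export
apply_preprocess <- function(values, record, context = NULL) {
  for (rec in as_record_list(record)) {
    if (rec$transform == "yeo_johnson") {
      use <- if (is.null(context)) rep(TRUE, length(values)) else
        !(as.character(context) %in% rec$exclude_context)
      values[use] <- car::yjPower(values[use], rec$lambda)
    }
    values <- (values - rec$standardize_mean) / rec$standardize_sd
  }
  values
}

#' @rdname apply_preprocess
#' @export
invert_preprocess <- function(values, record, context = NULL) {
  for (rec in rev(as_record_list(record))) {
    values <- values * rec$standardize_sd + rec$standardize_mean
    if (rec$transform == "yeo_johnson") {
      use <- if (is.null(context)) rep(TRUE, length(values)) else
        !(as.character(context) %in% rec$exclude_context)
      values[use] <- yj_inverse(values[use], rec$lambda)
    }
  }
  values
}

# analytic inverse of the Yeo-Johnson transform
yj_inverse <- function(y, lambda) {
  x <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) > 1e-12) {
    x[pos] <- (lambda * y[pos] + 1)^(1 / lambda) - 1
  } else {
    x[pos] <- expm1(y[pos])
  }
  if (abs(2 - lambda) > 1e-12) {
    x[!pos] <- 1 - (1 - (2 - lambda) * y[!pos])^(1 / (2 - lambda))
  } else {
    x[!pos] <- 1 - exp(-y[!pos])
  }
  x
}

as_record_list <- function(record) {
  if (inherits(record, "preprocess_record")) list(record) else record
}

#' @export
print.preprocess_record <- function(x, ...) {
  cat("Preprocess record for trait '", paste(x$trait, collapse = ","), "': ",
      x$transform, sep = "")
  if (x$transform == "yeo_johnson") cat(" (lambda = ", signif(x$lambda, 4), ")", sep = "")
  if (length(x$exclude_context)) {
    cat(", contexts exempt:", paste(x$exclude_context, collapse = ", "))
  }
  cat("; center =", signif(x$standardize_mean, 4),
      "scale =", signif(x$standardize_sd, 4), "\n")
  invisible(x)
}
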