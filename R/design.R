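#' Candidate variance-structure specifications
#'
#' The candidate set contains four nested double-hierarchical Gaussian models
#' that differ only in which variance components are allowed to vary across
#' population-by-sex groups:
#'
#' * `M1` (null): one among-individual SD, one within-individual (residual) SD.
#' * `M2`: among-individual SD varies by group; residual SD shared.
#' * `M3`: residual SD varies by group; among-individual SD shared.
#' * `M4`: both SDs vary by group.
#'
#' All four share the same mean model: fixed effects for population, sex,
#' their interaction and context (treatment coding, first level as baseline),
#' plus a random intercept per individual. In M2/M4 the random intercept's
#' prior SD depends on the individual's group; no individual-level slopes over
#' context are fitted.
#'
#' @param model One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param formula Fixed-effect formula for the mean model; default
#'   `value ~ population * sex + context`.
#' @param groups Optional character vector of the 4 group labels in display
#'   order; if `NULL` it is derived from the data (population-major order,
#'   e.g. PKF, PKM, PMF, PMM).
#' @return A `model_spec` object.
#' @export
model_spec <- function(model = c("M1", "M2", "M3", "M4"),
                       formula = value ~ population * sex + context,
                       groups = NULL) {
  model <- match.arg(model)
  flags <- switch(model,
    M1 = c(FALSE, FALSE), M2 = c(TRUE, FALSE),
    M3 = c(FALSE, TRUE),  M4 = c(TRUE, TRUE))
  structure(
    list(model_id = model, va_by_group = flags[1], vw_by_group = flags[2],
         formula = formula, groups = groups),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model ", x$model_id, ": among-individual SD ",
      if (x$va_by_group) "by group" else "shared",
      ", residual SD ", if (x$vw_by_group) "by group" else "shared", "\n",
      "  mean model: ", deparse(x$formula), "\n", sep = "")
  invisible(x)
}

#' Build design structures for a trial table
#'
#' Assembles the fixed-effect design matrix (treatment coding), the
#' observation-to-individual incidence map, and the group index per individual
#' and per observation.
#'
#' @param table A `trial_table` (see [as_trial_table()]).
#' @param spec A `model_spec`.
#' @return A `dhgm_design` list with elements `X` (n x p design), `y`
#'   (response), `indiv` (integer individual index per observation),
#'   `individuals` (labels), `gi` (group index per individual), `gk` (group
#'   index per observation), `groups` (group labels) and `spec`.
#' @details Factor terms with a single observed level raise a rank-deficiency
#'   error naming the term; an aliased design matrix raises an error naming
#'   the aliased columns. Row order of `table` never affects downstream
#'   results (individuals and groups are indexed by sorted label).
#' @export
build_design <- function(table, spec = model_spec("M1")) {
  table <- if (inherits(table, "trial_table")) table else as_trial_table(table)
  mf_vars <- all.vars(spec$formula)
  for (v in setdiff(mf_vars, "value")) {
    col <- table[[v]]
    if (is.null(col)) stop("term '", v, "' not found in the trial table", call. = FALSE)
    if (is.factor(col) && length(unique(as.character(col[!is.na(col)]))) < 2) {
      stop("rank deficiency: term '", v, "' has a single observed level", call. = FALSE)
    }
  }
  X <- stats::model.matrix(spec$formula, data = table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  individuals <- sort(unique(as.character(table$individual)))
  indiv <- match(as.character(table$individual), individuals)
  grp <- trial_group(table)
  groups <- spec$groups %||% levels(grp)
  if (!all(levels(grp) %in% groups)) {
    stop("group labels in data (", paste(levels(grp), collapse = ", "),
         ") do not match spec groups (", paste(groups, collapse = ", "), ")")
  }
  gk <- match(as.character(grp), groups)
  gi <- gk[match(individuals, as.character(table$individual))]
  y <- stats::model.response(stats::model.frame(spec$formula, data = table))
  # canonical observation order (individual, context, trait): fits are exactly
  # invariant to the row order of the input table
  ord <- order(indiv, as.integer(table$context), as.character(table$trait))
  rownames(X) <- NULL
  structure(
    list(X = X[ord, , drop = FALSE], y = as.numeric(y)[ord],
         indiv = indiv[ord], individuals = individuals,
         gi = gi, gk = gk[ord], groups = groups, spec = spec,
         row_order = ord,
         terms = attr(X, "assign"),
         term_labels = attr(stats::terms(spec$formula), "term.labels")),
    class = "dhgm_design")
}

# number of distinct SD parameters implied by the spec flags
n_sd_groups <- function(by_group, n_groups) if (by_group) n_groups else 1L

# map a length-1-or-G SD vector onto unit indices (one value per obs/individual)
expand_sd <- function(sd, idx) if (length(sd) == 1L) rep(sd, length(idx)) else sd[idx]
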