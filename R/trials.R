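#' Read a long-format behavioral trial table
#'
#' Reads a delimited text file with one row per individual-by-context trial and
#' validates it into the analysis-ready long format used throughout the
#' package: columns `individual`, `population`, `sex`, `context`, optionally
#' `trait`, and a numeric `value`.
#'
#' Rows with a missing trait value are dropped and counted; the count is
#' available as `attr(x, "drop_report")`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping the canonical
#'   column names (`individual`, `population`, `sex`, `context`, `trait`,
#'   `value`) to the column names used in the file, e.g.
#'   `c(individual = "lizard_id", value = "distance_cm")`. Canonical names not
#'   listed are assumed to be present verbatim.
#' @param sep Field separator, default comma.
#'
#' @return A `trial_table`: a `data.frame` with the canonical columns,
#'   `population`/`sex`/`context` as factors, and attributes `drop_report`
#'   (number of rows dropped for missing values) and `group` recording the
#'   population-by-sex group of every row.
#'
#' @details Validation enforces that each individual carries exactly one
#'   (population, sex) label pair and that no (individual, context, trait)
#'   combination is duplicated. The population-by-sex group is a pure function
#'   of the population and sex labels; its levels are ordered population-major
#'   (e.g. PKF, PKM, PMF, PMM).
#'
#' @seealso [standardize_trait()], [gaussianize_trait()], [simulate_study()]
#' @export
read_trials <- function(path, column_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("individual", "population", "sex", "context", "trait", "value")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad)) stop("unknown column_map entries: ", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  required <- setdiff(canonical, "trait")
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    individual = as.character(raw[[map["individual"]]]),
    population = as.character(raw[[map["population"]]]),
    sex        = as.character(raw[[map["sex"]]]),
    context    = as.character(raw[[map["context"]]]),
    stringsAsFactors = FALSE
  )
  out$trait <- if (map["trait"] %in% names(raw)) as.character(raw[[map["trait"]]]) else "trait"
  out$value <- suppressWarnings(as.numeric(raw[[map["value"]]]))
  n_drop <- sum(is.na(out$value))
  out <- out[!is.na(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out <- as_trial_table(out)
  attr(out, "drop_report") <- n_drop
  out
}

#' Validate a data frame as a trial table
#'
#' @param x A data.frame with columns `individual`, `population`, `sex`,
#'   `context`, `value` and optionally `trait`.
#' @return The validated `trial_table` with factor columns and a `group`
#'   attribute (population-by-sex factor, population-major level order).
#' @export
as_trial_table <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("individual", "population", "sex", "context", "value")
  miss <- setdiff(needed, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"trait" %in% names(x)) x$trait <- "trait"
  if (!all(is.finite(x$value))) stop("trait values must be finite numbers")

  # one (population, sex) pair per individual
  lab <- unique(x[, c("individual", "population", "sex")])
  dup <- lab$individual[duplicated(lab$individual)]
  if (length(dup)) {
    stop("individual(s) with conflicting population/sex labels: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  # no duplicated (individual, context, trait)
  key <- paste(x$individual, x$context, x$trait, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (individual, context, trait) row(s), e.g.: ",
         gsub("\r", " / ", key[duplicated(key)][1]), call. = FALSE)
  }
  x$population <- factor(x$population, levels = sort(unique(x$population)))
  x$sex <- factor(x$sex, levels = sort(unique(x$sex)))
  if (!is.factor(x$context)) x$context <- factor(x$context, levels = unique(x$context))
  class(x) <- c("trial_table", "data.frame")
  attr(x, "group") <- trial_group(x)
  x
}

# population-by-sex group factor, population-major level order (PKF PKM PMF PMM)
trial_group <- function(x) {
  lev <- as.vector(t(outer(levels(x$population), levels(x$sex), paste0)))
  factor(paste0(as.character(x$population), as.character(x$sex)), levels = lev)
}

#' @export
print.trial_table <- function(x, ...) {
  cat("Trial table:", nrow(x), "trials,",
      length(unique(x$individual)), "individuals,",
      nlevels(attr(x, "group")), "population-by-sex groups,",
      nlevels(x$context), "contexts\n")
  dr <- attr(x, "drop_report")
  if (!is.null(dr) && dr > 0) cat("  (", dr, " rows with missing values dropped on read)\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
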