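#' Build a formulation screening dataset
#'
#' A dataset couples a design space with screening observations: one row per
#' measurement (replicates are separate rows, never averaged) holding the
#' feature values, the measured response, a replicate index and a provenance
#' tag.
#'
#' @param space A [design_space()].
#' @param data Data frame with one column per (non-derived) feature, the
#'   response column, and optionally `replicate_id` and `source_tag`.
#'   Derived feature columns are computed from their parents when absent.
#' @param response Name of the response column.
#' @param unit Response unit label.
#' @param direction `"minimize"` (e.g. infectious titer loss) or
#'   `"maximize"` (e.g. glass transition temperature of the freeze
#'   concentrate). The direction is configured, never inferred from data.
#' @param validate `"warn"` (default) keeps out-of-bounds values with a
#'   warning — historical screening data often predates the bounds of the
#'   current design space — while `"strict"` rejects them.
#' @return An object of class `formulation_dataset`.
#' @export
formulation_dataset <- function(space, data, response,
                                unit = "",
                                direction = c("minimize", "maximize"),
                                validate = c("warn", "strict")) {
  direction <- match.arg(direction)
  validate <- match.arg(validate)
  stopifnot(inherits(space, "design_space"), is.data.frame(data))
  if (!response %in% names(data)) {
    stop_formbo(sprintf("response column '%s' not found", response), "formbo_schema_error")
  }
  data <- as.data.frame(data)
  data <- compute_derived(space, data)
  feats <- feature_names(space)
  missing <- setdiff(feats, names(data))
  if (length(missing)) {
    stop_formbo(paste0("missing feature column(s): ", paste(missing, collapse = ", ")),
                "formbo_schema_error")
  }
  for (col in c(feats, response)) {
    if (!is.numeric(data[[col]])) {
      stop_formbo(sprintf("column '%s' must be numeric", col), "formbo_parse_error")
    }
  }
  if (!"replicate_id" %in% names(data)) data$replicate_id <- 1L
  if (!"source_tag" %in% names(data)) data$source_tag <- "historical"
  bounds <- feature_bounds(space)
  check <- setdiff(feats, feature_names(space, roles = "derived"))
  for (f in check) {
    out <- data[[f]] < bounds[f, "lower"] - 1e-12 | data[[f]] > bounds[f, "upper"] + 1e-12
    if (any(out)) {
      msg <- sprintf("%d value(s) of '%s' outside [%g, %g]",
                     sum(out), f, bounds[f, "lower"], bounds[f, "upper"])
      if (validate == "strict") stop_formbo(msg, "formbo_range_error") else warning(msg, call. = FALSE)
    }
  }
  structure(
    list(space = space,
         data = data[, c(feats, response, "replicate_id", "source_tag")],
         response = response,
         response_spec = list(name = response, unit = unit, direction = direction)),
    class = "formulation_dataset"
  )
}

#' @export
print.formulation_dataset <- function(x, ...) {
  cat(sprintf("<formulation_dataset> %d observations, %d features, response '%s' (%s)\n",
              nrow(x$data), length(x$space$features), x$response,
              x$response_spec$direction))
  invisible(x)
}

#' Number of observations in a dataset
#' @param dataset A `formulation_dataset`.
#' @return Integer count of observation rows.
#' @export
n_observations <- function(dataset) nrow(dataset$data)

#' Feature matrix and response vector of a dataset
#'
#' @param dataset A `formulation_dataset`.
#' @param features Optional subset of feature names (defaults to all).
#' @return `dataset_features()`: numeric matrix (rows = observations);
#'   `dataset_response()`: numeric vector.
#' @export
dataset_features <- function(dataset, features = NULL) {
  features <- features %||% feature_names(dataset$space)
  as.matrix(dataset$data[, features, drop = FALSE])
}

#' @rdname dataset_features
#' @export
dataset_response <- function(dataset) dataset$data[[dataset$response]]

#' Read a screening dataset from CSV
#'
#' The CSV dialect is fixed: comma separator, `"."` decimal mark, UTF-8, and
#' a mandatory header naming each feature plus the response. Unknown columns
#' are ignored with a warning; absent derived-feature columns are computed
#' from their parents; row order is preserved.
#'
#' @inheritParams formulation_dataset
#' @param path CSV file path.
#' @param response Response column name.
#' @return A `formulation_dataset`.
#' @seealso [write_dataset()] for the lossless inverse.
#' @export
load_dataset <- function(path, space, response, unit = "",
                         direction = c("minimize", "maximize"),
                         validate = c("warn", "strict")) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!response %in% names(df)) {
    stop_formbo(sprintf("response column '%s' missing from %s", response, path),
                "formbo_schema_error")
  }
  feats <- feature_names(space)
  known <- c(feats, response, "replicate_id", "source_tag")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown column(s): %s", paste(unknown, collapse = ", ")),
            call. = FALSE)
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  for (col in intersect(names(df), c(feats, response))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop_formbo(sprintf("non-numeric value in column '%s', row %d", col, bad),
                  "formbo_parse_error")
    }
  }
  formulation_dataset(space, df, response, unit = unit,
                      direction = direction, validate = validate)
}

#' Write a screening dataset to CSV
#'
#' Values are written with 15 significant digits so a load/save/load
#' round-trip is lossless to 12 significant digits.
#'
#' @param dataset A `formulation_dataset`.
#' @param path Output CSV path.
#' @export
write_dataset <- function(dataset, path) {
  df <- dataset$data
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Append a derived (summed) feature to a dataset
#'
#' Mirrors the common screening practice of pooling two process sources of
#' the same compound — e.g. albumin carried over from bioprocessing plus
#' albumin spiked as an excipient — into one total-concentration feature.
#'
#' @param dataset A `formulation_dataset`.
#' @param spec A derived [feature_spec()] whose parents exist in the dataset.
#' @return A new `formulation_dataset` with the derived column appended.
#' @export
add_derived_feature <- function(dataset, spec) {
  stopifnot(inherits(dataset, "formulation_dataset"), inherits(spec, "feature_spec"))
  if (spec$role != "derived") {
    stop_formbo("spec must have role = 'derived'", "formbo_config_error")
  }
  if (spec$name %in% feature_names(dataset$space)) {
    stop_formbo(sprintf("feature '%s' already exists", spec$name), "formbo_config_error")
  }
  feats <- c(unname(dataset$space$features), list(spec))
  space2 <- design_space(feats, constraints = dataset$space$constraints)
  formulation_dataset(space2, dataset$data, dataset$response,
                      unit = dataset$response_spec$unit,
                      direction = dataset$response_spec$direction)
}

#' Scale dataset features onto the unit hypercube
#'
#' Each feature column is mapped affinely by `(v - lower) / (upper - lower)`
#' using its design-space bounds, so that a single kernel length-scale is
#' meaningful across features measured in different units. The attached
#' inverse map restores original units to within 1e-12 relative tolerance.
#'
#' @param dataset A `formulation_dataset`, or a numeric matrix if `space`
#'   is given.
#' @param space Design space (taken from the dataset when omitted).
#' @param features Optional feature subset.
#' @param strict Reject values outside bounds (default `FALSE`: values are
#'   scaled as-is and may fall outside `[0, 1]`).
#' @return List with `X` (scaled matrix) and `unscale` (function mapping a
#'   scaled matrix back to original units).
#' @export
scale_to_unit <- function(dataset, space = NULL, features = NULL, strict = FALSE) {
  if (inherits(dataset, "formulation_dataset")) {
    space <- dataset$space
    features <- features %||% feature_names(space)
    M <- dataset_features(dataset, features)
  } else {
    stopifnot(inherits(space, "design_space"))
    M <- as.matrix(dataset)
    features <- features %||% colnames(M)
  }
  b <- feature_bounds(space, features)
  if (strict) {
    out <- sweep(M, 2, b[, "lower"], "<") | sweep(M, 2, b[, "upper"], ">")
    if (any(out)) stop_formbo("value(s) outside feature bounds", "formbo_range_error")
  }
  X <- sweep(sweep(M, 2, b[, "lower"], "-"), 2, b[, "upper"] - b[, "lower"], "/")
  colnames(X) <- features
  list(
    X = X,
    unscale = function(U) {
      U <- as.matrix(U)
      out <- sweep(sweep(U, 2, b[, "upper"] - b[, "lower"], "*"), 2, b[, "lower"], "+")
      colnames(out) <- features
      out
    }
  )
}

# Scale an arbitrary matrix of original-unit values for the given features.
unit_scale_matrix <- function(space, M, features = colnames(M)) {
  scale_to_unit(as.matrix(M), space = space, features = features)$X
}
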