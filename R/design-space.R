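#' Describe a single formulation feature
#'
#' A feature is one axis of the formulation design space: an excipient
#' concentration, a process covariate (such as the starting infectious titer
#' of a batch), or a feature derived from others (such as a total
#' concentration summed over two process sources of the same protein).
#'
#' @param name Feature name (unique within a design space).
#' @param lower,upper Finite bounds in the feature's own units
#'   (`lower < upper`).
#' @param unit Unit label, metadata only (e.g. `"mg/mL"`, `"% w/v"`,
#'   `"log10 PFU/mL"`). No unit conversion is ever attempted.
#' @param role One of `"excipient"`, `"covariate"`, `"derived"`.
#' @param parents For derived features, character vector of parent feature
#'   names (at least one). Derived values are the sum of the parents.
#' @return An object of class `feature_spec`.
#' @examples
#' feature_spec("spiked_rHSA", 0, 15, unit = "mg/mL")
#' @export
feature_spec <- function(name, lower, upper, unit = "",
                         role = c("excipient", "covariate", "derived"),
                         parents = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is_number(lower) || !is_number(upper) || !(lower < upper)) {
    stop_formbo(sprintf("feature '%s': bounds must be finite with lower < upper", name),
                "formbo_config_error")
  }
  if (role == "derived" && length(parents) < 1L) {
    stop_formbo(sprintf("derived feature '%s' needs at least one parent", name),
                "formbo_config_error")
  }
  if (role != "derived" && length(parents)) {
    stop_formbo(sprintf("feature '%s': only derived features may have parents", name),
                "formbo_config_error")
  }
  structure(
    list(name = name, unit = unit, lower = as.numeric(lower),
         upper = as.numeric(upper), role = role,
         parents = as.character(parents %||% character())),
    class = "feature_spec"
  )
}

#' Assemble a formulation design space
#'
#' The design space is the ordered list of features over which screening,
#' surrogate modeling and experiment suggestion operate, together with
#' optional linear inequality constraints (for example a cap on total solute
#' to keep suggestions below solubility limits).
#'
#' @param ... `feature_spec` objects (or a single list of them).
#' @param constraints Optional list of constraints from
#'   [linear_constraint()]. Each is enforced when candidate experiments are
#'   generated, so the optimizer cannot propose physically nonsensical
#'   formulations.
#' @return An object of class `design_space`.
#' @examples
#' sp <- design_space(
#'   feature_spec("residual_rHSA", 0, 1.5, "mg/mL"),
#'   feature_spec("spiked_rHSA", 0, 15, "mg/mL"),
#'   feature_spec("total_rHSA", 0, 16.5, "mg/mL", role = "derived",
#'                parents = c("residual_rHSA", "spiked_rHSA"))
#' )
#' feature_names(sp)
#' @export
design_space <- function(..., constraints = list()) {
  feats <- list(...)
  if (length(feats) == 1L && is.list(feats[[1L]]) && !inherits(feats[[1L]], "feature_spec")) {
    feats <- feats[[1L]]
  }
  if (!length(feats) || !all(vapply(feats, inherits, logical(1), "feature_spec"))) {
    stop_formbo("design_space() expects feature_spec objects", "formbo_config_error")
  }
  nms <- vapply(feats, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_formbo("feature names must be unique", "formbo_config_error")
  }
  names(feats) <- nms
  for (f in feats) {
    if (f$role == "derived" && !all(f$parents %in% nms)) {
      stop_formbo(sprintf("derived feature '%s': parents must exist in the design space", f$name),
                  "formbo_config_error")
    }
  }
  for (ct in constraints) {
    if (!inherits(ct, "linear_constraint")) {
      stop_formbo("constraints must be linear_constraint objects", "formbo_config_error")
    }
    if (!all(names(ct$coefficients) %in% nms)) {
      stop_formbo("constraint references unknown feature(s)", "formbo_config_error")
    }
  }
  structure(list(features = feats, constraints = constraints), class = "design_space")
}

#' Linear inequality constraint over design-space features
#'
#' Encodes `sum(coefficients * values) <= rhs`.
#'
#' @param coefficients Named numeric vector of feature coefficients.
#' @param rhs Right-hand-side bound.
#' @return An object of class `linear_constraint`.
#' @export
linear_constraint <- function(coefficients, rhs) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)), is_number(rhs))
  structure(list(coefficients = coefficients, rhs = as.numeric(rhs)),
            class = "linear_constraint")
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("<design_space> %d features, %d constraints\n",
              length(x$features), length(x$constraints)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.design_space <- function(x, ...) {
  data.frame(
    name = vapply(x$features, `[[`, character(1), "name"),
    unit = vapply(x$features, `[[`, character(1), "unit"),
    lower = vapply(x$features, `[[`, numeric(1), "lower"),
    upper = vapply(x$features, `[[`, numeric(1), "upper"),
    role = vapply(x$features, `[[`, character(1), "role"),
    parents = vapply(x$features, function(f) paste(f$parents, collapse = "+"),
                     character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Feature names of a design space
#'
#' @param space A `design_space`.
#' @param roles Optional subset of roles to keep.
#' @return Character vector of names, in design-space order.
#' @export
feature_names <- function(space, roles = NULL) {
  stopifnot(inherits(space, "design_space"))
  nms <- names(space$features)
  if (!is.null(roles)) {
    keep <- vapply(space$features, function(f) f$role %in% roles, logical(1))
    nms <- nms[keep]
  }
  nms
}

feature_bounds <- function(space, features = feature_names(space)) {
  lo <- vapply(space$features[features], `[[`, numeric(1), "lower")
  hi <- vapply(space$features[features], `[[`, numeric(1), "upper")
  cbind(lower = lo, upper = hi)
}

# Fill in derived columns from their parents (sum rule); overwrites nothing
# that is already present and consistent.
compute_derived <- function(space, df) {
  for (f in space$features) {
    if (f$role != "derived") next
    if (!all(f$parents %in% names(df))) {
      if (f$name %in% names(df)) next
      stop_formbo(sprintf("cannot compute derived feature '%s': parents missing", f$name),
                  "formbo_schema_error")
    }
    val <- rowSums(df[, f$parents, drop = FALSE])
    if (!f$name %in% names(df)) df[[f$name]] <- val
  }
  df
}

# TRUE for rows satisfying every linear constraint.
satisfies_constraints <- function(space, df) {
  ok <- rep(TRUE, nrow(df))
  for (ct in space$constraints) {
    vals <- as.matrix(df[, names(ct$coefficients), drop = FALSE]) %*% ct$coefficients
    ok <- ok & (as.numeric(vals) <= ct$rhs + 1e-12)
  }
  ok
}

#' Write or read a design space as JSON
#'
#' @param space A `design_space`.
#' @param path File path.
#' @return `read_design_space()` returns a `design_space`.
#' @export
write_design_space <- function(space, path) {
  stopifnot(inherits(space, "design_space"))
  feats <- lapply(space$features, function(f) {
    list(name = f$name, unit = f$unit, lower = f$lower, upper = f$upper,
         role = f$role, parents = f$parents)
  })
  cons <- lapply(space$constraints, function(ct) {
    list(coefficients = as.list(ct$coefficients), rhs = ct$rhs)
  })
  jsonlite::write_json(list(features = unname(feats), constraints = cons),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design_space
#' @export
read_design_space <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- lapply(obj$features, function(f) {
    feature_spec(f$name, f$lower, f$upper, unit = f$unit %||% "",
                 role = f$role %||% "excipient",
                 parents = unlist(f$parents) %||% NULL)
  })
  cons <- lapply(obj$constraints %||% list(), function(ct) {
    linear_constraint(unlist(ct$coefficients), ct$rhs)
  })
  design_space(feats, constraints = cons)
}
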