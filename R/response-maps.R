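#' Grid predictions over two features
#'
#' Evaluates a fitted model on a regular grid over two chosen features with
#' every other feature held at a fixed context (mid-bounds by default) —
#' the data behind a response-surface heatmap such as predicted titer loss
#' over residual vs spiked albumin concentration.
#'
#' @param model A `fitted_model`.
#' @param space The [design_space()].
#' @param feature_x,feature_y Names of the grid features (both must be
#'   model inputs).
#' @param fixed_context Named list/vector of values for the remaining
#'   model features; missing entries default to mid-bounds. Derived model
#'   features are recomputed from their parents.
#' @param resolution Grid points per axis (default 50).
#' @return An object of class `grid_map`: `x_values`, `y_values` (strictly
#'   increasing, original units), `matrix` (rows indexed by y, columns by
#'   x), `feature_x`, `feature_y`, `fixed_context`.
#' @export
grid_predict <- function(model, space, feature_x, feature_y,
                         fixed_context = NULL, resolution = 50L) {
  stopifnot(inherits(model, "fitted_model"), inherits(space, "design_space"),
            resolution >= 2L)
  for (f in c(feature_x, feature_y)) {
    if (!f %in% model$feature_names) {
      stop_formbo(sprintf("'%s' is not a model input", f), "formbo_config_error")
    }
  }
  bx <- feature_bounds(space, feature_x)
  by <- feature_bounds(space, feature_y)
  xs <- seq(bx[1, "lower"], bx[1, "upper"], length.out = resolution)
  ys <- seq(by[1, "lower"], by[1, "upper"], length.out = resolution)

  others <- setdiff(model$feature_names, c(feature_x, feature_y))
  derived <- feature_names(space, roles = "derived")
  ctx <- list()
  for (f in setdiff(others, derived)) {
    v <- fixed_context[[f]]
    if (is.null(v)) {
      b <- feature_bounds(space, f)
      v <- mean(b)
    }
    ctx[[f]] <- v
  }
  miss <- setdiff(setdiff(others, derived), names(ctx))
  if (length(miss)) {
    stop_formbo(paste0("missing context feature(s): ", paste(miss, collapse = ", ")),
                "formbo_config_error")
  }
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(grid$x, grid$y)
  names(df) <- c(feature_x, feature_y)
  for (f in names(ctx)) df[[f]] <- ctx[[f]]
  df <- compute_derived(space, df)
  preds <- predict(model, df[, model$feature_names, drop = FALSE])
  structure(
    list(feature_x = feature_x, feature_y = feature_y,
         x_values = xs, y_values = ys,
         matrix = matrix(preds, nrow = resolution, byrow = TRUE,
                         dimnames = list(NULL, NULL)),
         fixed_context = ctx),
    class = "grid_map"
  )
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map> %s x %s, %d x %d cells, predictions in [%.4g, %.4g]\n",
              x$feature_x, x$feature_y, length(x$x_values), length(x$y_values),
              min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Extract an optimal zone from a grid map
#'
#' Collects all grid cells whose prediction is at or below a threshold
#' (minimization; the engine's canonical direction) and reports them both
#' as a cell set and as bounding intervals on the two axes — the "operating
#' zone" communicated to process and quality control.
#'
#' @param map A [grid_predict()] result.
#' @param threshold Numeric cutoff; default is the 20th percentile of the
#'   grid predictions (type-1 quantile, so the cell count tracks the
#'   percentile exactly up to ties).
#' @return An object of class `response_zone`: `threshold`, `cells` (data
#'   frame of i = y index, j = x index, prediction), `x_range`, `y_range`
#'   (NULL when empty).
#' @export
extract_zone <- function(map, threshold = NULL) {
  stopifnot(inherits(map, "grid_map"))
  threshold <- threshold %||% stats::quantile(map$matrix, 0.2, type = 1, names = FALSE)
  if (!is.finite(threshold)) stop_formbo("threshold must be finite", "formbo_config_error")
  hit <- which(map$matrix <= threshold, arr.ind = TRUE)
  if (nrow(hit)) {
    cells <- data.frame(i = hit[, 1], j = hit[, 2],
                        prediction = map$matrix[hit])
    x_range <- range(map$x_values[cells$j])
    y_range <- range(map$y_values[cells$i])
  } else {
    cells <- data.frame(i = integer(), j = integer(), prediction = numeric())
    x_range <- NULL
    y_range <- NULL
  }
  structure(list(threshold = threshold, cells = cells,
                 x_range = x_range, y_range = y_range,
                 feature_x = map$feature_x, feature_y = map$feature_y),
            class = "response_zone")
}

#' @export
print.response_zone <- function(x, ...) {
  if (!nrow(x$cells)) {
    cat(sprintf("<response_zone> empty (threshold %.4g)\n", x$threshold))
  } else {
    cat(sprintf("<response_zone> %d cell(s) <= %.4g; %s in [%.4g, %.4g], %s in [%.4g, %.4g]\n",
                nrow(x$cells), x$threshold,
                x$feature_x, x$x_range[1], x$x_range[2],
                x$feature_y, x$y_range[1], x$y_range[2]))
  }
  invisible(x)
}

#' Write a grid map (CSV matrix + JSON axes) or a zone (JSON)
#'
#' @param map A `grid_map`.
#' @param path Base path: `<path>.csv` receives the prediction matrix,
#'   `<path>.json` the axes and fixed context.
#' @export
write_grid_map <- function(map, path) {
  stopifnot(inherits(map, "grid_map"))
  utils::write.csv(as.data.frame(map$matrix), paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(feature_x = map$feature_x, feature_y = map$feature_y,
                            x_values = map$x_values, y_values = map$y_values,
                            fixed_context = map$fixed_context),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_map
#' @param zone A `response_zone`.
#' @export
write_zone <- function(zone, path) {
  stopifnot(inherits(zone, "response_zone"))
  jsonlite::write_json(list(threshold = zone$threshold,
                            feature_x = zone$feature_x, feature_y = zone$feature_y,
                            x_range = zone$x_range, y_range = zone$y_range,
                            cells = zone$cells),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
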