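#' Encode storage time in weeks as a log3 coordinate
#'
#' Storage times sampled on the geometric grid 0, 3, 9, 27, 81, 243 weeks are
#' expressed as powers of three (3^0 .. 3^5) and log-transformed so that the
#' x-axis intervals are homogeneous: `x = log3(weeks)`. The week-0 baseline
#' (sampled 14 days post-fermentation) occupies the 3^0 slot by convention,
#' so `encode_time(0) == 0`; log3(0) itself is undefined.
#'
#' @param weeks numeric vector of non-negative storage times in real weeks.
#' @param strict_grid if `TRUE`, reject times not on the default geometric
#'   grid (`0` and the powers of three up to 243).
#' @return numeric vector of log3-time coordinates.
#' @examples
#' encode_time(c(0, 3, 9, 27, 81, 243))  # 0 1 2 3 4 5
#' @seealso [decode_time()] for the antilog back-transform.
#' @export
encode_time <- function(weeks, strict_grid = FALSE) {
  if (!is.numeric(weeks)) stop("`weeks` must be numeric", call. = FALSE)
  if (any(!is.finite(weeks)) || any(weeks < 0)) {
    stop("storage times must be finite and >= 0 weeks", call. = FALSE)
  }
  if (strict_grid) {
    grid <- default_time_grid()
    off <- weeks[vapply(weeks, function(w) min(abs(w - grid)) > 1e-9, logical(1))]
    if (length(off) > 0) {
      stop("times off the geometric grid in strict mode: ",
           paste(unique(off), collapse = ", "), call. = FALSE)
    }
  }
  ifelse(weeks == 0, 0, log(weeks) / log(3))
}

#' Decode a log3 coordinate back to real weeks
#'
#' The antilog `3^x`, used to report shelf-life on the real-week scale after
#' the quadratic construction has been carried out in log3 coordinates.
#' Inverse of [encode_time()] for all positive times.
#'
#' @param x numeric vector of finite log3-time coordinates.
#' @return numeric vector of times in weeks.
#' @examples
#' decode_time(5)       # 243
#' decode_time(3.830)   # ~67.2 weeks
#' @export
decode_time <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("log3-time coordinates must be finite numbers", call. = FALSE)
  }
  3^x
}

#' The default geometric sampling grid in weeks
#'
#' @return `c(0, 3, 9, 27, 81, 243)`, i.e. 0 plus 3^(1..5).
#' @export
default_time_grid <- function() c(0, 3^(1:5))

#' Collapse assay samples for one treatment cell into a fit-ready series
#'
#' Filters the assay table to one treatment cell, encodes times with
#' [encode_time()], and either averages replicates within each time frame
#' (`"per_time_means"`, the default used for trajectory fits) or keeps every
#' replicate row (`"replicate_level"`).
#'
#' @param samples assay tibble as produced by [generate_assay()] or
#'   [read_samples()].
#' @param compound,drying_temp_C,condition treatment labels selecting the cell.
#' @param aggregation `"per_time_means"` or `"replicate_level"`.
#' @return a `shelf_series`: tibble with columns `x` (log3-time) and `y`
#'   (concentration, ug/ml), plus attributes `label` and `aggregation`.
#' @export
to_series <- function(samples, compound, drying_temp_C, condition,
                      aggregation = c("per_time_means", "replicate_level")) {
  aggregation <- match.arg(aggregation)
  keep <- samples$compound == compound &
    samples$drying_temp_C == drying_temp_C &
    samples$condition == condition
  cell <- samples[keep, , drop = FALSE]
  if (length(unique(cell$time_weeks)) < 3) {
    stop("insufficient data: need >= 3 distinct time frames in cell ",
         compound, "/", drying_temp_C, "/", condition, call. = FALSE)
  }
  if (aggregation == "per_time_means") {
    pts <- cell |>
      dplyr::group_by(.data$time_weeks) |>
      dplyr::summarise(y = mean(.data$concentration_ug_per_ml), .groups = "drop") |>
      dplyr::arrange(.data$time_weeks)
    pts <- tibble::tibble(x = encode_time(pts$time_weeks), y = pts$y)
  } else {
    cell <- dplyr::arrange(cell, .data$time_weeks, .data$replicate)
    pts <- tibble::tibble(x = encode_time(cell$time_weeks),
                          y = cell$concentration_ug_per_ml)
  }
  new_shelf_series(pts,
                   label = paste(compound, drying_temp_C, condition, sep = "/"),
                   aggregation = aggregation)
}

new_shelf_series <- function(points, label = "", aggregation = "per_time_means") {
  stopifnot(all(c("x", "y") %in% names(points)))
  structure(tibble::as_tibble(points),
            label = label, aggregation = aggregation,
            class = c("shelf_series", class(tibble::tibble())))
}

#' Build a series directly from (x, y) points
#'
#' Convenience constructor for series already in log3 coordinates, mainly for
#' worked examples and tests.
#'
#' @param x log3-time coordinates.
#' @param y concentrations (ug/ml).
#' @param label optional cell label.
#' @return a `shelf_series`.
#' @export
shelf_series <- function(x, y, label = "") {
  stopifnot(length(x) == length(y))
  new_shelf_series(tibble::tibble(x = as.numeric(x), y = as.numeric(y)),
                   label = label)
}

#' @export
print.shelf_series <- function(x, ...) {
  cat("<shelf_series> ", attr(x, "label"), " [", attr(x, "aggregation"),
      "], ", nrow(x), " points\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
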