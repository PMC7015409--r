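#' Fit a quadratic mean trajectory by ordinary least squares
#'
#' Fits y = a x^2 + b x + c to a series in log3-time, minimising the residual
#' sum of squares. With exactly three distinct x values the fit interpolates
#' and R-squared is exactly 1. R-squared is defined as `1 - SSE/SST`, with
#' the convention R-squared = 0 when the response has zero variance.
#'
#' @param series a `shelf_series` (or data frame with columns `x`, `y`).
#' @return a `quadratic_model` with fields `a`, `b`, `c`, `r_squared`,
#'   `n_points`, `sse`, `sst`, `x_range`.
#' @export
fit_quadratic <- function(series) {
  d <- as.data.frame(series)[, c("x", "y")]
  if (length(unique(d$x)) < 3) {
    stop("insufficient data: quadratic fit needs >= 3 distinct x values",
         call. = FALSE)
  }
  fit <- lm(y ~ x + I(x^2), data = d)
  if (fit$rank < 3) stop("rank-deficient design for quadratic fit", call. = FALSE)
  cf <- coef(fit)
  sse <- sum(fit$residuals^2)
  sst <- sum((d$y - mean(d$y))^2)
  structure(list(a = unname(cf[["I(x^2)"]]),
                 b = unname(cf[["x"]]),
                 c = unname(cf[["(Intercept)"]]),
                 r_squared = if (sst > 0) 1 - sse / sst else 0,
                 n_points = nrow(d), sse = sse, sst = sst,
                 x_range = range(d$x)),
            class = "quadratic_model")
}

#' Construct a quadratic model directly from coefficients
#'
#' Used for worked examples where the fitted equation is already known
#' (e.g. the published y = -0.0594 x^2 + 0.2275 x + 0.3876).
#'
#' @param a,b,c quadratic coefficients (a != 0).
#' @param x_range observed x range, used to flag extrapolated shelf-lives.
#' @return a `quadratic_model`.
#' @export
quadratic_model <- function(a, b, c, x_range = c(0, 5)) {
  if (a == 0) stop("a = 0 is not a parabola; use a linear model", call. = FALSE)
  structure(list(a = a, b = b, c = c, r_squared = NA_real_,
                 n_points = NA_integer_, sse = NA_real_, sst = NA_real_,
                 x_range = x_range),
            class = "quadratic_model")
}

#' Fit a straight line by ordinary least squares
#'
#' @param series a `shelf_series` (or data frame with columns `x`, `y`).
#' @return a `linear_model` with `slope`, `intercept`, `r_squared`,
#'   `n_points`, `sse`, `sst`, `x_range`.
#' @export
fit_linear <- function(series) {
  d <- as.data.frame(series)[, c("x", "y")]
  if (length(unique(d$x)) < 2) {
    stop("insufficient data: linear fit needs >= 2 distinct x values",
         call. = FALSE)
  }
  fit <- lm(y ~ x, data = d)
  cf <- coef(fit)
  sse <- sum(fit$residuals^2)
  sst <- sum((d$y - mean(d$y))^2)
  structure(list(slope = unname(cf[["x"]]),
                 intercept = unname(cf[["(Intercept)"]]),
                 r_squared = if (sst > 0) 1 - sse / sst else 0,
                 n_points = nrow(d), sse = sse, sst = sst,
                 x_range = range(d$x)),
            class = "linear_model")
}

#' Evaluate a fitted model at log3-time coordinates
#'
#' @param model a `quadratic_model` or `linear_model`.
#' @param x log3-time coordinate(s).
#' @return fitted concentration(s).
#' @export
predict_trajectory <- function(model, x) {
  if (inherits(model, "quadratic_model")) {
    model$a * x^2 + model$b * x + model$c
  } else if (inherits(model, "linear_model")) {
    model$slope * x + model$intercept
  } else {
    stop("not a fitted trajectory model", call. = FALSE)
  }
}

#' Classification thresholds for relation typing
#'
#' @param preference_margin quadratic is preferred over linear only when its
#'   R-squared exceeds the linear R-squared by at least this much.
#' @param flat_sst series with total sum of squares below this are flat.
#' @param min_r_squared if no model reaches this R-squared the series is flat.
#' @return a list of thresholds.
#' @export
classify_control <- function(preference_margin = 0.05,
                             flat_sst = 1e-6,
                             min_r_squared = 0.5) {
  list(preference_margin = preference_margin,
       flat_sst = flat_sst,
       min_r_squared = min_r_squared)
}

#' Classify the concentration-versus-storage-time relation of a series
#'
#' Labels a series as `positive_quadratic` (rise-then-fall: quadratic
#' preferred with a < 0 and b > 0 — the shelf-life-predictable shape),
#' `negative_linear` (monotone decline, linear preferred), `flat`
#' (no usable signal: near-zero total variation or no model reaching the
#' minimum R-squared), or `other`.
#'
#' @param series a `shelf_series`.
#' @param control thresholds from [classify_control()].
#' @return a `relation_class` with `label`, `chosen_model`, and both fits
#'   (`quadratic` may be `NULL` with only 2 distinct x values).
#' @export
classify_relation <- function(series, control = classify_control()) {
  d <- as.data.frame(series)[, c("x", "y")]
  sst <- sum((d$y - mean(d$y))^2)
  lin <- fit_linear(series)
  quad <- if (length(unique(d$x)) >= 3) fit_quadratic(series) else NULL

  make <- function(label, chosen) {
    structure(list(label = label, chosen_model = chosen,
                   quadratic = quad, linear = lin,
                   series_label = attr(series, "label")),
              class = "relation_class")
  }

  if (sst < control$flat_sst) return(make("flat", NULL))
  best_r2 <- max(lin$r_squared, if (is.null(quad)) -Inf else quad$r_squared)
  if (best_r2 < control$min_r_squared) return(make("flat", NULL))

  quad_preferred <- !is.null(quad) &&
    (quad$r_squared - lin$r_squared) >= control$preference_margin
  if (quad_preferred) {
    if (quad$a < 0 && quad$b > 0) return(make("positive_quadratic", quad))
    return(make("other", quad))
  }
  if (lin$slope < 0) return(make("negative_linear", lin))
  make("other", lin)
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("<quadratic_model> y = %.4g x^2 + %.4g x + %.4g  (R2 = %s, n = %s)\n",
              x$a, x$b, x$c, format(round(x$r_squared, 4)), x$n_points))
  invisible(x)
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear_model> y = %.4g x + %.4g  (R2 = %s, n = %s)\n",
              x$slope, x$intercept, format(round(x$r_squared, 4)), x$n_points))
  invisible(x)
}

#' @export
print.relation_class <- function(x, ...) {
  cat("<relation_class>", x$series_label, "->", x$label, "\n")
  invisible(x)
}
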