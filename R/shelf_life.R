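#' Vertex (extremum) of a fitted parabola
#'
#' For a downward-opening trajectory (a < 0) this is the storage coordinate
#' of the concentration maximum, x = -b/(2a) in log3-time; the parabola is
#' symmetric about it.
#'
#' @param model a `quadratic_model`.
#' @return the extremum in log3-time.
#' @export
quad_extremum <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  if (model$a == 0) stop("a = 0: not a parabola", call. = FALSE)
  -model$b / (2 * model$a)
}

#' Real roots of a fitted parabola
#'
#' Solves a x^2 + b x + c = 0 with the quadratic formula. For the
#' shelf-life-relevant case (a < 0, c > 0) the discriminant is positive and
#' the roots straddle zero.
#'
#' @param model a `quadratic_model`.
#' @return `c(root_neg, root_pos)` in ascending order.
#' @export
quad_roots <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  a <- model$a; b <- model$b; c <- model$c
  if (a == 0) stop("a = 0: not a parabola", call. = FALSE)
  disc <- b^2 - 4 * a * c
  if (disc < 0) {
    stop("no real roots: discriminant b^2 - 4ac < 0", call. = FALSE)
  }
  r <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  sort(r)
}

#' Shelf-life coordinate of a positive-quadratic trajectory
#'
#' The parabola-symmetry construction: the horizontal line through the
#' initial (post-fermentation) concentration c meets the fitted parabola
#' again at x3, the log3-time at which the concentration has returned to its
#' starting level — the shelf-life coordinate. By symmetry x3 equals the
#' positive root minus the absolute value of the negative root, which is
#' algebraically -b/a and twice the extremum. Both routes are computed and
#' cross-checked; a disagreement beyond 1e-9 (relative) aborts loudly.
#'
#' @param model a `quadratic_model` with a < 0, b > 0, c > 0.
#' @return x3 in log3-time.
#' @export
shelf_life_x <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  if (!(model$a < 0 && model$b > 0 && model$c > 0)) {
    stop("shelf-life construction needs a positive quadratic (a < 0, b > 0, c > 0)",
         call. = FALSE)
  }
  r <- quad_roots(model)
  x3_roots <- r[2] - abs(r[1])
  x3_vertex <- 2 * quad_extremum(model)   # = -b/a
  if (abs(x3_roots - x3_vertex) > 1e-9 * max(1, abs(x3_vertex))) {
    stop("internal inconsistency: root-subtraction and twice-extremum ",
         "routes disagree", call. = FALSE)
  }
  x3_roots
}

#' Estimate shelf-life from a classified relation
#'
#' Only the rise-then-fall (`positive_quadratic`) shape admits the symmetry
#' construction; for it the estimate carries the extremum, both roots, x3,
#' and the antilogged shelf-life 3^x3 in real weeks (raw and rounded to the
#' nearest whole week). The fitted concentration at x3 is verified to equal
#' the intercept c (the y3 = y1 closure) within 1e-6. Monotone-declining,
#' flat and other relations return `predictable = FALSE` with a reason, as
#' do degenerate fits (c <= 0, or no real roots). Estimates whose x3 lies
#' beyond the observed design range are flagged `extrapolated` rather than
#' suppressed.
#'
#' @param relation a `relation_class` from [classify_relation()], or a
#'   `quadratic_model` directly.
#' @return a `shelf_life_estimate`.
#' @export
estimate_shelf_life <- function(relation) {
  if (inherits(relation, "quadratic_model")) {
    model <- relation
    label <- if (model$a < 0 && model$b > 0) "positive_quadratic" else "other"
  } else {
    stopifnot(inherits(relation, "relation_class"))
    model <- relation$chosen_model
    label <- relation$label
  }

  not_predictable <- function(reason) {
    structure(list(predictable = FALSE, reason = reason, label = label),
              class = "shelf_life_estimate")
  }

  if (label == "negative_linear") {
    return(not_predictable("monotone decline; quadratic construction inapplicable"))
  }
  if (label == "flat") {
    return(not_predictable("no storage-time signal; nothing to extrapolate"))
  }
  if (label != "positive_quadratic") {
    return(not_predictable("relation is neither positive quadratic nor informative"))
  }
  if (model$c <= 0) {
    return(not_predictable("non-positive initial concentration; construction undefined"))
  }
  if (model$b^2 - 4 * model$a * model$c < 0) {
    return(not_predictable("no real roots: parabola never reaches zero"))
  }

  ext <- quad_extremum(model)
  r <- quad_roots(model)
  x3 <- shelf_life_x(model)
  y3 <- predict_trajectory(model, x3)
  if (abs(y3 - model$c) > 1e-6) {
    stop("internal inconsistency: fitted value at x3 does not close on c",
         call. = FALSE)
  }
  weeks <- decode_time(x3)
  structure(list(
    predictable = TRUE,
    label = label,
    extremum_x = ext,
    root_neg = r[1],
    root_pos = r[2],
    x3 = x3,
    shelf_life_weeks = weeks,
    shelf_life_weeks_rounded = round(weeks),
    y_at_x3 = y3,
    extrapolated = is.numeric(model$x_range) && x3 > max(model$x_range),
    reason = "positive quadratic; symmetry construction applies"
  ), class = "shelf_life_estimate")
}

#' @export
print.shelf_life_estimate <- function(x, ...) {
  if (!x$predictable) {
    cat("<shelf_life_estimate> not predictable:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<shelf_life_estimate> extremum x2 = %.4f; roots (%.4f, %.4f); x3 = %.4f\n",
      x$extremum_x, x$root_neg, x$root_pos, x$x3))
    cat(sprintf("  shelf-life = 3^x3 = %.1f weeks (~%d weeks)%s\n",
                x$shelf_life_weeks, x$shelf_life_weeks_rounded,
                if (isTRUE(x$extrapolated)) " [extrapolated beyond observed range]" else ""))
  }
  invisible(x)
}

#' Run the published worked example
#'
#' Applies the full construction to the one published fitted equation
#' (y = -0.0594 x^2 + 0.2275 x + 0.3876 for cucurbitacin A, 52 degC drying,
#' tropical storage) and prints extremum, roots, x3 and the antilogged
#' shelf-life.
#'
#' @param quiet suppress printing.
#' @return the `shelf_life_estimate`, invisibly.
#' @export
demo_worked_example <- function(quiet = FALSE) {
  model <- quadratic_model(-0.0594, 0.2275, 0.3876, x_range = c(0, 5))
  est <- estimate_shelf_life(model)
  if (!quiet) {
    cat("Worked example: y = -0.0594 x^2 + 0.2275 x + 0.3876 (log3-time)\n")
    print(est)
  }
  invisible(est)
}
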