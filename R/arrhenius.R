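#' Fit an integrated rate law of a given reaction order
#'
#' Classical shelf-life kinetics fit concentration decay in *real* time to
#' the integrated rate law of order n: order 0, C(t) = c0 - k t; order 1,
#' C(t) = c0 exp(-k t); order 2, 1/C(t) = 1/c0 + k t; general n != 1,
#' C(t)^(1-n) = c0^(1-n) + (n-1) k t. Each is linear in its transform, so
#' the fit is OLS on the transformed response; k, c0 and an R-squared on the
#' original concentration scale are reported. A fit is `valid` when k >= 0
#' (a decay) and the back-transformed trajectory is finite over the data.
#'
#' Points with C <= 0 are excluded (with a message) from transforms that
#' cannot accommodate them (any n > 0 here uses log or a negative power of C).
#'
#' @param weeks storage times in real weeks (not log3 coordinates).
#' @param conc concentrations (ug/ml).
#' @param n reaction order (non-negative real).
#' @return a `reaction_order_model` with `order_n`, `k`, `c0`, `r_squared`,
#'   `sse`, `n_points`, `valid`.
#' @export
fit_order <- function(weeks, conc, n) {
  stopifnot(length(weeks) == length(conc), n >= 0)
  if (any(weeks < 0)) stop("times must be >= 0 weeks", call. = FALSE)
  d <- data.frame(t = as.numeric(weeks), C = as.numeric(conc))
  if (n > 0) {
    bad <- d$C <= 0
    if (any(bad)) {
      message(sum(bad), " point(s) with C <= 0 excluded from the order-", n,
              " transform")
      d <- d[!bad, , drop = FALSE]
    }
  }
  if (length(unique(d$t)) < 3) {
    stop("transform-domain error: fewer than 3 usable time points for order ",
         n, call. = FALSE)
  }

  if (n == 1) {
    fit <- lm(log(C) ~ t, data = d)
    k <- -coef(fit)[["t"]]
    c0 <- exp(coef(fit)[["(Intercept)"]])
    chat <- function(t) c0 * exp(-k * t)
  } else if (n == 0) {
    fit <- lm(C ~ t, data = d)
    k <- -coef(fit)[["t"]]
    c0 <- coef(fit)[["(Intercept)"]]
    chat <- function(t) c0 - k * t
  } else {
    p <- 1 - n
    fit <- lm(I(C^p) ~ t, data = d)
    slope <- coef(fit)[["t"]]
    k <- slope / (n - 1)
    b0 <- coef(fit)[["(Intercept)"]]
    c0 <- if (b0 > 0) b0^(1 / p) else NA_real_
    chat <- function(t) {
      base <- b0 + slope * t
      ifelse(base > 0, base^(1 / p), NA_real_)
    }
  }

  # a numerically-zero slope (constant series) must not fail the k >= 0 check
  if (is.finite(k) && abs(k) < 1e-12 * max(1, abs(c0))) k <- 0

  pred <- chat(d$t)
  ok <- all(is.finite(pred))
  sse <- if (ok) sum((d$C - pred)^2) else Inf
  sst <- sum((d$C - mean(d$C))^2)
  r2 <- if (ok && sst > 0) 1 - sse / sst else if (ok) 0 else NA_real_
  structure(list(order_n = n, k = k, c0 = c0,
                 r_squared = r2, sse = sse, n_points = nrow(d),
                 valid = ok && is.finite(k) && k >= 0 && is.finite(c0)),
            class = "reaction_order_model")
}

#' Select the best-fitting reaction order on a grid
#'
#' Grid search over reaction orders minimising the SSE on the original
#' concentration scale; ties break toward the smaller (simpler) order. When
#' no order gives a valid decay fit the SSE-best model is returned with
#' `valid = FALSE`.
#'
#' @param weeks storage times in real weeks.
#' @param conc concentrations (ug/ml).
#' @param n_grid candidate orders (default 0 to 3 in steps of 0.25).
#' @return the selected `reaction_order_model`.
#' @export
best_order <- function(weeks, conc, n_grid = seq(0, 3, by = 0.25)) {
  fits <- lapply(n_grid, function(n) {
    tryCatch(suppressMessages(fit_order(weeks, conc, n)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("no reaction order could be fitted", call. = FALSE)
  sses <- vapply(fits, function(f) if (f$valid) f$sse else Inf, numeric(1))
  if (all(!is.finite(sses))) {
    # nothing valid: report the least-bad raw fit, flagged invalid
    raw <- vapply(fits, function(f) f$sse, numeric(1))
    best <- fits[[which.min(raw)]]
    best$valid <- FALSE
    return(best)
  }
  fits[[which.min(sses)]]  # which.min takes the first (smallest n) on ties
}

#' Test a stored series for conformity to Arrhenius-type monotone decay
#'
#' A series conforms when a classical reaction-order model describes it: the
#' best integrated-rate-law fit is a genuine decay (k > 0) with R-squared at
#' or above `r2_threshold`, and the trajectory has no interior concentration
#' maximum (a downward-opening quadratic in log3-time whose vertex falls
#' strictly inside the observed range — the rise-then-fall signature that
#' defeats monotone rate laws). The verdict's reason names the first failed
#' criterion.
#'
#' @param weeks storage times in real weeks (>= 4 time points).
#' @param conc concentrations (ug/ml).
#' @param r2_threshold minimum R-squared for a conforming decay fit.
#' @param n_grid candidate orders passed to [best_order()].
#' @return a `conformity_verdict` with `conforms`, `best_order`, `reason`.
#' @export
conformity_test <- function(weeks, conc, r2_threshold = 0.8,
                            n_grid = seq(0, 3, by = 0.25)) {
  if (length(unique(weeks)) < 4) {
    stop("conformity test needs >= 4 distinct time points", call. = FALSE)
  }
  verdict <- function(conforms, best, reason) {
    structure(list(conforms = conforms, best_order = best, reason = reason),
              class = "conformity_verdict")
  }
  sst <- sum((conc - mean(conc))^2)
  if (sst < 1e-10) {
    return(verdict(FALSE, NULL, "no decay signal (constant concentration)"))
  }
  # rise-then-fall screen on the log3 axis used throughout the pipeline:
  # a downward-opening quadratic with an interior vertex, confirmed by the
  # data actually rising materially above the initial concentration (an OLS
  # quadratic fitted to convex monotone decay can bow upward spuriously)
  ser <- shelf_series(encode_time(weeks), conc)
  quad <- fit_quadratic(ser)
  vertex <- if (quad$a != 0) -quad$b / (2 * quad$a) else NA_real_
  observed_rise <- max(conc) - conc[which.min(weeks)]
  if (quad$a < 0 && quad$b > 0 &&
      is.finite(vertex) && vertex > min(ser$x) && vertex < max(ser$x) &&
      observed_rise > 0.1 * diff(range(conc))) {
    return(verdict(FALSE, NULL, sprintf(
      "interior concentration maximum at x = %.3f (rise-then-fall, non-Arrhenius)",
      vertex)))
  }
  best <- best_order(weeks, conc, n_grid)
  if (!best$valid || best$k <= 0) {
    return(verdict(FALSE, best, "no valid decay fit (k <= 0 at every order)"))
  }
  if (best$r_squared < r2_threshold) {
    return(verdict(FALSE, best, sprintf(
      "best decay fit explains too little (R2 = %.3f < %.2f)",
      best$r_squared, r2_threshold)))
  }
  verdict(TRUE, best, sprintf("order-%.2g decay fit, k = %.4g per week, R2 = %.3f",
                              best$order_n, best$k, best$r_squared))
}

#' Two-temperature Arrhenius activation energy
#'
#' From rate constants at two absolute temperatures,
#' Ea = R ln(k1/k2) / (1/T2 - 1/T1) with R = 8.314 J/(mol K). Symmetric in
#' its argument pairs and invariant under a common rescaling of the rates.
#'
#' @param k1,k2 positive rate constants (same units).
#' @param T1,T2 absolute temperatures in kelvin, T1 != T2.
#' @return activation energy in J/mol.
#' @export
activation_energy <- function(k1, T1, k2, T2) {
  if (k1 <= 0 || k2 <= 0) stop("rate constants must be > 0", call. = FALSE)
  if (T1 <= 0 || T2 <= 0) stop("temperatures must be in kelvin (> 0)", call. = FALSE)
  if (T1 == T2) stop("temperatures must differ", call. = FALSE)
  8.314 * log(k1 / k2) / (1 / T2 - 1 / T1)
}

#' @export
print.reaction_order_model <- function(x, ...) {
  cat(sprintf("<reaction_order_model> n = %.2g, k = %.4g per week, c0 = %.4g, R2 = %s, valid = %s\n",
              x$order_n, x$k, x$c0, format(round(x$r_squared, 4)), x$valid))
  invisible(x)
}

#' @export
print.conformity_verdict <- function(x, ...) {
  cat("<conformity_verdict>", if (x$conforms) "conforms:" else "does not conform:",
      x$reason, "\n")
  invisible(x)
}
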