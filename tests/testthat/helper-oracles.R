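# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: roots by sign-change bisection, polynomial OLS by
# Cramer's rule on hand-built normal equations, ANOVA by naive double loops.

# Bisection root finder for f on [lo, hi] with a sign change.
bisect_root <- function(f, lo, hi, iter = 200) {
  stopifnot(sign(f(lo)) != sign(f(hi)))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Both roots of a*x^2 + b*x + c via bisection around the vertex.
bisect_quad_roots <- function(a, b, c, span = 1e3) {
  f <- function(x) a * x^2 + b * x + c
  v <- -b / (2 * a)
  sort(c(bisect_root(f, v - span, v), bisect_root(f, v, v + span)))
}

# Quadratic OLS by Cramer's rule on explicitly accumulated normal equations.
cramer_quadratic <- function(x, y) {
  S <- function(p) sum(x^p)
  X <- matrix(c(length(x), S(1), S(2),
                S(1), S(2), S(3),
                S(2), S(3), S(4)), 3, 3, byrow = TRUE)
  rhs <- c(sum(y), sum(x * y), sum(x^2 * y))
  det3 <- function(m) {
    m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
      m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
      m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  }
  d <- det3(X)
  coefs <- vapply(1:3, function(j) {
    Xj <- X; Xj[, j] <- rhs; det3(Xj) / d
  }, numeric(1))
  # returned as (c, b, a) order of powers 0,1,2 -> name them
  list(c = coefs[1], b = coefs[2], a = coefs[3])
}

# One-way ANOVA sums of squares by naive double loops over groups.
naive_anova_ss <- function(y, group) {
  group <- as.character(group)
  levels <- unique(group)
  grand <- mean(y)
  ss_trt <- 0; ss_err <- 0; ss_tot <- 0
  for (lv in levels) {
    yi <- y[group == lv]
    m <- mean(yi)
    ss_trt <- ss_trt + length(yi) * (m - grand)^2
    for (v in yi) ss_err <- ss_err + (v - m)^2
  }
  for (v in y) ss_tot <- ss_tot + (v - grand)^2
  list(ss_treatment = ss_trt, ss_error = ss_err, ss_total = ss_tot)
}

# Random downward-opening parabola with positive initial level (the
# shelf-life-predictable class).
random_positive_quadratic <- function() {
  a <- -runif(1, 0.01, 2)
  b <- runif(1, 0.05, 3)
  c <- runif(1, 0.05, 5)
  quadratic_model(a, b, c)
}

# Analytic reaction-order decay series on a week grid.
decay_series <- function(n, c0, k, weeks) {
  conc <- switch(as.character(n),
    "0" = c0 - k * weeks,
    "1" = c0 * exp(-k * weeks),
    "2" = 1 / (1 / c0 + k * weeks),
    (c0^(1 - n) + (n - 1) * k * weeks)^(1 / (1 - n))
  )
  data.frame(weeks = weeks, conc = conc)
}
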