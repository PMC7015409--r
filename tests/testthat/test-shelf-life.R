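# Frozen oracle values for the published tropical cucurbitacin-A equation
# y = -0.0594 x^2 + 0.2275 x + 0.3876, computed independently by hand
# arithmetic (vertex) and sign-change bisection (roots) before implementation:
#   extremum 1.914983, roots (-1.277573, 5.107539), x3 3.829966,
#   3^x3 = 67.198 weeks.

test_that("worked example: extremum, roots, x3 and weeks match the oracle", {
  m <- quadratic_model(-0.0594, 0.2275, 0.3876)
  expect_equal(quad_extremum(m), 1.9149, tolerance = 1e-3)
  expect_equal(quad_roots(m), c(-1.2776, 5.1076), tolerance = 1e-3)
  expect_equal(shelf_life_x(m), 3.8300, tolerance = 1e-3)

  est <- demo_worked_example(quiet = TRUE)
  expect_true(est$predictable)
  expect_equal(est$x3, 3.829966, tolerance = 1e-5)
  expect_equal(est$shelf_life_weeks, 67.198, tolerance = 1e-3)
  expect_equal(est$shelf_life_weeks_rounded, 67)
  expect_false(est$extrapolated)

  # cross-check against the bisection oracle at test time
  r <- bisect_quad_roots(-0.0594, 0.2275, 0.3876)
  expect_equal(quad_roots(m), r, tolerance = 1e-6)
})

test_that("extremum and roots handle simple closed-form cases", {
  expect_equal(quad_extremum(quadratic_model(-1, 0, 1)), 0)
  expect_equal(quad_extremum(quadratic_model(-1, 2, 1)), 1)
  expect_equal(quad_roots(quadratic_model(1, 0, -1)), c(-1, 1))
  expect_error(quad_roots(quadratic_model(1, 0, 1)), "no real roots")
  expect_equal(shelf_life_x(quadratic_model(-1, 2, 1)), 2)
})

test_that("x3 identities hold on random positive quadratics", {
  set.seed(314)
  for (i in 1:300) {
    m <- random_positive_quadratic()
    r <- quad_roots(m)
    x3 <- shelf_life_x(m)
    expect_equal(x3, -m$b / m$a, tolerance = 1e-9)
    expect_equal(x3, 2 * quad_extremum(m), tolerance = 1e-9)
    expect_equal(x3, r[2] + r[1], tolerance = 1e-9)      # sum of roots = -b/a
    expect_lt(r[1], 0); expect_gt(r[2], 0)
    expect_gt(quad_extremum(m), 0)
    # closure: fitted value at x3 returns to the initial level c (y3 = y1)
    expect_equal(predict_trajectory(m, x3), m$c, tolerance = 1e-6)
    # oracle agreement
    expect_equal(r, bisect_quad_roots(m$a, m$b, m$c), tolerance = 1e-6)
  }
})

test_that("shelf-life is invariant to rescaling the concentration axis", {
  m <- quadratic_model(-0.0594, 0.2275, 0.3876)
  for (k in c(0.1, 2, 37)) {
    mk <- quadratic_model(k * m$a, k * m$b, k * m$c)
    expect_equal(shelf_life_x(mk), shelf_life_x(m), tolerance = 1e-12)
    expect_equal(estimate_shelf_life(mk)$shelf_life_weeks,
                 estimate_shelf_life(m)$shelf_life_weeks, tolerance = 1e-9)
  }
})

test_that("non-predictable relations return reasons, not errors", {
  s <- generate_assay(study_design(noise_sd = 0, seed = 1))
  chilled <- estimate_shelf_life(classify_relation(to_series(s, "cuA", 52, "chilled")))
  expect_false(chilled$predictable)
  expect_match(chilled$reason, "monotone decline")

  flat <- estimate_shelf_life(classify_relation(to_series(s, "cuA", 100, "tropical")))
  expect_false(flat$predictable)
  expect_match(flat$reason, "no storage-time signal")

  # degenerate coefficient configurations route to not-predictable
  no_roots <- estimate_shelf_life(quadratic_model(-1, 2, -2))
  expect_false(no_roots$predictable)
  sunk <- estimate_shelf_life(quadratic_model(-1, 2, 0))
  expect_false(sunk$predictable)
  expect_match(sunk$reason, "initial concentration")
})

test_that("an x3 beyond the observed grid is flagged extrapolated", {
  s <- generate_assay(study_design(noise_sd = 0, seed = 1))
  est <- estimate_shelf_life(classify_relation(to_series(s, "cuB", 52, "tropical")))
  expect_true(est$predictable)
  expect_true(est$extrapolated)
  expect_equal(est$shelf_life_weeks, 825, tolerance = 1e-6)

  inside <- estimate_shelf_life(classify_relation(to_series(s, "cuB", 52, "chilled")))
  expect_true(inside$predictable)
  expect_false(inside$extrapolated)
  expect_equal(inside$shelf_life_weeks, 35, tolerance = 1e-6)
})

test_that("shelf_life_x enforces the positive-quadratic precondition", {
  expect_error(shelf_life_x(quadratic_model(1, 1, 1)), "positive quadratic")
  expect_error(quad_extremum(structure(list(a = 0, b = 1, c = 1),
                                       class = "quadratic_model")),
               "not a parabola")
})
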