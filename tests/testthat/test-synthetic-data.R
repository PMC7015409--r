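test_that("default trajectories match the study's cell structure", {
  tr <- default_trajectories()
  cuA_trop <- tr[["cuA/52/tropical"]]
  expect_equal(cuA_trop$shape, "positive_quadratic")
  expect_equal(cuA_trop$coefficients, c(-0.0594, 0.2275, 0.3876))
  expect_equal(tr[["cuA/52/chilled"]]$shape, "negative_linear")
  expect_equal(tr[["cuB/52/tropical"]]$shape, "positive_quadratic")
  expect_equal(tr[["cuB/52/chilled"]]$shape, "positive_quadratic")
  for (k in grep("/100/", names(tr), value = TRUE)) {
    expect_equal(tr[[k]]$shape, "flat")
    expect_lt(tr[[k]]$coefficients, 0.1)
  }
  # cuB tropical symmetry point lies beyond the observed grid
  kB <- tr[["cuB/52/tropical"]]$coefficients
  expect_gt(-kB[2] / kB[1], 5)
})

test_that("trajectory_spec enforces shape constraints", {
  expect_error(trajectory_spec("positive_quadratic", c(0.1, 0.2, 0.3)), "constraints")
  expect_error(trajectory_spec("negative_linear", c(0.5, 1)), "constraints")
  expect_error(trajectory_spec("flat", -1), "constraints")
  expect_error(trajectory_spec("positive_quadratic", c(-1, 1)), "coefficient")
})

test_that("mean_response evaluates the mean structures", {
  quad <- trajectory_spec("positive_quadratic", c(-0.0594, 0.2275, 0.3876))
  expect_equal(mean_response(quad, 0), 0.3876)
  expect_equal(mean_response(quad, 1.9149), 0.6054, tolerance = 1e-4)
  flat <- trajectory_spec("flat", 0.1)
  expect_equal(mean_response(flat, c(0, 2, 17)), rep(0.1, 3))
  lin <- trajectory_spec("negative_linear", c(-0.5, 1))
  expect_equal(mean_response(lin, c(0, 1, 4)), c(1, 0.5, 0))  # clipped at 0
  expect_error(mean_response(quad, -1), ">= 0")
  expect_error(mean_response(list(shape = "quad"), 1), "invalid")
})

test_that("generate_assay produces the full crossed design reproducibly", {
  d <- study_design(seed = 7)
  s1 <- generate_assay(d)
  s2 <- generate_assay(d)
  expect_equal(nrow(s1), 2 * 2 * 2 * 6 * 10)  # 480
  expect_identical(s1, s2)
  expect_true(all(s1$concentration_ug_per_ml >= 0))
  expect_setequal(unique(s1$time_weeks), c(0, 3, 9, 27, 81, 243))
  # different seed, different draws
  s3 <- generate_assay(study_design(seed = 8))
  expect_false(identical(s1$concentration_ug_per_ml, s3$concentration_ug_per_ml))
})

test_that("noise-free replicates equal the mean response exactly", {
  s <- generate_assay(study_design(noise_sd = 0, seed = 1))
  tr <- default_trajectories()
  cell <- s[s$compound == "cuB" & s$drying_temp_C == 52 & s$condition == "chilled", ]
  mu <- mean_response(tr[["cuB/52/chilled"]], encode_time(cell$time_weeks))
  expect_equal(cell$concentration_ug_per_ml, mu, tolerance = 1e-14)
})

test_that("generation fails clearly when a cell has no trajectory", {
  tr <- default_trajectories()
  tr[["cuA/52/tropical"]] <- NULL
  expect_error(generate_assay(study_design(), tr), "no trajectory")
})

test_that("study_design validates its invariants", {
  expect_error(study_design(time_frames_weeks = c(0, 3, 3)), "strictly increasing")
  expect_error(study_design(time_frames_weeks = c(-1, 3)), "strictly increasing")
  expect_error(study_design(n_replicates = 1), "n_replicates")
  expect_error(study_design(noise_sd = -0.1), "noise_sd")
  expect_error(study_design(drying_temps_C = 60), "52")
})

test_that("noise-free cells refit to the generating coefficients exactly", {
  s <- generate_assay(study_design(noise_sd = 0, seed = 5))
  tr <- default_trajectories()
  q <- fit_quadratic(to_series(s, "cuA", 52, "tropical"))
  expect_equal(c(q$a, q$b, q$c), tr[["cuA/52/tropical"]]$coefficients,
               tolerance = 1e-9)
  l <- fit_linear(to_series(s, "cuA", 52, "chilled"))
  expect_equal(c(l$slope, l$intercept), tr[["cuA/52/chilled"]]$coefficients,
               tolerance = 1e-9)
  qB <- fit_quadratic(to_series(s, "cuB", 52, "tropical"))
  expect_equal(c(qB$a, qB$b, qB$c), tr[["cuB/52/tropical"]]$coefficients,
               tolerance = 1e-9)
})

test_that("coefficient estimates are unbiased under noise (Monte Carlo)", {
  # cuB/52/tropical: mean trajectory stays >= 0.65 so zero-clipping is
  # negligible and the Gaussian error model holds essentially exactly
  tr <- default_trajectories()["cuB/52/tropical"]
  truth <- tr[[1]]$coefficients
  M <- 60
  est <- matrix(NA_real_, M, 3)
  for (m in seq_len(M)) {
    d <- study_design(compounds = "cuB", drying_temps_C = 52,
                      conditions = "tropical", n_replicates = 1000,
                      seed = 1000 + m)
    s <- suppressMessages(generate_assay(d, tr))
    q <- fit_quadratic(to_series(s, "cuB", 52, "tropical"))
    est[m, ] <- c(q$a, q$b, q$c)
  }
  bias <- colMeans(est) - truth
  mc_se <- apply(est, 2, stats::sd) / sqrt(M)
  expect_true(all(abs(bias) <= 3 * mc_se))
})

test_that("assay CSV writer emits the documented schema", {
  s <- generate_assay(study_design(compounds = "cuA", drying_temps_C = 52,
                                   conditions = "tropical", seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(s, path)
  header <- readLines(path, n = 1)
  expect_identical(
    header,
    "compound,drying_temp_C,condition,time_weeks,replicate,concentration_ug_per_ml,ph")
})
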