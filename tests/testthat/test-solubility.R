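test_that("soluble fraction inversion recovers compositions from annealed Tgs", {
  bckv <- bckv_params(56.8, 107, 25, 5, 0)
  # exact inversion at an interior composition
  w <- soluble_fraction_from_tg(bckv_tg(bckv, 0.25), bckv, nominal_w_api = 0.25)
  expect_equal(as.numeric(w), 0.25, tolerance = 1e-6)
  # polymer Tg maps to zero API
  expect_equal(as.numeric(soluble_fraction_from_tg(107, bckv)), 0)
  # out-of-range Tg errors
  expect_error(soluble_fraction_from_tg(150, bckv), "outside the attainable")

  # non-monotone curve: nearest-to-nominal root is chosen and flagged
  wavy <- bckv_params(100, 110, -120, 0, 0)   # deep minimum mid-composition
  tg_target <- bckv_tg(wavy, 0.2)
  got <- soluble_fraction_from_tg(tg_target, wavy, nominal_w_api = 0.2)
  expect_equal(as.numeric(got), 0.2, tolerance = 1e-6)
  expect_gt(attr(got, "n_roots"), 1L)
})

test_that("exponential boundary fit recovers generating parameters", {
  # noise-free refit (positive-branch toy parameters)
  x <- seq(0.05, 0.6, length.out = 8)
  tt <- 160 + 5 * exp(8 * x)
  f <- fit_solubility_curve(data.frame(w_soluble = x, t_annealing = tt))
  expect_equal(c(f$y0, f$A, f$R0), c(160, 5, 8), tolerance = 1e-6)

  # 1 K temperature noise: parameters within 95% confidence intervals
  set.seed(7)
  noisy <- data.frame(w_soluble = x,
                      t_annealing = tt + rnorm(length(x), 0, 1))
  fn <- fit_solubility_curve(noisy, y0_init = 160)
  z <- z_score(c(fn$y0, fn$A, fn$R0), c(160, 5, 8), attr(fn, "se"))
  expect_true(all(abs(z) < qt(0.975, length(x) - 3)))

  # under-determined input errors
  expect_error(
    fit_solubility_curve(data.frame(w_soluble = c(0.1, 0.2),
                                    t_annealing = c(150, 160))),
    ">= 4 points")
})

test_that("forward evaluation and solubility_at are mutually inverse", {
  curve <- solubility_curve(y0 = 160.9, A = -1368.6, R0 = -7)
  tt <- curve$y0 + curve$A * exp(curve$R0 * 0.3)
  expect_equal(as.numeric(solubility_at(curve, tt)), 0.3, tolerance = 1e-12)

  # insoluble branch: no solution -> 0 with flag (loratadine/praziquantel-like)
  pos <- solubility_curve(y0 = 160, A = 5, R0 = 8)  # T(x) >= 165 everywhere
  s <- solubility_at(pos, 25)
  expect_identical(as.numeric(s), 0)
  expect_true(attr(s, "insoluble"))

  # clipping flag above full miscibility
  wide <- solubility_curve(y0 = 0, A = 1, R0 = 1)
  s2 <- solubility_at(wide, 10)   # ln(10) > 1
  expect_identical(as.numeric(s2), 1)
  expect_true(attr(s2, "clipped"))
})

test_that("annealing pipeline recovers a CXB-like ambient solubility", {
  truth <- cxb_like_truth()
  target <- as.numeric(solubility_at(truth$curve, 25))   # 0.330

  # noise-free: exact recovery through inversion, saturation filter and fit
  rec0 <- make_annealing_dataset(truth$curve, truth$bckv, noise_sigma = 0,
                                 seed = 1)
  res0 <- solubility_from_annealing(rec0, truth$bckv, melting_point = 160.9)
  expect_equal(as.numeric(res0$solubility_25), target, tolerance = 1e-6)

  # 1 K Tg noise at the default annealing design (9 compositions x 3
  # replicates, ~60 degC above the predicted blend Tg): ambient solubility
  # recovered within 2 percentage points
  rec1 <- make_annealing_dataset(truth$curve, truth$bckv, noise_sigma = 1,
                                 seed = 1)
  res1 <- solubility_from_annealing(rec1, truth$bckv, melting_point = 160.9)
  expect_lt(abs(as.numeric(res1$solubility_25) - target), 0.02)

  # fully dissolved conditions are recognised and excluded from the boundary
  expect_true(any(!res1$points$saturated))
  expect_true(all(res1$points$nominal_w_api[!res1$points$saturated] <= 0.6))
})
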