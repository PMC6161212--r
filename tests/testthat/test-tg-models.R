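test_that("Couchman-Karasz prediction honours its endpoint and k = 1 identities", {
  b <- blend_spec(toy_api, toy_polymer, 0.5)
  expect_equal(ck_tg(b, w_api = 0), toy_polymer$tg)
  expect_equal(ck_tg(b, w_api = 1), toy_api$tg)

  # k_CK = 1 reduces to the linear Kelvin-weighted mean
  api1 <- material_props("A", tg = 50, delta_cp = 0.40)
  b1 <- blend_spec(api1, toy_polymer, 0.25)
  lin_k <- 0.25 * (50 + 273.15) + 0.75 * (110 + 273.15)
  expect_equal(ck_tg(b1), lin_k - 273.15)

  # monotone in composition between the endpoint Tgs
  w <- seq(0, 1, by = 0.01)
  tgs <- ck_tg(b, w_api = w)
  expect_true(all(diff(tgs) < 0))
  expect_true(all(tgs <= toy_polymer$tg + 1e-9 & tgs >= toy_api$tg - 1e-9))
})

test_that("CK deviations of the reference blends reproduce the reported signs and sizes", {
  # frozen oracle values from direct Kelvin-scale evaluation of the mixing
  # rule with the packaged Table constants (hand-checked)
  fx <- load_paper_fixtures()
  expect_equal(ck_deviation(fx$blends[["CXB 30%"]]), 8.794, tolerance = 1e-3)
  expect_equal(ck_deviation(fx$blends[["NAP 30%"]]), -16.170, tolerance = 1e-3)
  expect_equal(ck_deviation(fx$blends[["PZQ 30%"]]), -14.816, tolerance = 1e-3)

  # a record whose measured Tg equals the prediction has zero deviation
  b <- blend_spec(toy_api, toy_polymer, 0.3)
  rec <- blend_record(b, tg_measured = ck_tg(b))
  expect_equal(ck_deviation(rec), 0)
})

test_that("BCKV curve reduces to linear mixing and pins its endpoints", {
  p0 <- bckv_params(300, 400, 0, 0, 0)
  expect_equal(bckv_tg(p0, 0.5), 350)
  p <- bckv_params(300, 400, -40, 10, 5)
  expect_equal(bckv_tg(p, 0), 400)
  expect_equal(bckv_tg(p, 1), 300)
  expect_error(bckv_tg(p, 1.5), "\\[0, 1\\]")
})

test_that("BCKV fitting recovers generating coefficients", {
  truth <- bckv_params(56.8, 107, -40, 10, 5)
  w <- seq(0.1, 0.9, by = 0.1)

  # noise-free: recovery to numerical tolerance
  d0 <- make_tg_dataset(truth, w_api = w, noise_sigma = 0, seed = 1)
  f0 <- fit_bckv(d0, 56.8, 107)
  expect_equal(c(f0$a0, f0$a1, f0$a2), c(-40, 10, 5), tolerance = 1e-6)
  expect_gt(attr(f0, "adj_r_squared"), 0.99)
  # evaluating the fit at the data compositions reproduces the inputs
  expect_equal(bckv_tg(f0, w), d0$tg, tolerance = 1e-8)

  # 0.5 K noise: coefficients within 95% confidence intervals
  d1 <- make_tg_dataset(truth, w_api = w, noise_sigma = 0.5, seed = 1)
  f1 <- fit_bckv(d1, 56.8, 107)
  se <- attr(f1, "se")
  z <- z_score(c(f1$a0, f1$a1, f1$a2), c(-40, 10, 5), se)
  expect_true(all(abs(z) < qt(0.975, attr(f1, "n_fit") - 3)))

  # data on the linear rule -> all coefficients ~ 0
  lin <- data.frame(w_api = w, tg = w * 56.8 + (1 - w) * 107)
  fl <- fit_bckv(lin, 56.8, 107)
  expect_equal(c(fl$a0, fl$a1, fl$a2), c(0, 0, 0), tolerance = 1e-9)

  # reduced-order fits with few interior points
  two <- data.frame(w_api = c(0.3, 0.7), tg = bckv_tg(truth, c(0.3, 0.7)))
  f2 <- fit_bckv(two, 56.8, 107)
  expect_identical(f2$a2, 0)
  one <- data.frame(w_api = 0.5, tg = bckv_tg(truth, 0.5))
  fone <- fit_bckv(one, 56.8, 107)
  expect_identical(c(fone$a1, fone$a2), c(0, 0))
  none <- data.frame(w_api = c(0, 1), tg = c(107, 56.8))
  expect_error(fit_bckv(none, 56.8, 107), "interior")
})

test_that("extremal BCKV-CK gap diagnostic locates the largest discrepancy", {
  fx <- load_paper_fixtures()
  nap <- fx$materials$Naproxen
  cop <- fx$materials$Copovidone
  pts <- data.frame(w_api = c(0.1, 0.3),
                    tg = c(fx$blends[["NAP 10%"]]$tg_measured,
                           fx$blends[["NAP 30%"]]$tg_measured))
  fit <- fit_bckv(pts, nap$tg, cop$tg)
  ext <- bckv_ck_extremum(fit, blend_spec(nap, cop, 0.3))
  expect_lt(ext$gap, 0)            # naproxen deviates negatively
  expect_gt(abs(ext$gap), 10)
  expect_true(ext$w_api > 0 && ext$w_api < 1)
})
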