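test_that("Carreau-Yasuda evaluation matches closed-form values", {
  f <- flow_curve_fit(1000, 1, 2, 0.5, 150)
  expect_equal(eval_viscosity(f, 0), 1000)                    # plateau limit
  expect_equal(eval_viscosity(f, 1), 1000 * 2^(-0.25))        # hand value
  expect_error(eval_viscosity(f, -1), "non-negative")
  # non-increasing in rate for shear-thinning n <= 1
  g <- 10^seq(-3, 3, length.out = 60)
  expect_true(all(diff(eval_viscosity(f, g)) <= 0))
  # Newtonian reduction: n = 1 is flat
  fn <- flow_curve_fit(1000, 1, 2, 1, 150)
  expect_equal(eval_viscosity(fn, g), rep(1000, length(g)))
})

test_that("single sweep yields an identity master curve", {
  s <- frequency_sweep(150, 2 * pi * 10^seq(1, -1, length.out = 9),
                       rep(1e4, 9))
  mc <- build_master_curve(list(s), t_ref = 150)
  expect_equal(unname(mc$shift_factors), 1)
  expect_equal(mc$points$omega, sort(s$omega))
})

test_that("TTS shifting recovers known WLF shift factors from synthetic sweeps", {
  sw <- make_saos_dataset(cop_truth$cy, cop_truth$wlf, noise_sigma = 0, seed = 1)
  mc <- build_master_curve(sw, t_ref = 150)
  truth_a <- shift_factor_at(cop_truth$wlf,
                             as.numeric(names(mc$shift_factors)))
  expect_lt(max(abs(log10(mc$shift_factors) - log10(truth_a))), 1e-3)
  # shift factors decrease with temperature for a thermorheologically
  # simple melt
  expect_true(all(diff(log10(mc$shift_factors)) < 0))

  # re-referencing identity: a_T(t_ref') = a_T(t_ref) / a_{t_ref'}
  mc140 <- build_master_curve(sw, t_ref = 140)
  rr <- rereference_shift_factors(mc, 140)
  expect_lt(max(abs(log10(rr) - log10(mc140$shift_factors))), 1e-3)
})

test_that("sweeps that cannot overlap raise an error naming the pair", {
  s1 <- frequency_sweep(150, 2 * pi * 10^seq(1, 0, length.out = 5),
                        1e4 * (10^seq(1, 0, length.out = 5))^-0.5)
  # a single-point sweep can never share a two-point overlap window
  s2 <- frequency_sweep(160, 2 * pi, 5e3)
  err <- tryCatch(build_master_curve(list(s1, s2), t_ref = 150),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "150.0 degC")
  expect_match(conditionMessage(err), "160.0 degC")
})

test_that("Carreau-Yasuda fitting recovers generating parameters", {
  g <- 10^seq(-2, 3, length.out = 25)
  truth <- flow_curve_fit(1e4, 1, 2, 0.3, 150)
  pts <- data.frame(gamma_dot = g, eta = eval_viscosity(truth, g))
  fit <- fit_carreau_yasuda(pts, t_ref = 150)
  expect_equal(c(fit$eta0, fit$lam, fit$a, fit$n), c(1e4, 1, 2, 0.3),
               tolerance = 1e-6)

  # flat (Newtonian) data fit back a flat curve
  flat <- data.frame(gamma_dot = g, eta = rep(500, length(g)))
  ffit <- fit_carreau_yasuda(flat, t_ref = 150)
  expect_equal(eval_viscosity(ffit, g), rep(500, length(g)), tolerance = 1e-6)

  # fewer than 5 points falls back to the reduced fit with a = 2
  few <- pts[seq(1, 25, by = 7), ]
  rfit <- fit_carreau_yasuda(few, t_ref = 150)
  expect_true(attr(rfit, "reduced"))
  expect_identical(rfit$a, 2)
})

test_that("WLF fitting recovers generating constants and behaves at t0", {
  temps <- seq(130, 180, by = 10)
  truth <- wlf_params(8, 120, 150)
  a_t <- setNames(shift_factor_at(truth, temps), temps)
  expect_equal(unname(a_t[["150"]]), 1)
  fit <- fit_wlf(a_t, t0 = 150)
  expect_equal(c(fit$c1, fit$c2), c(8, 120), tolerance = 1e-4)
  # a_T strictly decreasing above t0 for positive constants
  expect_true(all(diff(shift_factor_at(fit, seq(150, 200, by = 5))) < 0))
  expect_error(fit_wlf(a_t[c("140", "150", "160")], t0 = 150), "at least 3")
})

test_that("full TTS + CY + WLF round trip recovers all six parameters at 2% noise", {
  sw <- make_saos_dataset(cop_truth$cy, cop_truth$wlf, noise_sigma = 0.02,
                          seed = 1)
  expect_equal(sum(vapply(sw, function(s) length(s$omega), 0L)), 45L)
  mc <- build_master_curve(sw, t_ref = 150)

  # master-curve residual no worse than the injected noise
  cy <- fit_carreau_yasuda(mc)
  expect_lt(attr(cy, "rms_log_resid"), 0.02 / log(10) * 1.5)

  wlf <- fit_wlf(mc)
  se_cy <- attr(cy, "se")
  se_w <- attr(wlf, "se")
  z <- c(z_score(log(cy$eta0), log(1e4), se_cy[1]),
         z_score(log(cy$lam), log(0.5), se_cy[2]),
         z_score(log(cy$a), log(2), se_cy[3]),
         z_score(cy$n, 0.3, se_cy[4]),
         z_score(wlf$c1, 8, se_w[1]),
         z_score(wlf$c2, 120, se_w[2]))
  expect_true(all(abs(z) < 1.96))
})

test_that("SAOS CSV reader handles frequency and modulus input forms", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature_C,frequency_Hz,eta_star_Pa_s",
               "150,10,900", "150,1,1000", "160,10,800", "160,1,950"), path)
  sw <- read_saos_csv(path)
  expect_length(sw, 2L)
  expect_equal(sw[[1]]$omega, 2 * pi * c(10, 1))   # Hz -> rad/s, descending

  # moduli form: |eta*| = sqrt(G'^2 + G''^2) / omega
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature_C,omega_rad_s,g_prime_Pa,g_double_prime_Pa",
               "150,1,300,400", "150,10,3000,4000"), path2)
  sw2 <- read_saos_csv(path2)
  expect_equal(sw2[[1]]$eta_star, c(500, 500))

  # round trip through the writer
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_saos_csv(sw, path3)
  expect_equal(read_saos_csv(path3), sw)
})
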