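test_that("specific mechanical energy matches the dimensional oracle", {
  # 2*pi*100 rpm * 1 N m / 60 = 10.472 W; over 0.12 kg/h -> 87.27 W h/kg
  run <- extrusion_run(100, 0.12, torque = 2.2, idle_torque = 1.2)
  expect_equal(as.numeric(compute_sme(run)), 87.266, tolerance = 1e-4)

  # exactly linear in net torque and screw speed, inverse in feed rate
  base <- as.numeric(compute_sme(run))
  expect_equal(as.numeric(compute_sme(extrusion_run(100, 0.12, 3.2, 1.2))),
               2 * base)
  expect_equal(as.numeric(compute_sme(extrusion_run(200, 0.12, 2.2, 1.2))),
               2 * base)
  expect_equal(as.numeric(compute_sme(extrusion_run(100, 0.24, 2.2, 1.2))),
               base / 2)

  # torque at or below idle clamps to zero with a flag
  expect_equal(as.numeric(compute_sme(extrusion_run(100, 0.12, 1.2))), 0)
  clamped <- compute_sme(extrusion_run(100, 0.12, 0.5))
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "torque_clamped"))
  expect_error(extrusion_run(100, 0, 2), "positive")
})

test_that("1-D energy demonstrator accounts are consistent and labelled", {
  run <- extrusion_run(100, 0.12, 0)
  eb <- simulate_energy_1d(flow = cop_truth$cy, wlf = cop_truth$wlf,
                           run = run, barrel_temp = 150)
  expect_s3_class(eb, "energy_breakdown")
  expect_gte(eb$dissipated, 0)
  expect_gte(eb$conduction, 0)
  expect_equal(eb$sme, eb$dissipated + eb$conduction)
  expect_identical(eb$melting, 0)
  expect_true(any(grepl("demonstrator", eb$assumptions)))

  # inviscid melt dissipates nothing
  inviscid <- flow_curve_fit(0, 0.5, 2, 0.3, 150)
  eb0 <- simulate_energy_1d(flow = inviscid, wlf = cop_truth$wlf,
                            run = run, barrel_temp = 150)
  expect_identical(eb0$dissipated, 0)

  # screw geometry validation
  expect_error(screw_element("conveying", 30, 12, channel_depth = 0),
               "channel depth")
  expect_equal(sum(vapply(default_screw_config(), `[[`, 0, "length")), 300)
})

test_that("dissipated energy is monotone in zero-shear viscosity", {
  run <- extrusion_run(100, 0.12, 0)
  eta0s <- 10^seq(2, 5, length.out = 10)
  diss <- vapply(eta0s, function(e0) {
    f <- flow_curve_fit(e0, cop_truth$cy$lam, cop_truth$cy$a,
                        cop_truth$cy$n, 150)
    simulate_energy_1d(flow = f, wlf = cop_truth$wlf, run = run,
                       barrel_temp = 150)$dissipated
  }, 0)
  expect_true(all(diff(diss) >= 0))
})

test_that("lower API content predicts higher energy demand for every reference API", {
  # 10% blends have higher Tg -> higher eta0 -> more dissipation than 30%
  fx <- load_paper_fixtures()
  corr <- default_tg_eta0_correlation()
  run <- extrusion_run(100, 0.12, 0)
  for (api in c("CXB", "LOR", "NAP", "PZQ")) {
    sme <- vapply(c(10, 30), function(pct) {
      tg <- fx$blends[[sprintf("%s %d%%", api, pct)]]$tg_measured
      bl <- generate_model_flow_curve(cop_truth$cy, cop_truth$wlf, corr, tg)
      simulate_energy_1d(flow = bl, wlf = cop_truth$wlf, run = run,
                         barrel_temp = 150)$sme
    }, 0)
    expect_gt(sme[1], sme[2])
  }

  # near-identical flow curves (measured vs model-based NAP 10%) give
  # near-identical energies: ~1% viscosity difference -> ~1% dissipation
  mk <- function(e0) flow_curve_fit(e0, cop_truth$cy$lam * e0 / 1e4,
                                    cop_truth$cy$a, cop_truth$cy$n, 150)
  e_meas <- simulate_energy_1d(flow = mk(7198), wlf = cop_truth$wlf,
                               run = run, barrel_temp = 150)$dissipated
  e_model <- simulate_energy_1d(flow = mk(7141), wlf = cop_truth$wlf,
                                run = run, barrel_temp = 150)$dissipated
  expect_gt(e_meas, e_model)
  expect_lt(abs(e_meas - e_model) / e_meas, 0.02)
})
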