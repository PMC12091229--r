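test_that("elastic simulator reproduces the Hertz closed form", {
  # (4/3) * 1000 Pa * sqrt(25 um) * (1 um)^1.5 = 6.67 nN
  probe <- probe_config(R_tip = 25, k_cant = 1e6)  # quasi-rigid cantilever
  rec <- simulate_elastic_curve(1000, probe, max_depth = 2)
  h <- rec$z - probe$z_contact
  i <- which.min(abs(h - 1))
  expect_equal(rec$F[i] * 1e3, 6.667, tolerance = 1e-3)  # nN
  # pre-contact force is identically zero
  expect_true(all(rec$F[rec$z < probe$z_contact] == 0))
})

test_that("elastic simulator accounts for cantilever compliance", {
  probe <- noiseless_probe()
  rec <- simulate_elastic_curve(9200, probe, max_depth = 2)
  # at the last sample, h + F/k must equal the base travel past contact
  h <- compute_indentation(suppressWarnings(segment_phases(rec)),
                           probe$z_contact)
  n <- length(rec$t)
  expect_equal(h[n] + rec$F[n] / probe$k_cant,
               rec$z[n] - probe$z_contact, tolerance = 1e-9)
  # deflection is a visible fraction of the travel for a stiff sample
  expect_gt(rec$F[n] / probe$k_cant, 0.01)
})

test_that("simulators are pure functions of (parameters, seed)", {
  probe <- probe_config(noise_sd = 2, seed = 42)
  r1 <- simulate_elastic_curve(1300, probe)
  r2 <- simulate_elastic_curve(1300, probe)
  expect_identical(r1$F, r2$F)
  m <- sls_material(2000, 1300, 2)
  h1 <- simulate_relaxation_record(m, probe)
  h2 <- simulate_relaxation_record(m, probe)
  expect_identical(h1$F, h2$F)
  probe2 <- probe_config(noise_sd = 2, seed = 43)
  expect_false(identical(r1$F, simulate_elastic_curve(1300, probe2)$F))
})

test_that("simulator rejects invalid parameters", {
  probe <- noiseless_probe()
  expect_error(simulate_elastic_curve(-5, probe), class = "invalid_parameter")
  expect_error(probe_config(R_tip = -1), class = "invalid_parameter")
  expect_error(sls_material(1000, 2000, 1), class = "invalid_parameter")
  expect_error(sls_material(1000, 500, -1), class = "invalid_parameter")
  expect_error(simulate_elastic_curve(1000, probe, max_depth = 0.5),
               class = "invalid_parameter")
})

test_that("rigid-hold SLS records follow the analytic decay", {
  probe <- noiseless_probe()
  # alpha = 1: elastic limit, flat hold
  m1 <- sls_material(2000, 2000, 2)
  rec <- simulate_relaxation_record(m1, probe)
  hold <- rec$F[rec$phase == "hold"]
  expect_equal(max(hold) - min(hold), 0, tolerance = 1e-12)
  # alpha = 0.648, tau = 2: 10-s relaxation (1-alpha)(1-e^-5) ~ 35.0 %
  m2 <- sls_material(2000, 0.648 * 2000, 2)
  rec2 <- simulate_relaxation_record(m2, probe)
  st <- relaxation_percentage(segment_phases(rec2))
  expect_equal(st$r_relax, sls_relax_pct(0.648, 2), tolerance = 0.01)
  # tau -> 0: hold force immediately at alpha * F_max
  m3 <- sls_material(2000, 0.5 * 2000, 1e-4)
  rec3 <- simulate_relaxation_record(m3, probe)
  Fh <- rec3$F[rec3$phase == "hold"]
  Fmax <- max(rec3$F[rec3$phase == "load"])
  expect_equal(Fh[1] / Fmax, 0.5, tolerance = 1e-3)
})

test_that("compliance-coupled hold creeps forward as force decays", {
  probe <- noiseless_probe()
  m <- sls_material(2000, 1300, 2)
  rec <- simulate_relaxation_record(m, probe, mode = "compliant")
  hold <- which(rec$phase == "hold")
  Fh <- rec$F[hold]
  expect_true(all(diff(Fh) <= 1e-12))          # force decays monotonically
  expect_true(all(diff(rec$z[hold]) == 0))     # base truly fixed
  # tip creeps in: indentation h = z - zc - F/k increases during the hold
  h <- (rec$z[hold] - probe$z_contact) - Fh / probe$k_cant
  expect_true(all(diff(h) >= 0))
  # decay bracketed between zero and the rigid-hold amount
  st <- relaxation_percentage(segment_phases(rec))
  expect_gt(st$r_relax, 0)
  expect_lt(st$r_relax, sls_relax_pct(m$alpha, m$tau))
})

test_that("null Ct simulation yields fold change exactly 1 everywhere", {
  eff <- data.frame(gene = rep(c("A", "B"), each = 2),
                    day = rep(c(0, 7), 2), log2fc = 0)
  ct <- simulate_ct_table(eff, n_reps = 4, seed = 1)
  fc <- fold_change_ddct(delta_ct(ct))
  expect_true(all(fc$fold == 1))
})

test_that("injected log2 effects pass through the ddCt pipeline", {
  eff <- data.frame(gene = "A", day = c(0, 7), log2fc = c(0, 1))
  ct <- simulate_ct_table(eff, n_reps = 4, seed = 1)
  fc <- fold_change_summary(fold_change_ddct(delta_ct(ct)))
  expect_equal(fc$fold[fc$day == 7], 2)
  expect_equal(fc$fold[fc$day == 0], 1)
})

test_that("undetected trajectories drive first_detection_day", {
  eff <- data.frame(gene = "MKX", day = c(0, 2, 4, 7),
                    log2fc = c(NA, NA, 0, 1))
  ct <- simulate_ct_table(eff, n_reps = 4, seed = 1)
  expect_equal(first_detection_day(ct, "MKX"), 4)
  expect_true(all(ct$ct[ct$gene == "MKX" & ct$day < 4] == 35))
  expect_false(any(ct$detected[ct$gene == "MKX" & ct$day < 4]))
})

test_that("ct generator refuses a conflicting reference gene", {
  eff <- data.frame(gene = "YWHAZ", day = 0, log2fc = 0)
  expect_error(simulate_ct_table(eff, n_reps = 4),
               class = "configuration_error")
})

test_that("orientation generator covers the dispersion limits", {
  perfect <- simulate_orientations(c(`0` = 0), seed = 1)
  expect_true(all(perfect$angle_deg == 0))
  unif <- simulate_orientations(c(`0` = Inf), n_cells = 4000,
                                n_constructs = 1, seed = 1)
  expect_equal(mean(unif$angle_deg), 45, tolerance = 0.03)
  expect_true(all(unif$angle_deg >= 0 & unif$angle_deg <= 90))
  a1 <- simulate_orientations(seed = 5)
  a2 <- simulate_orientations(seed = 5)
  expect_identical(a1$angle_deg, a2$angle_deg)
  expect_error(simulate_orientations(n_cells = 10),
               class = "invalid_parameter")
})

test_that("diameter generator matches the per-day design", {
  exact <- simulate_diameters(day_sds = c(`0` = 0, `7` = 0, `14` = 0,
                                          `21` = 0), seed = 1)
  expect_true(all(exact$diameter_mm[exact$day == 0] == 2.08))
  expect_true(all(exact$diameter_mm[exact$day == 21] == 0.55))
  big <- simulate_diameters(n_per_day = 4000, seed = 2)
  expect_equal(mean(big$diameter_mm[big$day == 0]), 2.08, tolerance = 0.005)
  d1 <- simulate_diameters(seed = 3)
  expect_identical(d1, simulate_diameters(seed = 3))
})
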