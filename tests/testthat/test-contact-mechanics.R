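test_that("indentation arithmetic accounts for cantilever deflection", {
  meta <- list(k_cant = 0.5, R_tip = 37.5, rate = 1000, label = "x")
  n <- 201                          # z hits 2 um exactly
  z <- seq(0, 10, length.out = n)
  F <- rep(0.5, n)
  rec <- force_record(seq_len(n) * 1e-3, z, F, meta)
  seg <- suppressWarnings(segment_phases(rec))
  h <- compute_indentation(seg, z_contact = 0)
  # z - zc = 2 um, F = 0.5 uN, k = 0.5 N/m -> deflection 1 um, h = 1 um
  i <- which.min(abs(z - 2))
  expect_equal(h[i], 1, tolerance = 1e-6)
  # pre-contact samples clip to zero
  expect_true(all(h[z < 1] == 0))
  # rigid cantilever limit: h -> z - zc
  meta_r <- meta; meta_r$k_cant <- 1e9
  rec_r <- force_record(rec$t, z, F, meta_r)
  h_r <- compute_indentation(suppressWarnings(segment_phases(rec_r)), 0)
  expect_equal(h_r[i], 2, tolerance = 1e-6)
  # missing k_cant is a configuration error
  rec_nok <- rec; rec_nok$meta$k_cant <- NULL
  class(rec_nok) <- "force_record"
  expect_error(compute_indentation(suppressWarnings(segment_phases(rec_nok)), 0),
               class = "configuration_error")
})

test_that("contact point is recovered on simulator output", {
  probe <- noiseless_probe()
  fit <- suppressWarnings(
    detect_contact_point(simulate_elastic_curve(1300, probe)))
  expect_lt(abs(fit$z_contact - 5), 0.05)
  # noisy curve: within 0.2 um
  noisy <- probe_config(noise_sd = 1, seed = 2)
  fit_n <- suppressWarnings(
    detect_contact_point(simulate_elastic_curve(1300, noisy)))
  expect_lt(abs(fit_n$z_contact - 5), 0.2)
  # flat noise-only record -> no-contact error
  flat <- force_record(seq(0, 1, length.out = 500),
                       seq(0, 10, length.out = 500),
                       withr::with_seed(1, rnorm(500, 0, 1e-3)),
                       list(k_cant = 0.5, R_tip = 37.5, rate = 500,
                            label = "flat"))
  expect_error(suppressWarnings(detect_contact_point(flat)),
               class = "no_contact")
})

test_that("Hertz fit recovers the printed day-0 and day-21 medians", {
  probe <- noiseless_probe()
  for (E_kPa in c(1.3, 9.2)) {
    fit <- suppressWarnings(
      analyze_indent(simulate_elastic_curve(E_kPa * 1000, probe)))
    expect_equal(fit$E_eff / 1000, E_kPa, tolerance = 0.01)
  }
})

test_that("degenerate and windowing cases behave as specified", {
  h <- seq(0, 1.2, by = 0.005)
  # F identically zero -> E 0, rmse 0
  fit0 <- fit_hertz(h, rep(0, length(h)), R_tip = 37.5)
  expect_equal(fit0$E_eff, 0)
  expect_equal(fit0$rmse, 0)
  # fewer than 10 in-window samples
  expect_error(fit_hertz(c(rep(2, length(h) - 5), h[1:5]),
                         rep(0, length(h)), 37.5),
               class = "insufficient_depth")
  # window truncation: [0.8, 1) um fits with a warning, < 0.8 rejects
  probe <- noiseless_probe()
  rec <- simulate_elastic_curve(1300, probe)
  zc <- probe$z_contact
  hh <- compute_indentation(suppressWarnings(segment_phases(rec)), zc)
  keep <- hh <= 0.9
  expect_warning(fit_t <- fit_hertz(hh[keep], rec$F[seq_along(hh)][keep], 37.5),
                 "truncated")
  expect_equal(fit_t$E_eff, 1300, tolerance = 0.01)
  keep2 <- hh <= 0.7
  expect_error(fit_hertz(hh[keep2], rec$F[seq_along(hh)][keep2], 37.5),
               class = "insufficient_depth")
})

test_that("forward/inverse recovery holds over the modulus-radius grid", {
  for (E in c(100, 400, 1300, 9200, 1e5)) {
    for (R in c(25, 50)) {
      probe <- probe_config(R_tip = R)
      fit <- suppressWarnings(
        analyze_indent(simulate_elastic_curve(E, probe)))
      expect_lt(abs(fit$E_eff - E) / E, 0.01)
    }
  }
})

test_that("recovered modulus increases strictly with true modulus", {
  grid <- c(100, 400, 1300, 9200, 1e5)
  rec <- vapply(grid, function(E)
    suppressWarnings(
      analyze_indent(simulate_elastic_curve(E, noiseless_probe())))$E_eff,
    numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("fit is scale-equivariant and baseline-invariant", {
  probe <- noiseless_probe()
  rec <- simulate_elastic_curve(1300, probe)
  seg <- suppressWarnings(segment_phases(rec))
  zc <- probe$z_contact
  h <- compute_indentation(seg, zc)
  F <- rec$F[seg$load]
  E1 <- fit_hertz(h, F, 37.5)$E_eff
  E3 <- fit_hertz(h, 3 * F, 37.5)$E_eff
  expect_equal(E3, 3 * E1, tolerance = 1e-12)
  # constant pre-contact offset removed by baseline subtraction in detection
  shifted <- rec
  shifted$F <- rec$F + 0.004
  fit_s <- suppressWarnings(detect_contact_point(shifted))
  expect_equal(fit_s$E_eff, 1300, tolerance = 0.01)
})

test_that("closed-form estimator agrees with nonlinear least squares", {
  probe <- noiseless_probe()
  rec <- simulate_elastic_curve(2500, probe)
  seg <- suppressWarnings(segment_phases(rec))
  h <- compute_indentation(seg, probe$z_contact)
  F <- rec$F[seg$load]
  keep <- h > 0 & h <= 1
  E_cf <- fit_hertz(h, F, 37.5)$E_eff
  nls_fit <- minpack.lm::nlsLM(
    Fk ~ (4 / 3) * E * sqrt(37.5e-6) * (hk * 1e-6)^1.5 / 1e-6,
    data = data.frame(hk = h[keep], Fk = F[keep]),
    start = list(E = 1000))
  expect_equal(E_cf, unname(coef(nls_fit)["E"]), tolerance = 1e-6)
})

test_that("construct aggregation averages five sites", {
  cm <- construct_modulus(c(1000, 2000, 3000, 4000, 5000), "c1", 0)
  expect_equal(cm$mean_E, 3000)
  expect_warning(one <- construct_modulus(1500, "c2", 0), "1 site")
  expect_equal(one$mean_E, 1500)
  expect_error(construct_modulus(numeric(0)), class = "invalid_parameter")
})

test_that("plotting-position CDF puts the median at 0.5", {
  cdf <- modulus_cdf(c(2, 1, 3))
  expect_equal(cdf$value, c(1, 2, 3))
  expect_equal(cdf$p, c(1 / 6, 1 / 2, 5 / 6))
  expect_equal(cdf$median, 2)
  # even n: interpolation between plotting positions
  expect_equal(modulus_cdf(c(1, 2, 3, 4))$median, 2.5)
  # all equal: vertical CDF at that value
  expect_equal(modulus_cdf(rep(7, 5))$median, 7)
  expect_equal(modulus_cdf(42)$median, 42)
})
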