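test_that("delta-Ct normalises each sample to the reference gene", {
  ct <- data.frame(gene = c("A", "YWHAZ", "A", "YWHAZ", "B"),
                   sample_id = c("s1", "s1", "s2", "s2", "s3"),
                   day = 0, ct = c(25, 20, 22, 21, 30))
  expect_warning(d <- delta_ct(ct), "s3")
  expect_equal(d$dct[d$sample_id == "s1"], 5)
  expect_equal(d$dct[d$sample_id == "s2"], 1)
  expect_false("s3" %in% d$sample_id)        # no reference -> dropped
  expect_false("YWHAZ" %in% d$gene)
  # gene equal to reference would give dCt 0 for every sample
  ct2 <- data.frame(gene = c("YWHAZ", "A"), sample_id = "s1", day = 0,
                    ct = c(20, 20))
  expect_equal(delta_ct(ct2)$dct, 0)
  expect_error(delta_ct(ct[ct$gene != "YWHAZ", ]),
               class = "configuration_error")
})

test_that("ddCt fold changes normalise the control group to exactly 1", {
  dct <- data.frame(gene = "A",
                    sample_id = sprintf("s%d", 1:6),
                    day = rep(c(0, 7), each = 3),
                    dct = c(4, 5, 6, 2, 3, 4), detected = TRUE)
  fc <- fold_change_ddct(dct, control_day = 0)
  smry <- fold_change_summary(fc)
  expect_identical(smry$fold[smry$day == 0], 1)
  # ddCt = -2 on average at day 7 -> group fold 4
  expect_equal(smry$fold[smry$day == 7], 4)
  # per-sample identities
  expect_equal(fc$fold[fc$day == 7 & fc$ddct == -1], 2)
  expect_equal(2^-3.3219, 0.1, tolerance = 1e-4)
  # a sample sitting at the control mean has fold exactly 1
  expect_equal(fc$fold[fc$dct == 5 & fc$day == 0], 1)
  expect_error(fold_change_ddct(dct, control_day = 3),
               class = "configuration_error")
})

test_that("first-detection-day control anchors each gene separately", {
  eff <- data.frame(gene = rep(c("EARLY", "LATE"), each = 3),
                    day = rep(c(0, 4, 7), 2),
                    log2fc = c(0, 1, 2, NA, 0, 1))
  ct <- simulate_ct_table(eff, n_reps = 4, seed = 1)
  fc <- fold_change_ddct(delta_ct(ct), control_day = "first_detection")
  smry <- fold_change_summary(fc)
  expect_equal(unique(smry$control_day[smry$gene == "EARLY"]), 0)
  expect_equal(unique(smry$control_day[smry$gene == "LATE"]), 4)
  expect_identical(smry$fold[smry$gene == "LATE" & smry$day == 4], 1)
})

test_that("single-pass 2-SD exclusion follows the stated rule", {
  # nine zeros and a ten: mean 1, sd sqrt(10); |10 - 1| > 2 sd -> dropped
  x <- c(rep(0, 9), 10)
  f <- exclude_outliers_2sd(x)
  expect_equal(as.numeric(f), rep(0, 9))
  expect_equal(attr(f, "excluded"), 10L)
  # symmetric 3-point set untouched (max |z| = 1)
  expect_equal(as.numeric(exclude_outliers_2sd(c(1, 2, 3))), c(1, 2, 3))
  # all equal: sd 0, nothing excluded
  expect_equal(as.numeric(exclude_outliers_2sd(rep(5, 6))), rep(5, 6))
  # n < 3 returned unchanged with a warning
  expect_warning(u <- exclude_outliers_2sd(c(1, 100)), "fewer than 3")
  expect_equal(as.numeric(u), c(1, 100))
  # single application, not iterated: the 9/1 split after exclusion is final
  x2 <- c(rep(0, 8), 5, 50)
  f2 <- exclude_outliers_2sd(x2)
  expect_true(5 %in% f2)   # 5 survives even though it is extreme post-drop
})

test_that("exclusion never removes more than half the group", {
  for (s in 1:25) {
    x <- withr::with_seed(s, stats::rcauchy(11))  # heavy tails
    f <- suppressWarnings(exclude_outliers_2sd(x))
    expect_lte(length(attr(f, "excluded")), floor(length(x) / 2))
  }
})

test_that("detection calling walks the design days in order", {
  ct <- data.frame(gene = "G",
                   day = rep(c(0, 2, 4, 7), each = 4),
                   detected = c(rep(FALSE, 8), rep(TRUE, 8)))
  expect_equal(first_detection_day(ct, "G"), 4)
  ct$detected <- TRUE
  expect_equal(first_detection_day(ct, "G"), 0)
  ct$detected <- FALSE
  expect_true(is.na(first_detection_day(ct, "G")))
  # half the replicates is enough
  ct$detected <- rep(c(TRUE, FALSE), 8)
  expect_equal(first_detection_day(ct, "G"), 0)
  expect_error(first_detection_day(ct, "MISSING"),
               class = "configuration_error")
})

test_that("exact Mann-Whitney matches its stated examples", {
  t1 <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(t1$U, 0)
  expect_equal(t1$p.value, 1 / 3)
  t2 <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t2$U, 0)
  expect_equal(t2$p.value, 0.1)
  # complete overlap of tied singletons
  expect_equal(mann_whitney_exact(5, 5)$p.value, 1)
  expect_error(mann_whitney_exact(numeric(0), 1),
               class = "invalid_parameter")
})

test_that("exact test equals full enumeration for all sizes <= 6", {
  for (s in 1:40) {
    sizes <- withr::with_seed(s, sample(1:6, 2, replace = TRUE))
    vals <- withr::with_seed(s + 1000,
                             sample(1:1000, sum(sizes)))  # no ties
    a <- vals[seq_len(sizes[1])]
    b <- vals[-seq_len(sizes[1])]
    got <- mann_whitney_exact(a, b)
    expect_equal(got$p.value, mw_enumerate(a, b), tolerance = 1e-12)
    # and agrees with the reference implementation
    expect_equal(got$p.value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("null pipeline is exact and silent; effects are recovered", {
  genes <- data.frame(gene = rep(c("A", "B"), each = 3),
                      day = rep(c(0, 7, 21), 2), log2fc = 0)
  ct <- simulate_ct_table(genes, n_reps = 6, seed = 3)
  fc <- fold_change_ddct(delta_ct(ct))
  expect_true(all(fc$fold == 1))
  for (g in c("A", "B")) {
    d <- fc[fc$gene == g, ]
    for (dd in c(7, 21)) {
      p <- mann_whitney_exact(d$dct[d$day == 0], d$dct[d$day == dd])$p.value
      expect_gte(p, 0.05)
    }
  }

  # expected fold recovery at noise sd 0.2 cycles, n = 14 per day:
  # averaged over independent experiments the recovered fold is within 5 %
  eff <- data.frame(gene = "A", day = c(0, 7, 21), log2fc = c(0, 1, 2.5))
  folds <- vapply(1:20, function(s) {
    ct <- simulate_ct_table(eff, n_reps = 14, noise_sd = 0.2, seed = 100 + s)
    smry <- fold_change_summary(fold_change_ddct(delta_ct(ct)))
    c(smry$fold[smry$day == 7], smry$fold[smry$day == 21])
  }, numeric(2))
  expect_lt(abs(mean(folds[1, ]) - 2) / 2, 0.05)
  expect_lt(abs(mean(folds[2, ]) - 2^2.5) / 2^2.5, 0.05)
})

test_that("significance stars follow the conventional tiers", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 9e-4, 9e-5, NA)),
               c("ns", "*", "**", "***", "****", NA))
})
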