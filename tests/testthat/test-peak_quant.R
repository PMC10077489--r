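# Gaussian fitting, peak-to-peak, SNR, QC and hierarchical aggregation.

test_that("exact Gaussian samples are recovered to 1e-6 relative error", {
  d <- seq(0, 2, by = 0.05)
  cases <- list(c(100, 1.0, 0.15, 10), c(55, 0.6, 0.08, 0),
                c(2000, 1.4, 0.3, 150))
  for (p in cases) {
    v <- p[1] * exp(-(d - p[2])^2 / (2 * p[3]^2)) + p[4]
    f <- fit_gaussian(d, v)
    expect_true(f$converged)
    expect_lt(abs(f$amplitude - p[1]) / p[1], 1e-6)
    expect_lt(abs(f$center - p[2]) / p[2], 1e-6)
    expect_lt(abs(f$sigma - p[3]) / p[3], 1e-6)
    expect_lt(abs(f$baseline - p[4]) / max(p[4], 1), 1e-6)
  }
})

test_that("noisy fits agree with the brute-force grid-search oracle", {
  d <- seq(0, 2, by = 0.05)
  set.seed(101)
  for (i in 1:20) {
    amp <- runif(1, 50, 150); ctr <- runif(1, 0.4, 1.6)
    sig <- runif(1, 0.08, 0.3); base <- runif(1, 0, 20)
    v <- amp * exp(-(d - ctr)^2 / (2 * sig^2)) + base + rnorm(length(d), 0, 5)
    f <- fit_gaussian(d, v)
    expect_true(f$converged)
    expect_lte(abs(f$center - grid_fit_oracle(d, v)), 0.001 + 1e-9)
  }
})

test_that("degenerate profiles are flagged, not fitted", {
  d <- seq(0, 2, by = 0.05)
  flat <- fit_gaussian(d, rep(7, length(d)))
  expect_false(flat$converged)
  expect_equal(flat$reason, "flat_profile")
  expect_error(fit_gaussian(d[1:5], rnorm(5)), "at least 8")
})

test_that("peak_to_peak is the signed centre difference", {
  mkfit <- function(center, conv = TRUE) {
    structure(list(center = center, converged = conv), class = "gaussian_fit")
  }
  expect_equal(peak_to_peak(mkfit(1.00), mkfit(1.30)), 0.30)
  expect_equal(peak_to_peak(mkfit(1.2), mkfit(1.2)), 0)
  expect_equal(peak_to_peak(mkfit(1.30), mkfit(1.00)), -0.30)
  expect_error(peak_to_peak(mkfit(1, conv = FALSE), mkfit(2)), "converged")
})

test_that("SNR is amplitude over residual SD, averaged over valid lines", {
  expect_equal(compute_snr(make_meas(rep(0.3, 5), amp = 100, rsd = 10)), 10)
  expect_equal(compute_snr(make_meas(rep(0.3, 5), amp = 150, rsd = 5)), 30)
  expect_identical(compute_snr(make_meas(rep(0.3, 5), amp = 100, rsd = 0)),
                   Inf)
  expect_error(compute_snr(make_meas(0.3, valid = FALSE)), "no valid lines")
})

test_that("loop summaries apply the SD/SNR exclusion rule", {
  qc <- qc_config(min_valid_lines = 2L)
  sd_exact <- function(target_sd, n = 10, mean = 0.3) {
    mean + scale(seq_len(n))[, 1] * target_sd
  }
  # SD 8.0 > 7.5 with high SNR: excluded for sd
  s <- summarize_loop(make_meas(sd_exact(8), amp = 300, rsd = 10), qc)
  expect_true(s$excluded); expect_equal(s$reason, "sd")
  expect_equal(s$sd_p2p_um, 8)
  # SD 2.0, SNR 14: excluded for snr
  s <- summarize_loop(make_meas(sd_exact(2), amp = 140, rsd = 10), qc)
  expect_true(s$excluded); expect_equal(s$reason, "snr")
  # SD 2.0, SNR 30: included, mean is the arithmetic mean
  vals <- sd_exact(2, mean = 0.42)
  s <- summarize_loop(make_meas(vals, amp = 300, rsd = 10), qc)
  expect_false(s$excluded)
  expect_equal(s$mean_p2p_um, mean(vals))
  # boundary cases retained
  s <- summarize_loop(make_meas(sd_exact(7.5), amp = 150, rsd = 10), qc)
  expect_false(s$excluded)
  # no valid lines
  s <- summarize_loop(make_meas(rep(NA_real_, 3), valid = FALSE), qc)
  expect_true(s$excluded); expect_equal(s$reason, "no_valid_lines")
  # too few valid lines
  s <- summarize_loop(make_meas(c(0.3, 0.31), amp = 300, rsd = 1),
                      qc_config(min_valid_lines = 50L))
  expect_true(s$excluded); expect_equal(s$reason, "low_n")
  # orientation anomaly flagged, not excluded
  s <- summarize_loop(make_meas(c(rep(0.3, 7), rep(-0.2, 3)), amp = 300,
                                rsd = 1), qc)
  expect_true(s$orientation_anomaly)
  expect_false("orientation" %in% strsplit(s$reason, ",")[[1]])
})

test_that("sd threshold unit conversion is explicit", {
  m <- make_meas(0.3 + scale(1:10)[, 1] * 0.02, amp = 300, rsd = 1)
  expect_false(summarize_loop(m, qc_config(min_valid_lines = 2L))$excluded)
  # the same loop in nm units: SD 20 nm > 7.5 nm -> excluded
  s <- summarize_loop(m, qc_config(sd_unit = "nm", min_valid_lines = 2L))
  expect_true(s$excluded)
  expect_error(qc_config(sd_unit = "px"), "pixel_size")
})

test_that("hierarchical aggregation is unweighted mean-of-means", {
  tab <- data.frame(
    loop_id = paste0("L", 1:6),
    glomerulus_id = c("G1", "G1", "G2", "G2", "G3", "G3"),
    subject_id = c("S1", "S1", "S1", "S1", "S2", "S2"),
    group = "g",
    mean_p2p_um = c(0.2, 0.4, 0.5, 0.5, 0.1, 0.3),
    excluded = FALSE)
  agg <- aggregate_hierarchy(tab)
  expect_equal(sort(agg$glomerulus$mean_value), c(0.2, 0.3, 0.5))
  expect_equal(agg$subject$mean_value[agg$subject$subject_id == "S1"], 0.4)
  expect_equal(agg$subject$mean_value[agg$subject$subject_id == "S2"], 0.2)
  expect_equal(agg$group$mean_value, 0.3)

  # single loop identity
  one <- tab[1, ]
  expect_equal(aggregate_hierarchy(one)$subject$mean_value, 0.2)

  # excluding one loop removes it from its glomerulus mean
  tab2 <- tab; tab2$excluded[1] <- TRUE
  agg2 <- aggregate_hierarchy(tab2)
  expect_equal(agg2$glomerulus$mean_value[agg2$glomerulus$glomerulus_id == "G1"],
               0.4)

  # permutation invariance within levels
  perm <- tab[sample(nrow(tab)), ]
  agg3 <- aggregate_hierarchy(perm)
  expect_equal(agg3$group$mean_value, agg$group$mean_value)
  expect_equal(agg3$subject[order(agg3$subject$subject_id), "mean_value"],
               agg$subject[order(agg$subject$subject_id), "mean_value"])

  # a glomerulus losing all loops is omitted with a warning
  tab3 <- tab; tab3$excluded[tab3$glomerulus_id == "G1"] <- TRUE
  expect_warning(agg4 <- aggregate_hierarchy(tab3), "all loops excluded")
  expect_false("G1" %in% agg4$glomerulus$glomerulus_id)
  expect_equal(agg4$subject$mean_value[agg4$subject$subject_id == "S1"], 0.5)
})
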