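# Synthetic generators: ring images, cohorts, TEM tables, decay traces.

test_that("loop truth validates its invariants", {
  expect_error(loop_truth(radius_membrane = 0.2, glx_offset = 0.3), "smaller")
  expect_error(loop_truth(pixel_size = 0), "pixel_size")
  expect_error(loop_truth(glx_offset = -0.1), "glx_offset")
  expect_error(loop_truth(psf_sigma = 0, ring_width = 0), "zero-width")
})

test_that("identical truth reproduces images bit for bit", {
  tr <- small_loop(noise_model = "gaussian", noise_sd_frac = 0.05, seed = 99)
  a <- suppressMessages(make_loop_image(tr))
  b <- suppressMessages(make_loop_image(tr))
  expect_identical(a$images$glx_channel, b$images$glx_channel)
  expect_identical(a$images$membrane_channel, b$images$membrane_channel)
})

test_that("coincident rings give proportional channels", {
  tr <- small_loop(glx_offset = 0, peak_glx = 10000, peak_membrane = 30000)
  res <- make_loop_image(tr)
  expect_equal(res$images$glx_channel * 3, res$images$membrane_channel,
               tolerance = 1e-9)
})

test_that("radial peak of each channel sits at its ring radius", {
  # oracle: brute-force numerical convolution of the ideal circle with the
  # Gaussian PSF, evaluated densely along a ray through the centre
  tr <- loop_truth(radius_membrane = 5, glx_offset = 0.3, psf_sigma = 0.1,
                   pixel_size = 0.05, noise_model = "none")
  res <- make_loop_image(tr)
  rs <- seq(3.5, 6, by = 0.001)
  for (ch in c("membrane", "glx")) {
    R <- if (ch == "membrane") 5 else 4.7
    img <- if (ch == "membrane") res$images$membrane_channel
           else res$images$glx_channel
    oracle <- ring_conv_oracle(rs, R, 0.1)
    expect_lt(abs(rs[which.max(oracle)] - R), 0.002)
    # image radial maximum within half a pixel of the ring radius (bilinear
    # maxima sit on pixel centres, so exactly half a pixel is attainable)
    xs <- tr$center[1] + rs
    vals <- glxquant:::bilinear_sample(img, xs, rep(tr$center[2], length(rs)),
                                       tr$pixel_size)
    expect_lte(abs(rs[which.max(vals)] - R), tr$pixel_size / 2 + 1e-9)
    # rendered pixels match the oracle evaluated at the exact pixel radii
    n <- nrow(img)
    px_c <- (seq_len(n) - 0.5) * tr$pixel_size
    r_px <- sqrt(matrix((px_c - tr$center[1])^2, n, n, byrow = TRUE) +
                 matrix((px_c - tr$center[2])^2, n, n))
    band <- which(abs(r_px - R) < 0.4)
    pick <- band[seq(1, length(band), length.out = 500)]
    oracle_px <- ring_conv_oracle(r_px[pick], R, 0.1)
    scale <- max(img) / max(ring_conv_oracle(rs, R, 0.1))
    expect_lt(max(abs(img[pick] - scale * oracle_px)) / max(img), 0.005)
  }
})

test_that("blurred ring conserves total mass (unit-sum PSF)", {
  tr <- small_loop()
  res <- make_loop_image(tr)
  img <- res$images$membrane_channel
  # analytic total of the scaled profile: peak/max(f) * unit ring mass 2*pi*R
  s <- tr$psf_sigma
  fmax <- max(glxquant:::ring_radial_profile(
    seq(tr$radius_membrane - 6 * s, tr$radius_membrane + 6 * s,
        length.out = 4001), tr$radius_membrane, s))
  expected <- tr$peak_membrane / fmax * 2 * pi * tr$radius_membrane
  expect_equal(sum(img) * tr$pixel_size^2, expected, tolerance = 0.01)
})

test_that("noiseless loop images are rotationally symmetric", {
  res <- make_loop_image(small_loop())
  m <- res$images$membrane_channel
  rot90 <- function(x) t(x)[, rev(seq_len(nrow(x))), drop = FALSE]
  expect_equal(rot90(m), m, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("too-small field of view is a descriptive error", {
  expect_error(make_loop_image(small_loop(fov_um = 5)), "field of view")
})

test_that("negative-intensity clipping after noise is reported", {
  tr <- small_loop(noise_model = "gaussian", noise_sd_frac = 0.1, seed = 5)
  expect_message(make_loop_image(tr), "clipped")
})

test_that("glx_outside places the glycocalyx ring abluminally", {
  res <- make_loop_image(small_loop(glx_outside = TRUE))
  expect_equal(res$truth$radius_glx, 2.8)
})

test_that("cohort generation matches counts and truth structure", {
  dir <- withr::local_tempdir()
  groups <- data.frame(label = c("a", "b"), mean_offset_um = c(0.2, 0.4),
                       sd_um = c(0, 0), n_subjects = c(2, 2))
  spec <- cohort_spec(groups, glomeruli_per_subject = 2,
                      loops_per_glomerulus = 3,
                      loop_params = small_loop(), seed = 4)
  man <- make_cohort(spec, dir)
  expect_equal(nrow(man), 2 * 2 * 2 * 3)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "seeds.csv")))
  # zero between-subject SD: all offsets within a group equal the group mean
  expect_equal(unique(man$true_offset_um[man$group == "a"]), 0.2)
  expect_equal(unique(man$true_offset_um[man$group == "b"]), 0.4)
  # determinism
  man2 <- make_cohort(spec, withr::local_tempdir())
  expect_equal(man$true_offset_um, man2$true_offset_um)
  expect_equal(man$seed, man2$seed)
})

test_that("cohort subject offsets track group means within sampling error", {
  # offsets only require the manifest; tiny images keep this cheap
  dir <- withr::local_tempdir()
  groups <- data.frame(label = c("lo", "hi"), mean_offset_um = c(0.2, 0.4),
                       sd_um = c(0.05, 0.05), n_subjects = c(12, 12))
  lp <- loop_truth(radius_membrane = 1.2, glx_offset = 0.3, psf_sigma = 0.1,
                   pixel_size = 0.1, noise_model = "none")
  spec <- cohort_spec(groups, glomeruli_per_subject = 1,
                      loops_per_glomerulus = 1, loop_params = lp, seed = 21)
  man <- make_cohort(spec, dir)
  se <- 0.05 / sqrt(12)
  for (g in c("lo", "hi")) {
    mu <- groups$mean_offset_um[groups$label == g]
    subj <- unique(man[man$group == g, c("subject_id", "true_offset_um")])
    expect_lt(abs(mean(subj$true_offset_um) - mu), 3 * se)
  }
})

test_that("TEM generator realizes requested thickness structure", {
  # all-zero thicknesses -> fully uncovered
  res0 <- make_tem_annotation(tem_truth(n_intersections = 10,
                                        thickness_mean_nm = 0,
                                        thickness_sd_nm = 0, seed = 1))
  expect_equal(res0$truth$achieved_uncovered_fraction, 1.0)
  # constructed fraction: 20 intersections, 7 at <= 10 nm
  res <- make_tem_annotation(tem_truth(n_intersections = 20,
                                       fraction_uncovered = 0.35, seed = 2))
  expect_equal(res$truth$achieved_uncovered_fraction, 0.35)
  expect_equal(sum(res$truth$true_thicknesses_nm <= 10), 7L)
  # coordinates realize the drawn thicknesses exactly
  inter <- res$annotation[res$annotation$record_type == "intersection", ]
  d <- sqrt((inter$x1_nm - inter$x0_nm)^2 + (inter$y1_nm - inter$y0_nm)^2)
  expect_equal(d, res$truth$true_thicknesses_nm, tolerance = 1e-9)
  # sampling theory: n = 1000 normal draws, mean within 3 SE
  big <- make_tem_annotation(tem_truth(n_intersections = 1000,
                                       thickness_mean_nm = 200,
                                       thickness_sd_nm = 50, seed = 3))
  expect_lt(abs(mean(big$truth$true_thicknesses_nm) - 200), 3 * 50 / sqrt(1000))
  # determinism
  res_b <- make_tem_annotation(tem_truth(n_intersections = 20,
                                         fraction_uncovered = 0.35, seed = 2))
  expect_identical(res$annotation, res_b$annotation)
})

test_that("decay trace follows the stated one-compartment model", {
  # zero permeability: constant at I0
  tr0 <- make_decay_trace(decay_truth(ps_true = 0, noise_sd = 0))
  expect_true(all(tr0$intensities == 1000))
  # closed form at t = 60 s for k = 0.01 s^-1
  tr <- make_decay_trace(decay_truth(ps_true = 0.025, radius = 5, I0 = 1000,
                                     I_inf = 100, noise_sd = 0))
  expect_equal(tr$intensities[tr$times == 60], 100 + 900 * exp(-0.6),
               tolerance = 1e-12)
  # same seed -> identical noisy trace
  a <- make_decay_trace(decay_truth(noise_sd = 10, seed = 8))
  b <- make_decay_trace(decay_truth(noise_sd = 10, seed = 8))
  expect_identical(a$intensities, b$intensities)
  expect_error(decay_truth(radius = 0), "radius")
})
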