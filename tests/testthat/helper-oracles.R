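# Shared fixtures and independent oracles.

# Small, fast loop for unit tests (the acceptance suite uses the full-size
# stated-world geometry).
small_loop <- function(radius_membrane = 2.5, glx_offset = 0.3,
                       psf_sigma = 0.1, pixel_size = 0.05,
                       noise_model = "none", ...) {
  loop_truth(radius_membrane = radius_membrane, glx_offset = glx_offset,
             psf_sigma = psf_sigma, pixel_size = pixel_size,
             noise_model = noise_model, ...)
}

# Independent oracle for the blurred-ring radial profile: brute-force
# numerical convolution of an ideal circle (discretized as n_pts point
# sources of equal line mass) with a unit-mass isotropic Gaussian, evaluated
# at radii r along a ray through the centre.
ring_conv_oracle <- function(r, R, s, n_pts = 20000L) {
  theta <- (seq_len(n_pts) - 0.5) * 2 * pi / n_pts
  px <- R * cos(theta); py <- R * sin(theta)
  mass <- 2 * pi * R / n_pts
  vapply(r, function(ri) {
    d2 <- (ri - px)^2 + py^2
    sum(exp(-d2 / (2 * s^2))) * mass / (2 * pi * s^2)
  }, numeric(1))
}

# Independent brute-force (center, sigma) grid-search oracle for the Gaussian
# fit: profiled RSS (amplitude/baseline solved in closed form per grid node),
# coarse pass at 0.005 um then a fine pass at `res` around the coarse
# optimum. Returns the grid-optimal center.
grid_fit_oracle <- function(distances, values, res = 0.001) {
  n <- length(values)
  sy <- sum(values); syy <- sum(values^2)
  rss_grid <- function(centers, sigmas) {
    best <- c(Inf, NA, NA)
    for (s in sigmas) {
      G <- exp(-outer(distances, centers, "-")^2 / (2 * s^2))
      sg <- colSums(G); sgg <- colSums(G^2); sgy <- colSums(G * values)
      det <- n * sgg - sg^2
      a <- (n * sgy - sg * sy) / det
      b <- (sy - a * sg) / n
      rss <- syy - 2 * a * sgy - 2 * b * sy + a^2 * sgg + 2 * a * b * sg +
        n * b^2
      rss[det <= 0 | !is.finite(rss)] <- Inf
      i <- which.min(rss)
      if (rss[i] < best[1]) best <- c(rss[i], centers[i], s)
    }
    best
  }
  rng <- range(distances)
  coarse <- rss_grid(seq(rng[1], rng[2], by = 0.005),
                     seq(2 * res, diff(rng) / 2, by = 0.005))
  fine <- rss_grid(seq(max(rng[1], coarse[2] - 0.006),
                       min(rng[2], coarse[2] + 0.006), by = res),
                   seq(max(res, coarse[3] - 0.006), coarse[3] + 0.006,
                       by = res))
  fine[2]
}

# Constructed line-measurement table with prescribed per-line peak-to-peak
# values and membrane amplitude / residual SD (for QC and SNR tests).
make_meas <- function(p2p, amp = 100, rsd = 1, loop_id = "L1",
                      valid = TRUE) {
  k <- length(p2p)
  data.frame(line_id = sprintf("l%03d", seq_len(k)), loop_id = loop_id,
             p2p_um = p2p, valid = rep_len(valid, k), reason = NA_character_,
             glx_center_um = 0.8, glx_amplitude = amp, glx_sigma_um = 0.1,
             glx_residual_sd = rep_len(rsd, k),
             mem_center_um = 0.8 + p2p, mem_amplitude = rep_len(amp, k),
             mem_sigma_um = 0.1, mem_residual_sd = rep_len(rsd, k),
             stringsAsFactors = FALSE)
}
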