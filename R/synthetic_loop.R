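# Synthetic two-channel capillary-loop images with known ground truth.
#
# The membrane channel is an ideal circle of radius radius_membrane; the
# glycocalyx channel an ideal circle displaced glx_offset towards the lumen
# (or outwards with glx_outside = TRUE, for negative controls). Both circles
# have zero intrinsic width (configurable via ring_width) and are blurred by
# an isotropic Gaussian PSF, so the true radial peak positions are known
# analytically: the blurred profile of a unit-mass circle of radius R is
#   f(r) = (R / s^2) * exp(-(r^2 + R^2) / (2 s^2)) * I0(r R / s^2)
# with s^2 = psf_sigma^2 + ring_width^2 and I0 the modified Bessel function.

#' Ground truth for one synthetic capillary loop image
#'
#' @param radius_membrane Membrane ring radius (um).
#' @param glx_offset Luminal displacement of the glycocalyx ring relative to
#'   the membrane ring (um); this is the true peak-to-peak value.
#' @param psf_sigma Isotropic Gaussian PSF sigma (um).
#' @param pixel_size Physical pixel size (um/px).
#' @param ring_width Intrinsic Gaussian cross-section SD of each ring (um);
#'   0 gives ideal zero-width circles.
#' @param peak_glx,peak_membrane Peak intensity of each channel (arbitrary
#'   units; keep below 65535 if images are written as 16-bit TIFF).
#' @param background_glx,background_membrane Constant background per channel.
#' @param noise_model One of \code{"none"}, \code{"gaussian"},
#'   \code{"poisson"}. Gaussian noise SD is \code{noise_sd_frac} times the
#'   channel peak intensity.
#' @param noise_sd_frac Gaussian noise SD as a fraction of peak intensity.
#' @param glx_outside Place the glycocalyx ring outside the membrane ring
#'   (negative-control geometry).
#' @param fov_um Side length of the square field of view (um). Default
#'   leaves room for the loop, 3 PSF sigmas, and a 2 um profile line.
#' @param center Loop centre (um), default the field-of-view centre.
#' @param seed Integer seed; identical truth (including seed) reproduces the
#'   images bit for bit.
#' @return A \code{loop_truth} list.
#' @export
loop_truth <- function(radius_membrane = 5, glx_offset = 0.3, psf_sigma = 0.1,
                       pixel_size = 0.05, ring_width = 0,
                       peak_glx = 20000, peak_membrane = 30000,
                       background_glx = 0, background_membrane = 0,
                       noise_model = c("none", "gaussian", "poisson"),
                       noise_sd_frac = 0.02, glx_outside = FALSE,
                       fov_um = NULL, center = NULL, seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_number(radius_membrane, "radius_membrane", 0, strict_min = TRUE)
  check_number(glx_offset, "glx_offset", 0)
  if (glx_offset >= radius_membrane) {
    stopf("glx_offset (%g) must be smaller than radius_membrane (%g)",
          glx_offset, radius_membrane)
  }
  check_number(psf_sigma, "psf_sigma", 0)
  check_number(pixel_size, "pixel_size", 0, strict_min = TRUE)
  check_number(ring_width, "ring_width", 0)
  if (psf_sigma + ring_width <= 0) {
    stopf("psf_sigma + ring_width must be > 0 to rasterize a zero-width ring")
  }
  if (is.null(fov_um)) {
    fov_um <- 2 * (radius_membrane + max(3 * psf_sigma, 1.5))
  }
  if (is.null(center)) center <- c(fov_um / 2, fov_um / 2)
  structure(list(
    radius_membrane = radius_membrane, glx_offset = glx_offset,
    psf_sigma = psf_sigma, pixel_size = pixel_size, ring_width = ring_width,
    peak_glx = peak_glx, peak_membrane = peak_membrane,
    background_glx = background_glx, background_membrane = background_membrane,
    noise_model = noise_model, noise_sd_frac = noise_sd_frac,
    glx_outside = isTRUE(glx_outside), fov_um = fov_um, center = center,
    seed = as.integer(seed)
  ), class = "loop_truth")
}

# Radial profile of a unit-mass circle of radius R blurred by an isotropic
# Gaussian of SD s, evaluated with the exponentially-scaled Bessel function
# to stay finite at large r*R/s^2.
ring_radial_profile <- function(r, R, s) {
  z <- r * R / s^2
  (R / s^2) * exp(-(r - R)^2 / (2 * s^2)) * besselI(z, 0, expon.scaled = TRUE)
}

# Peak height of the blurred-ring profile, used to scale channels to a
# requested peak intensity.
ring_profile_max <- function(R, s) {
  r <- seq(max(0, R - 5 * s), R + 5 * s, length.out = 4001)
  max(ring_radial_profile(r, R, s))
}

#' Render a synthetic two-channel loop image
#'
#' @param truth A \code{\link{loop_truth}}.
#' @return List with \code{images} (a \code{\link{channel_image_pair}}) and
#'   the \code{truth} record (with the glycocalyx ring radius added as
#'   \code{radius_glx}).
#' @export
make_loop_image <- function(truth) {
  stopifnot(inherits(truth, "loop_truth"))
  s <- sqrt(truth$psf_sigma^2 + truth$ring_width^2)
  R_mem <- truth$radius_membrane
  R_glx <- R_mem + if (truth$glx_outside) truth$glx_offset else -truth$glx_offset
  margin <- 3 * truth$psf_sigma
  half <- truth$fov_um / 2
  reach <- max(abs(truth$center - half)) + max(R_mem, R_glx) + margin
  if (reach > half + 1e-9) {
    stopf(paste0("field of view (%g um) too small: loop of radius %g um at ",
                 "(%g, %g) plus 3*psf_sigma margin needs %g um"),
          truth$fov_um, max(R_mem, R_glx), truth$center[1], truth$center[2],
          2 * reach)
  }
  n <- max(8L, round(truth$fov_um / truth$pixel_size))
  px <- (seq_len(n) - 0.5) * truth$pixel_size
  # rows index y, columns index x; pixel centres at (i - 0.5) * pixel_size
  r <- sqrt(matrix((px - truth$center[1])^2, n, n, byrow = TRUE) +
            matrix((px - truth$center[2])^2, n, n, byrow = FALSE))
  # the profile depends on radius only: evaluate the Bessel form on a dense
  # 1-D grid and interpolate; beyond 6 blur widths it is < 2e-8 of the peak
  render <- function(R, peak, bg) {
    rg <- seq(max(0, R - 6 * s), R + 6 * s, length.out = 4001L)
    fg <- ring_radial_profile(rg, R, s)
    out <- matrix(bg, n, n)
    band <- abs(r - R) <= 6 * s
    out[band] <- bg + peak * stats::approx(rg, fg, r[band])$y / max(fg)
    out
  }
  glx <- render(R_glx, truth$peak_glx, truth$background_glx)
  mem <- render(R_mem, truth$peak_membrane, truth$background_membrane)
  if (truth$noise_model != "none") {
    noisy <- with_seed(truth$seed, {
      add_noise <- function(img, peak) {
        if (truth$noise_model == "gaussian") {
          img + stats::rnorm(length(img), sd = truth$noise_sd_frac * peak)
        } else {
          matrix(stats::rpois(length(img), lambda = pmax(img, 0)), nrow(img))
        }
      }
      list(glx = add_noise(glx, truth$peak_glx),
           mem = add_noise(mem, truth$peak_membrane))
    })
    glx <- noisy$glx; mem <- noisy$mem
    n_clip <- sum(glx < 0) + sum(mem < 0)
    if (n_clip > 0) {
      message(sprintf("clipped %d negative pixel(s) to 0 after noise", n_clip))
      glx[glx < 0] <- 0; mem[mem < 0] <- 0
    }
  }
  truth$radius_glx <- R_glx
  list(images = channel_image_pair(glx, mem, truth$pixel_size), truth = truth)
}
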