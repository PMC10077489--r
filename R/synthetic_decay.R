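# Synthetic trapped-glomerulus fluorescence decay traces. The lumen is
# modelled as one well-mixed compartment: after the perfusate switch at
# t = 0 the labelled-albumin intensity follows
#   I(t) = I_inf + (I0 - I_inf) * exp(-k t),   k = 2 * Ps / r
# (washout of a cylinder of radius r through its wall at permeability Ps).

#' Ground truth for a synthetic permeability decay trace
#'
#' @param ps_true True apparent albumin permeability (um/s).
#' @param radius Capillary radius (um).
#' @param I0 Intensity at the perfusate switch.
#' @param I_inf Asymptotic intensity (default 0; a nonzero floor biases the
#'   first-minute rate estimate, see the methods vignette).
#' @param sampling_rate_hz Samples per second.
#' @param duration_s Trace length (s); >= 60 for the default fitting window.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param glomerulus_id,subject_id Hierarchy labels.
#' @param seed Integer seed.
#' @return A \code{decay_truth} list.
#' @export
decay_truth <- function(ps_true = 0.025, radius = 5, I0 = 1000, I_inf = 0,
                        sampling_rate_hz = 1, duration_s = 90, noise_sd = 0,
                        glomerulus_id = "G01", subject_id = "S01", seed = 1L) {
  check_number(ps_true, "ps_true", 0)
  check_number(radius, "radius", 0, strict_min = TRUE)
  check_number(sampling_rate_hz, "sampling_rate_hz", 0, strict_min = TRUE)
  check_number(duration_s, "duration_s", 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  structure(list(ps_true = ps_true, radius = radius, I0 = I0, I_inf = I_inf,
                 sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 noise_sd = noise_sd, glomerulus_id = glomerulus_id,
                 subject_id = subject_id, seed = as.integer(seed)),
            class = "decay_truth")
}

#' Generate a synthetic decay trace
#'
#' @param truth A \code{\link{decay_truth}}.
#' @return A \code{decay_trace}: list with \code{times} (s, starting at the
#'   switch, t = 0), \code{intensities}, \code{t0}, \code{radius},
#'   \code{glomerulus_id}, \code{subject_id} and the generating \code{truth}.
#' @export
make_decay_trace <- function(truth) {
  stopifnot(inherits(truth, "decay_truth"))
  k <- 2 * truth$ps_true / truth$radius
  times <- seq(0, truth$duration_s, by = 1 / truth$sampling_rate_hz)
  ideal <- truth$I_inf + (truth$I0 - truth$I_inf) * exp(-k * times)
  intensities <- if (truth$noise_sd > 0) {
    with_seed(truth$seed,
              pmax(ideal + stats::rnorm(length(ideal), sd = truth$noise_sd), 0))
  } else ideal
  structure(list(times = times, intensities = intensities, t0 = 0,
                 radius = truth$radius, glomerulus_id = truth$glomerulus_id,
                 subject_id = truth$subject_id, truth = truth),
            class = "decay_trace")
}
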