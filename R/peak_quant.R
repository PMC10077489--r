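# Gaussian peak fitting of intensity profiles, per-line peak-to-peak
# distances, SD/SNR quality-control exclusion, and hierarchical averaging
# (lines -> loop -> glomerulus -> subject -> group).

#' Fit a Gaussian peak to an intensity profile
#'
#' Nonlinear least squares of
#' \code{amplitude * exp(-(d - center)^2 / (2 sigma^2)) + baseline}.
#' The amplitude and baseline are profiled out (solved by linear least
#' squares at each candidate (center, sigma)), and (center, sigma) are
#' optimized by bounded quasi-Newton (\code{L-BFGS-B}) initialized from
#' (argmax, quarter of the sampled range). Bounds: center within the sampled
#' range, sigma in [step, range].
#'
#' @param distances Sample positions (um from line start), strictly
#'   increasing, uniformly spaced.
#' @param values Intensities at \code{distances}.
#' @return A \code{gaussian_fit} list: \code{amplitude}, \code{center},
#'   \code{sigma}, \code{baseline}, \code{rss}, \code{residual_sd},
#'   \code{converged}, \code{reason}, \code{n}.
#' @export
fit_gaussian <- function(distances, values) {
  n <- length(distances)
  if (n < 8L || length(values) != n) {
    stopf("at least 8 samples required (got %d)", n)
  }
  not_conv <- function(reason) {
    structure(list(amplitude = NA_real_, center = NA_real_, sigma = NA_real_,
                   baseline = NA_real_, rss = NA_real_, residual_sd = NA_real_,
                   converged = FALSE, reason = reason, n = n),
              class = "gaussian_fit")
  }
  if (max(values) - min(values) <= 0) return(not_conv("flat_profile"))
  rng <- range(distances)
  span <- diff(rng)
  step <- distances[2] - distances[1]

  # profile the linear parameters: for fixed (center, sigma) the optimal
  # (baseline, amplitude) solve a 2x2 normal system
  lin_solve <- function(g) {
    sg <- sum(g); sgg <- sum(g * g); sy <- sum(values); sgy <- sum(g * values)
    det <- n * sgg - sg * sg
    if (det <= 1e-12 * n * max(sgg, 1)) return(NULL)
    a <- (n * sgy - sg * sy) / det
    b <- (sy - a * sg) / n
    c(a, b)
  }
  obj <- function(p) {
    g <- exp(-(distances - p[1])^2 / (2 * p[2]^2))
    ab <- lin_solve(g)
    if (is.null(ab)) return(sum((values - mean(values))^2))
    sum((values - ab[2] - ab[1] * g)^2)
  }
  init <- c(distances[which.max(values)], span / 4)
  lower <- c(rng[1], step)
  upper <- c(rng[2], span)
  fit <- tryCatch(
    stats::optim(init, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e4, pgtol = 1e-12, maxit = 500L)),
    error = function(e) e)
  if (inherits(fit, "error")) return(not_conv(conditionMessage(fit)))

  # damped Gauss-Newton polish on (center, sigma): L-BFGS-B stalls at ~1e-5
  # relative precision when residuals approach machine zero; a Gauss-Newton
  # fixed point is a stationary point of the RSS, so reaching one also
  # certifies convergence when the line search aborted (status 52)
  p <- fit$par
  at_fixed_point <- FALSE
  for (it in 1:50) {
    g <- exp(-(distances - p[1])^2 / (2 * p[2]^2))
    ab <- lin_solve(g)
    if (is.null(ab)) break
    r <- values - ab[2] - ab[1] * g
    J <- cbind(ab[1] * g * (distances - p[1]) / p[2]^2,
               ab[1] * g * (distances - p[1])^2 / p[2]^3)
    delta <- tryCatch(qr.solve(J, r), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    if (sum(abs(delta)) < 1e-8 * max(span, 1)) { at_fixed_point <- TRUE; break }
    rss0 <- sum(r^2)
    lambda <- 1
    repeat {
      cand <- pmin(pmax(p + lambda * delta, lower), upper)
      gc_ <- exp(-(distances - cand[1])^2 / (2 * cand[2]^2))
      abc <- lin_solve(gc_)
      rss1 <- if (is.null(abc)) Inf
              else sum((values - abc[2] - abc[1] * gc_)^2)
      if (rss1 <= rss0 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (!is.finite(rss1) || rss1 > rss0) {
      # no downhill direction left; a micro-step that cannot improve the RSS
      # is numerically a stationary point
      if (sum(abs(delta)) < 1e-6 * max(span, 1)) at_fixed_point <- TRUE
      break
    }
    moved <- sum(abs(cand - p))
    p <- cand
    if (moved < 1e-10 * max(span, 1)) { at_fixed_point <- TRUE; break }
  }
  g <- exp(-(distances - p[1])^2 / (2 * p[2]^2))
  ab <- lin_solve(g)
  if (is.null(ab)) return(not_conv("degenerate_profile"))
  res <- values - ab[2] - ab[1] * g
  converged <- fit$convergence == 0L || at_fixed_point
  structure(list(amplitude = ab[1], center = p[1], sigma = p[2],
                 baseline = ab[2], rss = sum(res^2),
                 residual_sd = stats::sd(res),
                 converged = converged,
                 reason = if (converged) NA_character_ else fit$message,
                 n = n), class = "gaussian_fit")
}

#' Signed peak-to-peak distance between two channel fits
#'
#' Positive when the glycocalyx peak is luminal to (precedes) the membrane
#' peak along the inside-to-outside line; the sign is preserved, not folded.
#'
#' @param glx_fit,membrane_fit Converged \code{gaussian_fit} objects.
#' @return Signed distance in um: \code{membrane_fit$center - glx_fit$center}.
#' @export
peak_to_peak <- function(glx_fit, membrane_fit) {
  if (!isTRUE(glx_fit$converged) || !isTRUE(membrane_fit$converged)) {
    stopf("peak_to_peak requires two converged fits")
  }
  membrane_fit$center - glx_fit$center
}

#' Measure all profile lines of one loop
#'
#' Samples each line, fits both channels, and computes per-line signed
#' peak-to-peak distances.
#'
#' @param images A \code{\link{channel_image_pair}}.
#' @param lines List of \code{profile_line}.
#' @param loop_id Loop label carried into the output.
#' @return Data frame, one row per line: \code{line_id}, \code{loop_id},
#'   \code{p2p_um}, \code{valid}, \code{reason}, per-channel fit columns
#'   (\code{glx_center_um}, \code{mem_center_um}, \code{mem_amplitude},
#'   \code{mem_residual_sd}, ...).
#' @export
measure_loop <- function(images, lines, loop_id = "loop") {
  rows <- lapply(lines, function(ln) {
    prof <- sample_profile(images, ln)
    gf <- fit_gaussian(prof$distances, prof$glx_values)
    mf <- fit_gaussian(prof$distances, prof$membrane_values)
    valid <- isTRUE(gf$converged) && isTRUE(mf$converged)
    reason <- if (valid) NA_character_ else {
      paste(stats::na.omit(c(
        if (!isTRUE(gf$converged)) paste0("glx:", gf$reason),
        if (!isTRUE(mf$converged)) paste0("membrane:", mf$reason))),
        collapse = ";")
    }
    data.frame(line_id = ln$line_id, loop_id = loop_id,
               p2p_um = if (valid) peak_to_peak(gf, mf) else NA_real_,
               valid = valid, reason = reason,
               glx_center_um = gf$center, glx_amplitude = gf$amplitude,
               glx_sigma_um = gf$sigma, glx_residual_sd = gf$residual_sd,
               mem_center_um = mf$center, mem_amplitude = mf$amplitude,
               mem_sigma_um = mf$sigma, mem_residual_sd = mf$residual_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quality-control configuration for loop summaries
#'
#' The exclusion rule follows the published protocol: a loop is excluded when
#' the SD of its line peak-to-peak values exceeds \code{sd_max} and/or its
#' signal-to-noise ratio falls below \code{snr_min}. The unit in which the SD
#' is compared is an explicit field (\code{sd_unit}): the protocol does not
#' state one, so no silent conversion is applied; \code{"report"} compares in
#' the unit the pipeline reports (um), \code{"nm"} and \code{"px"} convert
#' first.
#'
#' @param sd_max SD exclusion threshold (default 7.5; strictly greater
#'   excludes).
#' @param sd_unit Unit of \code{sd_max}: \code{"report"} (um), \code{"nm"},
#'   or \code{"px"}.
#' @param snr_min SNR exclusion threshold (default 15; strictly smaller
#'   excludes).
#' @param min_valid_lines Minimum converged lines for a usable loop (default
#'   50 for the 200-line automated mode; use 3 for manual mode).
#' @param snr_channel Channel whose fit feeds the SNR: \code{"membrane"}
#'   (default) or \code{"glx"}.
#' @param pixel_size Pixel size (um/px), required only for
#'   \code{sd_unit = "px"}.
#' @return A \code{qc_config} list.
#' @export
qc_config <- function(sd_max = 7.5, sd_unit = c("report", "nm", "px"),
                      snr_min = 15, min_valid_lines = 50L,
                      snr_channel = c("membrane", "glx"), pixel_size = NULL) {
  sd_unit <- match.arg(sd_unit)
  snr_channel <- match.arg(snr_channel)
  check_number(sd_max, "sd_max", 0, strict_min = TRUE)
  check_number(snr_min, "snr_min", 0, strict_min = TRUE)
  if (sd_unit == "px" && is.null(pixel_size)) {
    stopf("sd_unit = 'px' requires pixel_size")
  }
  structure(list(sd_max = sd_max, sd_unit = sd_unit, snr_min = snr_min,
                 min_valid_lines = as.integer(min_valid_lines),
                 snr_channel = snr_channel, pixel_size = pixel_size),
            class = "qc_config")
}

#' Signal-to-noise ratio of a loop's line measurements
#'
#' Per valid line, the fitted peak amplitude of the chosen channel divided by
#' the SD of that fit's residuals, then averaged over lines. A zero residual
#' SD (perfect fit) yields \code{Inf}, which never triggers the SNR
#' exclusion.
#'
#' @param measurements \code{\link{measure_loop}} output.
#' @param channel \code{"membrane"} (default) or \code{"glx"}.
#' @return Dimensionless ratio (possibly \code{Inf}).
#' @export
compute_snr <- function(measurements, channel = c("membrane", "glx")) {
  channel <- match.arg(channel)
  ok <- measurements$valid
  if (!any(ok)) stopf("no valid lines: SNR undefined")
  amp <- if (channel == "membrane") measurements$mem_amplitude[ok]
         else measurements$glx_amplitude[ok]
  rsd <- if (channel == "membrane") measurements$mem_residual_sd[ok]
         else measurements$glx_residual_sd[ok]
  snr_line <- ifelse(rsd <= 0, Inf, amp / rsd)
  mean(snr_line)
}

#' Summarize and quality-control one loop
#'
#' Mean and SD of the signed peak-to-peak over valid (converged) lines; the
#' loop is excluded when SD > sd_max, SNR < snr_min, or fewer than
#' \code{min_valid_lines} lines converged. Boundary values (SD equal to
#' sd_max, SNR equal to snr_min) are retained. Loops where more than 10% of
#' valid lines have negative peak-to-peak are flagged
#' \code{orientation_anomaly} but not excluded.
#'
#' @param measurements \code{\link{measure_loop}} output for one loop.
#' @param qc A \code{\link{qc_config}}.
#' @return One-row data frame: \code{loop_id}, \code{mean_p2p_um},
#'   \code{sd_p2p_um}, \code{snr}, \code{n_valid_lines}, \code{excluded},
#'   \code{reason}, \code{orientation_anomaly}.
#' @export
summarize_loop <- function(measurements, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"))
  loop_id <- measurements$loop_id[1]
  ok <- measurements$valid
  n_valid <- sum(ok)
  if (n_valid == 0L) {
    return(data.frame(loop_id = loop_id, mean_p2p_um = NA_real_,
                      sd_p2p_um = NA_real_, snr = NA_real_,
                      n_valid_lines = 0L, excluded = TRUE,
                      reason = "no_valid_lines", orientation_anomaly = FALSE,
                      stringsAsFactors = FALSE))
  }
  p2p <- measurements$p2p_um[ok]
  m <- mean(p2p)
  s <- if (n_valid > 1L) stats::sd(p2p) else 0
  snr <- compute_snr(measurements, qc$snr_channel)
  verdict <- apply_qc(s, snr, n_valid, qc)
  data.frame(loop_id = loop_id, mean_p2p_um = m, sd_p2p_um = s, snr = snr,
             n_valid_lines = n_valid, excluded = verdict$excluded,
             reason = verdict$reason,
             orientation_anomaly = mean(p2p < 0) > 0.1,
             stringsAsFactors = FALSE)
}

#' Apply the SD/SNR exclusion rule to loop statistics
#'
#' The rule itself: exclude when SD (in the configured unit) is strictly
#' greater than \code{sd_max}, when SNR is strictly smaller than
#' \code{snr_min}, or when too few lines converged. Values exactly at a
#' threshold are retained.
#'
#' @param sd_p2p SD of the loop's line peak-to-peak values (report units,
#'   um).
#' @param snr Loop signal-to-noise ratio (may be \code{Inf}).
#' @param n_valid_lines Number of converged lines.
#' @param qc A \code{\link{qc_config}}.
#' @return List: \code{excluded} (flag), \code{reason} (comma-joined codes
#'   among \code{"sd"}, \code{"snr"}, \code{"low_n"}, or \code{NA}).
#' @export
apply_qc <- function(sd_p2p, snr, n_valid_lines, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"))
  s_cmp <- switch(qc$sd_unit,
                  report = sd_p2p,
                  nm = sd_p2p * 1000,
                  px = sd_p2p / qc$pixel_size)
  reasons <- c(if (s_cmp > qc$sd_max) "sd",
               if (snr < qc$snr_min) "snr",
               if (n_valid_lines < qc$min_valid_lines) "low_n")
  list(excluded = length(reasons) > 0L,
       reason = if (length(reasons)) paste(reasons, collapse = ",")
                else NA_character_)
}

#' Hierarchical mean-of-means aggregation
#'
#' Unweighted mean of loop means per glomerulus, of glomerulus means per
#' subject, and of subject means per group, omitting excluded loops (and any
#' glomerulus or subject left with no contributing members, with a warning).
#'
#' @param loop_table Data frame with columns \code{loop_id},
#'   \code{glomerulus_id}, \code{subject_id}, \code{group}, a value column,
#'   and optionally \code{excluded} (dropped rows).
#' @param value Name of the value column (default \code{"mean_p2p_um"}).
#' @return List of data frames \code{glomerulus}, \code{subject},
#'   \code{group}, each with \code{mean_value} and \code{n} (members
#'   averaged).
#' @export
aggregate_hierarchy <- function(loop_table, value = "mean_p2p_um") {
  need <- c("loop_id", "glomerulus_id", "subject_id", "group", value)
  if (!all(need %in% names(loop_table))) {
    stopf("loop table must have columns: %s", paste(need, collapse = ", "))
  }
  keep <- if ("excluded" %in% names(loop_table)) !loop_table$excluded
          else rep(TRUE, nrow(loop_table))
  dropped_gl <- unique(loop_table$glomerulus_id[!keep])
  tab <- loop_table[keep & !is.na(loop_table[[value]]), , drop = FALSE]
  all_gl <- unique(loop_table[, c("glomerulus_id", "subject_id", "group")])
  if (!nrow(tab)) {
    warning("no included loops; empty aggregation")
    empty <- data.frame(mean_value = numeric(0), n = integer(0))
    return(list(glomerulus = empty, subject = empty, group = empty))
  }
  mean_by <- function(df, keys, val) {
    ag <- stats::aggregate(df[[val]], df[keys], mean)
    names(ag)[ncol(ag)] <- "mean_value"
    cnt <- stats::aggregate(df[[val]], df[keys], length)
    ag$n <- cnt$x
    ag
  }
  gl <- mean_by(tab, c("group", "subject_id", "glomerulus_id"), value)
  lost_gl <- setdiff(all_gl$glomerulus_id, gl$glomerulus_id)
  if (length(lost_gl)) {
    warning(sprintf("glomeruli with all loops excluded, omitted: %s",
                    paste(lost_gl, collapse = ", ")))
  }
  su <- mean_by(gl, c("group", "subject_id"), "mean_value")
  all_su <- unique(loop_table$subject_id)
  lost_su <- setdiff(all_su, su$subject_id)
  if (length(lost_su)) {
    warning(sprintf("subjects with no contributing glomeruli, omitted: %s",
                    paste(lost_su, collapse = ", ")))
  }
  gr <- mean_by(su, "group", "mean_value")
  list(glomerulus = gl, subject = su, group = gr)
}
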