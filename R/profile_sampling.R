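# Capillary-loop contour extraction and perpendicular profile sampling.
#
# Coordinates are continuous micrometres with pixel centres at
# (i - 0.5) * pixel_size (1-based row/column i); matrices index [y, x].

#' Two co-registered channel images
#'
#' @param glx_channel,membrane_channel Numeric matrices of equal dimension
#'   (glycocalyx-lectin channel and membrane channel).
#' @param pixel_size Physical pixel size (um/px).
#' @return A \code{channel_image_pair}.
#' @export
channel_image_pair <- function(glx_channel, membrane_channel, pixel_size) {
  stopifnot(is.matrix(glx_channel), is.matrix(membrane_channel))
  if (!identical(dim(glx_channel), dim(membrane_channel))) {
    stopf("channel images must share dimensions")
  }
  check_number(pixel_size, "pixel_size", 0, strict_min = TRUE)
  if (min(glx_channel) < 0 || min(membrane_channel) < 0) {
    stopf("intensities must be >= 0")
  }
  structure(list(glx_channel = glx_channel,
                 membrane_channel = membrane_channel,
                 pixel_size = pixel_size), class = "channel_image_pair")
}

#' Read a two-page loop TIFF into a channel image pair
#'
#' Page 1 is taken as the glycocalyx channel, page 2 as the membrane channel.
#'
#' @param path TIFF path.
#' @param pixel_size Override for the pixel size; default uses the TIFF
#'   resolution tags and fails if they are absent.
#' @return A \code{\link{channel_image_pair}}.
#' @export
read_image_pair <- function(path, pixel_size = NULL) {
  tf <- read_tiff16(path)
  if (length(tf$pages) < 2L) stopf("'%s' has %d page(s); two channels expected",
                                   path, length(tf$pages))
  if (is.null(pixel_size)) {
    pixel_size <- tf$pixel_size_um
    if (is.na(pixel_size)) {
      stopf("'%s' carries no pixel-size metadata (resolution tags); supply pixel_size explicitly",
            path)
    }
  }
  channel_image_pair(tf$pages[[1]], tf$pages[[2]], pixel_size)
}

# Bilinear interpolation at continuous (x, y) um positions. Positions must
# stay within the grid of pixel centres.
bilinear_sample <- function(m, x_um, y_um, pixel_size) {
  cx <- x_um / pixel_size + 0.5
  cy <- y_um / pixel_size + 0.5
  if (any(cx < 1 | cx > ncol(m) | cy < 1 | cy > nrow(m))) {
    return(NULL)
  }
  x0 <- pmin(floor(cx), ncol(m) - 1L); y0 <- pmin(floor(cy), nrow(m) - 1L)
  fx <- cx - x0; fy <- cy - y0
  i00 <- cbind(y0, x0); i10 <- cbind(y0, x0 + 1)
  i01 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * fx * (1 - fy) +
    m[i01] * (1 - fx) * fy + m[i11] * fx * fy
}

# Separable Gaussian blur via banded dense multiplication; edges renormalized.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  smooth_dim <- function(n) {
    K <- matrix(0, n, n)
    for (j in -half:half) {
      idx <- seq_len(n)
      tgt <- idx + j
      keep <- tgt >= 1 & tgt <= n
      K[cbind(idx[keep], tgt[keep])] <- K[cbind(idx[keep], tgt[keep])] +
        k[j + half + 1]
    }
    K / rowSums(K)
  }
  smooth_dim(nrow(m)) %*% m %*% t(smooth_dim(ncol(m)))
}

# Otsu threshold over a 256-bin histogram; ties broken by the first (lowest)
# maximizing bin, a fixed deterministic scan order.
otsu_threshold <- function(m) {
  rng <- range(m)
  if (diff(rng) <= 0) return(NA_real_)
  h <- tabulate(pmin(floor((m - rng[1]) / diff(rng) * 256) + 1L, 256L), 256L)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(256) - 0.5) / 256 * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[256]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Extract the membrane-ridge contour of a capillary loop
#'
#' Smooths the membrane channel, thresholds it (Otsu by default), then casts
#' rays from the lumen seed point: along each ray the ridge position is the
#' sub-pixel maximum of the smoothed intensity within the first thresholded
#' crossing. The radii are low-pass filtered as a periodic Fourier series,
#' giving a smooth closed contour.
#'
#' @param images A \code{\link{channel_image_pair}}.
#' @param seed_point Lumen-side point \code{c(x_um, y_um)} inside the loop.
#' @param n_angles Number of rays (and returned contour points).
#' @param smooth_sigma_um Gaussian smoothing SD applied before ridge search.
#' @param threshold Intensity threshold; default Otsu on the smoothed image.
#' @param harmonics Number of Fourier harmonics kept when smoothing the
#'   radius profile.
#' @return A \code{loop_contour}: list with \code{points} (n x 2 matrix, um),
#'   \code{closed = TRUE}, \code{interior_point}, \code{mean_radius} and
#'   \code{perimeter}.
#' @export
extract_contour <- function(images, seed_point, n_angles = 360L,
                            smooth_sigma_um = 0.1, threshold = NULL,
                            harmonics = 8L) {
  stopifnot(inherits(images, "channel_image_pair"))
  px <- images$pixel_size
  m <- images$membrane_channel
  w_um <- ncol(m) * px; h_um <- nrow(m) * px
  if (seed_point[1] <= 0 || seed_point[1] >= w_um ||
      seed_point[2] <= 0 || seed_point[2] >= h_um) {
    stopf("seed point (%g, %g) um lies outside the image (%g x %g um)",
          seed_point[1], seed_point[2], w_um, h_um)
  }
  sm <- gaussian_blur(m, smooth_sigma_um / px)
  if (max(sm) - min(sm) <= 1e-6 * max(abs(sm), 1)) {
    stopf("no closed ridge found around the seed point (membrane channel flat or empty)")
  }
  if (is.null(threshold)) threshold <- otsu_threshold(sm)
  if (is.na(threshold) || max(sm) <= threshold) {
    stopf("no closed ridge found around the seed point (membrane channel flat or empty)")
  }
  step <- px / 4
  max_r <- sqrt(w_um^2 + h_um^2)
  rs <- seq(step, max_r, by = step)
  angles <- (seq_len(n_angles) - 1L) * 2 * pi / n_angles
  radii <- numeric(n_angles)
  for (a in seq_len(n_angles)) {
    dx <- cos(angles[a]); dy <- sin(angles[a])
    xs <- seed_point[1] + rs * dx; ys <- seed_point[2] + rs * dy
    inside <- xs >= px / 2 & xs <= w_um - px / 2 &
      ys >= px / 2 & ys <= h_um - px / 2
    vals <- bilinear_sample(sm, xs[inside], ys[inside], px)
    above <- which(vals > threshold)
    if (!length(above)) {
      stopf("no closed ridge found around the seed point (ray at %.1f deg never crosses the ridge)",
            angles[a] * 180 / pi)
    }
    first <- above[1]
    run_end <- first
    while (run_end < length(vals) && vals[run_end + 1] > threshold) {
      run_end <- run_end + 1
    }
    if (run_end == length(vals)) {
      stopf("ridge touches the image border along the ray at %.1f deg",
            angles[a] * 180 / pi)
    }
    peak <- first + which.max(vals[first:run_end]) - 1L
    r_hat <- rs[inside][peak]
    if (peak > 1 && peak < length(vals)) {   # sub-pixel quadratic refinement
      y1 <- vals[peak - 1]; y2 <- vals[peak]; y3 <- vals[peak + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) r_hat <- r_hat + step * 0.5 * (y1 - y3) / den
    }
    radii[a] <- r_hat
  }
  radii <- fourier_smooth_periodic(radii, harmonics)
  pts <- cbind(seed_point[1] + radii * cos(angles),
               seed_point[2] + radii * sin(angles))
  peri <- sum(sqrt(rowSums((pts - pts[c(2:n_angles, 1), ])^2)))
  structure(list(points = pts, closed = TRUE, interior_point = seed_point,
                 mean_radius = mean(radii), perimeter = peri),
            class = "loop_contour")
}

# Low-pass a periodic signal by truncating its Fourier series.
fourier_smooth_periodic <- function(x, harmonics) {
  n <- length(x)
  f <- stats::fft(x)
  keep <- c(1L, seq(2L, harmonics + 1L), seq(n - harmonics + 1L, n))
  f[setdiff(seq_len(n), keep)] <- 0
  Re(stats::fft(f, inverse = TRUE)) / n
}

new_profile_line <- function(start, end, step, line_id = NA_character_) {
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) stopf("profile line '%s' has zero length", line_id)
  check_number(step, "step", 0, strict_min = TRUE)
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 length = len, step = step, line_id = line_id),
            class = "profile_line")
}

#' Place perpendicular profile lines automatically along a contour
#'
#' Anchors \code{n_lines} points at equal arc-length spacing along the closed
#' contour; each line is perpendicular to the local tangent, centred on the
#' anchor, and oriented lumen (inside) to abluminal (outside).
#'
#' @param contour A \code{\link{extract_contour}} result.
#' @param n_lines Number of lines (default 200, the automated protocol).
#' @param length Line length in um (default 2, centred on the contour).
#' @param step Sampling step along the line in um (default 0.05).
#' @return List of \code{profile_line} objects.
#' @export
place_lines_auto <- function(contour, n_lines = 200L, length = 2, step = 0.05) {
  stopifnot(inherits(contour, "loop_contour"))
  if (n_lines < 1L) stopf("n_lines must be >= 1")
  if (floor(length / step) + 1 < 8) {
    stopf("length/step yields %d samples; at least 8 required",
          floor(length / step) + 1)
  }
  pts <- contour$points
  n <- nrow(pts)
  seg <- pts[c(2:n, 1), ] - pts
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[n + 1]
  targets <- (seq_len(n_lines) - 1L) * total / n_lines
  lines <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    j <- findInterval(targets[i], cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), n)
    t_frac <- (targets[i] - cum[j]) / seg_len[j]
    anchor <- pts[j, ] + t_frac * seg[j, ]
    tangent <- seg[j, ] / seg_len[j]
    normal <- c(-tangent[2], tangent[1])
    if (sum((anchor - contour$interior_point) * normal) < 0) normal <- -normal
    lines[[i]] <- new_profile_line(anchor - normal * length / 2,
                                   anchor + normal * length / 2,
                                   step, sprintf("auto_%03d", i))
    lines[[i]]$tangent <- tangent
    lines[[i]]$anchor <- anchor
  }
  lines
}

#' Convert manually drawn ROI segments to profile lines
#'
#' Segments are used exactly as drawn (the stated orientation, lumen to
#' abluminal, is preserved; no reorientation is applied).
#'
#' @param roi_lines Data frame with columns \code{x0_um}, \code{y0_um},
#'   \code{x1_um}, \code{y1_um} and optionally \code{loop_id}, or a list of
#'   \code{list(start=, end=)} pairs.
#' @param step Sampling step (um).
#' @return List of \code{profile_line} objects.
#' @export
place_lines_manual <- function(roi_lines, step = 0.05) {
  if (is.data.frame(roi_lines)) {
    roi_lines <- lapply(seq_len(nrow(roi_lines)), function(i) {
      list(start = c(roi_lines$x0_um[i], roi_lines$y0_um[i]),
           end = c(roi_lines$x1_um[i], roi_lines$y1_um[i]),
           loop_id = if ("loop_id" %in% names(roi_lines)) roi_lines$loop_id[i]
                     else NA_character_)
    })
  }
  if (!length(roi_lines)) {
    warning("no ROI segments supplied; returning an empty line list")
    return(list())
  }
  lapply(seq_along(roi_lines), function(i) {
    seg <- roi_lines[[i]]
    ln <- new_profile_line(seg$start, seg$end, step,
                           sprintf("manual_%03d", i))
    ln$loop_id <- seg$loop_id
    ln
  })
}

#' Sample both channels along a profile line
#'
#' @param images A \code{\link{channel_image_pair}}.
#' @param line A \code{profile_line}.
#' @return An \code{intensity_profile}: list with \code{distances} (um from
#'   the line start), \code{glx_values}, \code{membrane_values},
#'   \code{line_id}.
#' @export
sample_profile <- function(images, line) {
  stopifnot(inherits(images, "channel_image_pair"),
            inherits(line, "profile_line"))
  d <- seq(0, line$length, by = line$step)
  u <- (line$end - line$start) / line$length
  xs <- line$start[1] + d * u[1]
  ys <- line$start[2] + d * u[2]
  g <- bilinear_sample(images$glx_channel, xs, ys, images$pixel_size)
  m <- bilinear_sample(images$membrane_channel, xs, ys, images$pixel_size)
  if (is.null(g) || is.null(m)) {
    stopf("profile line '%s' exits the image bounds", line$line_id)
  }
  structure(list(distances = d, glx_values = g, membrane_values = m,
                 line_id = line$line_id), class = "intensity_profile")
}

#' Read manual ROI segments from CSV
#'
#' Expected columns: \code{loop_id}, \code{x0_um}, \code{y0_um},
#' \code{x1_um}, \code{y1_um}.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_roi_lines <- function(path) {
  df <- read_csv_prov(path)
  need <- c("loop_id", "x0_um", "y0_um", "x1_um", "y1_um")
  if (!all(need %in% names(df))) {
    stopf("ROI file '%s' must have columns: %s", path,
          paste(need, collapse = ", "))
  }
  df
}

#' Read lumen seed points from CSV
#'
#' Expected columns: \code{loop_id}, \code{x_um}, \code{y_um}.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_seed_points <- function(path) {
  df <- read_csv_prov(path)
  need <- c("loop_id", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stopf("seed-point file '%s' must have columns: %s", path,
          paste(need, collapse = ", "))
  }
  df
}

#' Write a debug overlay of contour and lines as PNG
#'
#' Requires the optional \pkg{png} package; the pipeline never depends on it.
#'
#' @param images A \code{\link{channel_image_pair}}.
#' @param contour A \code{loop_contour}.
#' @param lines List of \code{profile_line}.
#' @param path Output PNG path.
#' @return \code{path}, invisibly; \code{NULL} with a warning if \pkg{png}
#'   is unavailable.
#' @export
write_overlay_png <- function(images, contour, lines, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    warning("package 'png' not available; overlay not written")
    return(invisible(NULL))
  }
  m <- images$membrane_channel
  g <- images$glx_channel
  sc <- function(x) (x - min(x)) / max(diff(range(x)), 1e-12)
  img <- array(0, c(dim(m), 3))
  img[, , 1] <- sc(m); img[, , 2] <- sc(g)
  px <- images$pixel_size
  paint <- function(x_um, y_um, ch) {
    cx <- pmin(pmax(round(x_um / px + 0.5), 1), ncol(m))
    cy <- pmin(pmax(round(y_um / px + 0.5), 1), nrow(m))
    for (c3 in seq_len(3)) {
      img[cbind(cy, cx, c3)] <<- if (c3 == ch) 1 else 0
    }
  }
  paint(contour$points[, 1], contour$points[, 2], 3)
  for (ln in lines) {
    d <- seq(0, ln$length, by = ln$step)
    u <- (ln$end - ln$start) / ln$length
    paint(ln$start[1] + d * u[1], ln$start[2] + d * u[2], 1)
  }
  atomic_write(path, function(tmp) png::writePNG(img, tmp))
}
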