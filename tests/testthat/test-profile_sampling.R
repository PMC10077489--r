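# Contour extraction, line placement and sub-pixel profile sampling.

truth <- small_loop()
fixture <- make_loop_image(truth)
images <- fixture$images
contour <- extract_contour(images, truth$center)

test_that("contour recovers the membrane ridge geometry", {
  expect_lt(abs(contour$mean_radius - truth$radius_membrane),
            truth$pixel_size)
  expect_lt(abs(contour$perimeter - 2 * pi * truth$radius_membrane),
            0.02 * 2 * pi * truth$radius_membrane)
  expect_true(contour$closed)
  expect_gte(nrow(contour$points), 8L)
  expect_equal(contour$interior_point, truth$center)
})

test_that("contour extraction fails descriptively on degenerate input", {
  blank <- channel_image_pair(images$glx_channel,
                              matrix(7, nrow(images$glx_channel),
                                     ncol(images$glx_channel)),
                              images$pixel_size)
  expect_error(extract_contour(blank, truth$center), "no closed ridge")
  expect_error(extract_contour(images, c(-1, 3)), "outside the image")
  # loop pushed against the border: ridge runs off the frame
  shifted <- loop_truth(radius_membrane = 2.5, glx_offset = 0.3,
                        psf_sigma = 0.1, pixel_size = 0.05,
                        noise_model = "none", fov_um = 8,
                        center = c(1.4, 4))
  expect_error(make_loop_image(shifted), "field of view")
})

test_that("contour extraction is equivariant under 90-degree rotation", {
  rot90 <- function(x) t(x)[, rev(seq_len(nrow(x))), drop = FALSE]
  rot_images <- channel_image_pair(rot90(images$glx_channel),
                                   rot90(images$membrane_channel),
                                   images$pixel_size)
  rot_contour <- extract_contour(rot_images, truth$center)
  expect_equal(rot_contour$mean_radius, contour$mean_radius,
               tolerance = 1e-3)
  r1 <- sort(sqrt(rowSums(sweep(contour$points, 2, truth$center)^2)))
  r2 <- sort(sqrt(rowSums(sweep(rot_contour$points, 2, truth$center)^2)))
  expect_equal(r1, r2, tolerance = 1e-3)
})

test_that("automatic placement yields n perpendicular, well-spread lines", {
  lines <- place_lines_auto(contour, n_lines = 50, length = 2, step = 0.05)
  expect_length(lines, 50L)
  for (ln in lines) {
    dir <- (ln$end - ln$start) / ln$length
    expect_lt(abs(sum(dir * ln$tangent)), 1e-6)
    expect_equal(ln$length, 2)
  }
  # circular contour: midpoint distance to centre constant within 1%
  mids <- t(vapply(lines, function(ln) (ln$start + ln$end) / 2, numeric(2)))
  md <- sqrt(rowSums(sweep(mids, 2, truth$center)^2))
  expect_lt(diff(range(md)) / mean(md), 0.01)
  # uniform coverage: max anchor gap <= 1.5 * perimeter / n
  anchors <- t(vapply(lines, function(ln) ln$anchor, numeric(2)))
  gaps <- sqrt(rowSums((anchors[c(2:50, 1), ] - anchors)^2))
  expect_lte(max(gaps), 1.5 * contour$perimeter / 50)
  # orientation: line start is on the lumen side of its end
  d_start <- sqrt(rowSums(sweep(t(vapply(lines, `[[`, numeric(2), "start")),
                                2, truth$center)^2))
  d_end <- sqrt(rowSums(sweep(t(vapply(lines, `[[`, numeric(2), "end")),
                              2, truth$center)^2))
  expect_true(all(d_start < d_end))
})

test_that("automatic placement rejects invalid geometry", {
  expect_error(place_lines_auto(contour, n_lines = 0), "n_lines")
  expect_error(place_lines_auto(contour, length = 0.2, step = 0.05),
               "at least 8")
})

test_that("manual segments convert faithfully", {
  rois <- data.frame(loop_id = "L1",
                     x0_um = c(1, 2, 3), y0_um = c(1, 1, 1),
                     x1_um = c(1, 2, 3), y1_um = c(3, 3, 3))
  lines <- place_lines_manual(rois, step = 0.05)
  expect_length(lines, 3L)
  expect_equal(lines[[1]]$start, c(1, 1))
  expect_equal(lines[[1]]$end, c(1, 3))
  expect_length(seq(0, lines[[1]]$length, by = lines[[1]]$step), 41L)
  expect_warning(empty <- place_lines_manual(list()), "no ROI segments")
  expect_length(empty, 0L)
  bad <- data.frame(loop_id = "L1", x0_um = 1, y0_um = 1, x1_um = 1,
                    y1_um = 1)
  expect_error(place_lines_manual(bad), "zero length")
})

test_that("profile sampling is sub-pixel, oriented and bounded", {
  # constant image samples constant
  const <- channel_image_pair(matrix(3, 50, 50), matrix(11, 50, 50), 0.1)
  ln <- glxquant:::new_profile_line(c(1, 1), c(3, 3), 0.05, "t")
  prof <- sample_profile(const, ln)
  expect_equal(prof$glx_values, rep(3, length(prof$distances)),
               tolerance = 1e-12)
  expect_equal(prof$membrane_values, rep(11, length(prof$distances)),
               tolerance = 1e-12)
  expect_equal(unique(round(diff(prof$distances), 12)), 0.05)

  # reverse line gives the mirrored profile
  rev_ln <- glxquant:::new_profile_line(c(3, 3), c(1, 1), 0.05, "t_rev")
  lines <- place_lines_auto(contour, n_lines = 8)
  p_fwd <- sample_profile(images, lines[[1]])
  p_rev <- sample_profile(
    images, glxquant:::new_profile_line(lines[[1]]$end, lines[[1]]$start,
                                        0.05, "rev"))
  expect_equal(p_fwd$membrane_values, rev(p_rev$membrane_values),
               tolerance = 1e-12)

  # membrane maximum near line midpoint for contour-centred lines
  expect_lt(abs(p_fwd$distances[which.max(p_fwd$membrane_values)] - 1), 0.1)

  # out-of-bounds line names itself
  far <- glxquant:::new_profile_line(c(-0.4, 1), c(2, 1), 0.05, "runaway")
  expect_error(sample_profile(images, far), "runaway")
})

test_that("glycocalyx peak precedes membrane peak on every line", {
  lines <- place_lines_auto(contour, n_lines = 40)
  for (ln in lines) {
    prof <- sample_profile(images, ln)
    expect_lt(prof$distances[which.max(prof$glx_values)],
              prof$distances[which.max(prof$membrane_values)])
  }
})
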