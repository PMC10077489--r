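# Multi-subject synthetic cohorts: a group structure (e.g. control /
# diabetic / treated) over subjects, glomeruli and capillary loops, one
# two-page TIFF per loop plus a manifest CSV carrying the ground truth.

#' Specify a synthetic imaging cohort
#'
#' @param groups Data frame with columns \code{label}, \code{mean_offset_um}
#'   (group mean of the true glycocalyx offset), \code{sd_um}
#'   (between-subject SD) and \code{n_subjects}.
#' @param glomeruli_per_subject,loops_per_glomerulus Counts (>= 1).
#' @param loop_params A \code{\link{loop_truth}} supplying the per-loop image
#'   parameters other than \code{glx_offset} and \code{seed}.
#' @param seed Integer master seed; per-loop seeds are derived from it.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(groups, glomeruli_per_subject = 3L,
                        loops_per_glomerulus = 3L,
                        loop_params = loop_truth(), seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("label", "mean_offset_um", "sd_um", "n_subjects") %in%
                names(groups)))
  if (any(groups$n_subjects < 1L)) stopf("all group n_subjects must be >= 1")
  if (any(groups$sd_um < 0)) stopf("between-subject SDs must be >= 0")
  if (glomeruli_per_subject < 1L || loops_per_glomerulus < 1L) {
    stopf("all counts must be >= 1")
  }
  structure(list(groups = groups,
                 glomeruli_per_subject = as.integer(glomeruli_per_subject),
                 loops_per_glomerulus = as.integer(loops_per_glomerulus),
                 loop_params = loop_params, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of synthetic loop images on disk
#'
#' Draws one true glycocalyx offset per subject (normal around the group
#' mean, truncated to stay inside \code{(0, radius_membrane)}), renders every
#' loop image as a two-page 16-bit TIFF (page 1 glycocalyx channel, page 2
#' membrane channel), and writes \code{manifest.csv} and \code{seeds.csv}
#' (lumen seed points for the automated pipeline).
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly; columns \code{subject_id},
#'   \code{group}, \code{glomerulus_id}, \code{loop_id}, \code{path},
#'   \code{true_offset_um}, \code{pixel_size_um}, \code{seed}.
#' @export
make_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stopf("cannot create output directory '%s'", dir)
  probe <- file.path(dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stopf("output directory '%s' is not writable", dir)
  unlink(probe)

  lp <- spec$loop_params
  rows <- list(); seed_rows <- list(); idx <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    grp <- spec$groups[g, ]
    for (s in seq_len(grp$n_subjects)) {
      subject_id <- sprintf("%s_S%02d", grp$label, s)
      offset <- with_seed(derive_seed(spec$seed, g * 10000L + s), {
        min(max(stats::rnorm(1, grp$mean_offset_um, grp$sd_um), 1e-3),
            lp$radius_membrane - 1e-3)
      })
      for (gl in seq_len(spec$glomeruli_per_subject)) {
        for (lo in seq_len(spec$loops_per_glomerulus)) {
          idx <- idx + 1L
          loop_seed <- derive_seed(spec$seed, idx)
          truth <- lp
          truth$glx_offset <- offset
          truth$seed <- loop_seed
          class(truth) <- "loop_truth"
          res <- make_loop_image(truth)
          path <- file.path(dir, sprintf("%s_G%02d_L%02d.tif", subject_id, gl, lo))
          write_tiff16(path,
                       list(res$images$glx_channel, res$images$membrane_channel),
                       truth$pixel_size)
          rows[[idx]] <- data.frame(
            subject_id = subject_id, group = grp$label,
            glomerulus_id = sprintf("%s_G%02d", subject_id, gl),
            loop_id = sprintf("%s_G%02d_L%02d", subject_id, gl, lo),
            path = path, true_offset_um = offset,
            pixel_size_um = truth$pixel_size, seed = loop_seed,
            stringsAsFactors = FALSE)
          seed_rows[[idx]] <- data.frame(
            loop_id = rows[[idx]]$loop_id,
            x_um = truth$center[1], y_um = truth$center[2],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_csv_prov(manifest, file.path(dir, "manifest.csv"),
                 c(generator = "glxquant::make_cohort", seed = spec$seed))
  write_csv_prov(do.call(rbind, seed_rows), file.path(dir, "seeds.csv"),
                 c(generator = "glxquant::make_cohort", seed = spec$seed))
  invisible(manifest)
}
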