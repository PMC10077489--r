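# Pipeline entry points: configured end-to-end runs over files, plus the two
# cohort-level normalization formulas (log2 fold change, corrected total
# intensity). All outputs are CSV with a leading provenance comment line
# carrying the package version and the md5 of the materialized config, and
# are written atomically (temp file + rename), so a fatal error never leaves
# a partial summary.

#' Default pipeline configuration
#'
#' All tunables with their defaults; user-supplied configs are merged over
#' this so every echoed config is complete and self-describing.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    mode = "auto",
    images = list(manifest = NULL, seeds = NULL, rois = NULL,
                  pixel_size_um = NULL),
    lines = list(n_lines = 200L, length_um = 2, step_um = 0.05),
    contour = list(n_angles = 360L, smooth_sigma_um = 0.1, harmonics = 8L),
    qc = list(sd_max = 7.5, sd_unit = "report", snr_min = 15,
              min_valid_lines = NULL, snr_channel = "membrane"),
    tem = list(annotation = NULL, uncovered_max_nm = 10),
    permeability = list(traces = NULL, metadata = NULL, window_s = 60,
                        bias_correct = TRUE),
    out_dir = ".",
    report_units = "um",
    seed = 1L
  )
}

# Merge user config (list or YAML path) over the defaults, recursively.
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: '%s'", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  utils::modifyList(default_config(), config)
}

# Echo the materialized config next to the outputs and hash it; returns the
# provenance vector embedded in every output CSV.
echo_config <- function(config, out_dir, name) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, "_config.yaml"))
  atomic_write(path, function(tmp) yaml::write_yaml(config, tmp))
  c(package = "glxquant",
    version = as.character(utils::packageVersion("glxquant")),
    config_md5 = unname(tools::md5sum(path)),
    units = config$report_units)
}

#' Run the peak-to-peak pipeline over a cohort on disk
#'
#' Full chain per loop: read two-channel TIFF, extract the membrane contour
#' (auto mode) or take manual ROI segments, place profile lines, sample,
#' Gaussian-fit both channels, compute signed peak-to-peak, apply SD/SNR QC,
#' then aggregate loop -> glomerulus -> subject -> group. All referenced
#' files are validated before any image is processed, so a missing input
#' never produces partial summaries.
#'
#' @param config Config list or YAML path; see \code{\link{default_config}}.
#'   Required: \code{images$manifest}; \code{images$seeds} (auto mode) or
#'   \code{images$rois} (manual mode).
#' @return List of data frames (\code{lines}, \code{loops},
#'   \code{glomerulus}, \code{subject}, \code{group}), invisibly; CSVs
#'   written under \code{config$out_dir}.
#' @export
run_p2p <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$images$manifest)) stopf("config: images$manifest is required")
  manifest <- read_csv_prov(cfg$images$manifest)
  need <- c("subject_id", "group", "glomerulus_id", "loop_id", "path")
  if (!all(need %in% names(manifest))) {
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  }
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing)) {
    stopf("manifest references missing image file(s): %s",
          paste(missing, collapse = ", "))
  }
  if (is.null(cfg$qc$min_valid_lines)) {
    cfg$qc$min_valid_lines <- if (cfg$mode == "auto") 50L else 3L
  }
  qc <- qc_config(sd_max = cfg$qc$sd_max, sd_unit = cfg$qc$sd_unit,
                  snr_min = cfg$qc$snr_min,
                  min_valid_lines = cfg$qc$min_valid_lines,
                  snr_channel = cfg$qc$snr_channel,
                  pixel_size = cfg$images$pixel_size_um)
  seeds <- rois <- NULL
  if (cfg$mode == "auto") {
    if (is.null(cfg$images$seeds)) stopf("auto mode requires images$seeds")
    seeds <- read_seed_points(cfg$images$seeds)
  } else if (cfg$mode == "manual") {
    if (is.null(cfg$images$rois)) stopf("manual mode requires images$rois")
    rois <- read_roi_lines(cfg$images$rois)
  } else stopf("mode must be 'auto' or 'manual'")

  prov <- echo_config(cfg, cfg$out_dir, "p2p")
  all_lines <- list(); loop_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    images <- read_image_pair(row$path, cfg$images$pixel_size_um)
    lines <- if (cfg$mode == "auto") {
      sp <- seeds[seeds$loop_id == row$loop_id, , drop = FALSE]
      if (!nrow(sp)) stopf("no seed point for loop '%s'", row$loop_id)
      contour <- extract_contour(images, c(sp$x_um[1], sp$y_um[1]),
                                 n_angles = cfg$contour$n_angles,
                                 smooth_sigma_um = cfg$contour$smooth_sigma_um,
                                 harmonics = cfg$contour$harmonics)
      place_lines_auto(contour, n_lines = cfg$lines$n_lines,
                       length = cfg$lines$length_um, step = cfg$lines$step_um)
    } else {
      seg <- rois[rois$loop_id == row$loop_id, , drop = FALSE]
      if (!nrow(seg)) stopf("no ROI segments for loop '%s'", row$loop_id)
      place_lines_manual(seg, step = cfg$lines$step_um)
    }
    meas <- measure_loop(images, lines, loop_id = row$loop_id)
    all_lines[[i]] <- meas
    summ <- summarize_loop(meas, qc)
    summ$glomerulus_id <- row$glomerulus_id
    summ$subject_id <- row$subject_id
    summ$group <- row$group
    loop_rows[[i]] <- summ
    message(sprintf("[p2p] loop %s: %d/%d lines valid%s", row$loop_id,
                    summ$n_valid_lines, nrow(meas),
                    if (summ$excluded) paste0(" EXCLUDED (", summ$reason, ")")
                    else ""))
  }
  lines_df <- do.call(rbind, all_lines)
  loops_df <- do.call(rbind, loop_rows)
  agg <- aggregate_hierarchy(loops_df, "mean_p2p_um")
  out <- file.path(cfg$out_dir, c("p2p_lines.csv", "p2p_loops.csv",
                                  "p2p_glomeruli.csv", "p2p_subjects.csv",
                                  "p2p_groups.csv"))
  write_csv_prov(lines_df, out[1], prov)
  write_csv_prov(loops_df, out[2], prov)
  write_csv_prov(agg$glomerulus, out[3], prov)
  write_csv_prov(agg$subject, out[4], prov)
  write_csv_prov(agg$group, out[5], prov)
  invisible(list(lines = lines_df, loops = loops_df,
                 glomerulus = agg$glomerulus, subject = agg$subject,
                 group = agg$group))
}

#' Run the TEM morphometry pipeline
#'
#' @param config Config list or YAML path; required: \code{tem$annotation}.
#'   Capillaries act as the loop level of the hierarchy; a \code{group}
#'   column in the annotation is honoured, otherwise all subjects form one
#'   group \code{"all"}.
#' @return List of data frames (\code{capillary}, \code{glomerulus},
#'   \code{subject}), invisibly; CSVs under \code{config$out_dir}.
#' @export
run_tem <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$tem$annotation)) stopf("config: tem$annotation is required")
  ann <- read_tem_annotation(cfg$tem$annotation)
  prov <- echo_config(cfg, cfg$out_dir, "tem")
  cap <- tem_summarize(ann, uncovered_max = cfg$tem$uncovered_max_nm)
  cap$group <- if ("group" %in% names(ann)) {
    ann$group[match(cap$subject_id, ann$subject_id)]
  } else "all"
  agg_value <- function(col) {
    tab <- cap[!is.na(cap[[col]]), , drop = FALSE]
    if (!nrow(tab)) return(NULL)
    tab$loop_id <- tab$capillary_id
    tab$excluded <- FALSE
    aggregate_hierarchy(tab, col)
  }
  metrics <- c("mean_thickness_nm", "coverage_pct", "gbm_width_nm",
               "foot_process_width_nm", "slit_width_nm",
               "fenestration_density_per_um", "foot_process_density_per_um")
  per_level <- function(level) {
    pieces <- lapply(metrics, function(m) {
      a <- agg_value(m)
      if (is.null(a)) return(NULL)
      df <- a[[level]]
      names(df)[names(df) == "mean_value"] <- m
      df$n <- NULL
      df
    })
    pieces <- Filter(Negate(is.null), pieces)
    if (!length(pieces)) return(data.frame())
    Reduce(function(x, y) merge(x, y, all = TRUE), pieces)
  }
  gl <- per_level("glomerulus")
  su <- per_level("subject")
  write_csv_prov(cap, file.path(cfg$out_dir, "tem_capillaries.csv"), prov)
  write_csv_prov(gl, file.path(cfg$out_dir, "tem_glomeruli.csv"), prov)
  write_csv_prov(su, file.path(cfg$out_dir, "tem_subjects.csv"), prov)
  invisible(list(capillary = cap, glomerulus = gl, subject = su))
}

#' Run the permeability pipeline
#'
#' Fits every glomerulus trace; a trace that fails (e.g. shorter than the
#' window) is recorded with its error message and the run continues.
#'
#' @param config Config list or YAML path; required: \code{permeability$traces}
#'   and \code{permeability$metadata}.
#' @return List of data frames (\code{glomerulus}, \code{subject}),
#'   invisibly; CSVs under \code{config$out_dir}.
#' @export
run_perm <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$permeability$traces) || is.null(cfg$permeability$metadata)) {
    stopf("config: permeability$traces and permeability$metadata are required")
  }
  traces <- read_decay_traces(cfg$permeability$traces,
                              cfg$permeability$metadata)
  prov <- echo_config(cfg, cfg$out_dir, "perm")
  rows <- lapply(traces, function(tr) {
    res <- tryCatch({
      fit <- fit_initial_decline(tr, window_s = cfg$permeability$window_s,
                                 bias_correct = cfg$permeability$bias_correct)
      ps <- ps_alb_from_decline(fit, tr$radius)
      data.frame(glomerulus_id = tr$glomerulus_id,
                 subject_id = tr$subject_id, radius_um = tr$radius,
                 k_s = fit$k, k_raw_s = fit$k_raw,
                 ps_alb_um_s = ps$ps_alb_um_s, ps_alb_cm_s = ps$ps_alb_cm_s,
                 r_squared = fit$r_squared, n_samples = fit$n,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      message(sprintf("[perm] glomerulus %s failed: %s", tr$glomerulus_id,
                      conditionMessage(e)))
      data.frame(glomerulus_id = tr$glomerulus_id,
                 subject_id = tr$subject_id, radius_um = tr$radius,
                 k_s = NA_real_, k_raw_s = NA_real_, ps_alb_um_s = NA_real_,
                 ps_alb_cm_s = NA_real_, r_squared = NA_real_,
                 n_samples = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  gl <- do.call(rbind, rows)
  ok <- gl[is.na(gl$error), , drop = FALSE]
  su <- if (nrow(ok)) {
    ag <- stats::aggregate(ok[c("ps_alb_um_s", "k_s")], ok["subject_id"], mean)
    cnt <- stats::aggregate(ok$ps_alb_um_s, ok["subject_id"], length)
    ag$n_glomeruli <- cnt$x
    ag
  } else data.frame()
  write_csv_prov(gl, file.path(cfg$out_dir, "perm_glomeruli.csv"), prov)
  write_csv_prov(su, file.path(cfg$out_dir, "perm_subjects.csv"), prov)
  invisible(list(glomerulus = gl, subject = su))
}

#' Log2 fold change relative to a reference group
#'
#' Each value is divided by the mean of the reference group, then log2
#' transformed (the pooling normalization used for cohort readouts).
#'
#' @param values Numeric vector (> 0).
#' @param groups Group label per value.
#' @param reference_group Label of the reference group (non-empty).
#' @param subjects Optional subject labels used in error messages.
#' @return Data frame: \code{subject}, \code{group}, \code{value},
#'   \code{log2_fold_change}.
#' @export
log2_fold_change <- function(values, groups, reference_group,
                             subjects = NULL) {
  if (is.null(subjects)) subjects <- paste0("subject_", seq_along(values))
  if (length(groups) != length(values)) stopf("groups/values lengths differ")
  ref <- values[groups == reference_group]
  if (!length(ref)) stopf("reference group '%s' is empty", reference_group)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stopf("nonpositive value(s) for: %s", paste(subjects[bad], collapse = ", "))
  }
  ref_mean <- mean(ref)
  if (ref_mean <= 0) stopf("reference group mean must be > 0")
  data.frame(subject = subjects, group = groups, value = values,
             log2_fold_change = log2(values / ref_mean),
             stringsAsFactors = FALSE)
}

#' Corrected total intensity of a region
#'
#' Integrated density of the region minus (region area in pixels times the
#' mean gray value of the background region) — the standard corrected total
#' cell fluorescence formula. The raw components are returned so alternative
#' conventions can be recomputed.
#'
#' @param image Numeric matrix.
#' @param region_mask,background_mask Logical matrices matching \code{image},
#'   non-empty and disjoint.
#' @return List: \code{corrected}, \code{integrated_density},
#'   \code{area_px}, \code{background_mean}.
#' @export
corrected_total_intensity <- function(image, region_mask, background_mask) {
  stopifnot(is.matrix(image), identical(dim(image), dim(region_mask)),
            identical(dim(image), dim(background_mask)))
  if (!any(region_mask)) stopf("region mask is empty")
  if (!any(background_mask)) stopf("background mask is empty")
  if (any(region_mask & background_mask)) {
    stopf("region and background masks must be disjoint")
  }
  integrated <- sum(image[region_mask])
  area <- sum(region_mask)
  bg <- mean(image[background_mask])
  list(corrected = integrated - area * bg, integrated_density = integrated,
       area_px = area, background_mean = bg)
}
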