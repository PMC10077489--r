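# TEM grid-intersection morphometry: glycocalyx thickness and coverage,
# filtration-barrier widths, and linear densities, from annotation tables.
# The module consumes manual annotations; it does not segment micrographs.

#' Glycocalyx thickness at one grid intersection
#'
#' Euclidean distance (nm) from the luminal phospholipid point to the
#' farthest glycocalyx point.
#'
#' @param luminal,glycocalyx Numeric \code{c(x_nm, y_nm)} points.
#' @return Thickness in nm.
#' @export
point_thickness <- function(luminal, glycocalyx) {
  if (!all(is.finite(luminal)) || !all(is.finite(glycocalyx))) {
    stopf("both points must be finite")
  }
  sqrt(sum((glycocalyx - luminal)^2))
}

#' Glycocalyx coverage percentage
#'
#' A measurement of \code{uncovered_max} nm or less counts as uncovered
#' (boundary inclusive: exactly 10 nm is uncovered); coverage is the
#' percentage of measurements strictly above the threshold.
#'
#' @param thicknesses_nm Vector of thickness measurements (nm).
#' @param uncovered_max Uncovered threshold in nm (default 10).
#' @return Coverage in percent (0-100).
#' @export
coverage_percent <- function(thicknesses_nm, uncovered_max = 10) {
  if (!length(thicknesses_nm)) stopf("coverage requires at least one measurement")
  100 * mean(thicknesses_nm > uncovered_max)
}

#' Mean width of one annotation kind
#'
#' @param width_pairs Data frame with columns \code{kind}, \code{x0_nm},
#'   \code{y0_nm}, \code{x1_nm}, \code{y1_nm}.
#' @param kind One of \code{"gbm"}, \code{"foot_process"}, \code{"slit"}.
#' @return Mean Euclidean pair distance (nm).
#' @export
width_mean <- function(width_pairs, kind) {
  sel <- width_pairs[width_pairs$kind == kind, , drop = FALSE]
  if (!nrow(sel)) stopf("no width pairs of kind '%s'", kind)
  mean(sqrt((sel$x1_nm - sel$x0_nm)^2 + (sel$y1_nm - sel$y0_nm)^2))
}

#' Linear density along the GBM
#'
#' @param count Number of structures counted (fenestrations, foot processes).
#' @param gbm_length_um Length of GBM analysed (um).
#' @return Density per um.
#' @export
linear_density <- function(count, gbm_length_um) {
  check_number(count, "count", 0)
  if (!is.numeric(gbm_length_um) || length(gbm_length_um) != 1L ||
      !is.finite(gbm_length_um) || gbm_length_um <= 0) {
    stopf("gbm_length_um must be > 0")
  }
  count / gbm_length_um
}

#' Read a TEM annotation CSV
#'
#' Schema: \code{record_type} in \{intersection, width, count\}, \code{kind},
#' \code{x0_nm}, \code{y0_nm}, \code{x1_nm}, \code{y1_nm}, \code{count},
#' \code{gbm_length_um}, \code{capillary_id}, \code{glomerulus_id},
#' \code{subject_id}. Malformed rows are reported with their line numbers.
#'
#' @param path CSV path.
#' @return Validated annotation data frame.
#' @export
read_tem_annotation <- function(path) {
  df <- read_csv_prov(path)
  if (!nrow(df)) stopf("annotation file '%s' is empty", path)
  need <- c("record_type", "kind", "x0_nm", "y0_nm", "x1_nm", "y1_nm",
            "count", "gbm_length_um", "capillary_id", "glomerulus_id",
            "subject_id")
  if (!all(need %in% names(df))) {
    stopf("annotation file '%s' must have columns: %s", path,
          paste(need, collapse = ", "))
  }
  bad <- which(
    !(df$record_type %in% c("intersection", "width", "count")) |
    (df$record_type %in% c("intersection", "width") &
       (!is.finite(df$x0_nm) | !is.finite(df$y0_nm) |
        !is.finite(df$x1_nm) | !is.finite(df$y1_nm))) |
    (df$record_type == "count" &
       (!is.finite(df$count) | !is.finite(df$gbm_length_um) |
        df$gbm_length_um <= 0)))
  if (length(bad)) {
    stopf("malformed annotation rows in '%s' at data line(s): %s", path,
          paste(bad, collapse = ", "))
  }
  df
}

#' Summarize a TEM annotation table per capillary
#'
#' Computes mean glycocalyx thickness and coverage from intersection records,
#' mean widths per kind from width records, and linear densities from count
#' records, grouped by capillary. Fields whose records are absent are
#' reported as \code{NA}.
#'
#' @param annotation Annotation data frame
#'   (\code{\link{read_tem_annotation}} schema).
#' @param uncovered_max Uncovered threshold in nm (default 10).
#' @return Data frame, one row per capillary: \code{capillary_id},
#'   \code{glomerulus_id}, \code{subject_id}, \code{n_intersections},
#'   \code{mean_thickness_nm}, \code{coverage_pct}, \code{gbm_width_nm},
#'   \code{foot_process_width_nm}, \code{slit_width_nm},
#'   \code{fenestration_density_per_um}, \code{foot_process_density_per_um}.
#' @export
tem_summarize <- function(annotation, uncovered_max = 10) {
  keys <- unique(annotation[, c("capillary_id", "glomerulus_id", "subject_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- annotation[annotation$capillary_id == keys$capillary_id[i] &
                      annotation$glomerulus_id == keys$glomerulus_id[i] &
                      annotation$subject_id == keys$subject_id[i], ,
                      drop = FALSE]
    inter <- sub[sub$record_type == "intersection", , drop = FALSE]
    th <- if (nrow(inter)) {
      sqrt((inter$x1_nm - inter$x0_nm)^2 + (inter$y1_nm - inter$y0_nm)^2)
    } else numeric(0)
    widths <- sub[sub$record_type == "width", , drop = FALSE]
    wmean <- function(kind) {
      if (any(widths$kind == kind)) width_mean(widths, kind) else NA_real_
    }
    counts <- sub[sub$record_type == "count", , drop = FALSE]
    dens <- function(kind) {
      r <- counts[counts$kind == kind, , drop = FALSE]
      if (nrow(r)) linear_density(r$count[1], r$gbm_length_um[1]) else NA_real_
    }
    data.frame(capillary_id = keys$capillary_id[i],
               glomerulus_id = keys$glomerulus_id[i],
               subject_id = keys$subject_id[i],
               n_intersections = length(th),
               mean_thickness_nm = if (length(th)) mean(th) else NA_real_,
               coverage_pct = if (length(th))
                 coverage_percent(th, uncovered_max) else NA_real_,
               gbm_width_nm = wmean("gbm"),
               foot_process_width_nm = wmean("foot_process"),
               slit_width_nm = wmean("slit"),
               fenestration_density_per_um = dens("fenestration"),
               foot_process_density_per_um = dens("foot_process"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
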