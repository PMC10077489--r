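# Synthetic TEM grid-intersection annotation tables with known ground truth.

#' Ground truth for a synthetic TEM annotation table
#'
#' @param n_intersections Number of grid intersections annotated.
#' @param thickness_mean_nm,thickness_sd_nm Glycocalyx thickness distribution
#'   (normal, floored at 0 nm).
#' @param fraction_uncovered Target fraction of intersections with thickness
#'   <= 10 nm. \code{NA} (default) draws all thicknesses from the normal
#'   distribution and records the fraction that happens to land <= 10 nm;
#'   a number constructs exactly \code{round(n * fraction)} uncovered points
#'   (uniform on [0, 10] nm) and draws the rest from the normal truncated
#'   above 10 nm.
#' @param gbm_width_mean_nm,gbm_width_sd_nm GBM width pair distribution; set
#'   \code{n_gbm_pairs = 0} to omit.
#' @param n_gbm_pairs Number of GBM width pairs.
#' @param fenestrations,foot_processes Counts for linear densities.
#' @param gbm_length_um Length of GBM analysed (um).
#' @param capillary_id,glomerulus_id,subject_id Hierarchy labels.
#' @param seed Integer seed.
#' @return A \code{tem_truth} list.
#' @export
tem_truth <- function(n_intersections = 50L, thickness_mean_nm = 200,
                      thickness_sd_nm = 50, fraction_uncovered = NA,
                      gbm_width_mean_nm = 200, gbm_width_sd_nm = 20,
                      n_gbm_pairs = 10L, fenestrations = 12L,
                      foot_processes = 10L, gbm_length_um = 6,
                      capillary_id = "C01", glomerulus_id = "G01",
                      subject_id = "S01", seed = 1L) {
  check_number(n_intersections, "n_intersections", 1)
  check_number(thickness_mean_nm, "thickness_mean_nm", 0)
  check_number(thickness_sd_nm, "thickness_sd_nm", 0)
  if (!is.na(fraction_uncovered)) {
    check_number(fraction_uncovered, "fraction_uncovered", 0)
    if (fraction_uncovered > 1) stopf("'fraction_uncovered' must be <= 1")
  }
  check_number(gbm_length_um, "gbm_length_um", 0, strict_min = TRUE)
  structure(list(n_intersections = as.integer(n_intersections),
                 thickness_mean_nm = thickness_mean_nm,
                 thickness_sd_nm = thickness_sd_nm,
                 fraction_uncovered = fraction_uncovered,
                 gbm_width_mean_nm = gbm_width_mean_nm,
                 gbm_width_sd_nm = gbm_width_sd_nm,
                 n_gbm_pairs = as.integer(n_gbm_pairs),
                 fenestrations = as.integer(fenestrations),
                 foot_processes = as.integer(foot_processes),
                 gbm_length_um = gbm_length_um, capillary_id = capillary_id,
                 glomerulus_id = glomerulus_id, subject_id = subject_id,
                 seed = as.integer(seed)), class = "tem_truth")
}

#' Generate a synthetic TEM annotation table
#'
#' Each grid intersection becomes a pair of coordinates (luminal phospholipid
#' point, farthest glycocalyx point) whose Euclidean separation realizes the
#' requested thickness; width pairs and counts follow the same CSV schema the
#' analysis side consumes (see \code{\link{read_tem_annotation}}).
#'
#' @param truth A \code{\link{tem_truth}}.
#' @return List with \code{annotation} (data frame in the annotation schema)
#'   and \code{truth} with \code{achieved_uncovered_fraction} and
#'   \code{true_thicknesses_nm} filled in.
#' @export
make_tem_annotation <- function(truth) {
  stopifnot(inherits(truth, "tem_truth"))
  n <- truth$n_intersections
  th <- with_seed(truth$seed, {
    if (is.na(truth$fraction_uncovered)) {
      pmax(stats::rnorm(n, truth$thickness_mean_nm, truth$thickness_sd_nm), 0)
    } else {
      n_unc <- round(n * truth$fraction_uncovered)
      x <- numeric(n)
      unc_idx <- if (n_unc > 0) sample.int(n, n_unc) else integer(0)
      x[unc_idx] <- stats::runif(n_unc, 0, 10)
      n_cov <- n - n_unc
      if (n_cov > 0) {
        draw <- function(m) pmax(stats::rnorm(m, truth$thickness_mean_nm,
                                              truth$thickness_sd_nm), 0)
        y <- draw(n_cov)
        for (i in 1:100) {
          bad <- y <= 10
          if (!any(bad)) break
          y[bad] <- draw(sum(bad))
        }
        y[y <= 10] <- 10 + stats::runif(sum(y <= 10), 0.1, 1) # pathological SDs
        x[setdiff(seq_len(n), unc_idx)] <- y
      }
      x
    }
  })
  geom <- with_seed(derive_seed(truth$seed, 7L), {
    ang <- stats::runif(n + truth$n_gbm_pairs, 0, 2 * pi)
    ox <- stats::runif(n + truth$n_gbm_pairs, 0, 5000)
    oy <- stats::runif(n + truth$n_gbm_pairs, 0, 5000)
    gbm <- if (truth$n_gbm_pairs > 0) {
      pmax(stats::rnorm(truth$n_gbm_pairs, truth$gbm_width_mean_nm,
                        truth$gbm_width_sd_nm), 0)
    } else numeric(0)
    list(ang = ang, ox = ox, oy = oy, gbm = gbm)
  })
  ids <- unname(c(truth$capillary_id, truth$glomerulus_id, truth$subject_id))
  row_for <- function(type, kind, i, len, count = NA, gbm_len = NA) {
    data.frame(record_type = type, kind = kind,
               x0_nm = geom$ox[i], y0_nm = geom$oy[i],
               x1_nm = geom$ox[i] + len * cos(geom$ang[i]),
               y1_nm = geom$oy[i] + len * sin(geom$ang[i]),
               count = count, gbm_length_um = gbm_len,
               capillary_id = ids[1], glomerulus_id = ids[2],
               subject_id = ids[3], stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(n), function(i)
    row_for("intersection", "glycocalyx", i, th[i]))
  if (truth$n_gbm_pairs > 0) {
    rows <- c(rows, lapply(seq_len(truth$n_gbm_pairs), function(j)
      row_for("width", "gbm", n + j, geom$gbm[j])))
  }
  counts <- data.frame(
    record_type = "count", kind = c("fenestration", "foot_process"),
    x0_nm = NA, y0_nm = NA, x1_nm = NA, y1_nm = NA,
    count = c(truth$fenestrations, truth$foot_processes),
    gbm_length_um = truth$gbm_length_um,
    capillary_id = ids[1], glomerulus_id = ids[2], subject_id = ids[3],
    stringsAsFactors = FALSE)
  annotation <- rbind(do.call(rbind, rows), counts)
  rownames(annotation) <- NULL
  truth$true_thicknesses_nm <- th
  truth$achieved_uncovered_fraction <- mean(th <= 10)
  list(annotation = annotation, truth = truth)
}
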