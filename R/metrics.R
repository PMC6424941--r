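#' Per-ROI accuracy and precision summary of a T1 map
#'
#' For each labeled region of interest, reports the mean fitted T1 (the
#' accuracy proxy when a reference is available) and its sample standard
#' deviation (the precision proxy), over valid voxels only.
#'
#' @param map A `t1_map_result` from [fit_t1_map()], or a plain 3D numeric
#'   array (finite voxels are then treated as valid).
#' @param labels 3D array of non-negative integer ROI labels; 0 is
#'   background and is not reported.
#' @param truth Optional `ground_truth` from [build_phantom()] (or a 3D
#'   array of true T1); adds per-ROI `truth_t1_ms` and
#'   `bias_ms = mean - truth`.
#' @return A `data.frame` with columns `label`, `n_voxels`, `mean_t1_ms`,
#'   `sd_t1_ms` (sample SD, `n - 1`; `NA` for single-voxel ROIs) and, when
#'   `truth` is given, `truth_t1_ms` and `bias_ms`. Labels present in
#'   `labels` but without any valid voxel are dropped with a warning.
#' @export
roi_stats <- function(map, labels, truth = NULL) {
  if (inherits(map, "t1_map_result")) {
    vals <- map$t1_ms; valid <- map$valid
  } else {
    vals <- map; valid <- is.finite(map)
  }
  if (!identical(dim(vals), dim(labels)))
    stop("labels shape does not match the map")
  if (any(labels < 0)) stop("labels must be non-negative integers")
  truth_t1 <- NULL
  if (!is.null(truth))
    truth_t1 <- if (inherits(truth, "ground_truth")) truth$t1_ms else truth

  labs <- sort(unique(labels[labels > 0]))
  rows <- lapply(labs, function(l) {
    sel <- labels == l & valid
    nv <- sum(sel)
    if (nv == 0L) {
      warning(sprintf("ROI label %d has no valid voxels; excluded", l))
      return(NULL)
    }
    x <- vals[sel]
    out <- data.frame(label = l, n_voxels = nv, mean_t1_ms = mean(x),
                      sd_t1_ms = if (nv > 1L) stats::sd(x) else NA_real_)
    if (!is.null(truth_t1)) {
      tt <- unique(truth_t1[labels == l])
      tt <- if (length(tt) == 1L) tt else mean(truth_t1[sel])
      out$truth_t1_ms <- tt
      out$bias_ms <- out$mean_t1_ms - tt
    }
    out
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Bland-Altman agreement between two sets of paired ROI means
#'
#' Paired-difference agreement summary: differences `a - b`, their mean
#' (the bias) and the 95% limits of agreement
#' `bias +/- 1.96 * SD(differences)` (sample SD, `n - 1`).
#'
#' @param values_a,values_b Paired numeric vectors (e.g. per-ROI mean T1 of
#'   two techniques), equal length >= 2.
#' @param labels Optional identifiers for the pairs.
#' @return An object of class `bland_altman`: list with `means`, `diffs`,
#'   `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `labels`.
#' @examples
#' ba <- bland_altman(c(1000, 1200, 1400), c(990, 1210, 1390))
#' ba$bias
#' @export
bland_altman <- function(values_a, values_b, labels = NULL) {
  if (length(values_a) != length(values_b))
    stop("values_a and values_b must have equal length")
  if (length(values_a) < 2L)
    stop("at least 2 pairs are required")
  diffs <- values_a - values_b
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  structure(list(means = (values_a + values_b) / 2, diffs = diffs,
                 bias = bias, sd_diff = sd_diff,
                 loa_lower = bias - 1.96 * sd_diff,
                 loa_upper = bias + 1.96 * sd_diff,
                 labels = labels),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d pairs\n", length(x$diffs)))
  cat(sprintf("  bias %.2f, 95%% limits of agreement [%.2f, %.2f] (SD %.2f)\n",
              x$bias, x$loa_lower, x$loa_upper, x$sd_diff))
  invisible(x)
}

#' Simplified AHA 16-segment summary of a left-ventricular T1 map
#'
#' Partitions the myocardial mask of three slice groups (base, mid, apex)
#' into the standard American Heart Association segments — 6 segments of 60
#' degrees in the basal and mid rings, 4 of 90 degrees in the apical ring —
#' and reports mean and SD of T1 per segment. Segment 17 reports the blood
#' pool. Angles are measured from the anterior RV insertion point,
#' proceeding counterclockwise (anterior, then anteroseptal, ...), per the
#' AHA convention.
#'
#' @param map A `t1_map_result` or 3D array (as in [roi_stats()]).
#' @param myocardium_mask,blood_mask 3D logical arrays on the map grid.
#' @param lv_center_mm In-plane LV center, either a length-2 vector (x, y)
#'   in mm shared by all slices or an `nz x 2` matrix of per-slice centers.
#' @param rv_insertion_angle_deg Angle (degrees, counterclockwise from the
#'   +x axis) of the anterior RV insertion point; segment boundaries start
#'   there.
#' @param slice_partition Named list with integer vectors `base`, `mid`,
#'   `apex` of slice indices; must be disjoint.
#' @param spacing_mm In-plane voxel spacing used to place voxel centers in
#'   mm; defaults to the spacing stored in a `t1_map_result`, or unit
#'   spacing for a plain array.
#' @return An `aha_summary` data.frame: `segment` (1-17), `ring`,
#'   `n_voxels`, `mean_t1_ms`, `sd_t1_ms`. The attribute
#'   `"segment_labels"` holds the 3D array of per-voxel segment
#'   assignments (0 = unassigned).
#' @export
aha_segments <- function(map, myocardium_mask, blood_mask,
                         lv_center_mm, rv_insertion_angle_deg = 90,
                         slice_partition, spacing_mm = NULL) {
  if (inherits(map, "t1_map_result")) {
    vals <- map$t1_ms; valid <- map$valid
    sp <- spacing_mm %||% map$spacing_mm
  } else {
    vals <- map; valid <- is.finite(map); sp <- spacing_mm %||% c(1, 1, 1)
  }
  gs <- dim(vals)
  stopifnot(identical(dim(myocardium_mask), gs), identical(dim(blood_mask), gs))
  rings <- c("base", "mid", "apex")
  if (!all(rings %in% names(slice_partition)))
    stop("slice_partition needs elements 'base', 'mid', 'apex'")
  all_slices <- unlist(slice_partition[rings])
  if (anyDuplicated(all_slices))
    stop("apex/mid/base slice ranges must be disjoint")
  if (is.null(dim(lv_center_mm)))
    lv_center_mm <- matrix(lv_center_mm, nrow = gs[3], ncol = 2, byrow = TRUE)

  cx <- voxel_centers(gs[1], sp[1])
  cy <- voxel_centers(gs[2], sp[2])
  seg <- array(0L, gs)

  ring_of <- c(base = 0L, mid = 6L, apex = 12L)
  nseg_of <- c(base = 6L, mid = 6L, apex = 4L)
  for (ring in rings) {
    for (z in slice_partition[[ring]]) {
      msl <- myocardium_mask[, , z]
      if (!any(msl))
        stop(sprintf("myocardium mask is empty in the '%s' slice range (slice %d)",
                     ring, z))
      idx <- which(msl, arr.ind = TRUE)
      dx <- cx[idx[, 1]] - lv_center_mm[z, 1]
      dy <- cy[idx[, 2]] - lv_center_mm[z, 2]
      ang <- (atan2(dy, dx) * 180 / pi - rv_insertion_angle_deg) %% 360
      width <- 360 / nseg_of[[ring]]
      local <- pmin(floor(ang / width), nseg_of[[ring]] - 1L)
      seg[cbind(idx, z)] <- ring_of[[ring]] + local + 1L
    }
  }

  seg_ring <- c(rep("base", 6), rep("mid", 6), rep("apex", 4), "blood")
  rows <- lapply(1:17, function(s) {
    sel <- if (s == 17L) blood_mask & valid else seg == s & valid
    nv <- sum(sel)
    data.frame(segment = s, ring = seg_ring[s], n_voxels = nv,
               mean_t1_ms = if (nv) mean(vals[sel]) else NA_real_,
               sd_t1_ms = if (nv > 1) stats::sd(vals[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("aha_summary", "data.frame")
  attr(out, "segment_labels") <- seg
  out
}
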