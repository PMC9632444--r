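# SCI segmentation under the two threshold-based lesion definitions,
# contralateral NAWM mirroring, white-matter depth classification and
# lobe assignment.
#
# Definitions: a lesion ROI is kept under the FLAIR (SIT-trial-style)
# definition when it contains FLAIR-hyperintense voxels (>= 1.02 x mean
# cortical FLAIR intensity) and measures >= 3 mm in greatest dimension.
# The stringent FLAIR+T1w definition additionally requires voxels that
# are T1w-hypointense (<= 1.02 x mean cortical T1w intensity).

#' Lesion region of interest
#'
#' @param mask Logical 3D mask.
#' @param grid_name Which grid the mask lives on (`"FLAIR"`, `"T1w"`,
#'   `"GRE"`).
#' @param definition `"FLAIR"` or `"FLAIR+T1w"`.
#' @param voxel_size_mm Voxel size of the grid.
#' @param subject_id,lesion_id Identifiers.
#' @param excluded,reason Exclusion flag and reason.
#' @return Object of class `lesion_roi` with `volume_mm3` derived from
#'   the mask.
#' @export
lesion_roi <- function(mask, grid_name = "FLAIR", definition = "FLAIR",
                       voxel_size_mm = c(1, 1, 1), subject_id = NA,
                       lesion_id = NA, excluded = FALSE,
                       reason = NA_character_) {
  if (!excluded && sum(mask) == 0)
    stop("non-excluded lesion ROI must be nonempty")
  structure(list(mask = mask, grid_name = grid_name,
                 definition = definition,
                 voxel_size_mm = rep(voxel_size_mm, length.out = 3),
                 volume_mm3 = sum(mask) * prod(voxel_size_mm),
                 subject_id = subject_id, lesion_id = lesion_id,
                 excluded = excluded, reason = reason,
                 lobe = NA_character_, depth_fractions = NULL),
            class = "lesion_roi")
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat("lesion_roi [", x$definition, "] on", x$grid_name, "grid:",
      sum(x$mask), "voxels,", signif(x$volume_mm3, 4), "mm^3",
      if (x$excluded) paste0("(excluded: ", x$reason, ")") else "", "\n")
  invisible(x)
}

#' Mean intensity over the cortical mask
#'
#' @param image 3D intensity volume.
#' @param cortex_mask Logical mask of cortical grey matter (nonempty).
#' @return Arithmetic mean of `image` over the cortex.
#' @export
cortical_mean <- function(image, cortex_mask) {
  if (sum(cortex_mask) == 0) stop("empty cortex mask")
  mean(image[cortex_mask])
}

#' FLAIR hyperintensity threshold
#'
#' Retains seed-ROI voxels with FLAIR intensity at or above
#' `factor x cortex_mean` (default factor 1.02, boundary inclusive).
#' An ROI left empty is marked excluded ("no hyperintense voxels").
#'
#' @param seed_roi Logical mask or `lesion_roi` on the FLAIR grid.
#' @param flair FLAIR intensity volume.
#' @param cortex_mean Mean cortical FLAIR intensity, see
#'   [cortical_mean()].
#' @param factor Threshold factor (default 1.02).
#' @param ... Passed to [lesion_roi()] (ids, voxel size).
#' @return `lesion_roi` with definition `"FLAIR"`.
#' @export
apply_flair_threshold <- function(seed_roi, flair, cortex_mean,
                                  factor = 1.02, ...) {
  seed <- if (inherits(seed_roi, "lesion_roi")) seed_roi$mask else seed_roi
  if (sum(seed) == 0) stop("seed ROI empty")
  kept <- seed & (flair >= factor * cortex_mean)
  if (sum(kept) == 0)
    return(lesion_roi(kept, grid_name = "FLAIR", definition = "FLAIR",
                      excluded = TRUE, reason = "no hyperintense voxels",
                      ...))
  lesion_roi(kept, grid_name = "FLAIR", definition = "FLAIR", ...)
}

#' T1w hypointensity threshold (stringent definition)
#'
#' Retains FLAIR-definition voxels with T1w intensity at or below
#' `factor x cortex_mean_t1`. An ROI left empty did not persist under the
#' stringent definition and is marked excluded.
#'
#' @param flair_roi `lesion_roi` (or mask) already resampled onto the T1w
#'   grid.
#' @param t1w T1w intensity volume.
#' @param cortex_mean_t1 Mean cortical T1w intensity.
#' @param factor Threshold factor (default 1.02).
#' @param ... Passed to [lesion_roi()].
#' @return `lesion_roi` with definition `"FLAIR+T1w"`.
#' @export
apply_t1w_threshold <- function(flair_roi, t1w, cortex_mean_t1,
                                factor = 1.02, ...) {
  m <- if (inherits(flair_roi, "lesion_roi")) flair_roi$mask else flair_roi
  kept <- m & (t1w <= factor * cortex_mean_t1)
  if (sum(kept) == 0)
    return(lesion_roi(kept, grid_name = "T1w", definition = "FLAIR+T1w",
                      excluded = TRUE,
                      reason = "did not persist under T1w threshold", ...))
  lesion_roi(kept, grid_name = "T1w", definition = "FLAIR+T1w", ...)
}

#' Minimum-size gate (3 mm greatest dimension)
#'
#' The greatest axis-aligned extent of the mask, in mm, must reach 3 mm.
#'
#' @param roi Logical mask or `lesion_roi`.
#' @param voxel_size_mm Voxel size; taken from a `lesion_roi` when given.
#' @param min_mm Required greatest dimension (default 3).
#' @return List: `pass`, `greatest_dimension_mm`.
#' @export
size_gate <- function(roi, voxel_size_mm = NULL, min_mm = 3) {
  if (inherits(roi, "lesion_roi")) {
    if (is.null(voxel_size_mm)) voxel_size_mm <- roi$voxel_size_mm
    roi <- roi$mask
  }
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  if (sum(roi) == 0)
    return(list(pass = FALSE, greatest_dimension_mm = 0))
  ind <- arrayInd(which(roi), dim(roi))
  ext <- (apply(ind, 2, max) - apply(ind, 2, min) + 1) * voxel_size_mm
  list(pass = max(ext) >= min_mm, greatest_dimension_mm = max(ext))
}

#' Mirror an SCI into contralateral normal-appearing white matter
#'
#' Reflects the lesion mask across the mid-sagittal plane, then — staying
#' in the same transverse slices — searches deterministically for the
#' nearest in-plane shift that places the mirrored mask fully inside
#' white matter and disjoint from every SCI mask of the subject
#' (candidates ordered by shift length, ties in raster order). The voxel
#' count is preserved.
#'
#' @param sci_roi `lesion_roi` or logical mask on the target grid.
#' @param wm_mask Logical white-matter mask.
#' @param all_sci_masks List of all SCI masks of the subject (on the same
#'   grid) that the NAWM ROI must avoid.
#' @param midline_x 0-based x index of the mid-sagittal plane; defaults
#'   to the grid centre `(nx - 1) / 2`.
#' @param max_shift Search radius in voxels (default 20).
#' @return List: `nawm` (`lesion_roi` or NULL), `excluded`, `reason`,
#'   `shift` (applied in-plane shift).
#' @export
mirror_nawm <- function(sci_roi, wm_mask, all_sci_masks = list(),
                        midline_x = NULL, max_shift = 20) {
  roi <- if (inherits(sci_roi, "lesion_roi")) sci_roi else
    lesion_roi(sci_roi, grid_name = "GRE")
  mask <- roi$mask
  d <- dim(mask)
  if (is.null(midline_x)) midline_x <- (d[1] - 1) / 2
  ind <- arrayInd(which(mask), d)   # 1-based
  # reflect: x' = 2 * midline - x (0-based) -> 1-based: 2*midline - (x-1) + 1
  rx <- round(2 * midline_x - (ind[, 1] - 1)) + 1
  mirrored <- cbind(rx, ind[, 2], ind[, 3])

  sci_any <- array(FALSE, d)
  for (m in all_sci_masks) sci_any <- sci_any | m

  offs <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  offs <- offs[order(offs$dx^2 + offs$dy^2,
                     offs$dy, offs$dx), , drop = FALSE]
  n <- nrow(mirrored)
  for (k in seq_len(nrow(offs))) {
    cand <- mirrored
    cand[, 1] <- cand[, 1] + offs$dx[k]
    cand[, 2] <- cand[, 2] + offs$dy[k]
    if (any(cand[, 1] < 1 | cand[, 1] > d[1] |
            cand[, 2] < 1 | cand[, 2] > d[2])) next
    lin <- (cand[, 3] - 1) * d[1] * d[2] + (cand[, 2] - 1) * d[1] + cand[, 1]
    if (length(unique(lin)) < n) next
    if (all(wm_mask[lin]) && !any(sci_any[lin])) {
      nm <- array(FALSE, d); nm[lin] <- TRUE
      nawm <- lesion_roi(nm, grid_name = roi$grid_name,
                         definition = roi$definition,
                         voxel_size_mm = roi$voxel_size_mm,
                         subject_id = roi$subject_id,
                         lesion_id = roi$lesion_id)
      return(list(nawm = nawm, excluded = FALSE, reason = NA_character_,
                  shift = c(offs$dx[k], offs$dy[k])))
    }
  }
  list(nawm = NULL, excluded = TRUE,
       reason = "no valid contralateral NAWM position", shift = NULL)
}

#' Classify white-matter depth
#'
#' Euclidean distance transforms to the cortex and to the ventricles are
#' computed over white matter. Periventricular voxels are the
#' ventricle-proximal fraction (default 5%); among the remainder,
#' juxtacortical voxels are the cortex-proximal fraction (default 25%);
#' the rest are deep. Precedence: periventricular > juxtacortical >
#' deep. Percentiles follow the proximity reading of the distance-map
#' percentile rule (see the methods vignette); set `reading =
#' "distance"` for the literal distance-map percentiles (cortex-distal
#' selection).
#'
#' @param wm_mask,cortex_mask,ventricle_mask Disjoint logical masks;
#'   cortex and ventricle nonempty.
#' @param voxel_size_mm Voxel size in mm.
#' @param cortex_fraction Cortex-proximal WM fraction labelled
#'   juxtacortical (default 0.25, i.e. the 75th percentile of a cortical
#'   proximity map).
#' @param ventricle_fraction Ventricle-proximal WM fraction labelled
#'   periventricular (default 0.05).
#' @param reading `"proximity"` (default) or `"distance"`.
#' @return Object of class `depth_map`: `labels` (character array:
#'   `"periventricular"`, `"juxtacortical"`, `"deep"`, NA outside WM),
#'   `d_cortex`, `d_ventricle` (mm).
#' @export
classify_wm_depth <- function(wm_mask, cortex_mask, ventricle_mask,
                              voxel_size_mm = c(1, 1, 1),
                              cortex_fraction = 0.25,
                              ventricle_fraction = 0.05,
                              reading = c("proximity", "distance")) {
  reading <- match.arg(reading)
  if (sum(cortex_mask) == 0) stop("empty cortex mask")
  if (sum(ventricle_mask) == 0) stop("empty ventricle mask")
  if (sum(wm_mask) == 0) stop("empty white-matter mask")
  if (any(wm_mask & (cortex_mask | ventricle_mask)) ||
      any(cortex_mask & ventricle_mask))
    stop("masks must be disjoint")
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  dc <- distance_transform(cortex_mask, voxel_size_mm)
  dv <- distance_transform(ventricle_mask, voxel_size_mm)
  wm_idx <- which(wm_mask)
  dvw <- dv[wm_idx]; dcw <- dc[wm_idx]

  if (reading == "proximity") {
    pv_cut <- stats::quantile(dvw, ventricle_fraction, names = FALSE)
    jc_cut <- stats::quantile(dcw, cortex_fraction, names = FALSE)
    pv <- dvw <= pv_cut
    jc <- !pv & dcw <= jc_cut
  } else {
    # literal distance-map percentiles: 5th of d_ventricle,
    # 75th-and-above of d_cortex
    pv_cut <- stats::quantile(dvw, ventricle_fraction, names = FALSE)
    jc_cut <- stats::quantile(dcw, 1 - cortex_fraction, names = FALSE)
    pv <- dvw <= pv_cut
    jc <- !pv & dcw >= jc_cut
  }
  lab <- array(NA_character_, dim(wm_mask))
  lab[wm_idx] <- "deep"
  lab[wm_idx[pv]] <- "periventricular"
  lab[wm_idx[jc]] <- "juxtacortical"
  structure(list(labels = lab, d_cortex = dc, d_ventricle = dv,
                 cuts = c(periventricular = pv_cut, juxtacortical = jc_cut)),
            class = "depth_map")
}

#' Depth-class voxel fractions of an ROI
#' @param roi `lesion_roi` or logical mask on the depth map's grid.
#' @param depth_map A `depth_map`.
#' @return Named numeric vector of fractions summing to 1 over
#'   classified voxels.
#' @export
depth_fractions <- function(roi, depth_map) {
  m <- if (inherits(roi, "lesion_roi")) roi$mask else roi
  lab <- depth_map$labels[m]
  lab <- lab[!is.na(lab)]
  cls <- c("periventricular", "juxtacortical", "deep")
  if (length(lab) == 0)
    return(stats::setNames(rep(NA_real_, 3), cls))
  stats::setNames(as.numeric(table(factor(lab, levels = cls))) / length(lab),
                  cls)
}

#' Majority-vote lobe assignment
#'
#' @param roi `lesion_roi` or logical mask.
#' @param lobe_atlas Character (or factor) array on the same grid, values
#'   in `frontal`, `parietal`, `occipital`, `temporal`, `other`, NA
#'   outside the brain.
#' @return Lobe label; exact ties and ROIs wholly outside the atlas give
#'   `"other"`.
#' @export
assign_lobe <- function(roi, lobe_atlas) {
  m <- if (inherits(roi, "lesion_roi")) roi$mask else roi
  v <- as.character(lobe_atlas[m])
  v <- v[!is.na(v)]
  if (length(v) == 0) return("other")
  tab <- sort(table(v), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("other")
  names(tab)[1]
}

#' Synthetic lobe atlas for the phantom
#'
#' Partitions the brain mask into four lobes by simple geometric planes:
#' anterior half = frontal; posterior half split into parietal (upper),
#' occipital (lower-posterior) and temporal (lower-anterior-of-posterior).
#' A stand-in for an anatomical parcellation, sufficient to exercise the
#' lobe bookkeeping.
#'
#' @param brain_mask Logical brain mask.
#' @return Character array of lobe labels (NA outside the brain).
#' @export
synthetic_lobe_atlas <- function(brain_mask) {
  d <- dim(brain_mask)
  g <- grid_coords(d)
  y <- array(g[, 2], d); z <- array(g[, 3], d)
  lab <- array(NA_character_, d)
  ymid <- (d[2] - 1) / 2; zmid <- (d[3] - 1) / 2
  lab[brain_mask & y >= ymid] <- "frontal"
  lab[brain_mask & y < ymid & z >= zmid] <- "parietal"
  lab[brain_mask & y < ymid & z < zmid & y >= ymid / 2] <- "temporal"
  lab[brain_mask & y < ymid / 2 & z < zmid] <- "occipital"
  lab
}
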