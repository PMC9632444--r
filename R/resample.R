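# Moving volumes and ROI masks between the FLAIR, T1w and GRE grids.
# Registration *estimation* is out of scope: transforms are known affines
# (phantom sidecar or user-supplied matrices). Resampling is
# pull-resampling through the inverse affine at voxel centres, 0-based
# indices, voxel-centre convention.

#' Grid-to-grid affine transform
#'
#' @param source_grid,target_grid Lists with `dim` (length-3 integer) and
#'   `affine` (4x4 voxel-to-world matrix) describing each grid.
#' @param affine Optional explicit 4x4 source-voxel to target-voxel
#'   affine; by default derived from the two voxel-to-world affines.
#' @return Object of class `grid_transform`.
#' @export
grid_transform <- function(source_grid, target_grid, affine = NULL) {
  if (is.null(affine))
    affine <- solve(target_grid$affine) %*% source_grid$affine
  if (abs(det(affine)) < 1e-12) stop("degenerate affine")
  structure(list(source_grid = source_grid, target_grid = target_grid,
                 affine = affine),
            class = "grid_transform")
}

#' Resample a volume or mask through an affine transform
#'
#' Pull-resampling: every target voxel centre is mapped through the
#' inverse affine into the source grid and interpolated there. Masks must
#' use nearest-neighbour interpolation so they stay binary.
#'
#' @param volume 3D numeric or logical array on the source grid.
#' @param transform A [grid_transform()].
#' @param mode `"nearest"` or `"trilinear"`.
#' @return Array on the target grid; logical if the input was logical and
#'   mode is `"nearest"`.
#' @export
apply_affine <- function(volume, transform, mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(transform, "grid_transform"))
  was_logical <- is.logical(volume)
  if (was_logical && mode != "nearest")
    stop("masks must be resampled with nearest-neighbour interpolation")
  dim_out <- transform$target_grid$dim
  co <- grid_coords(dim_out)
  src <- affine_apply(solve(transform$affine), co)
  out <- array(sample_volume(volume * 1, src, mode), dim_out)
  if (was_logical) out > 0.5 else out
}

#' Post-resampling lesion exclusion gate
#'
#' Lesions reduced to 2 voxels or fewer after interpolation into the
#' native QSM (GRE) space are excluded.
#'
#' @param roi_mask Logical mask on the GRE grid, or a `lesion_roi`.
#' @return List with `keep` (logical), `n_voxels`, and `reason` (`NA` when
#'   kept).
#' @export
post_resample_gate <- function(roi_mask) {
  if (inherits(roi_mask, "lesion_roi")) roi_mask <- roi_mask$mask
  n <- sum(roi_mask)
  keep <- n > 2
  list(keep = keep, n_voxels = n,
       reason = if (keep) NA_character_
                else if (n == 0) "empty after interpolation"
                else "2 voxels or fewer after interpolation")
}
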