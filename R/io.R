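# Dataset export / import: NIfTI volumes (RNifti), a JSON sidecar with
# the acquisition protocol, grid affines and truth summary, and the
# lesion-specification CSV. Written volumes use double precision so that
# a round-trip read reproduces the arrays exactly.

#' @noRd
write_nii <- function(arr, path, affine) {
  img <- RNifti::asNifti(arr * 1)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  path
}

#' Write a simulated dataset to disk
#'
#' One magnitude + one phase NIfTI per echo (per coil when multi-coil),
#' FLAIR and T1w volumes on their native grids, the tissue labels,
#' ground-truth chi / R2* / M0 maps and brain mask, a JSON sidecar
#' (protocol, affines, lesion summary) and a lesion CSV.
#'
#' @param truth `tissue_phantom`.
#' @param series `megre_series`.
#' @param structurals Output of [simulate_structural()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the file manifest (named list of paths).
#' @export
write_dataset <- function(truth, series, structurals, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  manifest <- list()
  on_fail <- function(e) {
    unlink(written)
    stop("partial write cleaned up: ", conditionMessage(e))
  }
  tryCatch({
    w <- function(arr, name, affine) {
      p <- file.path(out_dir, paste0(name, ".nii.gz"))
      write_nii(arr, p, affine)
      written <<- c(written, p)
      p
    }
    aff_gre <- truth$affine
    coil_sets <- if (!is.null(series$data)) list(series$data) else series$coil_data
    ne <- length(series$echo_times_ms)
    megre <- character(0)
    for (ci in seq_along(coil_sets)) {
      for (e in seq_len(ne)) {
        tag <- if (length(coil_sets) > 1)
          sprintf("megre_coil%02d_echo%02d", ci, e)
        else sprintf("megre_echo%02d", e)
        megre <- c(megre,
                   w(Mod(coil_sets[[ci]][, , , e]), paste0(tag, "_mag"), aff_gre),
                   w(Arg(coil_sets[[ci]][, , , e]), paste0(tag, "_phase"), aff_gre))
      }
    }
    manifest$megre <- megre
    manifest$flair <- w(structurals$flair$data, "flair", structurals$flair$affine)
    manifest$t1w <- w(structurals$t1w$data, "t1w", structurals$t1w$affine)
    manifest$labels <- w(truth$label_grid, "labels", aff_gre)
    manifest$chi_truth <- w(truth$chi_map, "chi_truth", aff_gre)
    manifest$r2star_truth <- w(truth$r2star_map, "r2star_truth", aff_gre)
    manifest$m0_truth <- w(truth$m0_map, "m0_truth", aff_gre)
    manifest$brain_mask <- w(truth$brain_mask, "brain_mask", aff_gre)
    for (i in seq_along(truth$lesion_masks))
      manifest$lesion_masks[i] <-
        w(truth$lesion_masks[[i]], sprintf("lesion%02d_mask", i), aff_gre)

    les <- truth$lesions
    lesion_df <- if (length(les)) data.frame(
      id = seq_along(les),
      center_x = vapply(les, function(l) l$center[1], 0),
      center_y = vapply(les, function(l) l$center[2], 0),
      center_z = vapply(les, function(l) l$center[3], 0),
      semi_a = vapply(les, function(l) l$semi_axes[1], 0),
      semi_b = vapply(les, function(l) l$semi_axes[2], 0),
      semi_c = vapply(les, function(l) l$semi_axes[3], 0),
      delta_chi = vapply(les, function(l) l$delta_chi, 0),
      delta_r2star = vapply(les, function(l) l$delta_r2star, 0),
      flair_contrast = vapply(les, function(l) l$flair_contrast, 0),
      t1_pass_fraction = vapply(les, function(l) l$t1_pass_fraction, 0)
    ) else data.frame(id = integer(0))
    lesion_csv <- file.path(out_dir, "lesions.csv")
    utils::write.csv(lesion_df, lesion_csv, row.names = FALSE)
    written <- c(written, lesion_csv)
    manifest$lesions_csv <- lesion_csv

    sidecar <- list(
      protocol = unclass(series$protocol),
      affines = list(gre = aff_gre,
                     flair = structurals$flair$affine,
                     t1w = structurals$t1w$affine),
      n_lesions = length(les),
      voxel_size_gre = truth$voxel_size,
      echo_times_ms = series$echo_times_ms
    )
    sidecar_path <- file.path(out_dir, "dataset.json")
    jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                         digits = NA, matrix = "rowmajor")
    written <- c(written, sidecar_path)
    manifest$sidecar <- sidecar_path
    invisible(manifest)
  }, error = on_fail)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List: `megre` (complex 4D reassembled from magnitude + phase,
#'   single-coil only), `flair`, `t1w`, `labels`, `chi_truth`,
#'   `r2star_truth`, `m0_truth`, `brain_mask`, `lesions` (data.frame),
#'   `sidecar`, `affines`.
#' @export
read_dataset <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "dataset.json"),
                                 simplifyVector = TRUE)
  rd <- function(name) {
    img <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    array(as.numeric(img), dim(img))
  }
  te <- sidecar$echo_times_ms
  ne <- length(te)
  mags <- lapply(seq_len(ne), function(e) rd(sprintf("megre_echo%02d_mag", e)))
  phs <- lapply(seq_len(ne), function(e) rd(sprintf("megre_echo%02d_phase", e)))
  d <- dim(mags[[1]])
  megre <- array(0i, c(d, ne))
  for (e in seq_len(ne))
    megre[, , , e] <- mags[[e]] * exp(1i * phs[[e]])
  list(megre = megre,
       flair = rd("flair"), t1w = rd("t1w"), labels = rd("labels"),
       chi_truth = rd("chi_truth"), r2star_truth = rd("r2star_truth"),
       m0_truth = rd("m0_truth"), brain_mask = rd("brain_mask") > 0.5,
       lesions = utils::read.csv(file.path(dir, "lesions.csv")),
       sidecar = sidecar,
       affines = lapply(sidecar$affines, function(a) matrix(unlist(a), 4, 4,
                                                            byrow = TRUE)))
}
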