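# Digital brain phantom and MR signal simulation.
#
# The phantom is a nested-ellipsoid "brain" on the ME-GRE grid: a cortical
# grey-matter shell around a white-matter interior containing two
# CSF-filled ventricles and two deep grey nuclei. Silent cerebral infarcts
# are modelled as small ellipsoids inside white matter with user-set
# susceptibility / R2* offsets and FLAIR / T1w contrast behaviour. Every
# downstream stage (field fitting, dipole inversion, segmentation,
# statistics) can be validated against the ground truth stored here.

GAMMA_BAR_MHZ_PER_T <- 42.577  # proton gyromagnetic ratio / 2pi

#' Hz per ppm of field shift at a given B0
#' @noRd
hz_per_ppm <- function(b0_tesla) GAMMA_BAR_MHZ_PER_T * b0_tesla

#' ME-GRE acquisition protocol
#'
#' Bundles the acquisition parameters of the multi-echo gradient-echo
#' sequence: 7 echoes starting at 3 ms with 4 ms spacing at 3 T, 1.15 mm
#' isotropic voxels by default.
#'
#' @param b0_tesla Main field strength in tesla.
#' @param b0_direction Unit vector of the main field in grid coordinates.
#' @param echo_times_ms Strictly increasing echo times in milliseconds.
#' @param voxel_size_mm Voxel dimensions in mm (length 3).
#' @param n_coils Number of receive coils (>= 1).
#' @param snr Signal-to-noise ratio of the first-echo white-matter
#'   magnitude; `Inf` simulates a noiseless acquisition.
#' @param seed Integer seed governing all noise draws of the simulation.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(b0_tesla = 3.0,
                                 b0_direction = c(0, 0, 1),
                                 echo_times_ms = seq(3, 27, by = 4),
                                 voxel_size_mm = c(1.15, 1.15, 1.15),
                                 n_coils = 1L,
                                 snr = Inf,
                                 seed = 1L) {
  if (length(echo_times_ms) < 1) stop("echo list empty")
  if (any(diff(echo_times_ms) <= 0)) stop("echo_times must be strictly increasing")
  nb <- sqrt(sum(b0_direction^2))
  if (abs(nb - 1) > 1e-6) stop("b0_direction must be a unit vector")
  if (n_coils < 1) stop("n_coils must be >= 1")
  if (!(snr > 0)) stop("snr must be > 0")
  structure(list(b0_tesla = b0_tesla,
                 b0_direction = b0_direction / nb,
                 echo_times_ms = echo_times_ms,
                 voxel_size_mm = rep(voxel_size_mm, length.out = 3),
                 n_coils = as.integer(n_coils),
                 snr = snr, seed = as.integer(seed)),
            class = "acquisition_protocol")
}

#' Ellipsoidal lesion specification
#'
#' @param center Voxel coordinates (0-based) of the lesion centre on the
#'   phantom grid.
#' @param semi_axes Ellipsoid semi-axes in mm (all > 0).
#' @param delta_chi Susceptibility offset vs surrounding white matter (ppm).
#' @param delta_r2star R2* offset vs white matter (1/s).
#' @param flair_contrast Lesion FLAIR intensity as a multiple of the mean
#'   cortical FLAIR intensity (> 1.02 makes the lesion hyperintense under
#'   the segmentation threshold).
#' @param t1_pass_fraction Fraction of lesion voxels rendered hypointense
#'   on T1w (i.e. generated below the 1.02 x cortical-mean threshold).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, semi_axes, delta_chi = 0.0086,
                        delta_r2star = -2.5, flair_contrast = 1.25,
                        t1_pass_fraction = 1) {
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0")
  if (t1_pass_fraction < 0 || t1_pass_fraction > 1)
    stop("t1_pass_fraction must be in [0, 1]")
  structure(list(center = center, semi_axes = rep(semi_axes, length.out = 3),
                 delta_chi = delta_chi, delta_r2star = delta_r2star,
                 flair_contrast = flair_contrast,
                 t1_pass_fraction = t1_pass_fraction),
            class = "lesion_spec")
}

#' Default tissue parameter table
#'
#' Susceptibility offsets (ppm, referenced to cortical GM), R2* (1/s) and
#' proton-density-like M0 per tissue class. White-matter R2* defaults to
#' the normal-appearing-white-matter group mean; lesion defaults sit on the
#' corresponding lesion group means so that recovery tests target those
#' values.
#' @return Named list of per-tissue `chi` (ppm), `r2star` (1/s), `m0`,
#'   `flair` and `t1w` intensities.
#' @export
tissue_defaults <- function() {
  list(
    chi    = c(wm = -0.03, gm = 0.0,  csf = 0.02, dgm = 0.05),
    r2star = c(wm = 19.2,  gm = 15.0, csf = 1.0,  dgm = 30.0),
    m0     = c(wm = 800,   gm = 850,  csf = 1000, dgm = 850),
    flair  = c(wm = 100,   gm = 120,  csf = 30,   dgm = 115),
    t1w    = c(wm = 100,   gm = 70,   csf = 30,   dgm = 75),
    lesion_flair_fail = NA,           # lesion FLAIR from flair_contrast
    t1w_lesion_pass = 55,             # hypointense (below 1.02 x GM mean)
    t1w_lesion_fail = 95              # WM-like, above the T1w threshold
  )
}

# tissue label codes
LBL <- c(background = 0L, wm = 1L, gm = 2L, csf = 3L, dgm = 4L)

#' @noRd
ellipsoid_mask <- function(dim3, center_vox, semi_axes_mm, voxel_mm) {
  g <- grid_coords(dim3)
  q <- ((g[, 1] - center_vox[1]) * voxel_mm[1] / semi_axes_mm[1])^2 +
       ((g[, 2] - center_vox[2]) * voxel_mm[2] / semi_axes_mm[2])^2 +
       ((g[, 3] - center_vox[3]) * voxel_mm[3] / semi_axes_mm[3])^2
  array(q <= 1, dim3)
}

#' Build the digital brain phantom
#'
#' @param dim Grid dimensions (length 3, each >= 32); this is the ME-GRE
#'   grid the quantitative maps live on.
#' @param voxel_size_mm Voxel size in mm.
#' @param lesions List of [lesion_spec()] objects; all lesion voxels must
#'   fall inside white matter.
#' @param tissues Tissue parameter table, see [tissue_defaults()].
#' @param merge_overlaps How to treat overlapping lesion specs: `"error"`
#'   (default) rejects them, `"merge"` assigns overlapping voxels to the
#'   earlier lesion so no voxel is double-labelled.
#' @return An object of class `tissue_phantom` with fields `label_grid`,
#'   `chi_map` (ppm), `r2star_map` (1/s), `m0_map`, `brain_mask`,
#'   `lesion_masks`, `lesions`, `voxel_size`, `affine`.
#' @export
build_phantom <- function(dim = c(64, 64, 64),
                          voxel_size_mm = c(1.15, 1.15, 1.15),
                          lesions = list(),
                          tissues = tissue_defaults(),
                          merge_overlaps = "error") {
  dim <- as.integer(rep(dim, length.out = 3))
  if (any(dim < 32)) stop("grid must be at least 32^3")
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  c0 <- (dim - 1) / 2
  fov <- dim * voxel_size_mm

  lab <- array(LBL[["background"]], dim)
  brain <- ellipsoid_mask(dim, c0, 0.44 * fov, voxel_size_mm)
  inner <- ellipsoid_mask(dim, c0, 0.37 * fov, voxel_size_mm)
  lab[brain] <- LBL[["gm"]]          # cortical shell
  lab[inner] <- LBL[["wm"]]
  # two lateral ventricles, slightly anterior/posterior of centre
  for (s in c(-1, 1)) {
    vc <- c0 + s * c(0.08, 0.04, 0) * dim
    vent <- ellipsoid_mask(dim, vc, c(0.05, 0.12, 0.10) * fov, voxel_size_mm)
    lab[vent & inner] <- LBL[["csf"]]
  }
  # deep grey nuclei lateral to the ventricles
  for (s in c(-1, 1)) {
    dc <- c0 + s * c(0.17, 0.0, 0) * dim
    nuc <- ellipsoid_mask(dim, dc, c(0.045, 0.07, 0.06) * fov, voxel_size_mm)
    lab[nuc & lab == LBL[["wm"]]] <- LBL[["dgm"]]
  }

  wm <- lab == LBL[["wm"]]
  lesion_masks <- list()
  taken <- array(FALSE, dim)
  for (i in seq_along(lesions)) {
    ls <- lesions[[i]]
    m <- ellipsoid_mask(dim, ls$center, ls$semi_axes, voxel_size_mm)
    if (any(m & !wm))
      stop(sprintf("lesion %d extends outside white matter", i))
    if (any(m & taken)) {
      if (identical(merge_overlaps, "merge")) {
        m <- m & !taken
      } else {
        stop(sprintf("lesion %d overlaps an earlier lesion", i))
      }
    }
    taken <- taken | m
    lesion_masks[[i]] <- m
  }

  tis <- tissues
  chi <- array(0, dim); r2s <- array(0, dim); m0 <- array(0, dim)
  for (t in c("wm", "gm", "csf", "dgm")) {
    sel <- lab == LBL[[t]]
    chi[sel] <- tis$chi[[t]]; r2s[sel] <- tis$r2star[[t]]
    m0[sel]  <- tis$m0[[t]]
  }
  for (i in seq_along(lesion_masks)) {
    m <- lesion_masks[[i]]
    chi[m] <- tis$chi[["wm"]] + lesions[[i]]$delta_chi
    r2s[m] <- tis$r2star[["wm"]] + lesions[[i]]$delta_r2star
  }

  affine <- diag(c(voxel_size_mm, 1))
  structure(list(label_grid = lab, chi_map = chi, r2star_map = r2s,
                 m0_map = m0, brain_mask = brain,
                 lesion_masks = lesion_masks, lesions = lesions,
                 tissues = tis, voxel_size = voxel_size_mm, affine = affine),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("tissue_phantom:", paste(dim(x$label_grid), collapse = " x "),
      "grid,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm voxels,",
      length(x$lesions), "lesion(s)\n")
  invisible(x)
}

#' k-space dipole kernel
#'
#' D(k) = 1/3 - k_par^2 / |k|^2 with k_par the component along the main
#' field; D(0) = 0 (zero-mean field convention, equivalent to the
#' sphere-of-Lorentz correction).
#'
#' @param dim Grid dimensions.
#' @param voxel_size_mm Voxel size (mm); controls the k-space sampling.
#' @param b0_direction Unit vector of B0 in grid coordinates.
#' @return 3D array of kernel values in FFT (DC-first) ordering.
#' @export
dipole_kernel <- function(dim, voxel_size_mm = c(1, 1, 1),
                          b0_direction = c(0, 0, 1)) {
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (abs(sqrt(sum(b0_direction^2)) - 1) > 1e-6)
    stop("b0_direction must be a unit vector")
  dim <- as.integer(rep(dim, length.out = 3))
  kx <- fft_freq(dim[1], voxel_size_mm[1])
  ky <- fft_freq(dim[2], voxel_size_mm[2])
  kz <- fft_freq(dim[3], voxel_size_mm[3])
  KX <- array(kx, dim)
  KY <- array(rep(ky, each = dim[1]), dim)
  KZ <- array(rep(kz, each = dim[1] * dim[2]), dim)
  kpar <- KX * b0_direction[1] + KY * b0_direction[2] + KZ * b0_direction[3]
  k2 <- KX^2 + KY^2 + KZ^2
  D <- 1 / 3 - kpar^2 / k2
  D[k2 == 0] <- 0
  D
}

#' Forward dipole field of a susceptibility distribution
#'
#' Convolves the susceptibility map with the unit dipole response in
#' k-space. The grid is zero-padded to twice the field of view before the
#' convolution to suppress wrap-around, then cropped back.
#'
#' @param chi_map 3D susceptibility map in ppm.
#' @param voxel_size_mm Voxel size in mm.
#' @param b0_direction Unit B0 vector.
#' @param pad If `TRUE` (default) zero-pad to 2x the grid.
#' @return Field shift delta-B/B0 in ppm, zero mean over the padded grid.
#' @export
forward_field <- function(chi_map, voxel_size_mm = c(1, 1, 1),
                          b0_direction = c(0, 0, 1), pad = TRUE) {
  if (!all(is.finite(chi_map))) stop("chi_map must be finite")
  d <- dim(chi_map)
  # the uniform component of chi produces no field (D(0) = 0 convention);
  # remove it before padding so the convention survives zero-padding
  chi_map <- chi_map - mean(chi_map)
  dp <- if (pad) 2L * d else d
  D <- dipole_kernel(dp, voxel_size_mm, b0_direction)
  f <- Re(ifftn(fftn(pad_array(chi_map, dp)) * D))
  crop_array(f, d)
}

#' @noRd
coil_sensitivities <- function(dim3, n_coils) {
  if (n_coils == 1)
    return(list(list(mag = array(1, dim3), phase = 0)))
  g <- grid_coords(dim3)
  nx <- (g[, 1] / (dim3[1] - 1)) - 0.5
  ny <- (g[, 2] / (dim3[2] - 1)) - 0.5
  out <- vector("list", n_coils)
  for (c in seq_len(n_coils)) {
    th <- 2 * pi * (c - 1) / n_coils
    # smooth low-order polynomial magnitude peaking toward the coil side
    mag <- 0.6 + 0.8 * (0.5 + nx * cos(th) + ny * sin(th))^2
    out[[c]] <- list(mag = array(mag, dim3), phase = th / 2)
  }
  out
}

#' Simulate the multi-echo gradient-echo acquisition
#'
#' Signal model per voxel and echo:
#' `M0 * exp(-R2* TE) * exp(i (phi0 + 2 pi f TE))` with `f` the dipole
#' field of the phantom susceptibility converted to Hz at the protocol's
#' field strength. Complex Gaussian noise is added to reach the requested
#' first-echo white-matter SNR; all draws are governed by `protocol$seed`.
#'
#' @param truth A `tissue_phantom`.
#' @param protocol An `acquisition_protocol`.
#' @param phi0 Receiver phase offset map (radians) or scalar; default 0.
#' @return Object of class `megre_series`: complex 4D `data`
#'   (x, y, z, echo) — or a list `coil_data` of complex 4D arrays when
#'   `n_coils > 1` — plus `echo_times_ms`, `field_hz` (ground-truth field),
#'   `affine`, `b0_direction`, `protocol`.
#' @export
simulate_megre <- function(truth, protocol, phi0 = 0) {
  stopifnot(inherits(truth, "tissue_phantom"),
            inherits(protocol, "acquisition_protocol"))
  if (length(protocol$echo_times_ms) == 0) stop("echo list empty")
  d <- dim(truth$label_grid)
  delta_ppm <- forward_field(truth$chi_map, truth$voxel_size,
                             protocol$b0_direction)
  f_hz <- delta_ppm * hz_per_ppm(protocol$b0_tesla)
  te_s <- protocol$echo_times_ms / 1000
  ne <- length(te_s)
  if (length(phi0) == 1) phi0 <- array(phi0, d)

  clean <- array(0i, c(d, ne))
  for (e in seq_len(ne)) {
    clean[, , , e] <- truth$m0_map * exp(-truth$r2star_map * te_s[e]) *
      exp(1i * (phi0 + 2 * pi * f_hz * te_s[e]))
  }

  wm <- truth$label_grid == LBL[["wm"]]
  sigma <- if (is.finite(protocol$snr)) {
    mean(Mod(clean[, , , 1])[wm]) / protocol$snr
  } else 0

  sens <- coil_sensitivities(d, protocol$n_coils)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(protocol$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))

  make_noisy <- function(x) {
    if (sigma == 0) return(x)
    x + complex(real = rnorm(length(x), sd = sigma),
                imaginary = rnorm(length(x), sd = sigma))
  }

  out <- list(echo_times_ms = protocol$echo_times_ms,
              field_hz = f_hz, affine = truth$affine,
              b0_direction = protocol$b0_direction, protocol = protocol)
  if (protocol$n_coils == 1) {
    out$data <- make_noisy(clean)
  } else {
    out$coil_data <- lapply(sens, function(s) {
      arr <- clean
      for (e in seq_len(ne))
        arr[, , , e] <- arr[, , , e] * s$mag * exp(1i * s$phase)
      make_noisy(arr)
    })
  }
  structure(out, class = "megre_series")
}

#' @export
print.megre_series <- function(x, ...) {
  arr <- if (!is.null(x$data)) x$data else x$coil_data[[1]]
  cat("megre_series:", paste(dim(arr)[1:3], collapse = " x "), "grid,",
      length(x$echo_times_ms), "echoes,",
      if (!is.null(x$coil_data)) paste(length(x$coil_data), "coils") else "1 coil",
      "\n")
  invisible(x)
}

#' @noRd
structural_grid <- function(fov_mm, voxel_mm) {
  dim3 <- pmax(1L, as.integer(round(fov_mm / voxel_mm)))
  list(dim = dim3, voxel = voxel_mm, affine = diag(c(voxel_mm, 1)))
}

#' Resample phantom labels / masks to a structural grid (nearest neighbour)
#' @noRd
labels_on_grid <- function(vol, src_affine, dst_grid) {
  co <- grid_coords(dst_grid$dim)
  world <- affine_apply(dst_grid$affine, co)
  src <- affine_apply(solve(src_affine), world)
  array(sample_volume(vol, src, "nearest"), dst_grid$dim)
}

#' Simulate FLAIR and T1w structural volumes
#'
#' Renders piecewise-constant structural contrasts on their native grids
#' (FLAIR 0.65 x 0.65 x 1 mm, T1w 1 mm isotropic by default) from the
#' phantom labels. Lesion voxels are made FLAIR-hyperintense at
#' `flair_contrast` times the mean cortical intensity; on T1w, exactly
#' `t1_pass_fraction` of each lesion's voxels (up to rounding) are
#' generated below the 1.02 x cortical-mean hypointensity threshold. The
#' realised per-lesion truth masks on both grids are returned for
#' segmentation oracles.
#'
#' @param truth A `tissue_phantom`.
#' @param flair_voxel_mm,t1w_voxel_mm Voxel sizes of the two grids.
#' @param threshold_factor The 1.02 intensity-threshold factor the
#'   segmentation uses; only needed here to place T1w pass/fail voxels on
#'   the correct side of it.
#' @return List with elements `flair`, `t1w` (each: `data`, `dim`, `voxel`,
#'   `affine`, `cortex_mask`, `wm_mask`, plus per-lesion truth masks
#'   `lesion_masks` and for T1w `lesion_pass_masks`), and `transforms`
#'   (grid-to-grid affines to/from the GRE grid).
#' @export
simulate_structural <- function(truth,
                                flair_voxel_mm = c(0.65, 0.65, 1.0),
                                t1w_voxel_mm = c(1.0, 1.0, 1.0),
                                threshold_factor = 1.02) {
  stopifnot(inherits(truth, "tissue_phantom"))
  tis <- truth$tissues
  if (tis$t1w[["wm"]] < tis$t1w[["gm"]])
    warning("T1w white matter below cortex: unexpected tissue ordering")
  d <- dim(truth$label_grid)
  fov <- d * truth$voxel_size
  render <- function(grid, intensities) {
    lab <- labels_on_grid(truth$label_grid, truth$affine, grid)
    img <- array(0, grid$dim)
    for (t in c("wm", "gm", "csf", "dgm"))
      img[lab == LBL[[t]]] <- intensities[[t]]
    list(lab = lab, img = img)
  }

  fg <- structural_grid(fov, rep(flair_voxel_mm, length.out = 3))
  tg <- structural_grid(fov, rep(t1w_voxel_mm, length.out = 3))
  fl <- render(fg, tis$flair)
  t1 <- render(tg, tis$t1w)

  cortex_mean_flair <- tis$flair[["gm"]]
  cortex_mean_t1 <- tis$t1w[["gm"]]

  les_flair <- list(); les_t1_all <- list(); les_t1_pass <- list()
  for (i in seq_along(truth$lesion_masks)) {
    ls <- truth$lesions[[i]]
    mf <- labels_on_grid(truth$lesion_masks[[i]] * 1, truth$affine, fg) > 0.5
    fl$img[mf] <- ls$flair_contrast * cortex_mean_flair
    les_flair[[i]] <- mf

    mt <- labels_on_grid(truth$lesion_masks[[i]] * 1, truth$affine, tg) > 0.5
    vox <- which(mt)
    k <- round(ls$t1_pass_fraction * length(vox))
    pass <- vox[seq_len(k)]            # deterministic: array order
    failv <- setdiff(vox, pass)
    t1$img[pass] <- tis$t1w_lesion_pass
    t1$img[failv] <- tis$t1w_lesion_fail
    les_t1_all[[i]] <- mt
    pm <- array(FALSE, tg$dim); pm[pass] <- TRUE
    les_t1_pass[[i]] <- pm
  }

  transforms <- list(
    gre_to_flair = grid_transform(list(dim = d, affine = truth$affine),
                                  list(dim = fg$dim, affine = fg$affine)),
    flair_to_t1w = grid_transform(list(dim = fg$dim, affine = fg$affine),
                                  list(dim = tg$dim, affine = tg$affine)),
    t1w_to_gre = grid_transform(list(dim = tg$dim, affine = tg$affine),
                                list(dim = d, affine = truth$affine)),
    flair_to_gre = grid_transform(list(dim = fg$dim, affine = fg$affine),
                                  list(dim = d, affine = truth$affine))
  )

  list(
    flair = list(data = fl$img, dim = fg$dim, voxel = fg$voxel,
                 affine = fg$affine,
                 cortex_mask = fl$lab == LBL[["gm"]],
                 wm_mask = fl$lab == LBL[["wm"]],
                 lesion_masks = les_flair,
                 cortex_mean = cortex_mean_flair),
    t1w = list(data = t1$img, dim = tg$dim, voxel = tg$voxel,
               affine = tg$affine,
               cortex_mask = t1$lab == LBL[["gm"]],
               wm_mask = t1$lab == LBL[["wm"]],
               lesion_masks = les_t1_all,
               lesion_pass_masks = les_t1_pass,
               cortex_mean = cortex_mean_t1),
    transforms = transforms
  )
}
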