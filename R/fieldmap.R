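# Total-field estimation from the multi-echo complex series: coil
# combination, voxelwise non-linear complex fit, Laplacian phase
# unwrapping with congruence restoration, and realignment with B0.

#' Combine per-coil complex echo series
#'
#' Phase-difference coil combination: each coil's constant phase offset is
#' estimated against the first coil from the first-echo images
#' (magnitude-weighted circular mean), removed, and the offset-free coil
#' signals are magnitude-weighted summed. A single-coil series is
#' returned unchanged.
#'
#' @param series `megre_series` with `coil_data` (list of complex 4D
#'   arrays) or single-coil `data`.
#' @return `megre_series` with a combined complex 4D `data` field.
#' @export
combine_coils <- function(series) {
  stopifnot(inherits(series, "megre_series"))
  if (!is.null(series$data)) return(series)
  coils <- series$coil_data
  d <- dim(coils[[1]])
  if (!all(vapply(coils, function(x) identical(dim(x), d), logical(1))))
    stop("mismatched coil grids")
  ref1 <- coils[[1]][, , , 1]
  num <- array(0i, d)
  wsum <- array(0, d[1:3])
  for (c in seq_along(coils)) {
    e1 <- coils[[c]][, , , 1]
    theta <- Arg(sum(e1 * Conj(ref1)))      # constant offset vs coil 1
    w <- Mod(e1)
    arr <- coils[[c]] * exp(-1i * theta)
    for (e in seq_len(d[4])) num[, , , e] <- num[, , , e] + w * arr[, , , e]
    wsum <- wsum + w
  }
  wsum[wsum == 0] <- 1
  for (e in seq_len(d[4])) num[, , , e] <- num[, , , e] / wsum
  out <- series
  out$coil_data <- NULL
  out$data <- num
  out
}

#' Brain mask from first-echo magnitude
#'
#' Otsu threshold, largest 6-connected component, then one
#' dilation-erosion closing pass.
#' @param magnitude 3D first-echo magnitude.
#' @return Logical mask.
#' @export
brain_mask_from_magnitude <- function(magnitude) {
  m <- magnitude > otsu_threshold(as.numeric(magnitude))
  m <- largest_component(m)
  erode6(dilate6(m))
}

#' Non-linear complex fit of the total field
#'
#' Fits the mono-exponential complex signal model
#' `A exp(-R2* TE) exp(i (phi0 + 2 pi f TE))` per voxel by damped
#' Gauss-Newton on the complex residuals. Initialisation uses the
#' log-linear magnitude fit for (A, R2*) and magnitude-squared-weighted
#' phase increments between adjacent echoes for (phi0, f). The returned
#' field is wrapped into the alias-free interval
#' `(-1/(2 dTE), +1/(2 dTE)]` Hz (dTE = smallest echo spacing).
#'
#' @param series Combined `megre_series` (complex 4D `data`).
#' @param mask Optional logical brain mask; derived from the first-echo
#'   magnitude by [brain_mask_from_magnitude()] when absent.
#' @param max_iter,tol Gauss-Newton iteration cap and relative residual
#'   change tolerance.
#' @return Object of class `field_map`: `total_field_hz`, `phi0_rad`,
#'   `residual` (RMS complex misfit per voxel), `mask`, `flags`
#'   (0 converged, 1 fallback to the phase-increment initial estimate,
#'   2 empty voxel), `alias_period_hz`, `iterations`, `residual_path`.
#' @export
fit_field_nonlinear <- function(series, mask = NULL, max_iter = 50,
                                tol = 1e-8) {
  stopifnot(inherits(series, "megre_series"))
  if (is.null(series$data)) series <- combine_coils(series)
  dat <- series$data
  te <- series$echo_times_ms / 1000
  ne <- length(te)
  if (ne < 3) stop("need at least 3 echoes for the non-linear field fit")
  d <- dim(dat)[1:3]
  if (is.null(mask)) mask <- brain_mask_from_magnitude(Mod(dat[, , , 1]))

  idx <- which(mask)
  nv <- length(idx)
  # echoes in columns, masked voxels in rows
  S <- matrix(0i, nv, ne)
  for (e in seq_len(ne)) S[, e] <- dat[, , , e][idx]
  magS <- Mod(S)
  empty <- rowSums(magS) == 0

  # ---- initialisation ----
  # (lnA, R2*) from OLS on log magnitude
  lmag <- log(pmax(magS, 1e-6 * max(magS, 1)))
  tbar <- mean(te); tc <- te - tbar
  den <- sum(tc^2)
  slope <- as.numeric(lmag %*% tc) / den
  lnA <- rowMeans(lmag) - slope * tbar
  r2s0 <- -slope
  # (f, phi0) from weighted phase increments
  dphi_num <- rowSums(S[, -1, drop = FALSE] * Conj(S[, -ne, drop = FALSE]))
  dte <- diff(te)
  omega <- Arg(dphi_num) / mean(dte)
  phi0 <- Arg(rowSums(S * exp(-1i * outer(as.numeric(omega), te))))

  model <- function(lnA, r2s, phi0, omega) {
    exp(outer(as.numeric(lnA), rep(1, ne)) - outer(as.numeric(r2s), te) +
          1i * (outer(as.numeric(phi0), rep(1, ne)) +
                outer(as.numeric(omega), te)))
  }
  rss <- function(M) rowSums(Mod(S - M)^2)

  M <- model(lnA, r2s0, phi0, omega)
  cur <- rss(M)
  fallback_rss <- cur
  flags <- integer(nv)
  flags[empty] <- 2L
  residual_path <- sqrt(mean(cur))
  n_iter <- 0L

  for (it in seq_len(max_iter)) {
    n_iter <- it
    R <- S - M
    m2 <- Mod(M)^2
    # J_k = M * g_k with g = (1, -t, i, i t); JtJ splits into two 2x2
    # blocks (magnitude and phase parameters decouple)
    a11 <- rowSums(m2)
    a12 <- -as.numeric(m2 %*% te)
    a22 <- as.numeric(m2 %*% (te^2))
    cr <- Conj(M) * R
    re_sum <- rowSums(Re(cr)); re_t <- as.numeric(Re(cr) %*% te)
    im_sum <- rowSums(Im(cr)); im_t <- as.numeric(Im(cr) %*% te)
    det_m <- det_p <- a11 * a22 - a12^2
    ok <- det_m > 1e-300
    # mag block: [a11 a12; a12 a22] [dlnA; dR2s] = [re_sum; -re_t]
    d_lnA <- (a22 * re_sum + a12 * re_t) / det_m
    d_r2s <- (-a11 * re_t - a12 * re_sum) / det_m
    # phase block: [a11 -a12; -a12 a22] [dphi0; domega] = [im_sum; im_t]
    d_phi0 <- (a22 * im_sum + a12 * im_t) / det_p
    d_omega <- (a12 * im_sum + a11 * im_t) / det_p
    d_lnA[!ok] <- 0; d_r2s[!ok] <- 0; d_phi0[!ok] <- 0; d_omega[!ok] <- 0

    # damped update: halve the step where the residual would increase
    step <- rep(1, nv)
    for (h in 1:6) {
      M_new <- model(lnA + step * d_lnA, r2s0 + step * d_r2s,
                     phi0 + step * d_phi0, omega + step * d_omega)
      new <- rss(M_new)
      worse <- new > cur & step > 1 / 32
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    accept <- new <= cur
    lnA[accept] <- (lnA + step * d_lnA)[accept]
    r2s0[accept] <- (r2s0 + step * d_r2s)[accept]
    phi0[accept] <- (phi0 + step * d_phi0)[accept]
    omega[accept] <- (omega + step * d_omega)[accept]
    prev <- cur
    cur[accept] <- new[accept]
    M <- model(lnA, r2s0, phi0, omega)
    residual_path <- c(residual_path, sqrt(mean(cur)))
    rel <- abs(sum(prev) - sum(cur)) / max(sum(prev), 1e-300)
    if (rel < tol) break
  }

  # non-convergence fallback: keep the weighted phase-increment estimate
  bad <- cur > fallback_rss * (1 + 1e-12) & !empty
  flags[bad] <- 1L

  dte_min <- min(diff(te))
  f_hz <- wrap_to(omega / (2 * pi), 1 / dte_min)
  f_hz[empty] <- 0; phi0[empty] <- 0

  to_vol <- function(v) { a <- array(0, d); a[idx] <- v; a }
  structure(list(total_field_hz = to_vol(f_hz),
                 phi0_rad = to_vol(wrap_to(phi0, 2 * pi)),
                 residual = to_vol(sqrt(cur / ne)),
                 mask = mask, flags = to_vol(flags),
                 alias_period_hz = 1 / dte_min,
                 iterations = n_iter, residual_path = residual_path),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat("field_map:", paste(dim(x$total_field_hz), collapse = " x "),
      "grid,", sum(x$mask), "masked voxels, alias period",
      signif(x$alias_period_hz, 4), "Hz\n")
  invisible(x)
}

#' Laplacian phase unwrapping with congruence restoration
#'
#' Estimates the unwrapped surface from the spectral Laplacian identity
#' `lap(phi) = cos(phi) lap(sin phi) - sin(phi) lap(cos phi)` (computed on
#' a mirror-padded grid, i.e. Neumann boundaries), then restores exact
#' congruence with the input: the output differs from the input by an
#' integer multiple of the period at every voxel. Disconnected mask
#' components are handled independently (the congruence step is
#' voxelwise) and their count is reported.
#'
#' @param x 3D phase volume in radians, or a field volume when `period`
#'   is set to the field alias period.
#' @param mask Logical mask; voxels outside are returned as zero.
#' @param period Wrap period; `2*pi` for phase, `alias_period_hz` for a
#'   field in Hz.
#' @return List: `unwrapped` (same units as input), `n_components`,
#'   `wrap_counts` (integer multiples applied).
#' @export
unwrap_field <- function(x, mask = NULL, period = 2 * pi) {
  d <- dim(x)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!all(is.finite(x[mask]))) stop("input must be finite inside the mask")
  phase <- x * (2 * pi / period)
  phase[!mask] <- 0
  p <- mirror_pad(phase)
  dp <- dim(p)
  kx <- fft_freq(dp[1]); ky <- fft_freq(dp[2]); kz <- fft_freq(dp[3])
  K2 <- array(kx^2, dp) + array(rep(ky^2, each = dp[1]), dp) +
    array(rep(kz^2, each = dp[1] * dp[2]), dp)
  lap <- function(v) Re(ifftn(fftn(v) * (-K2)))
  invlap <- function(v) {
    F <- fftn(v) / (-K2); F[K2 == 0] <- 0; Re(ifftn(F))
  }
  est <- crop_array(invlap(cos(p) * lap(sin(p)) - sin(p) * lap(cos(p))), d)
  k <- round((est - phase) / (2 * pi))
  out <- (phase + 2 * pi * k) * (period / (2 * pi))
  out[!mask] <- 0
  ncomp <- max(label_components(mask))
  list(unwrapped = out, n_components = ncomp, wrap_counts = k * mask)
}

#' Rotation matrix taking `from` onto `to` (both unit 3-vectors)
#' @noRd
rotation_between <- function(from, to) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (sum(v^2) < 1e-24) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Realign a volume with the main field direction
#'
#' Rotates the grid about its centre so that the output z-axis is
#' parallel to B0. Identity when B0 already lies along z. Masks should be
#' resampled nearest-neighbour, continuous maps trilinear.
#'
#' @param volume 3D array.
#' @param b0_direction Unit vector of B0 in the input grid frame.
#' @param voxel_size_mm Voxel size (mm).
#' @param interpolation `"nearest"` or `"trilinear"`.
#' @param affine Optional current voxel-to-world affine to update.
#' @param inverse Apply the inverse rotation instead.
#' @return List: `volume` (rotated), `rotation` (3x3), `affine` (updated
#'   4x4 or NULL).
#' @export
align_to_b0 <- function(volume, b0_direction, voxel_size_mm = c(1, 1, 1),
                        interpolation = c("trilinear", "nearest"),
                        affine = NULL, inverse = FALSE) {
  interpolation <- match.arg(interpolation)
  b0 <- b0_direction / sqrt(sum(b0_direction^2))
  R <- rotation_between(b0, c(0, 0, 1))
  if (inverse) R <- t(R)
  if (max(abs(R - diag(3))) < 1e-12) {
    return(list(volume = volume, rotation = diag(3), affine = affine))
  }
  d <- dim(volume)
  c0 <- (d - 1) / 2
  co <- grid_coords(d)
  # pull-resample: source coords = R^-1 (target - c) + c, in mm-scaled frame
  vs <- rep(voxel_size_mm, length.out = 3)
  mm <- sweep(co, 2, c0) * rep(vs, each = nrow(co))
  src_mm <- mm %*% R                       # R^-1 = t(R), applied as x %*% R
  src <- sweep(src_mm / rep(vs, each = nrow(co)), 2, c0, "+")
  out <- array(sample_volume(volume * 1, src, interpolation), d)
  if (is.logical(volume)) out <- out > 0.5
  R4 <- diag(4); R4[1:3, 1:3] <- R
  new_affine <- if (!is.null(affine)) affine %*% solve(R4) else NULL
  list(volume = out, rotation = R, affine = new_affine)
}
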