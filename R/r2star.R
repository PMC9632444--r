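# Voxelwise R2* relaxometry: ordinary least squares of log-magnitude on
# echo time, per voxel. R2* = -slope (1/s), M0 = exp(intercept).

#' Log-linear R2* fit
#'
#' Fits `ln S(TE) = ln M0 - R2* TE` per voxel by unweighted ordinary
#' least squares. Magnitudes are floored at 1e-6 times the volume maximum
#' before the log (zero-handling); voxels whose echoes are all at the
#' floor are flagged and returned with R2* = 0.
#'
#' @param magnitude 4D magnitude array (x, y, z, echo) or a
#'   `megre_series` (its modulus is used).
#' @param echo_times_ms Echo times in milliseconds (>= 2).
#' @param mask Optional logical mask; defaults to all voxels.
#' @return Object of class `r2star_map`: `r2star_s_inv`, `m0`,
#'   `r_squared` (per-voxel coefficient of determination), `mask`,
#'   `flags` (1 where all echoes were at the floor).
#' @export
fit_r2star_loglinear <- function(magnitude, echo_times_ms, mask = NULL) {
  if (inherits(magnitude, "megre_series")) {
    if (is.null(magnitude$data)) magnitude <- combine_coils(magnitude)
    echo_times_ms <- magnitude$echo_times_ms
    magnitude <- Mod(magnitude$data)
  }
  te <- echo_times_ms / 1000
  ne <- length(te)
  if (ne < 2) stop("need at least 2 echoes")
  stopifnot(dim(magnitude)[4] == ne)
  d <- dim(magnitude)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)

  idx <- which(mask)
  S <- matrix(0, length(idx), ne)
  for (e in seq_len(ne)) S[, e] <- magnitude[, , , e][idx]
  floor_val <- 1e-6 * max(S, 1e-300)
  flags <- as.integer(rowSums(S > floor_val) == 0)
  L <- log(pmax(S, floor_val))

  tc <- te - mean(te)
  slope <- as.numeric(L %*% tc) / sum(tc^2)
  intercept <- rowMeans(L) - slope * mean(te)
  fitted_ss <- slope^2 * sum(tc^2)
  tot_ss <- rowSums((L - rowMeans(L))^2)
  r2 <- ifelse(tot_ss > 0, pmin(1, pmax(0, fitted_ss / tot_ss)), 0)

  r2s <- -slope
  r2s[flags == 1L] <- 0
  to_vol <- function(v, fill = 0) { a <- array(fill, d); a[idx] <- v; a }
  structure(list(r2star_s_inv = to_vol(r2s),
                 m0 = to_vol(exp(intercept)),
                 r_squared = to_vol(r2),
                 mask = mask, flags = to_vol(flags)),
            class = "r2star_map")
}

#' @export
print.r2star_map <- function(x, ...) {
  v <- x$r2star_s_inv[x$mask]
  cat("r2star_map:", paste(dim(x$r2star_s_inv), collapse = " x "),
      "grid, R2* range [", signif(min(v), 4), ",", signif(max(v), 4),
      "] 1/s\n")
  invisible(x)
}
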