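# Low-level array helpers shared across modules: FFT wrappers, k-space
# coordinates, padding, morphology, connected components and a 3D Euclidean
# distance transform. All grids are 3D arrays indexed [x, y, z]; voxel
# indices are 0-based in world-coordinate computations (voxel-centre
# convention, RAS-like affines).

fftn <- function(x) stats::fft(x)

ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @noRd
fft_freq <- function(n, d = 1) {
  # cycles per unit length, standard FFT ordering (DC first)
  i <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1))
  i / (n * d)
}

#' Zero-pad an array symmetrically up to `dim_out`, content kept in the
#' lower corner block so that cropping is exact.
#' @noRd
pad_array <- function(x, dim_out, value = 0) {
  d <- dim(x)
  stopifnot(all(dim_out >= d))
  out <- array(value, dim_out)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

#' @noRd
crop_array <- function(x, dim_out) {
  x[seq_len(dim_out[1]), seq_len(dim_out[2]), seq_len(dim_out[3]), drop = FALSE]
}

#' Mirror (even) extension of a 3D array to twice its size along each axis;
#' yields Neumann-like boundaries for spectral Laplacian operations.
#' @noRd
mirror_pad <- function(x) {
  d <- dim(x)
  x <- x[c(seq_len(d[1]), rev(seq_len(d[1]))), , , drop = FALSE]
  x <- x[, c(seq_len(d[2]), rev(seq_len(d[2]))), , drop = FALSE]
  x[, , c(seq_len(d[3]), rev(seq_len(d[3]))), drop = FALSE]
}

#' Shift an array by integer offsets with zero fill (no wrap-around).
#' @noRd
shift_array <- function(x, offset) {
  d <- dim(x)
  out <- array(vector(typeof(x), 1), d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      src[[a]] <- seq_len(d[a] - o)
      dst[[a]] <- src[[a]] + o
    } else {
      src[[a]] <- seq(1 - o, d[a])
      dst[[a]] <- seq_len(d[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' 6-neighbourhood binary dilation / erosion (one iteration per call).
#' @noRd
dilate6 <- function(mask) {
  out <- mask
  for (a in 1:3) for (s in c(-1L, 1L)) {
    off <- c(0L, 0L, 0L); off[a] <- s
    out <- out | shift_array(mask, off)
  }
  out
}

#' @noRd
erode6 <- function(mask) !dilate6(!mask)

#' @noRd
dilate_n <- function(mask, n) {
  for (i in seq_len(n)) mask <- dilate6(mask)
  mask
}

#' Otsu's threshold on a numeric vector (256-bin histogram).
#' @noRd
otsu_threshold <- function(v, nbins = 256) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  r[1] + (k / nbins) * diff(r)
}

#' Label connected components of a 3D logical mask (6-connectivity).
#' Returns an integer array; 0 outside the mask.
#' @noRd
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  remaining <- which(mask)
  current <- 0L
  nvox <- prod(d)
  # linear-index offsets of the 6 neighbours, with bounds handled by
  # checking the voxel coordinate along the stepped axis
  while (length(remaining) > 0) {
    current <- current + 1L
    frontier <- remaining[1]
    lab[frontier] <- current
    while (length(frontier) > 0) {
      nxt <- integer(0)
      idx <- arrayInd(frontier, d)
      for (a in 1:3) for (s in c(-1L, 1L)) {
        ok <- idx[, a] + s >= 1L & idx[, a] + s <= d[a]
        if (!any(ok)) next
        step <- s * c(1L, d[1], d[1] * d[2])[a]
        cand <- frontier[ok] + step
        cand <- cand[mask[cand] & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- current
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  lab
}

#' Largest connected component of a logical mask.
#' @noRd
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) <= 1L) return(mask)
  keep <- which.max(tabulate(lab[lab > 0L]))
  lab == keep
}

# --- Euclidean distance transform (Felzenszwalb & Huttenlocher squared-EDT,
# --- separable lower-envelope-of-parabolas passes; supports anisotropic
# --- voxel sizes) ---

#' 1D squared distance transform of a sampled cost f at spacing h.
#' @noRd
edt_1d <- function(f, h = 1) {
  n <- length(f)
  if (n == 1) return(f)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  h2 <- h * h
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2 * h2 * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1] <- q; z[1] <- -Inf; z[2] <- Inf; break }
      } else {
        k <- k + 1L
        v[k] <- q; z[k] <- s; z[k + 1] <- Inf
        break
      }
    }
  }
  out <- numeric(n)
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    p <- v[k]
    out[q] <- h2 * (q - p)^2 + f[p]
  }
  out
}

#' Euclidean distance (in mm) from every voxel to the nearest TRUE voxel of
#' `target`, on an anisotropic grid.
#' @noRd
distance_transform <- function(target, voxel_size = c(1, 1, 1)) {
  d <- dim(target)
  big <- 4 * sum((d * voxel_size)^2)  # finite sentinel for "no source yet"
  f <- array(ifelse(target, 0, big), d)
  for (a in 1:3) {
    f <- apply(f, setdiff(1:3, a), edt_1d, h = voxel_size[a])
    # apply() returns the worked dimension first; restore [x,y,z] order
    f <- aperm(array(f, c(d[a], d[setdiff(1:3, a)])),
               order(c(a, setdiff(1:3, a))))
  }
  sqrt(f)
}

#' Trilinear / nearest-neighbour sampling of a 3D array at fractional
#' 0-based voxel coordinates (matrix n x 3). Out-of-grid points return
#' `fill`.
#' @noRd
sample_volume <- function(vol, coords, mode = c("trilinear", "nearest"),
                          fill = 0) {
  mode <- match.arg(mode)
  d <- dim(vol)
  n <- nrow(coords)
  out <- rep(fill, n)
  if (mode == "nearest") {
    ijk <- round(coords) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
          ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
          ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    lin <- (ijk[ok, 3] - 1) * d[1] * d[2] + (ijk[ok, 2] - 1) * d[1] + ijk[ok, 1]
    out[ok] <- vol[lin]
    return(out)
  }
  lo <- floor(coords)
  fr <- coords - lo
  ok <- lo[, 1] >= 0 & lo[, 1] <= d[1] - 1 &
        lo[, 2] >= 0 & lo[, 2] <= d[2] - 1 &
        lo[, 3] >= 0 & lo[, 3] <= d[3] - 1
  # clamp the upper corner so boundary voxels interpolate against themselves
  acc <- numeric(sum(ok))
  lo_ok <- lo[ok, , drop = FALSE]
  fr_ok <- fr[ok, , drop = FALSE]
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- pmin(lo_ok[, 1] + cx, d[1] - 1) + 1
    iy <- pmin(lo_ok[, 2] + cy, d[2] - 1) + 1
    iz <- pmin(lo_ok[, 3] + cz, d[3] - 1) + 1
    w <- (if (cx == 1) fr_ok[, 1] else 1 - fr_ok[, 1]) *
         (if (cy == 1) fr_ok[, 2] else 1 - fr_ok[, 2]) *
         (if (cz == 1) fr_ok[, 3] else 1 - fr_ok[, 3])
    lin <- (iz - 1) * d[1] * d[2] + (iy - 1) * d[1] + ix
    acc <- acc + w * vol[lin]
  }
  out[ok] <- acc
  out
}

#' 0-based voxel-centre coordinates of every voxel of a grid, n x 3.
#' @noRd
grid_coords <- function(dim3) {
  as.matrix(expand.grid(x = 0:(dim3[1] - 1), y = 0:(dim3[2] - 1),
                        z = 0:(dim3[3] - 1)))
}

#' Apply a 4x4 affine to n x 3 coordinates.
#' @noRd
affine_apply <- function(affine, coords) {
  stopifnot(ncol(coords) == 3)
  t(affine[1:3, 1:3] %*% t(coords) + affine[1:3, 4])
}

#' Wrap values into the half-open interval (-p/2, p/2].
#' @noRd
wrap_to <- function(x, period) {
  x - period * ceiling(x / period - 0.5)
}
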