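# Shared fixtures. Heavy objects are memoised so the standard phantom run
# is executed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# coordinates and radius-squared helper for sphere fixtures
sphere_chi <- function(n, radius, value = 0.1, center = NULL) {
  if (is.null(center)) center <- rep((n - 1) / 2, 3)
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  r2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  chi <- array(0, c(n, n, n))
  chi[r2 <= radius^2] <- value
  list(chi = chi, r2 = array(r2, c(n, n, n)))
}

# minimal synthetic multi-echo series from explicit per-voxel parameters
synthetic_series <- function(dim3 = c(6, 6, 4), f_hz = 10, phi0 = 0.5,
                             r2star = 25, m0 = 1000,
                             echo_times_ms = seq(3, 27, by = 4),
                             snr = Inf, seed = 1) {
  te <- echo_times_ms / 1000
  arr <- array(0i, c(dim3, length(te)))
  for (e in seq_along(te))
    arr[, , , e] <- m0 * exp(-r2star * te[e]) *
      exp(1i * (phi0 + 2 * pi * f_hz * te[e]))
  if (is.finite(snr)) {
    set.seed(seed)
    sigma <- m0 * exp(-r2star * te[1]) / snr
    arr <- arr + complex(real = rnorm(length(arr), sd = sigma),
                         imaginary = rnorm(length(arr), sd = sigma))
  }
  structure(list(data = arr, echo_times_ms = echo_times_ms,
                 b0_direction = c(0, 0, 1)),
            class = "megre_series")
}

std_config <- function() run_config()

# the standard 10-lesion noiseless phantom run (64^3), shared across files
std_run <- function() memo("std_run", suppressWarnings(run_all(std_config())))

std_truth <- function() memo("std_truth", {
  cfg <- std_config()
  build_phantom(cfg$dim, cfg$voxel_size_mm, cfg$lesions)
})

std_structurals <- function() memo("std_structurals",
                                   simulate_structural(std_truth()))

# paired vectors with exactly prescribed group means (seeded jitter,
# centred so the means are exact)
pairs_with_means <- function(mean_a, mean_b, n, sd = 1, seed = 42) {
  set.seed(seed)
  ja <- rnorm(n, sd = sd); ja <- ja - mean(ja)
  jb <- rnorm(n, sd = sd); jb <- jb - mean(jb)
  list(a = mean_a + ja, b = mean_b + jb)
}
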