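# Phantom construction, dipole forward model and acquisition simulation.

test_that("phantom with no lesions is piecewise constant by tissue", {
  p <- build_phantom(c(32, 32, 32), c(1, 1, 1), lesions = list())
  expect_length(p$lesions, 0)
  tis <- tissue_defaults()
  for (t in c("wm", "gm", "csf", "dgm")) {
    code <- c(wm = 1L, gm = 2L, csf = 3L, dgm = 4L)[[t]]
    sel <- p$label_grid == code
    expect_true(any(sel))
    expect_equal(unique(p$chi_map[sel]), tis$chi[[t]])
    expect_equal(unique(p$r2star_map[sel]), tis$r2star[[t]])
  }
  expect_equal(unique(p$chi_map[p$label_grid == 0L]), 0)
  # brain mask covers all nonzero labels
  expect_true(all(p$brain_mask[p$label_grid > 0L]))
})

test_that("ellipsoid lesion voxel count matches its analytic volume", {
  # semi-axes (3,3,3) mm on a 1 mm grid: (4/3) pi 27 ~ 113 voxels
  ctr <- c(19.5, 24, 15.5)
  p <- build_phantom(c(40, 32, 32), c(1, 1, 1),
                     lesions = list(lesion_spec(ctr, c(3, 3, 3))))
  n <- sum(p$lesion_masks[[1]])
  expect_lt(abs(n - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.15)
  # brute-force oracle: count voxel centres inside the ellipsoid inequality
  g <- expand.grid(x = 0:39, y = 0:31, z = 0:31)
  inside <- ((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2) <= 9
  expect_identical(n, sum(inside))
})

test_that("invalid lesion configurations are rejected", {
  # outside white matter: centred in background corner
  expect_error(
    build_phantom(c(32, 32, 32), c(1, 1, 1),
                  lesions = list(lesion_spec(c(2, 2, 2), c(2, 2, 2)))),
    "lesion 1")
  # overlapping specs: error by default, merged without double labels on demand
  l1 <- lesion_spec(c(22, 22, 15.5), c(2.5, 2.5, 2.5))
  l2 <- lesion_spec(c(21, 21, 15.5), c(2.5, 2.5, 2.5))
  expect_error(build_phantom(c(32, 32, 32), c(1, 1, 1), lesions = list(l1, l2)),
               "overlap")
  p <- build_phantom(c(32, 32, 32), c(1, 1, 1), lesions = list(l1, l2),
                     merge_overlaps = "merge")
  expect_equal(sum(p$lesion_masks[[1]] & p$lesion_masks[[2]]), 0)
  expect_error(lesion_spec(c(1, 1, 1), c(0, 1, 1)), "semi_axes")
})

test_that("forward field of a uniform susceptibility is zero", {
  chi <- array(0.3, c(32, 32, 32))
  f <- forward_field(chi, c(1, 1, 1))
  expect_lt(max(abs(f)), 1e-12)
})

test_that("sphere field matches the analytic dipole solution", {
  n <- 64
  s <- sphere_chi(n, 8, 0.1)
  f <- forward_field(s$chi, c(1, 1, 1))
  c0 <- (n - 1) / 2
  r <- sqrt(s$r2)
  # interior: Lorentz-corrected field is zero
  expect_lt(max(abs(f[r < 6])), 0.02 * 0.1)
  # exterior: delta = (dchi/3)(a/r)^3 (3 cos^2 theta - 1)
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  cz <- (g$z - c0) / pmax(as.numeric(r), 1e-12)
  fan <- array(ifelse(as.numeric(r) <= 8, 0,
                      (0.1 / 3) * (8 / as.numeric(r))^3 * (3 * cz^2 - 1)),
               dim(f))
  ext <- r > 10 & r < n / 2 - 2
  rms <- sqrt(mean((f[ext] - fan[ext])^2))
  expect_lt(rms / max(abs(fan[ext])), 0.05)
  # on-axis spot check: r = 2a, theta = 0 -> (0.1/3)(1/8)(2) ~ 0.00833 ppm
  pt <- f[c0 + 0.5 + 1, c0 + 0.5 + 1, round(c0 + 16) + 1]
  expect_lt(abs(pt - 0.1 / 12) / (0.1 / 12), 0.15)
})

test_that("forward field is linear and zero-mean", {
  set.seed(11)
  a <- array(rnorm(24^3, sd = 0.01), c(24, 24, 24))
  b <- array(rnorm(24^3, sd = 0.01), c(24, 24, 24))
  fa <- forward_field(a, c(1, 1, 1)); fb <- forward_field(b, c(1, 1, 1))
  fab <- forward_field(2 * a - 3 * b, c(1, 1, 1))
  expect_equal(fab, 2 * fa - 3 * fb, tolerance = 1e-10)
  # zero-mean convention is exact on the convolution grid
  expect_lt(abs(mean(forward_field(a, c(1, 1, 1), pad = FALSE))), 1e-12)
})

test_that("ME-GRE signal follows the closed-form model", {
  p <- build_phantom(c(32, 32, 32), c(1.15, 1.15, 1.15), lesions = list())
  # chi = 0 everywhere, phi0 = 0 -> phase identically zero
  p0 <- p; p0$chi_map[] <- 0
  prot <- acquisition_protocol(snr = Inf)
  s <- simulate_megre(p0, prot)
  expect_lt(max(abs(Arg(s$data))), 1e-12)
  # magnitude: M0 exp(-R2* TE); WM voxel at TE = 3 ms with R2* = 19.2
  wm <- p$label_grid == 1L
  m0_wm <- tissue_defaults()$m0[["wm"]]
  mag1 <- Mod(s$data[, , , 1])[wm]
  expect_equal(unique(round(mag1, 6)),
               round(m0_wm * exp(-19.2 * 0.003), 6))
  expect_equal(m0_wm * exp(-19.2 * 0.003), 0.944 * m0_wm,
               tolerance = 1e-4)
})

test_that("simulation noise is seeded, reproducible and correctly scaled", {
  p <- build_phantom(c(64, 64, 64), c(1.15, 1.15, 1.15), lesions = list())
  prot <- acquisition_protocol(snr = 50, seed = 9)
  s1 <- simulate_megre(p, prot)
  s2 <- simulate_megre(p, prot)
  expect_identical(s1$data, s2$data)
  s3 <- simulate_megre(p, acquisition_protocol(snr = 50, seed = 10))
  expect_false(identical(s1$data, s3$data))
  # empirical SNR within 5% of requested on a >= 64^3 grid
  clean <- simulate_megre(p, acquisition_protocol(snr = Inf))
  noise <- Re(s1$data[, , , 1] - clean$data[, , , 1])
  wm <- p$label_grid == 1L
  snr_emp <- mean(Mod(clean$data[, , , 1])[wm]) / sd(noise)
  expect_lt(abs(snr_emp - 50) / 50, 0.05)
  expect_error(acquisition_protocol(echo_times_ms = numeric(0)), "empty")
  expect_error(acquisition_protocol(b0_direction = c(0, 0, 2)), "unit")
})

test_that("structural contrasts honour the lesion contrast bookkeeping", {
  truth <- std_truth()
  st <- std_structurals()
  # every lesion voxel is FLAIR-hyperintense by construction
  thr <- 1.02 * st$flair$cortex_mean
  for (m in st$flair$lesion_masks)
    if (any(m)) expect_true(all(st$flair$data[m] >= thr))
  # t1_pass_fraction = 0 -> no hypointense voxels; = 1 -> all
  t1_thr <- 1.02 * st$t1w$cortex_mean
  fr <- vapply(truth$lesions, function(l) l$t1_pass_fraction, 0)
  for (i in seq_along(fr)) {
    n_all <- sum(st$t1w$lesion_masks[[i]])
    n_pass <- sum(st$t1w$lesion_pass_masks[[i]])
    expect_lte(abs(n_pass - round(fr[i] * n_all)), 1)
    below <- st$t1w$lesion_masks[[i]] & (st$t1w$data <= t1_thr)
    expect_identical(which(below), which(st$t1w$lesion_pass_masks[[i]]))
  }
  # fraction-0.5 lesion retains ~50% of its voxels under the T1w threshold
  i5 <- which(abs(fr - 0.5) < 1e-9)[1]
  expect_equal(sum(st$t1w$lesion_pass_masks[[i5]]),
               round(0.5 * sum(st$t1w$lesion_masks[[i5]])))
})

test_that("inverted T1w tissue ordering triggers a warning", {
  tis <- tissue_defaults()
  tis$t1w[["wm"]] <- 50   # below cortex: unexpected ordering
  p <- build_phantom(c(32, 32, 32), c(1.15, 1.15, 1.15), lesions = list(),
                     tissues = tis)
  expect_warning(simulate_structural(p), "ordering")
})

test_that("dataset round-trips exactly through NIfTI + sidecar", {
  dir <- file.path(tempdir(), "qsmsci_ds")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- run_config(dim = c(32, 32, 32), lesions = list(
    lesion_spec(c(22, 22, 15.5), c(2.5, 2.5, 2.5), t1_pass_fraction = 0.5)))
  truth <- build_phantom(cfg$dim, cfg$voxel_size_mm, cfg$lesions)
  prot <- acquisition_protocol(snr = 40, seed = 5)
  series <- simulate_megre(truth, prot)
  st <- simulate_structural(truth)
  man <- write_dataset(truth, series, st, dir)
  # one magnitude + one phase file per echo
  expect_length(man$megre, 2 * length(series$echo_times_ms))
  back <- read_dataset(dir)
  expect_equal(back$megre, series$data, tolerance = 1e-12)
  expect_equal(back$flair, st$flair$data)
  expect_equal(back$chi_truth, truth$chi_map)
  expect_equal(back$affines$gre, truth$affine)
  expect_equal(nrow(back$lesions), length(truth$lesions))
})
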