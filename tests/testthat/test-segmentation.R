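# Threshold-based SCI definitions, contralateral mirroring, depth and
# lobe classification.

test_that("cortical mean is the arithmetic mean over the cortex mask", {
  img <- array(100, c(8, 8, 4))
  m <- array(FALSE, c(8, 8, 4)); m[2:5, 2:5, 2] <- TRUE
  expect_equal(cortical_mean(img, m), 100)
  img[m][1:8] <- 80; img[m][9:16] <- 120
  expect_equal(cortical_mean(img, m), 100)
  expect_error(cortical_mean(img, array(FALSE, c(8, 8, 4))), "empty")
})

test_that("FLAIR threshold keeps the boundary and excludes dim seeds", {
  img <- array(90, c(10, 10, 4))
  seed <- array(FALSE, c(10, 10, 4)); seed[4:6, 4:6, 2] <- TRUE
  img[4, 4, 2] <- 1.02 * 100          # exactly at threshold: retained
  img[5, 5, 2] <- 110
  roi <- apply_flair_threshold(seed, img, 100)
  expect_false(roi$excluded)
  expect_true(roi$mask[4, 4, 2])
  expect_true(roi$mask[5, 5, 2])
  expect_equal(sum(roi$mask), 2)
  # all seed voxels below threshold: excluded with reason
  dim_img <- array(0.9 * 100, c(10, 10, 4))
  roi2 <- apply_flair_threshold(seed, dim_img, 100)
  expect_true(roi2$excluded)
  expect_match(roi2$reason, "hyperintense")
})

test_that("phantom FLAIR retention equals the generator's hyperintense count", {
  st <- std_structurals()
  cm <- cortical_mean(st$flair$data, st$flair$cortex_mask)
  for (i in seq_along(st$flair$lesion_masks)) {
    seed <- st$flair$lesion_masks[[i]]
    if (!any(seed)) next
    seed_d <- seed
    for (k in 1:2) {  # generous seed, as drawn around the visible lesion
      grown <- array(FALSE, dim(seed_d))
      for (a in 1:3) for (s in c(-1, 1)) {
        idx <- which(seed_d, arr.ind = TRUE)
        idx[, a] <- pmin(pmax(idx[, a] + s, 1), dim(seed_d)[a])
        grown[idx] <- TRUE
      }
      seed_d <- seed_d | grown
    }
    roi <- apply_flair_threshold(seed_d, st$flair$data, cm)
    expect_equal(sum(roi$mask), sum(seed))
  }
})

test_that("T1w threshold retains the generated pass fraction", {
  truth <- std_truth()
  st <- std_structurals()
  cm_t1 <- cortical_mean(st$t1w$data, st$t1w$cortex_mask)
  fr <- vapply(truth$lesions, function(l) l$t1_pass_fraction, 0)
  i5 <- which(abs(fr - 0.5) < 1e-9)[1]
  roi <- apply_t1w_threshold(st$t1w$lesion_masks[[i5]], st$t1w$data, cm_t1)
  expect_equal(sum(roi$mask), round(0.5 * sum(st$t1w$lesion_masks[[i5]])))
  # lesion brighter than the threshold everywhere: does not persist
  bright <- array(200, dim(st$t1w$data))
  roi2 <- apply_t1w_threshold(st$t1w$lesion_masks[[i5]], bright, cm_t1)
  expect_true(roi2$excluded)
  expect_match(roi2$reason, "persist")
  # persistence count across the fixture equals the brute-force count
  persists <- vapply(seq_along(fr), function(i) {
    m <- st$t1w$lesion_masks[[i]]
    sum(m & st$t1w$data <= 1.02 * cm_t1) >= 1
  }, TRUE)
  expect_equal(sum(persists), sum(round(fr * vapply(
    st$t1w$lesion_masks, sum, 0L)) >= 1))
})

test_that("size gate measures the greatest axis-aligned extent in mm", {
  m <- array(FALSE, c(10, 10, 10)); m[3:5, 4, 4] <- TRUE
  g <- size_gate(m, c(1.15, 1.15, 1.15))
  expect_equal(g$greatest_dimension_mm, 3 * 1.15)
  expect_true(g$pass)                    # 3.45 mm
  m2 <- array(FALSE, c(10, 10, 10)); m2[3:4, 4, 4] <- TRUE
  expect_false(size_gate(m2, c(1, 1, 1))$pass)   # 2 mm
  m3 <- array(FALSE, c(10, 10, 10)); m3[3, 3, 2:5] <- TRUE
  expect_true(size_gate(m3, c(0.65, 0.65, 1))$pass)  # 4 mm line
})

test_that("threshold definitions nest and tighten monotonically", {
  st <- std_structurals()
  cm <- cortical_mean(st$flair$data, st$flair$cortex_mask)
  cm_t1 <- cortical_mean(st$t1w$data, st$t1w$cortex_mask)
  tr <- std_run()$structurals$transforms$flair_to_t1w
  for (i in seq_along(st$flair$lesion_masks)) {
    seed <- st$flair$lesion_masks[[i]]
    if (!any(seed)) next
    fl <- apply_flair_threshold(seed, st$flair$data, cm)
    expect_true(all(which(fl$mask) %in% which(seed)))
    on_t1 <- apply_affine(fl$mask, tr, "nearest")
    stt <- apply_t1w_threshold(on_t1, st$t1w$data, cm_t1)
    expect_true(all(which(stt$mask) %in% which(on_t1)))
    # raising the threshold factor never increases the retained count
    counts <- vapply(c(1.0, 1.02, 1.1, 1.3),
                     function(fac) sum(apply_flair_threshold(
                       seed, st$flair$data, cm, factor = fac)$mask), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("mirroring reflects across the midline and avoids twin lesions", {
  d <- c(40, 20, 10)
  wm <- array(TRUE, d)
  sci <- array(FALSE, d); sci[30:32, 8:10, 4:5] <- TRUE
  # clean contralateral WM: pure reflection, no shift
  res <- mirror_nawm(lesion_roi(sci, "GRE"), wm, list(sci))
  expect_false(res$excluded)
  expect_equal(res$shift, c(0, 0))
  expect_equal(sum(res$nawm$mask), sum(sci))
  ref <- array(FALSE, d); ref[9:11, 8:10, 4:5] <- TRUE   # 1-based: x -> 41 - x
  expect_identical(which(res$nawm$mask), which(ref))
  # a twin lesion at the mirrored site forces a disjoint shifted position
  twin <- ref
  res2 <- mirror_nawm(lesion_roi(sci, "GRE"), wm, list(sci, twin))
  expect_false(res2$excluded)
  expect_gt(sum(abs(res2$shift)), 0)
  expect_equal(sum(res2$nawm$mask & twin), 0)
  expect_equal(sum(res2$nawm$mask), sum(sci))
  # no valid position: WM too small on the contralateral side
  wm2 <- wm; wm2[1:20, , ] <- FALSE
  res3 <- mirror_nawm(lesion_roi(sci, "GRE"), wm2, list(sci), max_shift = 5)
  expect_true(res3$excluded)
})

test_that("depth classes partition white matter with the stated fractions", {
  d <- c(40, 12, 12)
  cortex <- array(FALSE, d); cortex[1:2, , ] <- TRUE
  wm <- array(FALSE, d); wm[4:37, , ] <- TRUE
  vent <- array(FALSE, d); vent[39:40, , ] <- TRUE
  dm <- classify_wm_depth(wm, cortex, vent, c(1, 1, 1))
  # adjacent to the ventricle: periventricular
  expect_equal(dm$labels[37, 6, 6], "periventricular")
  # classes are disjoint and cover WM
  lab <- dm$labels[wm]
  expect_false(any(is.na(lab)))
  expect_true(all(is.na(dm$labels[!wm])))
  frac_pv <- mean(lab == "periventricular")
  expect_gt(frac_pv, 0.02); expect_lt(frac_pv, 0.09)  # 5% +- discretization
  frac_jc <- mean(lab == "juxtacortical")
  expect_gt(frac_jc, 0.18); expect_lt(frac_jc, 0.32)  # 25% +- discretization
  expect_error(classify_wm_depth(wm, array(FALSE, d), vent), "empty")
  expect_error(classify_wm_depth(wm | cortex, cortex, vent), "disjoint")
  # the literal distance-map reading selects cortex-distal voxels instead
  dm2 <- classify_wm_depth(wm, cortex, vent, c(1, 1, 1), reading = "distance")
  jc2 <- which(dm2$labels == "juxtacortical", arr.ind = TRUE)
  jc1 <- which(dm$labels == "juxtacortical", arr.ind = TRUE)
  expect_gt(mean(jc2[, 1]), mean(jc1[, 1]))
})

test_that("lobe assignment is by majority vote with ties to other", {
  d <- c(10, 10, 4)
  atlas <- array("parietal", d); atlas[, 6:10, ] <- "frontal"
  m <- array(FALSE, d); m[3:4, 7:8, 2] <- TRUE
  expect_equal(assign_lobe(m, atlas), "frontal")
  m2 <- array(FALSE, d); m2[3, 4:8, 2] <- TRUE   # 3 frontal, 2 parietal
  expect_equal(assign_lobe(m2, atlas), "frontal")
  m3 <- array(FALSE, d); m3[3, 4:7, 2] <- TRUE   # exact 2/2 split
  expect_equal(assign_lobe(m3, atlas), "other")
  outside <- array(FALSE, d); outside[1, 1, 1] <- TRUE
  expect_equal(assign_lobe(outside, array(NA_character_, d)), "other")
})
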