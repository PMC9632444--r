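# ROI summaries and the statistical layer.

test_that("roi_means reduces to the mask means with depth breakdowns", {
  mp <- array(3.5, c(10, 10, 4))
  sci <- array(FALSE, dim(mp)); sci[2:3, 2:3, 2] <- TRUE
  nawm <- array(FALSE, dim(mp)); nawm[7:8, 7:8, 2] <- TRUE
  r <- roi_means(mp, sci, nawm)
  expect_equal(r$mean_sci, 3.5); expect_equal(r$mean_nawm, 3.5)
  expect_equal(r$delta, 0)
  expect_error(roi_means(mp, array(FALSE, dim(mp)), nawm), "empty")
  # lesion split across two depth classes: hand-computed means
  mp2 <- mp; mp2[2, 2:3, 2] <- 10; mp2[3, 2:3, 2] <- 20
  labs <- array(NA_character_, dim(mp))
  labs[2, , ] <- "deep"; labs[3, , ] <- "juxtacortical"
  dm <- structure(list(labels = labs), class = "depth_map")
  r2 <- roi_means(mp2, sci, nawm, dm)
  bd <- r2$by_depth[order(r2$by_depth$depth), ]
  expect_equal(bd$mean_sci, c(10, 20))
  expect_equal(bd$n_voxels, c(2L, 2L))
})

test_that("paired delta reproduces printed-mean arithmetic and hand t-tests", {
  p <- pairs_with_means(-0.0067, -0.0153, n = 211, sd = 0.01)
  out <- paired_delta(p$a, p$b)
  expect_equal(out$delta, 0.0086, tolerance = 1e-9)
  # hand-computed: pairs (1,2),(2,2),(3,5) -> delta -1, t = -sqrt(3)
  h <- paired_delta(c(1, 2, 3), c(2, 2, 5))
  expect_equal(h$delta, -1)
  expect_equal(h$t, -sqrt(3), tolerance = 1e-9)
  expect_equal(h$df, 2)
  # identical pairs: delta 0, flagged degenerate
  z <- paired_delta(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$delta, 0)
  expect_true(z$degenerate)
  expect_true(is.na(z$t))
  expect_error(paired_delta(1:3, 1:4), "equal length")
})

test_that("Bland-Altman bias and limits of agreement are exact", {
  b0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(b0$bias, 0)
  expect_equal(c(b0$loa_lower, b0$loa_upper), c(0, 0))
  # differences {1, -1}: SD = sqrt(2), LOA = +- 2.771
  b <- bland_altman(c(2, 1), c(1, 2))
  expect_equal(b$bias, 0)
  expect_equal(b$sd_diff, sqrt(2))
  expect_equal(b$loa_upper, 1.96 * sqrt(2))
  expect_equal(round(b$loa_upper, 3), 2.772)
  expect_error(bland_altman(1, 1), "at least 2")
  # bias always equals the paired-delta estimate
  set.seed(6)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(bland_altman(x, y)$bias, paired_delta(x, y)$delta)
})

test_that("log-age correction removes exactly the log-age trend", {
  set.seed(9)
  ages <- runif(40, 8, 30)
  # values independent of age: unchanged
  v0 <- rep(5, 40)
  expect_equal(age_correct(v0, ages), v0)
  # exact linear-in-ln(age): collapses to the grand mean
  v1 <- 2 + 3 * log(ages)
  expect_equal(age_correct(v1, ages), rep(mean(v1), 40), tolerance = 1e-9)
  # output uncorrelated with ln(age)
  v2 <- rnorm(40) + 0.5 * log(ages)
  out <- age_correct(v2, ages)
  expect_lt(abs(cor(out, log(ages))), 1e-10)
  expect_warning(age_correct(v2, rep(10, 40)), "constant")
  # synthetic confound: group effect recoverable after correction
  grp <- rep(c(0, 1), each = 50)
  ages2 <- c(runif(50, 8, 15), runif(50, 15, 30))  # group confounded with age
  y <- 1.5 * grp + 2 * log(ages2) + rnorm(100, sd = 0.3)
  yc <- age_correct(y, ages2)
  est <- mean(yc[grp == 1]) - mean(yc[grp == 0])
  # residualizing a shared trend attenuates but must keep the effect within
  # its standard error band
  fit <- stats::lm(y ~ log(ages2) + grp)
  expect_lt(abs(unname(stats::coef(fit)["grp"]) - 1.5),
            2.5 * summary(fit)$coefficients["grp", 2])
})

test_that("sequential ANOVA matches algebra and hand-computed tables", {
  # single two-level factor: F equals t^2 of the equal-variance t-test
  set.seed(12)
  df <- data.frame(v = rnorm(30), g = rep(c("a", "b"), 15))
  a <- anova_effects(df, "v", factors = "g")
  tt <- t.test(v ~ g, data = df, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  # balanced two-factor fixture with brute-force sums of squares
  dd <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  set.seed(13)
  dd$y <- rnorm(12) + 2 * (dd$A == "a2") + 1 * (dd$B == "b2")
  a2 <- anova_effects(dd, "y", factors = c("A", "B"))
  gm <- mean(dd$y)
  ssa <- sum(tapply(dd$y, dd$A, function(v) length(v) * (mean(v) - gm)^2))
  fitA <- lm(y ~ A, dd); fitAB <- lm(y ~ A + B, dd)
  ssb <- sum(residuals(fitA)^2) - sum(residuals(fitAB)^2)
  sse <- sum(residuals(fitAB)^2)
  expect_equal(a2$F[1], (ssa / 1) / (sse / 9), tolerance = 1e-9)
  expect_equal(a2$F[2], (ssb / 1) / (sse / 9), tolerance = 1e-9)
  # aliased factor named in the error
  dd$C <- dd$A
  expect_error(anova_effects(dd, "y", factors = c("A", "C")), "alias")
})

test_that("null-simulation type-I error is nominal for the ANOVA factors", {
  set.seed(77)
  n_rep <- 1000
  p_age <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    df <- data.frame(v = rnorm(40),
                     age_years = runif(40, 8, 35),
                     group = sample(rep(c("SCA", "HC"), 20)),
                     lobe = sample(c("frontal", "parietal"), 40, TRUE),
                     volume_mm3 = exp(rnorm(40, 4)))
    p_age[r] <- anova_effects(df, "v")$p[1]
  }
  hits <- mean(p_age < 0.05)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(hits - 0.05), ci_half + 0.005)
  # p-values approximately uniform under the null
  expect_gt(suppressWarnings(ks.test(p_age, "punif"))$p.value, 0.001)
})

test_that("group comparisons use Student's t or ANOVA + Tukey as appropriate", {
  set.seed(15)
  v <- rnorm(40)
  same <- group_compare(c(v, v), rep(c("a", "b"), each = 40))
  expect_equal(unname(diff(same$means)), 0)
  expect_equal(same$p, 1, tolerance = 1e-9)
  # power: N(0,1) vs N(1,1), n = 50 each, significant in >= 95% of 200 reps
  sig <- vapply(1:200, function(r) {
    set.seed(3000 + r)
    g <- rep(c("a", "b"), each = 50)
    x <- c(rnorm(50), rnorm(50, 1))
    group_compare(x, g)$p < 0.05
  }, TRUE)
  expect_gte(mean(sig), 0.95)
  # three groups: Tukey intervals match the closed form
  set.seed(16)
  g3 <- rep(c("a", "b", "c"), each = 10)
  x3 <- rnorm(30) + rep(c(0, 0.5, 1.5), each = 10)
  out <- group_compare(x3, g3)
  expect_equal(out$method, "anova_tukey")
  mse <- sum(tapply(x3, g3, function(v) sum((v - mean(v))^2))) / 27
  half <- qtukey(0.95, 3, 27) / sqrt(2) * sqrt(mse * 2 / 10)
  dmean <- mean(x3[g3 == "b"]) - mean(x3[g3 == "a"])
  expect_equal(unname(out$tukey["b-a", "diff"]), dmean, tolerance = 1e-9)
  expect_equal(unname(out$tukey["b-a", "upr"] - out$tukey["b-a", "diff"]),
               half, tolerance = 1e-9)
  expect_warning(group_compare(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")),
                 "n < 2")
})

test_that("correlations behave at the extremes and on hand-computed cases", {
  d <- c(0.1, 0.4, 0.9, 1.3)
  expect_equal(cognition_correlate(d, 10 + 3 * d)$r, 1, tolerance = 1e-12)
  expect_error(cognition_correlate(c(1, 2), c(3, 4)), "3 subjects")
  expect_error(cognition_correlate(c(1, 1, 1), c(1, 2, 3)), "variance")
  # hand triple (1,2),(2,1),(3,3) -> r = 0.5
  expect_equal(correlate_paired(c(1, 2, 3), c(2, 1, 3))$r, 0.5)
  # null: |r| significant ~5% of the time
  set.seed(19)
  sig <- vapply(1:1000, function(r)
    cognition_correlate(rnorm(30), rnorm(30))$p < 0.05, TRUE)
  expect_lt(abs(mean(sig) - 0.05), 1.96 * sqrt(0.05 * 0.95 / 1000) + 0.005)
  # shuffled pairing on a large correlated fixture kills the correlation
  set.seed(20)
  a <- rnorm(2000); b <- a + rnorm(2000, sd = 0.1)
  expect_gt(correlate_paired(a, b)$r, 0.99)
  expect_lt(abs(correlate_paired(a, sample(b))$r), 0.08)
})

test_that("statistics are invariant to record order", {
  set.seed(23)
  rec <- data.frame(v = rnorm(40), age_years = runif(40, 8, 30),
                    group = rep(c("SCA", "HC"), 20),
                    lobe = sample(c("frontal", "parietal"), 40, TRUE),
                    volume_mm3 = exp(rnorm(40, 4)))
  perm <- sample(nrow(rec))
  a1 <- anova_effects(rec, "v")
  a2 <- anova_effects(rec[perm, ], "v")
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(paired_delta(rec$v, rec$age_years)$t,
               paired_delta(rec$v[perm], rec$age_years[perm])$t,
               tolerance = 1e-10)
})

test_that("subject summaries average within subject", {
  rec <- data.frame(subject_id = c("s1", "s1", "s2"),
                    group = c("SCA", "SCA", "HC"),
                    age_years = c(10, 10, 20),
                    mean_chi_sci = c(0.01, 0.03, 0.05),
                    mean_chi_nawm = c(0.00, 0.01, 0.02),
                    mean_r2s_sci = c(16, 17, 18),
                    mean_r2s_nawm = c(19, 19, 19))
  s <- subject_summaries(rec)
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_delta_chi[s$subject_id == "s1"], mean(c(0.01, 0.02)))
  expect_equal(s$n_lesions[s$subject_id == "s1"], 2)
})
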