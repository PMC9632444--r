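# Lesion-level ROI summaries and the group statistics: paired t,
# Bland-Altman agreement, log-age correction, sequential ANOVA, group
# comparisons with Tukey HSD, and Pearson correlations. Ordinary model
# fits go through base R (t.test, lm/aov, TukeyHSD, cor.test); lesions
# are treated as independent units throughout.

#' Per-lesion ROI means
#'
#' Arithmetic means of a quantitative map inside a lesion and its
#' mirrored NAWM ROI, with optional per-depth-class means when the
#' lesion spans multiple depth classes.
#'
#' @param map 3D quantitative map (chi in ppm or R2* in 1/s) or an
#'   object with field `chi_ppm` / `r2star_s_inv`.
#' @param sci_mask,nawm_mask Logical masks on the map's grid (nonempty).
#' @param depth_map Optional `depth_map` for per-class means.
#' @return List: `mean_sci`, `mean_nawm`, `delta`, `n_voxels`, and
#'   `by_depth` (data.frame, only for classes the lesion touches).
#' @export
roi_means <- function(map, sci_mask, nawm_mask, depth_map = NULL) {
  if (inherits(map, "susceptibility_map")) map <- map$chi_ppm
  if (inherits(map, "r2star_map")) map <- map$r2star_s_inv
  if (sum(sci_mask) == 0 || sum(nawm_mask) == 0) stop("empty ROI mask")
  out <- list(mean_sci = mean(map[sci_mask]),
              mean_nawm = mean(map[nawm_mask]),
              n_voxels = sum(sci_mask))
  out$delta <- out$mean_sci - out$mean_nawm
  if (!is.null(depth_map)) {
    lab <- depth_map$labels[sci_mask]
    keep <- !is.na(lab)
    if (any(keep)) {
      vals <- map[sci_mask][keep]
      spl <- split(vals, lab[keep])
      out$by_depth <- data.frame(depth = names(spl),
                                 mean_sci = vapply(spl, mean, 0),
                                 n_voxels = vapply(spl, length, 0L),
                                 row.names = NULL)
    }
  }
  out
}

#' Paired SCI-vs-NAWM difference
#'
#' Classical paired t-test of lesion means against their mirrored NAWM
#' means.
#'
#' @param values_sci,values_nawm Equal-length paired numeric vectors.
#' @return List: `delta` (mean difference), `sd_diff`, `t`, `df`, `p`,
#'   `n`, `degenerate` (TRUE when the differences have zero variance, in
#'   which case `t` and `p` are NA).
#' @export
paired_delta <- function(values_sci, values_nawm) {
  if (length(values_sci) != length(values_nawm))
    stop("paired vectors must have equal length")
  n <- length(values_sci)
  if (n < 2) stop("need at least 2 pairs")
  d <- values_sci - values_nawm
  if (stats::sd(d) == 0) {
    return(list(delta = mean(d), sd_diff = 0, t = NA_real_,
                df = n - 1, p = NA_real_, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(values_sci, values_nawm, paired = TRUE)
  list(delta = unname(tt$estimate), sd_diff = stats::sd(d),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n, degenerate = FALSE)
}

#' Bland-Altman agreement
#'
#' @param a,b Paired numeric vectors (n >= 2).
#' @return List: `bias` (= mean(a - b)), `sd_diff` (sample SD),
#'   `loa_lower`, `loa_upper` (bias -/+ 1.96 SD), `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       n = length(a), means = (a + b) / 2, diffs = d)
}

#' Log-age correction
#'
#' Removes the linear effect of log-transformed age by ordinary least
#' squares and restores the grand mean, so that the output is
#' uncorrelated with ln(age).
#'
#' @param values Numeric response vector.
#' @param ages Ages in years (> 0), same length, n >= 3.
#' @return Residualized values plus grand mean. Constant ages trigger a
#'   warning and an identity transform.
#' @export
age_correct <- function(values, ages) {
  if (length(values) != length(ages)) stop("length mismatch")
  if (length(values) < 3) stop("need at least 3 observations")
  if (any(ages <= 0)) stop("ages must be positive")
  if (stats::sd(ages) == 0) {
    warning("constant ages: returning values unchanged")
    return(values)
  }
  fit <- stats::lm(values ~ log(ages))
  unname(stats::residuals(fit)) + mean(values)
}

#' Sequential ANOVA over lesion records
#'
#' Type-I (sequential) sums of squares in the stated factor order,
#' matching the reported factor set: log age, group (sickle cell
#' status), lobe, log lesion volume.
#'
#' @param records Data frame of lesion records.
#' @param response Name of the response column.
#' @param factors Character vector of terms, in order; entries may be
#'   expressions of columns (e.g. `"log(age_years)"`).
#' @param type `"sequential"` (default) or `"type2"`.
#' @return Data.frame with columns `term`, `df`, `F`, `p`.
#' @export
anova_effects <- function(records, response,
                          factors = c("log(age_years)", "group", "lobe",
                                      "log(volume_mm3)"),
                          type = c("sequential", "type2")) {
  type <- match.arg(type)
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " + ")))
  fit <- stats::lm(fml, data = records)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased: ", paste(bad, collapse = ", "))
  }
  if (type == "sequential") {
    a <- stats::anova(fit)
    tab <- a[seq_along(factors), , drop = FALSE]
    data.frame(term = rownames(tab), df = tab$Df, F = tab$`F value`,
               p = tab$`Pr(>F)`, row.names = NULL)
  } else {
    # type-II: each term after all others except interactions
    out <- lapply(seq_along(factors), function(i) {
      reduced <- stats::lm(stats::as.formula(
        paste(response, "~", paste(factors[-i], collapse = " + "))),
        data = records)
      a <- stats::anova(reduced, fit)
      data.frame(term = factors[i], df = a$Df[2], F = a$F[2],
                 p = a$`Pr(>F)`[2])
    })
    do.call(rbind, out)
  }
}

#' Group comparison (Student's t or one-way ANOVA + Tukey HSD)
#'
#' @param values Numeric response.
#' @param groups Grouping factor; groups with fewer than 2 observations
#'   are dropped with a warning.
#' @return For 2 groups: list with `means`, `t`, `df`, `p`,
#'   `method = "student_t"` (equal-variance). For > 2: `means`, `F`,
#'   `p`, `tukey` (pairwise table), `method = "anova_tukey"`.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  cnt <- table(groups)
  if (any(cnt < 2)) {
    warning("dropping groups with n < 2: ",
            paste(names(cnt)[cnt < 2], collapse = ", "))
    keep <- groups %in% names(cnt)[cnt >= 2]
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with n >= 2")
  means <- tapply(values, groups, mean)
  if (nlevels(groups) == 2) {
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    list(means = means, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, method = "student_t")
  } else {
    fit <- stats::aov(values ~ groups)
    a <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    list(means = means, F = a$`F value`[1], p = a$`Pr(>F)`[1],
         tukey = tk, method = "anova_tukey")
  }
}

#' Pearson correlation of per-subject lesion summaries with cognition
#'
#' @param delta Per-subject mean SCI-NAWM differences (chi or R2*).
#' @param measure Cognition scores (FSIQ, WMI or PSI), same subjects.
#' @return List: `r`, `p`, `n`.
#' @export
cognition_correlate <- function(delta, measure) {
  ok <- is.finite(delta) & is.finite(measure)
  delta <- delta[ok]; measure <- measure[ok]
  if (length(delta) < 3) stop("need at least 3 subjects with both values")
  if (stats::sd(delta) == 0 || stats::sd(measure) == 0)
    stop("zero variance")
  ct <- stats::cor.test(delta, measure, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(delta))
}

#' Pearson correlation between paired SCI and NAWM means
#'
#' @param sci_means,nawm_means Paired numeric vectors.
#' @return List: `r`, `p`, `n`.
#' @export
correlate_paired <- function(sci_means, nawm_means) {
  if (length(sci_means) != length(nawm_means)) stop("length mismatch")
  cognition_correlate(sci_means, nawm_means)
}

#' Collapse lesion records to per-subject summaries
#'
#' Mean chi / R2* (SCI, NAWM and differences) across each subject's
#' lesions, for subjects with at least one non-excluded lesion.
#'
#' @param records Lesion record data.frame (one row per lesion).
#' @return Data.frame, one row per subject.
#' @export
subject_summaries <- function(records) {
  spl <- split(records, records$subject_id)
  out <- lapply(spl, function(r) {
    data.frame(subject_id = r$subject_id[1],
               group = r$group[1], age_years = r$age_years[1],
               n_lesions = nrow(r),
               mean_delta_chi = mean(r$mean_chi_sci - r$mean_chi_nawm),
               mean_delta_r2s = mean(r$mean_r2s_sci - r$mean_r2s_nawm))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
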