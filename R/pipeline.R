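# Orchestration: simulate -> reconstruct (field, QSM, R2*) -> segment ->
# pair -> summarize, as one deterministic run over the digital phantom.
# All protocol and processing constants are surfaced in the run config;
# none are hard-coded in the stages.

#' Standard phantom lesion set
#'
#' Ten ellipsoidal white-matter lesions placed deterministically around
#' the brain: a spread of sizes (including one below the 3 mm rule and
#' one that interpolates to 2 voxels or fewer on the GRE grid) and of
#' T1w pass fractions (0 to 1), so that every exclusion rule and both
#' lesion definitions are exercised by a single run.
#'
#' @param dim,voxel_size_mm Phantom grid geometry.
#' @return List of [lesion_spec()] objects.
#' @export
standard_lesion_set <- function(dim = c(64, 64, 64),
                                voxel_size_mm = c(1.15, 1.15, 1.15)) {
  dim <- rep(dim, length.out = 3)
  c0 <- (dim - 1) / 2
  fov <- dim * voxel_size_mm
  angles <- seq(0.15, 2 * pi, length.out = 11)[1:10]
  radii <- 0.26 * fov[1:2]
  semi <- list(c(3, 3, 3), c(2.5, 3.5, 2.5), c(3, 2.5, 3), c(4, 3, 3),
               c(1.6, 1.6, 1.6),        # small: strict ROI <= 2 GRE voxels
               c(3, 3, 2.5), c(2.5, 2.5, 3.5), c(3.5, 3, 2.5),
               c(1.4, 1.4, 1.4),        # below the 3 mm greatest-dimension rule
               c(3, 3.5, 3))
  frac <- c(0, 0.5, 1, 0.3, 0.1, 0, 0.7, 0.5, 1, 0.2)
  zoff <- c(0, 2, -2, 1, -1, 2, 0, -2, 1, -1)
  lapply(seq_len(10), function(i) {
    ctr <- c(c0[1] + radii[1] / voxel_size_mm[1] * cos(angles[i]),
             c0[2] + radii[2] / voxel_size_mm[2] * sin(angles[i]),
             c0[3] + zoff[i])
    lesion_spec(center = ctr, semi_axes = semi[[i]],
                t1_pass_fraction = frac[i])
  })
}

#' Run configuration
#'
#' Collects every tunable of the pipeline with the study defaults:
#' 7-echo ME-GRE at 3 T (TE1 = 3 ms, dTE = 4 ms, 1.15 mm isotropic),
#' Tikhonov weight alpha = 0.013, intensity-threshold factor 1.02,
#' depth percentiles 25% (cortex-proximal) / 5% (ventricle-proximal),
#' and both lesion definitions.
#'
#' @param dim Phantom grid dimensions.
#' @param voxel_size_mm GRE voxel size.
#' @param lesions List of [lesion_spec()]; default [standard_lesion_set()].
#' @param snr First-echo WM SNR (`Inf` = noiseless).
#' @param seed RNG seed for all noise draws.
#' @param alpha Tikhonov regularization weight.
#' @param threshold_factor FLAIR / T1w intensity-threshold factor.
#' @param cortex_fraction,ventricle_fraction Depth-class percentiles.
#' @param definitions Subset of `c("FLAIR", "FLAIR+T1w")`.
#' @param subject_id,group,age_years Covariates attached to the records.
#' @param n_coils Number of simulated receive coils.
#' @return Object of class `run_config`.
#' @export
run_config <- function(dim = c(64, 64, 64),
                       voxel_size_mm = c(1.15, 1.15, 1.15),
                       lesions = NULL, snr = Inf, seed = 7L,
                       alpha = 0.013, threshold_factor = 1.02,
                       cortex_fraction = 0.25, ventricle_fraction = 0.05,
                       definitions = c("FLAIR", "FLAIR+T1w"),
                       subject_id = "phantom01", group = "SCA",
                       age_years = 14, n_coils = 1L) {
  if (is.null(lesions)) lesions <- standard_lesion_set(dim, voxel_size_mm)
  structure(list(dim = rep(dim, length.out = 3),
                 voxel_size_mm = rep(voxel_size_mm, length.out = 3),
                 lesions = lesions, snr = snr, seed = as.integer(seed),
                 alpha = alpha, threshold_factor = threshold_factor,
                 cortex_fraction = cortex_fraction,
                 ventricle_fraction = ventricle_fraction,
                 definitions = definitions, subject_id = subject_id,
                 group = group, age_years = age_years,
                 n_coils = as.integer(n_coils),
                 echo_times_ms = seq(3, 27, by = 4), b0_tesla = 3.0,
                 b0_direction = c(0, 0, 1)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file whose keys match [run_config()] arguments
#'   (lesions given as a list of spec fields).
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$lesions))
    y$lesions <- lapply(y$lesions, function(l) do.call(lesion_spec, l))
  do.call(run_config, y)
}

#' Validate a run configuration
#'
#' @param config `run_config`.
#' @return Character vector of violations; empty when the config is ok.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(all(config$dim >= 32), "grid must be at least 32 in every dimension")
  chk(all(config$voxel_size_mm > 0), "voxel sizes must be positive")
  chk(config$alpha > 0, "alpha must be > 0")
  chk(config$snr > 0, "snr must be > 0")
  chk(config$threshold_factor > 0, "threshold_factor must be > 0")
  chk(!is.unsorted(config$echo_times_ms, strictly = TRUE),
      "echo_times must be strictly increasing")
  chk(abs(sqrt(sum(config$b0_direction^2)) - 1) < 1e-6,
      "b0_direction must be a unit vector")
  chk(config$cortex_fraction > 0 && config$cortex_fraction < 1,
      "cortex_fraction must be in (0, 1)")
  chk(config$ventricle_fraction > 0 && config$ventricle_fraction < 1,
      "ventricle_fraction must be in (0, 1)")
  chk(all(config$definitions %in% c("FLAIR", "FLAIR+T1w")),
      "definitions must be a subset of {FLAIR, FLAIR+T1w}")
  chk(length(config$definitions) >= 1, "at least one definition required")
  for (i in seq_along(config$lesions)) {
    l <- config$lesions[[i]]
    if (any(l$semi_axes <= 0)) v <- c(v, sprintf("lesion %d: semi_axes must be > 0", i))
    if (l$t1_pass_fraction < 0 || l$t1_pass_fraction > 1)
      v <- c(v, sprintf("lesion %d: t1_pass_fraction must be in [0, 1]", i))
  }
  v
}

#' @noRd
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251)) %% .Machine$integer.max)
}

#' Run the full phantom pipeline
#'
#' simulate (phantom, ME-GRE, structurals) -> field fit + unwrap -> PDF
#' background removal -> Tikhonov inversion -> R2* fit -> two-definition
#' SCI segmentation with contralateral NAWM mirroring -> per-lesion
#' records and paired statistics. Deterministic given `config$seed`.
#'
#' @param config A validated [run_config()].
#' @param out_dir Optional directory for `records.csv`,
#'   `statistics.json` and `manifest.json`.
#' @param verbose Print per-stage progress.
#' @return List: `records` (data.frame, one row per lesion and
#'   definition), `stats` (paired comparisons per definition),
#'   `excluded` (data.frame of excluded lesions with reasons), `maps`
#'   (chi, r2star, field), `truth`, `manifest`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, verbose = FALSE) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("stage %-12s %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  protocol <- acquisition_protocol(
    b0_tesla = config$b0_tesla, b0_direction = config$b0_direction,
    echo_times_ms = config$echo_times_ms,
    voxel_size_mm = config$voxel_size_mm, n_coils = config$n_coils,
    snr = config$snr, seed = config$seed)

  truth <- stage("phantom", build_phantom(config$dim, config$voxel_size_mm,
                                          config$lesions))
  series <- stage("megre", simulate_megre(truth, protocol))
  struct <- stage("structural",
                  simulate_structural(truth,
                                      threshold_factor = config$threshold_factor))

  series <- combine_coils(series)
  fm <- stage("fieldfit", fit_field_nonlinear(series, mask = truth$brain_mask))
  uw <- stage("unwrap", unwrap_field(fm$total_field_hz, fm$mask,
                                     period = fm$alias_period_hz))
  field_ppm <- field_hz_to_ppm(uw$unwrapped, config$b0_tesla)

  lf <- stage("pdf", remove_background_pdf(field_ppm, truth$brain_mask,
                                           config$voxel_size_mm,
                                           config$b0_direction))
  chi <- stage("qsm", invert_tikhonov(lf, alpha = config$alpha))
  r2s <- stage("r2star", fit_r2star_loglinear(Mod(series$data),
                                              config$echo_times_ms,
                                              truth$brain_mask))

  gre_grid <- list(dim = config$dim, affine = truth$affine)
  wm_gre <- truth$label_grid == 1L
  cortex_gre <- truth$label_grid == 2L
  vent_gre <- truth$label_grid == 3L
  depth <- stage("depth", classify_wm_depth(wm_gre, cortex_gre, vent_gre,
                                            config$voxel_size_mm,
                                            config$cortex_fraction,
                                            config$ventricle_fraction))
  atlas <- synthetic_lobe_atlas(truth$brain_mask)

  seg <- stage("segment", {
    cm_flair <- cortical_mean(struct$flair$data, struct$flair$cortex_mask)
    cm_t1 <- cortical_mean(struct$t1w$data, struct$t1w$cortex_mask)
    t_f2t <- struct$transforms$flair_to_t1w
    t_f2g <- struct$transforms$flair_to_gre
    t_t2g <- struct$transforms$t1w_to_gre
    rois <- list()
    for (i in seq_along(truth$lesions)) {
      seed_roi <- dilate_n(struct$flair$lesion_masks[[i]], 2)
      fl <- apply_flair_threshold(seed_roi, struct$flair$data, cm_flair,
                                  factor = config$threshold_factor,
                                  voxel_size_mm = struct$flair$voxel,
                                  subject_id = config$subject_id,
                                  lesion_id = i)
      entry <- list(lesion_id = i, flair = fl)
      if (!fl$excluded) {
        g <- size_gate(fl)
        if (!g$pass) {
          entry$flair$excluded <- TRUE
          entry$flair$reason <- "below 3 mm greatest dimension"
        }
      }
      if ("FLAIR+T1w" %in% config$definitions && !entry$flair$excluded) {
        on_t1 <- apply_affine(fl$mask, t_f2t, "nearest")
        st <- apply_t1w_threshold(on_t1, struct$t1w$data, cm_t1,
                                  factor = config$threshold_factor,
                                  voxel_size_mm = struct$t1w$voxel,
                                  subject_id = config$subject_id,
                                  lesion_id = i)
        if (!st$excluded) {
          g <- size_gate(st)
          if (!g$pass) {
            st$excluded <- TRUE
            st$reason <- "below 3 mm greatest dimension"
          }
        }
        entry$strict <- st
      } else if ("FLAIR+T1w" %in% config$definitions && entry$flair$excluded) {
        # a lesion that fails the FLAIR definition cannot satisfy the
        # stricter one; propagate the exclusion so every lesion is
        # accounted for under both definitions
        entry$strict <- lesion_roi(array(FALSE, struct$t1w$dim),
                                   grid_name = "T1w",
                                   definition = "FLAIR+T1w",
                                   voxel_size_mm = struct$t1w$voxel,
                                   subject_id = config$subject_id,
                                   lesion_id = i, excluded = TRUE,
                                   reason = entry$flair$reason)
      }
      rois[[i]] <- entry
    }
    rois
  })

  records <- stage("pair", {
    rows <- list(); excl <- list()
    # NAWM must avoid every identified SCI, excluded or not: use the
    # seed regions (dilated truth lesions) plus the segmented masks
    seed_masks_gre <- lapply(truth$lesion_masks, function(m) dilate_n(m, 1))
    gre_masks <- list(`FLAIR` = seed_masks_gre, `FLAIR+T1w` = seed_masks_gre)
    for (i in seq_along(seg)) {
      e <- seg[[i]]
      if ("FLAIR" %in% config$definitions && !e$flair$excluded)
        gre_masks$`FLAIR`[[length(gre_masks$`FLAIR`) + 1]] <-
          apply_affine(e$flair$mask, struct$transforms$flair_to_gre, "nearest")
      if (!is.null(e$strict) && !e$strict$excluded)
        gre_masks$`FLAIR+T1w`[[length(gre_masks$`FLAIR+T1w`) + 1]] <-
          apply_affine(e$strict$mask, struct$transforms$t1w_to_gre, "nearest")
    }
    for (i in seq_along(seg)) {
      e <- seg[[i]]
      defs <- list()
      if ("FLAIR" %in% config$definitions) defs$`FLAIR` <- e$flair
      if (!is.null(e$strict)) defs$`FLAIR+T1w` <- e$strict
      for (dn in names(defs)) {
        roi <- defs[[dn]]
        if (roi$excluded) {
          excl[[length(excl) + 1]] <- data.frame(
            lesion_id = i, definition = dn, reason = roi$reason)
          next
        }
        tr <- if (roi$grid_name == "FLAIR") struct$transforms$flair_to_gre
              else struct$transforms$t1w_to_gre
        gmask <- apply_affine(roi$mask, tr, "nearest")
        gate <- post_resample_gate(gmask)
        if (!gate$keep) {
          excl[[length(excl) + 1]] <- data.frame(
            lesion_id = i, definition = dn, reason = gate$reason)
          next
        }
        sci <- lesion_roi(gmask, grid_name = "GRE", definition = dn,
                          voxel_size_mm = config$voxel_size_mm,
                          subject_id = config$subject_id, lesion_id = i)
        mir <- mirror_nawm(sci, wm_gre, gre_masks[[dn]])
        if (mir$excluded) {
          excl[[length(excl) + 1]] <- data.frame(
            lesion_id = i, definition = dn, reason = mir$reason)
          next
        }
        mc <- roi_means(chi, sci$mask, mir$nawm$mask, depth)
        mr <- roi_means(r2s, sci$mask, mir$nawm$mask)
        df <- depth_fractions(sci, depth)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = config$subject_id, lesion_id = i, definition = dn,
          group = config$group, age_years = config$age_years,
          lobe = assign_lobe(sci, atlas),
          frac_periventricular = df[["periventricular"]],
          frac_juxtacortical = df[["juxtacortical"]],
          frac_deep = df[["deep"]],
          volume_mm3 = sci$volume_mm3, n_voxels = sum(sci$mask),
          mean_chi_sci = mc$mean_sci, mean_chi_nawm = mc$mean_nawm,
          mean_r2s_sci = mr$mean_sci, mean_r2s_nawm = mr$mean_nawm)
      }
    }
    list(records = if (length(rows)) do.call(rbind, rows) else NULL,
         excluded = if (length(excl)) do.call(rbind, excl) else NULL)
  })

  stats_out <- stage("stats", {
    out <- list()
    r <- records$records
    for (dn in config$definitions) {
      rd <- r[r$definition == dn, , drop = FALSE]
      if (is.null(rd) || nrow(rd) < 2) next
      out[[dn]] <- list(
        n_lesions = nrow(rd),
        chi = paired_delta(rd$mean_chi_sci, rd$mean_chi_nawm),
        r2star = paired_delta(rd$mean_r2s_sci, rd$mean_r2s_nawm),
        chi_bland_altman = bland_altman(rd$mean_chi_sci, rd$mean_chi_nawm)[
          c("bias", "sd_diff", "loa_lower", "loa_upper", "n")],
        r2s_bland_altman = bland_altman(rd$mean_r2s_sci, rd$mean_r2s_nawm)[
          c("bias", "sd_diff", "loa_lower", "loa_upper", "n")])
    }
    out
  })

  manifest <- list(package_version = as.character(utils::packageVersion("qsmsci")),
                   seed = config$seed, config_hash = config_hash(config),
                   n_lesions_config = length(config$lesions),
                   n_records = if (is.null(records$records)) 0L
                               else nrow(records$records),
                   definitions = config$definitions)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(records$records))
      utils::write.csv(records$records, file.path(out_dir, "records.csv"),
                       row.names = FALSE)
    jsonlite::write_json(stats_out, file.path(out_dir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(records = records$records, excluded = records$excluded,
       stats = stats_out,
       maps = list(chi = chi, r2star = r2s, field = fm, local_field = lf),
       truth = truth, structurals = struct, depth = depth,
       manifest = manifest)
}
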