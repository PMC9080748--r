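#' Simulate a complete sidewinding study
#'
#' Generates a morphometrics table and one representative sidewinding trial
#' per kinematics individual, with known ground truth. Wave parameters follow
#' the structure the downstream analyses look for: wavelength and amplitude
#' scale with body size (wavelength additionally reflecting relative body
#' width, so stouter snakes form looser curves), frequency varies widely and
#' independently of size and is positively correlated with skew angle, lift
#' height tracks amplitude (about an eighth of it), and speed follows
#' mechanically as frequency times stride. Individuals for kinematics are
#' drawn across the size range, as a field study would select them.
#'
#' @param n_individuals Individuals in the morphometrics sample (default 74).
#' @param n_kinematics Individuals with a digitized trial (default 26).
#' @param seed Integer seed.
#' @param frequency_log10_mean,frequency_log10_sd Distribution of cycle
#'   frequency (default centered on ~0.7 Hz).
#' @param wavelength_svl,amplitude_svl Wavelength and amplitude as fractions
#'   of SVL (defaults 0.35 and 0.25).
#' @param width_wavelength_effect Effect of relative body width on log
#'   wavelength (default 0.6).
#' @param skew_frequency_slope Degrees of skew per log10 unit of frequency
#'   residual (default 30).
#' @param noise_sd_cm Marker positional noise (default 0.1).
#' @param frame_rate_hz Recording rate (default 250).
#' @return List with `morpho` (data frame), `kin_ids`, `ground_truths`
#'   (list of [trial_ground_truth()]), and `trial_meta` (data frame).
#' @export
simulate_study <- function(n_individuals = 74L, n_kinematics = 26L, seed = 1L,
                           frequency_log10_mean = -0.15,
                           frequency_log10_sd = 0.12,
                           wavelength_svl = 0.35, amplitude_svl = 0.25,
                           width_wavelength_effect = 0.6,
                           skew_frequency_slope = 30,
                           noise_sd_cm = 0.1, frame_rate_hz = 250) {
  morpho <- generate_morphometrics(morpho_gen_config(n_individuals, seed = seed))
  set.seed(seed + 1L)
  # spread kinematics individuals over the size range
  ord <- order(morpho$svl_cm)
  take <- ord[round(seq(1, n_individuals, length.out = n_kinematics))]
  kin <- morpho[take, ]
  gts <- list()
  meta <- NULL
  for (i in seq_len(nrow(kin))) {
    ind <- kin[i, ]
    width_resid <- log10(ind$width50_cm) - log10(0.055 * ind$svl_cm)
    f <- 10^stats::rnorm(1, frequency_log10_mean, frequency_log10_sd)
    f_resid <- log10(f) - frequency_log10_mean
    lam <- wavelength_svl * ind$svl_cm *
      10^(width_wavelength_effect * width_resid + stats::rnorm(1, 0, 0.02))
    A <- amplitude_svl * ind$svl_cm * 10^stats::rnorm(1, 0, 0.03)
    skew <- 8 + skew_frequency_slope * f_resid + stats::rnorm(1, 0, 3)
    skew <- max(min(skew, 30), -8)
    H <- A / 8 * 10^stats::rnorm(1, 0, 0.05)
    # contact duty varies between individuals; stride (hence speed at a given
    # frequency) depends on it, so speed keeps unexplained variance beyond
    # the wave-geometry predictors, as in real locomotor data
    duty <- stats::runif(1, 0.42, 0.6)
    wave <- wave_params(f, lam, A, skew_deg = skew, lift_height_cm = H,
                        duty = duty,
                        handedness = sample(c("left", "right"), 1))
    n_frames <- ceiling((4.5 / f + 1.2) * frame_rate_hz)
    gt <- trial_ground_truth(
      wave, svl_cm = ind$svl_cm, tail_cm = ind$tail_cm,
      frame_rate_hz = frame_rate_hz, n_frames = n_frames,
      noise_sd_cm = noise_sd_cm,
      trial_id = paste0(ind$id, "_t1"), individual = ind$id, sex = ind$sex,
      age_class = ind$age_class,
      temperature_C = round(stats::runif(1, 20.5, 27), 1),
      seed = seed + 100L + i)
    gts[[gt$trial_id]] <- gt
    meta <- rbind(meta, data.frame(
      trial_id = gt$trial_id, individual = ind$id, sex = ind$sex,
      age_class = ind$age_class, svl_cm = ind$svl_cm,
      temperature_C = gt$temperature_C, handedness = wave$handedness,
      frame_rate_hz = frame_rate_hz, representative = TRUE))
  }
  list(morpho = morpho, kin_ids = kin$id, ground_truths = gts,
       trial_meta = meta)
}

#' Pipeline configuration
#'
#' @param smoothing A [smoothing_config()].
#' @param speed_band,height_band,wave_band Marker bands (defaults 3:7, 2:8,
#'   4:9).
#' @param min_prominence_deg Extremum-detection prominence threshold.
#' @param outlier_rule `"and"` or `"or"` (see [detect_outliers()]).
#' @param tie_rule ANCOVA AICc tie rule (see [ancova_search()]).
#' @param scaling_traits Named numeric vector: morphometric traits to scale
#'   and their isometric expectations. Scale counts are excluded by default
#'   (minimal variation / variance heterogeneity make log-log slopes
#'   uninformative for them).
#' @param kin_scaling_traits Same for kinematic variables.
#' @param seed Seed recorded in outputs and used for stochastic steps.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(smoothing = smoothing_config(),
                            speed_band = 3:7, height_band = 2:8,
                            wave_band = 4:9, min_prominence_deg = 5,
                            outlier_rule = "and", tie_rule = "best",
                            scaling_traits = c(
                              mass_g = 3, tail_cm = 1, width25_cm = 1,
                              width50_cm = 1, width75_cm = 1,
                              neck_width_cm = 1, head_width_cm = 1,
                              head_length_cm = 1),
                            kin_scaling_traits = c(
                              wavelength_cm = 1, amplitude_cm = 1,
                              height_lifted_mean = 1),
                            seed = 1L) {
  structure(list(smoothing = smoothing, speed_band = speed_band,
                 height_band = height_band, wave_band = wave_band,
                 min_prominence_deg = min_prominence_deg,
                 outlier_rule = outlier_rule, tie_rule = tie_rule,
                 scaling_traits = scaling_traits,
                 kin_scaling_traits = kin_scaling_traits,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Smooths every trial and extracts the per-trial kinematic variables, then
#' runs the scaling analyses (outlier screen, AICc ANCOVA search, RMA/OLS
#' slopes and isometry verdicts) on the morphometrics and on the
#' size-dependent kinematic variables, and finally the residual-based path
#' analysis (Pearson correlations, the default seven-variable speed model and
#' the sixteen-model menu). Writes per-stage CSVs and a run log when
#' `out_dir` is given. Deterministic given the seed.
#'
#' @param trials List of `marker_tracks` objects, or a trial metadata data
#'   frame plus `trial_dir` of marker CSVs (columns per
#'   [read_trial_metadata()]).
#' @param morpho Morphometrics data frame (or CSV path).
#' @param trial_meta Data frame with at least `trial_id`, `individual`,
#'   `svl_cm`, `sex`, `age_class`, `temperature_C`, `handedness`; if `NULL`,
#'   assembled from the trial objects' metadata.
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory for CSVs and the run log (`NULL` = none).
#' @param stages Character subset of `c("kinematics", "scaling", "path")`.
#' @return List of class `pipeline_result` with `kinematics`, `outliers`,
#'   `morpho_scaling`, `kin_scaling`, `ancova_models` (AICc-ranked model
#'   table per trait), `ancova_type3` (Type III tests of each selected
#'   model), `correlations`, `path_fit`, `path_menu`, `residuals`, `config`.
#' @export
run_pipeline <- function(trials, morpho, trial_meta = NULL,
                         cfg = pipeline_config(), out_dir = NULL,
                         stages = c("kinematics", "scaling", "path")) {
  if (is.character(morpho)) morpho <- read_morphometrics(morpho)
  res <- list(config = cfg)

  # --- kinematics -----------------------------------------------------------
  kin <- NULL
  if ("kinematics" %in% stages) {
    rows <- lapply(trials, function(tr) {
      stopifnot(inherits(tr, "marker_tracks"))
      k <- smooth_trial(tr, cfg$smoothing)
      extract_trial_kinematics(k, cfg$speed_band, cfg$height_band,
                               cfg$wave_band, cfg$min_prominence_deg)
    })
    kin <- do.call(rbind, rows)
    if (is.null(trial_meta)) {
      trial_meta <- do.call(rbind, lapply(trials, function(tr) {
        md <- tr$metadata
        data.frame(trial_id = md$trial_id, individual = md$individual,
                   sex = md$sex, age_class = md$age_class,
                   temperature_C = md$temperature_C,
                   handedness = md$handedness)
      }))
    }
    if (!"svl_cm" %in% names(trial_meta)) {
      trial_meta$svl_cm <- morpho$svl_cm[match(trial_meta$individual, morpho$id)]
    }
    kin <- merge(kin, trial_meta[, setdiff(names(trial_meta),
                                           c("handedness", "sex", "age_class"))],
                 by = c("trial_id", "individual"), sort = FALSE)
    kin <- merge(kin, trial_meta[, c("trial_id", "sex", "age_class")],
                 by = "trial_id", sort = FALSE)
    res$kinematics <- kin
  }

  # --- scaling --------------------------------------------------------------
  if ("scaling" %in% stages) {
    out_rows <- NULL
    flagged <- list()
    anc_rows <- NULL; t3_rows <- NULL
    for (trait in names(cfg$scaling_traits)) {
      fl <- detect_outliers(morpho, trait, rule = cfg$outlier_rule)
      flagged[[trait]] <- fl
      dat <- morpho[!morpho$id %in% fl, ]
      sf <- scaling_fit(dat, trait, expected = cfg$scaling_traits[[trait]],
                        tie_rule = cfg$tie_rule)
      out_rows <- rbind(out_rows, sf$groups)
      tab <- sf$search$table
      anc_rows <- rbind(anc_rows, cbind(trait = trait, rank = seq_len(nrow(tab)),
                                        tab))
      if (!is.null(sf$search$type3)) {
        t3 <- as.data.frame(sf$search$type3)
        t3_rows <- rbind(t3_rows, data.frame(
          trait = trait, term = rownames(t3), df = t3$Df,
          F = t3$`F value`, p = t3$`Pr(>F)`))
      }
    }
    res$outliers <- flagged
    res$morpho_scaling <- out_rows
    res$ancova_models <- anc_rows
    res$ancova_type3 <- t3_rows
    if (!is.null(kin)) {
      kin_rows <- NULL
      for (trait in names(cfg$kin_scaling_traits)) {
        ok <- !is.na(kin[[trait]])
        sf <- scaling_fit(kin[ok, ], trait,
                          expected = cfg$kin_scaling_traits[[trait]],
                          temperature = "temperature_C",
                          tie_rule = cfg$tie_rule)
        kin_rows <- rbind(kin_rows, sf$groups)
      }
      res$kin_scaling <- kin_rows
    }
  }

  # --- path analysis --------------------------------------------------------
  if ("path" %in% stages && !is.null(kin)) {
    pv <- data.frame(
      speed = kin$centroid_mean_speed, frequency = kin$frequency_hz,
      wavelength = kin$wavelength_cm, amplitude = kin$amplitude_cm,
      skew = kin$skew_deg, height = kin$height_lifted_mean,
      svl_cm = kin$svl_cm, sex = kin$sex, age_class = kin$age_class)
    pv$width50 <- morpho$width50_cm[match(kin$individual, morpho$id)]
    pv$mass <- morpho$mass_g[match(kin$individual, morpho$id)]
    pv$tail <- morpho$tail_cm[match(kin$individual, morpho$id)]
    pv$ventral <- morpho$ventral_count[match(kin$individual, morpho$id)]
    vars <- c("speed", "frequency", "wavelength", "amplitude", "skew",
              "height", "width50", "mass", "tail", "ventral")
    resid <- residualize(pv, vars,
                         log_transform = vars != "skew")
    res$residuals <- resid
    res$correlations <- pearson_matrix(resid)
    spec <- sidewinding_path_spec()
    cc <- stats::complete.cases(resid[, spec$variables])
    S <- stats::cor(resid[cc, spec$variables])
    res$path_fit <- fit_path_model(spec, S, sum(cc), seed = cfg$seed)
    menu <- sidewinding_path_menu()
    Slist <- list(); nvec <- integer(0)
    for (nm in names(menu)) {
      vs <- menu[[nm]]$variables
      cc <- stats::complete.cases(resid[, vs])
      Slist[[nm]] <- stats::cor(resid[cc, vs])
      nvec <- c(nvec, sum(cc))
    }
    res$path_menu <- model_menu_search(menu, Slist, nvec, seed = cfg$seed)
  }

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  class(res) <- "pipeline_result"
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) if (!is.null(x)) {
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE, na = "")
  }
  wcsv(res$kinematics, "trial_kinematics.csv")
  wcsv(res$morpho_scaling, "morpho_scaling.csv")
  wcsv(res$kin_scaling, "kinematic_scaling.csv")
  wcsv(res$ancova_models, "ancova_models.csv")
  wcsv(res$ancova_type3, "ancova_type3.csv")
  if (!is.null(res$path_fit) && isTRUE(res$path_fit$converged)) {
    wcsv(res$path_fit$estimates, "path_estimates.csv")
  }
  if (!is.null(res$path_menu)) wcsv(res$path_menu$table, "path_menu.csv")
  if (!is.null(res$correlations)) {
    utils::write.csv(round(res$correlations$r, 4),
                     file.path(out_dir, "residual_correlations.csv"))
  }
  ver <- tryCatch(as.character(utils::packageVersion("sidewindr")),
                  error = function(e) "dev")
  log <- c(paste("package sidewindr", ver),
           paste("R", getRversion()),
           paste("seed", res$config$seed),
           paste("generated", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
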