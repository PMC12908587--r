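# Synthetic study-input generators: cohort, calorimetry traces, DLW
# records, phylogeny. Every generator is deterministic given its seed, and
# the DLW/trace forward models are exact inverses of the energetics chain
# so that round-trip recovery is testable.

#' Configuration of the synthetic study
#'
#' Defaults restate the study conditions being emulated: 16 sedentary
#' overweight adults (ages 21-45, BMI 25-30, sex-balanced), half of whom
#' respond to training; 300 species with 9 planted predictor species
#' elevated ~1.5 log2 units in responders at baseline; responder
#' communities with half the subject-level spread of non-responders; a
#' +0.73 coupling between the Shannon-index change and TDEE adaptation and
#' a -0.65 coupling between baseline Shannon and RMR adaptation.
#'
#' @param n_subjects Cohort size (>= 4; default 16).
#' @param responder_fraction Fraction of responders in (0, 1); both groups
#'   must end up with >= 2 members (default 0.5).
#' @param n_species Species universe size (default 300).
#' @param n_predictor_species Planted predictive species (default 9).
#' @param predictor_log2_effect Log2 fold-difference of predictor species,
#'   responders vs non-responders, at baseline (default 1.5).
#' @param responder_dispersion_scale Multiplier < 1 tightening responder
#'   subject-level community spread (default 0.5).
#' @param rho_shannon_tdee Target correlation between the Shannon change
#'   and TDEE adaptation (default 0.73).
#' @param rho_shannon0_rmr Target (negative) correlation between baseline
#'   Shannon and RMR adaptation (default -0.65).
#' @param tdee_true_range,rmr_true_range Target spans of true energy
#'   expenditure (kcal/day); the cohort mean sits at the midpoint.
#' @param seed Run seed; all generator seeds derive from it.
#' @return Validated list of class `gf_synth_config`.
#' @export
synth_config <- function(n_subjects = 16L, responder_fraction = 0.5,
                         n_species = 300L, n_predictor_species = 9L,
                         predictor_log2_effect = 1.5,
                         responder_dispersion_scale = 0.5,
                         rho_shannon_tdee = 0.73,
                         rho_shannon0_rmr = -0.65,
                         tdee_true_range = c(2200, 3200),
                         rmr_true_range = c(1300, 1900),
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              responder_fraction = responder_fraction,
              n_species = as.integer(n_species),
              n_predictor_species = as.integer(n_predictor_species),
              predictor_log2_effect = predictor_log2_effect,
              responder_dispersion_scale = responder_dispersion_scale,
              rho_shannon_tdee = rho_shannon_tdee,
              rho_shannon0_rmr = rho_shannon0_rmr,
              tdee_true_range = tdee_true_range,
              rmr_true_range = rmr_true_range,
              seed = as.integer(seed))
  if (cfg$n_subjects < 4L || cfg$n_species < 2L) {
    stop("counts too small: need n_subjects >= 4 and n_species >= 2")
  }
  if (cfg$responder_fraction <= 0 || cfg$responder_fraction >= 1) {
    stop("responder_fraction must lie strictly in (0, 1)")
  }
  n_resp <- round(cfg$n_subjects * cfg$responder_fraction)
  if (n_resp < 2L || cfg$n_subjects - n_resp < 2L) {
    stop("responder_fraction leaves a group with < 2 subjects; ",
         "rank tests need >= 2 per group")
  }
  if (abs(cfg$rho_shannon_tdee) >= 1 || abs(cfg$rho_shannon0_rmr) >= 1) {
    stop("target correlations must satisfy |rho| < 1")
  }
  if (cfg$n_predictor_species >= cfg$n_species) {
    stop("n_predictor_species must be smaller than n_species")
  }
  if (cfg$responder_dispersion_scale <= 0) {
    stop("responder_dispersion_scale must be positive")
  }
  class(cfg) <- "gf_synth_config"
  cfg
}

species_ids <- function(n) {
  sprintf(paste0("sp%0", max(3L, nchar(n)), "d"), seq_len(n))
}

#' Generate a synthetic cohort with ground truth
#'
#' Demographics and body composition emulate the recruited population:
#' ages uniform in 21-45, BMI uniform in 25-30, sexes balanced, heights
#' sex-specific, fat fraction sex-specific. Post-training composition is
#' drawn so that exactly `round(n * responder_fraction)` subjects have a
#' strictly positive body-composition score `dFFM - dFM`, while total
#' weight change is centered at zero (sd 2.1 kg). True resting and total
#' energy expenditure are affine in fat-free mass plus noise; post values
#' add the exercise energy cost (TDEE only) and a planted subject-level
#' metabolic adaptation driven by latent standard-normal variables that
#' later couple to the microbiome generator.
#'
#' @param config A [synth_config()].
#' @return List with `cohort` (data frame, one row per subject) and
#'   `truth` (true energies, adaptations, latents, responder labels).
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "gf_synth_config"))
  n <- config$n_subjects
  with_seed(derive_seed(config$seed, 1L), {
    id <- sprintf("S%02d", seq_len(n))
    sex <- rep(c("F", "M"), length.out = n)
    age <- round(stats::runif(n, 21, 45))
    height_cm <- ifelse(sex == "F", stats::rnorm(n, 163, 6),
                        stats::rnorm(n, 177, 7))
    bmi_pre <- stats::runif(n, 25, 30)
    weight_pre <- bmi_pre * (height_cm / 100)^2
    fm_frac <- ifelse(sex == "F", stats::runif(n, 0.32, 0.42),
                      stats::runif(n, 0.25, 0.35))
    fm_pre <- weight_pre * fm_frac
    ffm_pre <- weight_pre - fm_pre

    n_resp <- round(n * config$responder_fraction)
    responder <- logical(n)
    responder[sample.int(n, n_resp)] <- TRUE
    # score = dFFM - dFM, strictly positive for responders only
    score <- ifelse(responder, stats::runif(n, 0.4, 2.5),
                    -stats::runif(n, 0.1, 2.5))
    d_weight <- stats::rnorm(n, 0, 2.1)
    d_ffm <- (d_weight + score) / 2
    d_fm <- (d_weight - score) / 2
    ffm_post <- ffm_pre + d_ffm
    fm_post <- fm_pre + d_fm
    weight_post <- ffm_post + fm_post

    # true energy expenditure: affine in FFM around the configured midpoints
    z_rmr <- stats::rnorm(n)
    z_tdee <- stats::rnorm(n)
    rmr_mid <- mean(config$rmr_true_range)
    tdee_mid <- mean(config$tdee_true_range)
    ffm_c <- ffm_pre - mean(ffm_pre)
    rmr_true_pre <- rmr_mid + 21.6 * ffm_c + stats::rnorm(n, 0, 40)
    tdee_true_pre <- tdee_mid + 34 * ffm_c + stats::rnorm(n, 0, 80)
    adaptation_rmr_true <- -60 + 80 * z_rmr
    adaptation_tdee_true <- -100 + 250 * z_tdee
    exercise_ee <- 20 * weight_pre / 7 # 20 kcal/kg/week prescription
    rmr_true_post <- rmr_mid + 21.6 * (ffm_post - mean(ffm_pre)) +
      adaptation_rmr_true + stats::rnorm(n, 0, 40)
    tdee_true_post <- tdee_mid + 34 * (ffm_post - mean(ffm_pre)) +
      exercise_ee + adaptation_tdee_true + stats::rnorm(n, 0, 80)

    vo2max_pre <- stats::runif(n, 25, 40)
    vo2max_post <- vo2max_pre +
      ifelse(responder, stats::rnorm(n, 3, 1.5), stats::rnorm(n, 0.3, 1.5))
    intake_pre <- tdee_true_pre + stats::rnorm(n, 0, 150)
    intake_post <- intake_pre + stats::rnorm(n, 0, 100)

    cohort <- data.frame(
      subject_id = id, sex = sex, age = age,
      height_cm = round(height_cm, 1),
      weight_pre = round(weight_pre, 2), weight_post = round(weight_post, 2),
      bmi_pre = round(bmi_pre, 2),
      bmi_post = round(weight_post / (height_cm / 100)^2, 2),
      fm_pre = round(fm_pre, 3), fm_post = round(fm_post, 3),
      ffm_pre = round(ffm_pre, 3), ffm_post = round(ffm_post, 3),
      vo2max_pre = round(vo2max_pre, 1), vo2max_post = round(vo2max_post, 1),
      caloric_intake_pre = round(intake_pre),
      caloric_intake_post = round(intake_post),
      stringsAsFactors = FALSE)
    # rounding must not flip the strict responder rule
    score_r <- (cohort$ffm_post - cohort$ffm_pre) -
      (cohort$fm_post - cohort$fm_pre)
    stopifnot(identical(score_r > 0, responder))
    truth <- data.frame(
      subject_id = id, responder_true = responder,
      rmr_true_pre = rmr_true_pre, rmr_true_post = rmr_true_post,
      tdee_true_pre = tdee_true_pre, tdee_true_post = tdee_true_post,
      adaptation_rmr_true = adaptation_rmr_true,
      adaptation_tdee_true = adaptation_tdee_true,
      exercise_ee = exercise_ee,
      z_rmr = z_rmr, z_tdee = z_tdee,
      stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth)
  })
}

#' Generate a 60-minute whole-room calorimetry gas-exchange trace
#'
#' Per-minute VO2/VCO2 readings whose final-20-minute Weir average equals
#' `rmr_true` up to multiplicative measurement noise. An optional settling
#' artifact (exponential decay, time constant `settle_tau` minutes)
#' inflates minutes 0-39 only, making the final-window averaging rule
#' consequential.
#'
#' @param rmr_true True resting metabolic rate (kcal/day, > 0).
#' @param noise_sd Multiplicative noise sd as a fraction (>= 0).
#' @param seed Optional RNG seed.
#' @param settle_amplitude Relative amplitude of the settling artifact at
#'   minute 0 (default 0, i.e. none).
#' @param settle_tau Artifact time constant in minutes.
#' @param trace_rq Respiratory quotient of the trace (VCO2/VO2).
#' @return Data frame `minute` (0-59), `vo2_L`, `vco2_L`.
#' @export
generate_gas_trace <- function(rmr_true, noise_sd = 0.02, seed = NULL,
                               settle_amplitude = 0, settle_tau = 10,
                               trace_rq = 0.8) {
  if (rmr_true <= 0) stop("rmr_true must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  minute <- 0:59
  ee_min <- rmr_true / 1440
  vo2_ss <- ee_min / (3.9 + 1.1 * trace_rq)
  vco2_ss <- trace_rq * vo2_ss
  settle <- ifelse(minute < 40, 1 + settle_amplitude * exp(-minute / settle_tau), 1)
  with_seed(seed, {
    noise_o <- 1 + stats::rnorm(60, 0, noise_sd)
    noise_c <- 1 + stats::rnorm(60, 0, noise_sd)
    data.frame(minute = minute,
               vo2_L = pmax(vo2_ss * settle * noise_o, 0),
               vco2_L = pmax(vco2_ss * settle * noise_c, 0))
  })
}

#' Forward-simulate a doubly-labeled-water enrichment record
#'
#' Doses follow the dosing protocol (1.8 g/kg TBW of 10 APE H2-18O and
#' 0.12 g/kg TBW of 99.9 APE 2H2O, with TBW = 0.73 x FFM upstream), and
#' the enrichment time course is the exact inverse of the energetics
#' chain: dilution spaces are the exchange-scaled body-water pool, the
#' deuterium elimination rate is `k_d`, and the oxygen rate is whatever
#' the two-point equation needs to reproduce `tdee_true` exactly at zero
#' analytic noise.
#'
#' @param tdee_true True TDEE (kcal/day, > 0).
#' @param tbw_true True total body water (kg, > 0).
#' @param body_mass Body mass (kg).
#' @param rq Respiratory quotient in \[0.7, 1.0\].
#' @param seed Optional RNG seed (used only when noise is nonzero).
#' @param k_d Deuterium elimination rate (1/day).
#' @param k_o Override of the oxygen elimination rate; if supplied at or
#'   below the two-point boundary the record is flagged `degenerate` and
#'   downstream inversion errors.
#' @param noise_delta_2h,noise_delta_18o Additive analytic noise sd on
#'   each measured enrichment (delta-permil).
#' @param baseline_delta_2h,baseline_delta_18o Background enrichments.
#' @param elapsed_days Days from dosing to the final voids.
#' @param constants Constant set shared with the inversion.
#' @return One-row data frame with the columns of [dlw_record_columns()]
#'   plus `degenerate`.
#' @export
generate_dlw_record <- function(tdee_true, tbw_true, body_mass,
                                rq = dlw_constants()$rq, seed = NULL,
                                k_d = 0.10, k_o = NULL,
                                noise_delta_2h = 0, noise_delta_18o = 0,
                                baseline_delta_2h = -55,
                                baseline_delta_18o = -8,
                                elapsed_days = 10,
                                constants = dlw_constants()) {
  if (tdee_true <= 0 || tbw_true <= 0) stop("tdee and tbw must be positive")
  if (rq < 0.7 || rq > 1.0) stop("respiratory quotient outside [0.7, 1.0]")
  mm <- constants$molar_mass_water
  tp <- constants$two_point
  tbw_mol <- tbw_true * 1000 / mm
  rco2_mol <- tdee_true / (3.9 / rq + 1.1) / constants$mol_to_l
  if (is.null(k_o)) {
    k_o <- (rco2_mol / (tp[["co2"]] * tbw_mol) + tp[["kd"]] * k_d) / tp[["ko"]]
  }
  degenerate <- tp[["ko"]] * k_o - tp[["kd"]] * k_d <= 0
  n_d <- constants$exch_2h * tbw_mol
  n_o <- constants$exch_18o * tbw_mol
  dose_18o_g <- 1.8 * tbw_true
  dose_2h_g <- 0.12 * tbw_true
  ape_18o <- 10; ape_2h <- 99.9
  rise_2h <- (dose_2h_g / mm) * (ape_2h / 100) / n_d
  rise_18o <- (dose_18o_g / mm) * (ape_18o / 100) / n_o
  dt_days <- elapsed_days - 4.5 / 24

  forward <- function(iso, base_delta, rise, k, noise_sd) {
    r_std <- constants[[paste0("r_std_", iso)]]
    x_base <- delta_to_molefrac(base_delta, r_std)
    x_plateau <- x_base + rise
    x_final <- x_base + rise * exp(-k * dt_days)
    d <- molefrac_to_delta(c(x_base, x_plateau, x_plateau, x_final, x_final),
                           r_std)
    if (noise_sd > 0) d <- d + stats::rnorm(5, 0, noise_sd)
    stats::setNames(d, paste0("delta_", iso, "_",
                              c("baseline", "plateau4h", "plateau5h",
                                "final2", "final3")))
  }
  vals <- with_seed(seed, {
    c(forward("2h", baseline_delta_2h, rise_2h, k_d, noise_delta_2h),
      forward("18o", baseline_delta_18o, rise_18o, k_o, noise_delta_18o))
  })
  out <- data.frame(dose_2h_g = dose_2h_g, dose_18o_g = dose_18o_g,
                    ape_2h = ape_2h, ape_18o = ape_18o,
                    as.list(vals),
                    dt_days = dt_days, elapsed_days = elapsed_days,
                    body_mass_kg = body_mass, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  out
}

#' Generate a random rooted phylogeny over the species universe
#'
#' Rooted bifurcating topology (`ape::rtree`) with exponential branch
#' lengths; tips are labeled with the species ids used by the abundance
#' generator. With two species the tree is a single cherry (2 leaves, 2
#' edges; no root stem edge).
#'
#' @param n_species Number of leaves (>= 2).
#' @param seed Optional RNG seed.
#' @return An `ape` `phylo` object.
#' @export
generate_tree <- function(n_species, seed = NULL) {
  if (n_species < 2L) stop("need at least 2 species")
  with_seed(seed, {
    tr <- ape::rtree(n_species, rooted = TRUE, br = stats::rexp)
    tr$tip.label <- species_ids(n_species)
    tr
  })
}
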