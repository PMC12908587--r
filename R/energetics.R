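# Indirect-calorimetry and doubly-labeled-water energetics.

#' Physical constants of the DLW and calorimetry calculations
#'
#' Returns the default constant set used throughout the energetics chain.
#' All of these are configurable because the literature offers variants:
#'
#' * `r_std_2h`, `r_std_18o`: VSMOW isotope-ratio standards
#'   (2H/1H = 155.76 ppm, 18O/16O = 2005.20 ppm) used for the
#'   delta-permil to mole-fraction conversion.
#' * `exch_2h`, `exch_18o`: isotopic-exchange corrections applied to the
#'   deuterium (1.041) and oxygen-18 (1.007) dilution spaces before
#'   averaging into total body water.
#' * `molar_mass_water`: 18.02 g/mol, applied uniformly to both dose
#'   waters (the dose bookkeeping and its inversion share this value).
#' * `two_point`: multipliers of the constant-folded Schoeller-form
#'   two-point CO2 production equation
#'   `rCO2 [mol/d] = co2 * TBW_mol * (ko * k_O - kd * k_D)`.
#' * `mol_to_l`: 22.4 L/mol (STP).
#' * `rq`: respiratory quotient 0.86 fixed for the TDEE conversion.
#'
#' @return Named list of constants.
#' @export
dlw_constants <- function() {
  list(
    r_std_2h = 155.76e-6,
    r_std_18o = 2005.20e-6,
    exch_2h = 1.041,
    exch_18o = 1.007,
    molar_mass_water = 18.02,
    two_point = c(co2 = 0.4554, ko = 1.01, kd = 1.04),
    mol_to_l = 22.4,
    rq = 0.86
  )
}

#' Convert isotope enrichment from delta-permil to mole fraction
#'
#' `delta` is the per-mil deviation of the isotope ratio from the standard
#' ratio `r_std`; the mole fraction is `R / (1 + R)` with
#' `R = r_std * (1 + delta/1000)`.
#'
#' @param delta Enrichment in delta-permil vs the standard.
#' @param r_std Standard isotope ratio (e.g. `dlw_constants()$r_std_18o`).
#' @return Mole fraction of the heavy isotope.
#' @export
delta_to_molefrac <- function(delta, r_std) {
  R <- r_std * (1 + delta / 1000)
  R / (1 + R)
}

#' Convert a heavy-isotope mole fraction back to delta-permil
#' @param x Mole fraction.
#' @param r_std Standard isotope ratio.
#' @return delta-permil enrichment.
#' @export
molefrac_to_delta <- function(x, r_std) {
  R <- x / (1 - x)
  (R / r_std - 1) * 1000
}

#' Weir equation energy expenditure
#'
#' `EE = 3.9 * VO2 + 1.1 * VCO2` with gas volumes in litres and energy in
#' kcal. Vectorized; linear and homogeneous in its arguments.
#'
#' @param vo2,vco2 Oxygen consumed and carbon dioxide produced (L).
#' @return Energy expenditure (kcal).
#' @export
weir_energy <- function(vo2, vco2) {
  if (any(vo2 < 0) || any(vco2 < 0)) stop("gas volumes must be non-negative")
  3.9 * vo2 + 1.1 * vco2
}

#' Resting metabolic rate from a 60-minute gas-exchange trace
#'
#' Applies the Weir equation per minute and averages the final 20 minutes
#' (minutes 40-59 of a 0-indexed hour): the settling period of a
#' whole-room measurement is discarded. The per-minute mean is scaled to
#' kcal/day.
#'
#' @param trace Data frame with columns `minute` (0..59), `vo2_L`,
#'   `vco2_L` (per-minute gas volumes in litres).
#' @param window Minutes used for the average (default the final 20).
#' @return RMR in kcal/day.
#' @export
rmr_from_trace <- function(trace, window = 40:59) {
  req <- c("minute", "vo2_L", "vco2_L")
  if (!all(req %in% names(trace))) {
    stop("trace needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(trace) < 60L) {
    stop("trace must cover 60 one-minute readings (got ", nrow(trace), ")")
  }
  if (is.unsorted(trace$minute, strictly = TRUE)) {
    stop("minute index must be strictly increasing")
  }
  sel <- trace$minute %in% window
  if (sum(sel) != length(window)) stop("trace does not cover the RMR window")
  ee_min <- weir_energy(trace$vo2_L[sel], trace$vco2_L[sel])
  mean(ee_min) * 1440
}

#' Isotope dilution space from the post-dose enrichment plateau
#'
#' `N = (dose_g / molar_mass) * (ape / 100) / rise`, where `rise` is the
#' heavy-isotope mole-fraction excess of the plateau (mean of the 4 h and
#' 5 h samples) over baseline.
#'
#' @param dose_g Dose mass (g) of labeled water.
#' @param ape Atom-percent excess of the dose (e.g. 10 for 18O, 99.9 for 2H).
#' @param molar_mass Molar mass of the dose water (g/mol).
#' @param rise Plateau-minus-baseline mole-fraction excess (> 0).
#' @return Dilution space (mol of body water).
#' @export
dilution_space <- function(dose_g, ape, molar_mass, rise) {
  stopifnot_scalar(dose_g, "dose_g")
  stopifnot_scalar(rise, "rise")
  if (dose_g <= 0) stop("dose must be positive")
  if (rise <= 0) {
    stop("enrichment rise must be positive (dose not detected / sample swap)")
  }
  (dose_g / molar_mass) * (ape / 100) / rise
}

#' Total body water from exchange-corrected dilution spaces
#'
#' `TBW_mol = ((N_D / exch_2h) + (N_O / exch_18o)) / 2`, converted to kg at
#' the molar mass of water. The deuterium space exceeds the oxygen space by
#' a few percent because 2H exchanges with non-aqueous hydrogen; a ratio
#' `N_D / N_O` outside \[1.0, 1.1\] triggers a warning.
#'
#' @param n_d,n_o Deuterium and oxygen-18 dilution spaces (mol).
#' @param constants Constant set, see [dlw_constants()].
#' @return List with `tbw_mol` and `tbw_kg`.
#' @export
total_body_water <- function(n_d, n_o, constants = dlw_constants()) {
  if (n_d <= 0 || n_o <= 0) stop("dilution spaces must be positive")
  ratio <- n_d / n_o
  if (ratio < 1.0 || ratio > 1.1) {
    warning(sprintf("implausible dilution-space ratio N_D/N_O = %.4f", ratio))
  }
  tbw_mol <- (n_d / constants$exch_2h + n_o / constants$exch_18o) / 2
  list(tbw_mol = tbw_mol, tbw_kg = tbw_mol * constants$molar_mass_water / 1000)
}

#' Isotope elimination rate from two enrichment time points
#'
#' `k = ln(start / end) / dt` on baseline-subtracted mole-fraction
#' excesses: `start` is the post-dose plateau excess, `end` the mean
#' day-10 void excess.
#'
#' @param enrich_start,enrich_end Mole-fraction excesses (> 0).
#' @param dt_days Elapsed time between the two points (days).
#' @return Elimination rate (1/day).
#' @export
elimination_rate <- function(enrich_start, enrich_end, dt_days) {
  if (enrich_start <= 0 || enrich_end <= 0) {
    stop("enrichment excesses must be positive")
  }
  if (dt_days <= 0) stop("dt must be positive")
  if (enrich_end >= enrich_start) {
    stop("final enrichment must lie below the plateau (no elimination)")
  }
  log(enrich_start / enrich_end) / dt_days
}

#' CO2 production rate from two-point DLW kinetics
#'
#' Constant-folded Schoeller-form two-point equation:
#' `rCO2 [mol/day] = 0.4554 * TBW_mol * (1.01 * k_O - 1.04 * k_D)`, with
#' the fractionated-water correction folded into the multipliers
#' (configurable via `constants$two_point`). Converted to L/day at STP.
#'
#' @param tbw_mol Total body water (mol).
#' @param k_o,k_d Oxygen-18 and deuterium elimination rates (1/day);
#'   physiology requires `k_o > k_d`.
#' @param constants Constant set, see [dlw_constants()].
#' @return List with `rco2_mol_day` and `rco2_l_day`.
#' @export
rco2_two_point <- function(tbw_mol, k_o, k_d, constants = dlw_constants()) {
  if (tbw_mol <= 0) stop("TBW must be positive")
  if (k_o <= 0 || k_d <= 0) stop("elimination rates must be positive")
  tp <- constants$two_point
  rate <- tp[["ko"]] * k_o - tp[["kd"]] * k_d
  if (rate <= 0) {
    stop("k_O <= (", tp[["kd"]], "/", tp[["ko"]], ") * k_D: ",
         "non-positive CO2 production (degenerate kinetics)")
  }
  mol_day <- tp[["co2"]] * tbw_mol * rate
  list(rco2_mol_day = mol_day, rco2_l_day = mol_day * constants$mol_to_l)
}

#' TDEE from the CO2 production rate at a fixed respiratory quotient
#'
#' With `VO2 = rCO2 / RQ`, the Weir equation gives
#' `TDEE = rCO2 * (3.9 / RQ + 1.1)` kcal/day.
#'
#' @param rco2_l_day CO2 production (L/day, >= 0).
#' @param rq Respiratory quotient in \[0.7, 1.0\] (default 0.86).
#' @return TDEE (kcal/day); 0 maps to 0.
#' @export
tdee_from_rco2 <- function(rco2_l_day, rq = dlw_constants()$rq) {
  if (rq < 0.7 || rq > 1.0) stop("respiratory quotient outside [0.7, 1.0]")
  if (any(rco2_l_day < 0)) stop("CO2 production must be non-negative")
  rco2_l_day * (3.9 / rq + 1.1)
}

#' Energy expenditure normalized to fat-free mass
#'
#' @param ee Energy expenditure (kcal/day).
#' @param ffm Fat-free mass (kg, > 0).
#' @return kcal per kg FFM per day.
#' @export
adaptive_ee <- function(ee, ffm) {
  if (any(ffm <= 0)) stop("fat-free mass must be positive")
  ee / ffm
}

#' Metabolic adaptation: measured minus body-composition-predicted EE change
#'
#' Fits ordinary least squares of baseline energy expenditure on baseline
#' fat-free mass and fat mass across the cohort, predicts each subject's
#' post-intervention EE from their post body composition with the baseline
#' coefficients, and returns
#' `adaptation = (EE_post - EE_pre) - (EE_post_hat - EE_pre_hat)` in
#' kcal/day. Negative values indicate energy conservation beyond what the
#' tissue change predicts. The alternative `"delta_reg"` method regresses
#' the EE change on the body-composition changes (with intercept, which
#' absorbs any cohort-mean adaptation) and returns its residuals.
#'
#' @param cohort Data frame with columns `<which>_pre`, `<which>_post`,
#'   `ffm_pre`, `fm_pre`, `ffm_post`, `fm_post`.
#' @param which `"rmr"` or `"tdee"`.
#' @param method `"baseline_coeff"` (default) or `"delta_reg"`.
#' @param kappa_max Condition-number threshold above which the FFM/FM
#'   design is declared collinear.
#' @return List with `adaptation` (named by `subject_id` when present),
#'   `coefficients`, `method`.
#' @export
metabolic_adaptation <- function(cohort, which = c("rmr", "tdee"),
                                 method = c("baseline_coeff", "delta_reg"),
                                 kappa_max = 1e8) {
  which <- match.arg(which)
  method <- match.arg(method)
  ee_pre <- cohort[[paste0(which, "_pre")]]
  ee_post <- cohort[[paste0(which, "_post")]]
  need <- c("ffm_pre", "fm_pre", "ffm_post", "fm_post")
  if (is.null(ee_pre) || is.null(ee_post) || !all(need %in% names(cohort))) {
    stop("cohort lacks required energy/body-composition columns")
  }
  cc <- stats::complete.cases(ee_pre, ee_post, cohort$ffm_pre, cohort$fm_pre,
                              cohort$ffm_post, cohort$fm_post)
  if (sum(cc) < 5L) stop("need at least 5 subjects with complete data")
  ffm0 <- cohort$ffm_pre[cc]; fm0 <- cohort$fm_pre[cc]
  ffm1 <- cohort$ffm_post[cc]; fm1 <- cohort$fm_post[cc]
  e0 <- ee_pre[cc]; e1 <- ee_post[cc]
  if (method == "baseline_coeff") {
    X <- cbind(1, ffm0, fm0)
    if (kappa(X, exact = TRUE) > kappa_max) {
      stop("FFM and FM are collinear at baseline; consider an FFM-only model")
    }
    beta <- stats::lm.fit(X, e0)$coefficients
    pred0 <- drop(X %*% beta)
    pred1 <- drop(cbind(1, ffm1, fm1) %*% beta)
    adaptation <- (e1 - e0) - (pred1 - pred0)
  } else {
    Xd <- cbind(1, ffm1 - ffm0, fm1 - fm0)
    if (kappa(Xd, exact = TRUE) > kappa_max) {
      stop("FFM and FM changes are collinear; consider an FFM-only model")
    }
    fit <- stats::lm.fit(Xd, e1 - e0)
    beta <- fit$coefficients
    adaptation <- fit$residuals
  }
  if (!is.null(cohort$subject_id)) {
    names(adaptation) <- cohort$subject_id[cc]
  }
  list(adaptation = adaptation, coefficients = beta, method = method,
       which = which, n = sum(cc))
}
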