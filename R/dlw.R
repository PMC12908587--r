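# The full doubly-labeled-water inversion: enrichment record -> TDEE.

dlw_record_columns <- function() {
  c("dose_2h_g", "dose_18o_g", "ape_2h", "ape_18o",
    "delta_2h_baseline", "delta_2h_plateau4h", "delta_2h_plateau5h",
    "delta_2h_final2", "delta_2h_final3",
    "delta_18o_baseline", "delta_18o_plateau4h", "delta_18o_plateau5h",
    "delta_18o_final2", "delta_18o_final3",
    "dt_days", "elapsed_days", "body_mass_kg")
}

#' Invert one doubly-labeled-water record to TDEE
#'
#' Runs the full chain on a single enrichment record: delta-permil to
#' mole-fraction conversion, plateau rises (mean of 4 h and 5 h samples
#' minus baseline), dilution spaces, exchange-corrected total body water,
#' two-point elimination rates from the plateau to the mean day-10 voids,
#' CO2 production, and TDEE at the fixed respiratory quotient.
#'
#' @param record One-row data frame (or list) with the columns of
#'   [dlw_record_columns()]: dose masses (g), dose atom-percent excesses,
#'   2H and 18O enrichments (delta-permil) at baseline / 4 h / 5 h plateau /
#'   two day-10 voids, `dt_days` (plateau-to-final elapsed days), and
#'   `body_mass_kg`.
#' @param constants Constant set, see [dlw_constants()].
#' @param rq Respiratory quotient for the energy conversion.
#' @return List with `tdee` (kcal/day), `rco2_l_day`, `tbw_kg`, `tbw_mol`,
#'   `n_d`, `n_o`, `k_d`, `k_o`.
#' @export
dlw_tdee <- function(record, constants = dlw_constants(),
                     rq = constants$rq) {
  record <- as.list(record)
  missing_cols <- setdiff(dlw_record_columns(), names(record))
  if (length(missing_cols) > 0L) {
    stop("DLW record lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (isTRUE(record$degenerate)) {
    stop("record flagged degenerate (k_O ~ k_D); CO2 production undefined")
  }
  mm <- constants$molar_mass_water

  chain_one <- function(iso) {
    r_std <- constants[[paste0("r_std_", iso)]]
    d <- function(col) delta_to_molefrac(record[[paste0("delta_", iso, "_", col)]], r_std)
    x_base <- d("baseline")
    x_plateau <- (d("plateau4h") + d("plateau5h")) / 2
    x_final <- (d("final2") + d("final3")) / 2
    rise <- x_plateau - x_base
    excess_end <- x_final - x_base
    if (excess_end <= 0) {
      stop("day-10 ", iso, " enrichment at or below baseline")
    }
    N <- dilution_space(record[[paste0("dose_", iso, "_g")]],
                        record[[paste0("ape_", iso)]], mm, rise)
    k <- elimination_rate(rise, excess_end, record$dt_days)
    list(N = N, k = k)
  }

  h <- chain_one("2h")
  o <- chain_one("18o")
  tbw <- total_body_water(h$N, o$N, constants)
  if (tbw$tbw_kg >= record$body_mass_kg) {
    warning("total body water exceeds body mass; check record")
  }
  rco2 <- rco2_two_point(tbw$tbw_mol, o$k, h$k, constants)
  tdee <- tdee_from_rco2(rco2$rco2_l_day, rq)
  list(tdee = tdee, rco2_l_day = rco2$rco2_l_day,
       tbw_kg = tbw$tbw_kg, tbw_mol = tbw$tbw_mol,
       n_d = h$N, n_o = o$N, k_d = h$k, k_o = o$k, rq = rq)
}

#' Invert a table of DLW records
#'
#' @param records Data frame, one row per subject x timepoint, with the
#'   columns of [dlw_record_columns()] plus optional `subject_id`,
#'   `timepoint`.
#' @param constants,rq See [dlw_tdee()].
#' @return Data frame with the per-record kinetics and TDEE appended.
#' @export
dlw_tdee_table <- function(records, constants = dlw_constants(),
                           rq = constants$rq) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    res <- dlw_tdee(records[i, , drop = FALSE], constants, rq)
    data.frame(tdee = res$tdee, rco2_l_day = res$rco2_l_day,
               tbw_kg = res$tbw_kg, n_d = res$n_d, n_o = res$n_o,
               k_d = res$k_d, k_o = res$k_o)
  })
  cbind(records[, intersect(c("subject_id", "timepoint"), names(records)),
                drop = FALSE],
        do.call(rbind, out))
}
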