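# Assemble the complete synthetic study and write/read it as plain text.

#' Simulate a complete synthetic study
#'
#' Runs every generator with seeds derived from `config$seed`: cohort and
#' ground truth, a rooted phylogeny, pre/post abundance tables with
#' planted effects, one 60-minute gas-exchange trace per subject and
#' timepoint (settling artifact amplitude 0.3, 2% multiplicative noise),
#' and one DLW record per subject and timepoint (TBW = 0.73 x FFM;
#' analytic noise 1.0 permil for 2H and 0.25 permil for 18O, matching the
#' duplicate-QC tolerances of the assay).
#'
#' @param config A [synth_config()].
#' @param trace_noise_sd,trace_settle Gas-trace noise and settling
#'   amplitude.
#' @param dlw_noise_2h,dlw_noise_18o DLW analytic noise (delta-permil).
#' @return List of class `gf_study`: `config`, `cohort`, `truth`, `tree`,
#'   `abundance` (table + metadata + planted info), `traces` (named list
#'   of data frames, `"S01_pre"` ...), `dlw` (data frame of records).
#' @export
simulate_study <- function(config = synth_config(), trace_noise_sd = 0.02,
                           trace_settle = 0.3, dlw_noise_2h = 1.0,
                           dlw_noise_18o = 0.25) {
  stopifnot(inherits(config, "gf_synth_config"))
  gen <- generate_cohort(config)
  tree <- generate_tree(config$n_species, seed = derive_seed(config$seed, 2L))
  abundance <- generate_abundance(config, gen$cohort, gen$truth, tree)
  n <- nrow(gen$cohort)
  traces <- list()
  dlw_rows <- list()
  for (i in seq_len(n)) {
    for (tp in c("pre", "post")) {
      key <- paste0(gen$cohort$subject_id[i], "_", tp)
      rmr_true <- gen$truth[[paste0("rmr_true_", tp)]][i]
      tdee_true <- gen$truth[[paste0("tdee_true_", tp)]][i]
      ffm <- gen$cohort[[paste0("ffm_", tp)]][i]
      weight <- gen$cohort[[paste0("weight_", tp)]][i]
      traces[[key]] <- generate_gas_trace(
        rmr_true, noise_sd = trace_noise_sd,
        seed = derive_seed(config$seed, 100L + 2L * i + (tp == "post")),
        settle_amplitude = trace_settle)
      rec <- generate_dlw_record(
        tdee_true, tbw_true = 0.73 * ffm, body_mass = weight,
        seed = derive_seed(config$seed, 300L + 2L * i + (tp == "post")),
        noise_delta_2h = dlw_noise_2h, noise_delta_18o = dlw_noise_18o)
      dlw_rows[[key]] <- cbind(
        data.frame(subject_id = gen$cohort$subject_id[i], timepoint = tp,
                   stringsAsFactors = FALSE), rec)
    }
  }
  dlw <- do.call(rbind, dlw_rows)
  rownames(dlw) <- NULL
  structure(list(config = config, cohort = gen$cohort, truth = gen$truth,
                 tree = tree, abundance = abundance, traces = traces,
                 dlw = dlw),
            class = "gf_study")
}

#' Write a synthetic study to plain-text files
#'
#' Layout under `dir`: `participants.csv`, `dlw.csv`,
#' `traces/<sample>.csv`, `abundance.tsv` (first column `species_id`, one
#' column per sample), `tree.nwk`, `ground_truth.json`,
#' `sample_metadata.csv`, and `run_manifest.json` recording the seed and
#' configuration.
#'
#' @param study A `gf_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "gf_study"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$cohort, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(study$dlw, file.path(dir, "dlw.csv"), row.names = FALSE)
  for (key in names(study$traces)) {
    utils::write.csv(study$traces[[key]],
                     file.path(dir, "traces", paste0(key, ".csv")),
                     row.names = FALSE)
  }
  ab <- data.frame(species_id = colnames(study$abundance$table),
                   t(study$abundance$table), check.names = FALSE)
  utils::write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(study$abundance$metadata,
                   file.path(dir, "sample_metadata.csv"), row.names = FALSE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(truth = study$truth,
         predictor_species = study$abundance$predictor_species,
         realized_correlations = as.list(study$abundance$realized)),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(seed = study$config$seed, config = unclass(study$config),
         created = format(Sys.time(), tz = "UTC"),
         package_version = as.character(utils::packageVersion("gutfit"))),
    file.path(dir, "run_manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read an abundance table written by [write_study()]
#'
#' @param path Path to the TSV (first column `species_id`, one column per
#'   sample).
#' @return Samples x species matrix.
#' @export
read_abundance <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- t(as.matrix(raw[, -1L, drop = FALSE]))
  colnames(m) <- raw$species_id
  m
}
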