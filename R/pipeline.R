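# End-to-end pipeline: simulate -> energetics -> classify -> diversity ->
# screen -> associate.

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes every stage of the analysis exactly as it would run on real
#' inputs: RMR from the calorimetry traces, TDEE from the DLW records,
#' responder classification and baseline balance, alpha/beta diversity
#' with PERMANOVA, dispersion and centroid-distance tests, the species
#' filter and cross-validated AUROC screen (with the multivariate
#' regularized check and the planted-vs-other AUROC comparison), and the
#' diversity-adaptation association panel.
#'
#' @param config A [synth_config()]; its seed drives everything.
#' @param study Optional pre-built study (from [simulate_study()]);
#'   simulated from `config` when `NULL`.
#' @param n_perm Permutations for PERMANOVA / dispersion tests.
#' @param screen_repeats,screen_k Cross-validation design of the screen.
#' @param out_dir Optional directory: when given, the study inputs and the
#'   key result tables are written there as plain text.
#' @return List of class `gf_pipeline` with components `study`, `energy`,
#'   `labels`, `balance`, `paired`, `adaptation`, `alpha`, `beta`,
#'   `screen`, `multivariate`, `group_auroc`, `associations`.
#' @export
run_study_pipeline <- function(config = synth_config(), study = NULL,
                               n_perm = 999, screen_repeats = 10L,
                               screen_k = 3L, out_dir = NULL) {
  if (is.null(study)) study <- simulate_study(config)
  cohort <- study$cohort
  n <- nrow(cohort)

  # --- energetics -----------------------------------------------------
  rmr <- vapply(study$traces, rmr_from_trace, numeric(1))
  tdee_tab <- dlw_tdee_table(study$dlw)
  key <- function(tp) paste0(cohort$subject_id, "_", tp)
  energy <- data.frame(
    subject_id = cohort$subject_id,
    rmr_pre = unname(rmr[key("pre")]), rmr_post = unname(rmr[key("post")]),
    tdee_pre = tdee_tab$tdee[match(key("pre"),
                                   paste0(tdee_tab$subject_id, "_",
                                          tdee_tab$timepoint))],
    tdee_post = tdee_tab$tdee[match(key("post"),
                                    paste0(tdee_tab$subject_id, "_",
                                           tdee_tab$timepoint))],
    stringsAsFactors = FALSE)
  energy$adaptive_rmr_pre <- adaptive_ee(energy$rmr_pre, cohort$ffm_pre)
  energy$adaptive_rmr_post <- adaptive_ee(energy$rmr_post, cohort$ffm_post)
  energy$adaptive_tdee_pre <- adaptive_ee(energy$tdee_pre, cohort$ffm_pre)
  energy$adaptive_tdee_post <- adaptive_ee(energy$tdee_post, cohort$ffm_post)
  cohort_energy <- merge(cohort, energy, by = "subject_id", sort = FALSE)

  # --- response -------------------------------------------------------
  labels <- classify_response(cohort)
  balance <- baseline_balance(cohort, labels)
  grp <- factor(ifelse(labels$responder, "responder", "non_responder"))
  paired <- list(
    weight = paired_change_test(cohort$weight_pre, cohort$weight_post, grp),
    vo2max = paired_change_test(cohort$vo2max_pre, cohort$vo2max_post, grp))

  adaptation <- list(
    rmr = metabolic_adaptation(cohort_energy, "rmr"),
    tdee = metabolic_adaptation(cohort_energy, "tdee"))

  # --- diversity ------------------------------------------------------
  tab <- study$abundance$table
  meta <- study$abundance$metadata
  alpha <- alpha_diversity(tab, study$tree)
  alpha <- merge(alpha, meta, by = "sample_id", sort = FALSE)
  sample_resp <- meta$responder[match(rownames(tab), meta$sample_id)]
  beta <- list()
  for (metric in c("weighted_unifrac", "bray_curtis")) {
    D <- beta_diversity(tab, metric, tree = study$tree)
    perm <- permanova(D, sample_resp, n_perm = n_perm,
                      seed = derive_seed(config$seed, 11L))
    disp <- dispersion_test(D, sample_resp, n_perm = n_perm,
                            seed = derive_seed(config$seed, 12L))
    beta[[metric]] <- list(D = D, permanova = perm, dispersion = disp,
                           centroid = centroid_distance_comparison(disp))
  }

  # --- screen ---------------------------------------------------------
  pre_ids <- meta$sample_id[meta$timepoint == "pre"]
  tab_pre <- tab[pre_ids, , drop = FALSE]
  resp_pre <- meta$responder[match(pre_ids, meta$sample_id)]
  kept <- filter_species(tab_pre)
  screen <- univariate_auroc_screen(tab_pre[, kept, drop = FALSE], resp_pre,
                                    repeats = screen_repeats, k = screen_k,
                                    seed = derive_seed(config$seed, 13L))
  multivariate <- multivariate_regularized(tab_pre[, kept, drop = FALSE],
                                           resp_pre,
                                           seed = derive_seed(config$seed, 14L))
  planted <- intersect(study$abundance$predictor_species, kept)
  group_auroc <- if (length(planted) > 0L && length(planted) < length(kept)) {
    compare_group_aurocs(screen, planted)
  } else NULL

  # --- associations ---------------------------------------------------
  h_pre <- alpha$shannon[match(key("pre"), alpha$sample_id)]
  h_post <- alpha$shannon[match(key("post"), alpha$sample_id)]
  associations <- diversity_adaptation_analysis(
    h_pre, h_post - h_pre,
    adaptation$rmr$adaptation[cohort$subject_id],
    adaptation$tdee$adaptation[cohort$subject_id])

  result <- structure(
    list(study = study, energy = cohort_energy, labels = labels,
         balance = balance, paired = paired, adaptation = adaptation,
         alpha = alpha, beta = beta, screen = screen,
         multivariate = multivariate, group_auroc = group_auroc,
         associations = associations),
    class = "gf_pipeline")

  if (!is.null(out_dir)) {
    write_study(study, out_dir)
    utils::write.csv(labels, file.path(out_dir, "response_labels.csv"),
                     row.names = FALSE)
    utils::write.table(balance, file.path(out_dir, "balance_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(screen),
                       file.path(out_dir, "screen_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(cohort_energy, file.path(out_dir, "energy_outcomes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(
        permanova = lapply(beta, function(b)
          list(f = b$permanova$f, p = b$permanova$p.value)),
        dispersion = lapply(beta, function(b)
          list(f = b$dispersion$f, p = b$dispersion$p.value)),
        centroid_comparison = lapply(beta, function(b)
          list(p = b$centroid$p.value)),
        associations = lapply(
          associations[c("pre_rmr", "pre_tdee", "delta_rmr", "delta_tdee")],
          function(a) list(r = a$r, p = a$p.value, n = a$n))),
      file.path(out_dir, "test_report.json"), digits = NA, auto_unbox = TRUE)
  }
  result
}

#' @method print gf_pipeline
#' @export
print.gf_pipeline <- function(x, ...) {
  counts <- attr(x$labels, "counts")
  cat("gutfit pipeline run\n")
  cat(sprintf("  subjects: %d (%d responders / %d non-responders)\n",
              nrow(x$energy), counts[["responder"]],
              counts[["non_responder"]]))
  cat(sprintf("  baseline balanced: %s\n", attr(x$balance, "balanced")))
  for (m in names(x$beta)) {
    cat(sprintf("  %s: PERMANOVA p = %.4g, dispersion p = %.4g\n",
                m, x$beta[[m]]$permanova$p.value,
                x$beta[[m]]$dispersion$p.value))
  }
  cat(sprintf("  highly predictive species: %d of %d screened\n",
              sum(x$screen$highly_predictive), nrow(x$screen)))
  a <- x$associations
  cat(sprintf("  dShannon ~ TDEE adaptation: r = %.2f (p = %.3g)\n",
              a$delta_tdee$r, a$delta_tdee$p.value))
  cat(sprintf("  Shannon(pre) ~ RMR adaptation: r = %.2f (p = %.3g)\n",
              a$pre_rmr$r, a$pre_rmr$p.value))
  invisible(x)
}
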