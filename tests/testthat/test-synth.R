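# Synthetic-data generators: determinism, planted structure, file I/O.

test_that("synth_config validates its invariants", {
  expect_s3_class(synth_config(), "gf_synth_config")
  expect_error(synth_config(responder_fraction = 1), "strictly")
  expect_error(synth_config(n_subjects = 6, responder_fraction = 0.1),
               "rank tests")
  expect_error(synth_config(rho_shannon_tdee = 1), "rho")
  expect_error(synth_config(n_predictor_species = 300, n_species = 300),
               "smaller")
})

test_that("generate_cohort plants the configured responder count", {
  cfg <- synth_config(seed = 71)
  gen <- generate_cohort(cfg)
  co <- gen$cohort
  expect_equal(nrow(co), 16)
  expect_equal(sum(gen$truth$responder_true), 8)
  score <- (co$ffm_post - co$ffm_pre) - (co$fm_post - co$fm_pre)
  expect_identical(score > 0, gen$truth$responder_true)
  expect_true(all(co$age >= 21 & co$age <= 45))
  expect_true(all(co$bmi_pre >= 25 & co$bmi_pre <= 30))
  expect_equal(sum(co$sex == "F"), 8)
  expect_equal(co$fm_pre + co$ffm_pre, co$weight_pre, tolerance = 0.02)
  # weight change centered near zero at the cohort level
  expect_lt(abs(mean(co$weight_post - co$weight_pre)), 2.1)
  # non-default responder fraction
  gen2 <- generate_cohort(synth_config(seed = 72, responder_fraction = 0.25))
  expect_equal(sum(gen2$truth$responder_true), 4)
})

test_that("classify_response recovers ground-truth labels exactly", {
  for (s in 73:77) {
    gen <- generate_cohort(synth_config(seed = s))
    labels <- classify_response(gen$cohort)
    expect_identical(labels$responder, gen$truth$responder_true)
  }
})

test_that("gas traces invert to the true RMR", {
  tr <- generate_gas_trace(1720.8, noise_sd = 0)
  expect_equal(tr$vo2_L, rep(0.25, 60))
  expect_equal(tr$vco2_L, rep(0.20, 60))
  expect_equal(rmr_from_trace(tr), 1720.8)
  # settling artifact only touches minutes 0-39
  tr_s <- generate_gas_trace(1720.8, noise_sd = 0, settle_amplitude = 0.3)
  expect_gt(tr_s$vo2_L[1], 0.25)
  expect_equal(rmr_from_trace(tr_s), 1720.8)
  # noisy recovery is unbiased to < 0.5%
  recovered <- vapply(1:200, function(s) {
    rmr_from_trace(generate_gas_trace(1800, noise_sd = 0.02, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(recovered) / 1800 - 1), 0.005)
  expect_error(generate_gas_trace(1800, noise_sd = -1), "non-negative")
})

test_that("DLW records follow the dosing protocol", {
  rec <- generate_dlw_record(2700, tbw_true = 36.5, body_mass = 82)
  expect_equal(rec$dose_18o_g, 1.8 * 36.5) # 65.7 g
  expect_equal(rec$dose_2h_g, 0.12 * 36.5)
  expect_equal(rec$ape_18o, 10)
  expect_equal(rec$ape_2h, 99.9)
  # monotone elimination: day-10 enrichment below the plateau
  expect_lt(rec$delta_18o_final2, rec$delta_18o_plateau4h)
  expect_error(generate_dlw_record(2700, 36.5, 82, rq = 1.2), "quotient")
})

test_that("trees cover the species universe deterministically", {
  tr <- generate_tree(30, seed = 78)
  expect_equal(sort(tr$tip.label), sprintf("sp%03d", 1:30))
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(generate_tree(30, seed = 78)))
  tr2 <- generate_tree(2, seed = 79)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(nrow(tr2$edge), 2)
  expect_error(generate_tree(1), "at least 2")
})

test_that("abundance tables are valid compositions with planted structure", {
  cfg <- synth_config(seed = 80)
  gen <- generate_cohort(cfg)
  tree <- generate_tree(cfg$n_species, seed = 81)
  ab <- generate_abundance(cfg, gen$cohort, gen$truth, tree)
  expect_equal(unname(rowSums(ab$table)), rep(1, 32), tolerance = 1e-9)
  expect_true(all(ab$table >= 0))
  expect_length(ab$predictor_species, 9)
  expect_true(all(ab$predictor_species %in% tree$tip.label))
  expect_true(all(is.finite(ab$realized)))
  # planted predictors are higher in responders at baseline
  pre <- ab$metadata$timepoint == "pre"
  resp <- ab$metadata$responder & pre
  nonresp <- !ab$metadata$responder & pre
  mean_diff <- colMeans(log(ab$table[resp, ab$predictor_species] + 1e-8)) -
    colMeans(log(ab$table[nonresp, ab$predictor_species] + 1e-8))
  expect_gt(mean(mean_diff), 0.5)
  # extreme planted effect degenerates the composition
  cfg_bad <- synth_config(seed = 80, predictor_log2_effect = 40,
                          n_predictor_species = 1)
  expect_error(generate_abundance(cfg_bad, gen$cohort, gen$truth, tree),
               "degenerate")
})

test_that("simulate_study is byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 82, n_subjects = 6, n_species = 40)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$abundance$table, s2$abundance$table)
  expect_identical(s1$dlw, s2$dlw)
  expect_identical(s1$traces, s2$traces)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("write_study round-trips through plain-text files", {
  cfg <- synth_config(seed = 83, n_subjects = 4, n_species = 25)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "run_manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  expect_equal(manifest$seed, 83)
  tab <- read_abundance(file.path(dir, "abundance.tsv"))
  expect_equal(tab, st$abundance$table, tolerance = 1e-12)
  co <- utils::read.csv(file.path(dir, "participants.csv"),
                        stringsAsFactors = FALSE)
  expect_equal(co$ffm_post, st$cohort$ffm_post)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, st$tree$tip.label)
})
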