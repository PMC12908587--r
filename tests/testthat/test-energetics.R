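# Calorimetry and DLW chain, unit by unit, then the full round trip.

test_that("weir_energy coefficients, linearity, errors", {
  expect_equal(weir_energy(1, 0), 3.9)
  expect_equal(weir_energy(0, 1), 1.1)
  expect_equal(weir_energy(0, 0), 0)
  expect_equal(weir_energy(452.4, 389.1), 3.9 * 452.4 + 1.1 * 389.1)
  set.seed(21)
  for (rep in 1:10) {
    x <- runif(1, 0, 2); y <- runif(1, 0, 2); a <- runif(1, 0, 5)
    expect_equal(weir_energy(a * x, a * y), a * weir_energy(x, y))
  }
  expect_error(weir_energy(-0.1, 0.2), "non-negative")
})

test_that("rmr_from_trace averages only the final 20 minutes", {
  tr <- data.frame(minute = 0:59, vo2_L = 0.25, vco2_L = 0.20)
  expect_equal(rmr_from_trace(tr), 1720.8)
  # junk in minutes 0-39 is irrelevant
  tr2 <- tr
  tr2$vo2_L[1:40] <- runif(40, 0, 5)
  tr2$vco2_L[1:40] <- runif(40, 0, 5)
  expect_equal(rmr_from_trace(tr2), 1720.8)
  expect_equal(rmr_from_trace(data.frame(minute = 0:59, vo2_L = 0,
                                         vco2_L = 0)), 0)
  expect_error(rmr_from_trace(tr[1:45, ]), "60")
})

test_that("dilution_space arithmetic, linearity, degenerate rise", {
  # 65.7 g of 10 APE dose water = 0.3646 mol excess; rise 1.643e-4
  n_o <- dilution_space(65.7, 10, 18.02, 1.643e-4)
  expect_equal(n_o, (65.7 / 18.02) * 0.1 / 1.643e-4, tolerance = 1e-12)
  expect_equal(n_o, 2219.1, tolerance = 1e-3)
  expect_equal(dilution_space(131.4, 10, 18.02, 1.643e-4), 2 * n_o)
  expect_error(dilution_space(65.7, 10, 18.02, 0), "rise")
})

test_that("total_body_water applies exchange corrections and warns", {
  res <- total_body_water(2311.0, 2235.5)
  expect_equal(res$tbw_mol, (2311.0 / 1.041 + 2235.5 / 1.007) / 2)
  expect_equal(res$tbw_kg, 40.0, tolerance = 1e-3)
  # constructed identity: N_D = 1.041 x, N_O = 1.007 x -> TBW_mol = x
  x <- 2000
  expect_equal(total_body_water(1.041 * x, 1.007 * x)$tbw_mol, x)
  expect_warning(total_body_water(2000, 2100), "ratio")
})

test_that("elimination_rate and its error paths", {
  expect_equal(elimination_rate(2e-4, 1e-4, 7), log(2) / 7)
  expect_equal(elimination_rate(4.0e-4, 1.2e-4, 9.75), log(10 / 3) / 9.75)
  expect_equal(elimination_rate(4.0e-4, 1.2e-4, 9.75), 0.123484,
               tolerance = 1e-5)
  expect_error(elimination_rate(2e-4, 2e-4, 7), "below the plateau")
})

test_that("rco2_two_point constants, boundary and linearity", {
  res <- rco2_two_point(2220, 0.12, 0.10)
  expect_equal(res$rco2_mol_day, 0.4554 * 2220 * (1.01 * 0.12 - 1.04 * 0.10))
  expect_equal(res$rco2_l_day, res$rco2_mol_day * 22.4)
  expect_equal(res$rco2_l_day, 389.5, tolerance = 0.1)
  expect_error(rco2_two_point(2220, 1.04 / 1.01 * 0.1, 0.1), "degenerate")
  expect_equal(rco2_two_point(4440, 0.12, 0.10)$rco2_l_day,
               2 * res$rco2_l_day)
})

test_that("tdee_from_rco2 respects the fixed RQ", {
  expect_equal(tdee_from_rco2(389.5, 0.86), 389.5 * (3.9 / 0.86 + 1.1))
  expect_equal(tdee_from_rco2(389.5, 0.86), 2194.9, tolerance = 0.2)
  expect_equal(tdee_from_rco2(1, 1.0), 5.0)
  expect_equal(tdee_from_rco2(0), 0)
  expect_error(tdee_from_rco2(100, 0.5), "quotient")
})

test_that("adaptive_ee normalizes per kg FFM", {
  expect_equal(adaptive_ee(2000, 50), 40)
  expect_equal(adaptive_ee(0, 50), 0)
  expect_equal(adaptive_ee(1720.8, 53.2), 1720.8 / 53.2)
  expect_error(adaptive_ee(2000, 0), "positive")
})

make_affine_cohort <- function(n, a, b, cc, seed) {
  set.seed(seed)
  ffm0 <- runif(n, 45, 65); fm0 <- runif(n, 20, 35)
  ffm1 <- ffm0 + rnorm(n, 0, 1); fm1 <- fm0 + rnorm(n, 0, 1)
  data.frame(subject_id = sprintf("S%02d", 1:n),
             ffm_pre = ffm0, fm_pre = fm0, ffm_post = ffm1, fm_post = fm1,
             rmr_pre = a + b * ffm0 + cc * fm0,
             rmr_post = a + b * ffm1 + cc * fm1)
}

test_that("metabolic_adaptation is zero on exactly affine cohorts", {
  co <- make_affine_cohort(16, 370, 21.6, 3.2, 22)
  res <- metabolic_adaptation(co, "rmr")
  expect_equal(unname(res$adaptation), rep(0, 16), tolerance = 1e-9)
  expect_equal(unname(res$coefficients), c(370, 21.6, 3.2), tolerance = 1e-8)
})

test_that("metabolic_adaptation equals measured dEE when composition is static", {
  co <- make_affine_cohort(10, 370, 21.6, 3.2, 23)
  co$ffm_post <- co$ffm_pre; co$fm_post <- co$fm_pre
  co$rmr_post <- co$rmr_pre + 120
  res <- metabolic_adaptation(co, "rmr")
  expect_equal(unname(res$adaptation), rep(120, 10), tolerance = 1e-9)
})

test_that("metabolic_adaptation recovers a planted shift on noisy cohorts", {
  means <- vapply(1:100, function(s) {
    co <- make_affine_cohort(16, 370, 21.6, 3.2, 1000 + s)
    set.seed(2000 + s)
    co$rmr_pre <- co$rmr_pre + rnorm(16, 0, 40)
    co$rmr_post <- co$rmr_post - 100 + rnorm(16, 0, 40)
    mean(metabolic_adaptation(co, "rmr")$adaptation)
  }, numeric(1))
  expect_lt(abs(mean(means) + 100), 15)
})

test_that("delta regression variant centers adaptation at zero", {
  co <- make_affine_cohort(16, 370, 21.6, 3.2, 24)
  co$rmr_post <- co$rmr_post - 100
  res <- metabolic_adaptation(co, "rmr", method = "delta_reg")
  expect_equal(mean(res$adaptation), 0, tolerance = 1e-9)
})

test_that("DLW forward model and inversion are exact inverses", {
  set.seed(25)
  for (rep in 1:10) {
    tdee <- runif(1, 1800, 3400); tbw <- runif(1, 28, 48)
    rec <- generate_dlw_record(tdee, tbw, body_mass = 85)
    inv <- dlw_tdee(rec)
    expect_equal(inv$tdee, tdee, tolerance = 1e-9)
    expect_equal(inv$tbw_kg, tbw, tolerance = 1e-9)
    expect_gt(inv$k_o, inv$k_d)
  }
})

test_that("degenerate DLW kinetics are flagged and refuse inversion", {
  rec <- generate_dlw_record(2500, 36, body_mass = 80, k_d = 0.1, k_o = 0.1)
  expect_true(rec$degenerate)
  expect_error(dlw_tdee(rec), "degenerate")
})
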