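# Synthetic cohort: volume and TGI formulas, growth model, correlation.

test_that("caliper volume formula and its symmetries", {
  expect_equal(tumor_volume(10, 10), 50)
  expect_equal(tumor_volume(7, 7), 24.5)
  expect_equal(tumor_volume(3 * 8, 3 * 5), 9 * tumor_volume(8, 5))
  expect_equal(tumor_volume(10, 4, formula = "lw2"), 80)
  expect_error(tumor_volume(4, 5))   # width must not exceed length
})

test_that("TGI worked examples evaluate exactly", {
  expect_equal(tgi(100, 150, 100, 300), 75)
  expect_equal(tgi(80, 80, 100, 250), 100)     # static treated tumor
  expect_equal(tgi(90, 180, 100, 200), 10)
  expect_equal(tgi(100, 200, 100, 200), 0)     # grows exactly like control
  expect_error(tgi(100, 150, 120, 120), "zero growth")
  # invariance under a common rescaling of all four volumes
  expect_equal(tgi(100, 150, 100, 300), tgi(700, 1050, 700, 2100))
})

test_that("zero-noise cohorts hit the closed-form limits", {
  aad <- c("40" = 0.4, "80" = 1, "120" = 0.8, "160" = 0.6)
  d0 <- cohort_design(noise_cv = 0, dose_effect_slope = 0, seed = 3)
  co0 <- simulate_cohort(d0, aad)
  expect_equal(co0$groups$tgi_percent[-1], rep(0, 4), tolerance = 1e-9)
  d1 <- cohort_design(noise_cv = 0, dose_effect_slope = 1, seed = 3)
  co1 <- simulate_cohort(d1, aad)
  # full suppression at AAD_norm = 1: treated tumor static -> TGI = 100
  expect_equal(co1$groups$tgi_percent[co1$groups$group == "80"], 100,
               tolerance = 1e-9)
  expect_error(simulate_cohort(d1, aad[-2]), "80")
  expect_error(simulate_cohort(d1, replace(aad, 1, 1.5)), "\\[0, 1\\]")
})

test_that("cohort simulation is deterministic and monotone in dose", {
  aad <- c("40" = 0.2, "80" = 0.9, "120" = 0.7, "160" = 0.5)
  d <- cohort_design(seed = 11)
  expect_identical(simulate_cohort(d, aad)$groups,
                   simulate_cohort(d, aad)$groups)
  co <- simulate_cohort(cohort_design(noise_cv = 0, seed = 5), aad)
  g <- co$groups[co$groups$group != "control", ]
  expect_equal(order(g$tgi_percent), order(aad[g$group]))
})

test_that("the effect slope is recovered exactly without noise", {
  aad <- c("40" = 0.3, "80" = 1, "120" = 0.75, "160" = 0.5)
  for (s in c(0.4, 0.8)) {
    d <- cohort_design(noise_cv = 0, dose_effect_slope = s, seed = 9)
    expect_equal(recover_effect_slope(simulate_cohort(d, aad)), s,
                 tolerance = 1e-6)
  }
})

test_that("pearson correlation matches hand-computed cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("TGI correlates with the generating dose metric", {
  aad <- c("40" = 0.55, "80" = 1, "120" = 0.85, "160" = 0.7)
  co <- simulate_cohort(cohort_design(noise_cv = 0, seed = 2), aad)
  expect_gt(correlate_aad_tgi(aad, co), 0.99)
  expect_error(correlate_aad_tgi(c("40" = 1, "80" = 1, "120" = 1,
                                   "160" = 1), co), "zero variance")
  # noisy replicates: the generating AAD beats an unrelated permutation
  perm <- setNames(aad[c(3, 4, 2, 1)], names(aad))
  r_gen <- r_perm <- numeric(200)
  for (i in seq_len(200)) {
    coi <- simulate_cohort(cohort_design(noise_cv = 0.15,
                                         dose_effect_slope = 0.8,
                                         seed = 1000 + i), aad)
    r_gen[i] <- correlate_aad_tgi(aad, coi)
    r_perm[i] <- correlate_aad_tgi(perm, coi)
  }
  expect_gt(median(r_gen), median(r_perm))
})
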