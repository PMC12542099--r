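test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- cohort_config(n_patients = 5, seed = 13)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_patients = 5, seed = 14))
  expect_false(identical(a[[1]]$ts$labels, c2[[1]]$ts$labels))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_patients = 1), "n_patients")
  expect_error(cohort_config(pcr_fraction = 1.2), "pcr_fraction")
  expect_error(cohort_config(grid_height = 0), "grid dimensions")
  co <- generate_cohort(cohort_config(n_patients = 10, pcr_fraction = 0.05,
                                      seed = 1))
  pcr <- vapply(co, function(p) p$pcr, 0)
  expect_true(all(c(0, 1) %in% pcr))   # both groups non-empty
})

test_that("pCR forces zero residual infiltration size", {
  co <- generate_cohort(cohort_config(n_patients = 12, pcr_fraction = 1,
                                      seed = 2))
  expect_true(all(vapply(co, function(p) p$ris_cm, 0) == 0))
  mixed <- generate_cohort(cohort_config(n_patients = 30, seed = 3))
  for (p in mixed) {
    if (p$pcr == 1) expect_identical(p$ris_cm, 0)
    else expect_gt(p$ris_cm, 0)
  }
})

test_that("non-pCR RIS is right-skewed with median near ris_scale", {
  co <- generate_cohort(cohort_config(n_patients = 300, pcr_fraction = 0.3,
                                      seed = 5, ris_scale = 1.35))
  ris <- vapply(co, function(p) p$ris_cm, 0)
  ris <- ris[ris > 0]
  expect_equal(median(ris), 1.35, tolerance = 0.2)
  expect_gt(mean(ris), median(ris))   # right skew
})

test_that("planted sTIL count shift matches the configured effect size", {
  cfg <- cohort_config(n_patients = 200, pcr_fraction = 0.5,
                       effect_size = 1.5, seed = 7)
  co <- generate_cohort(cfg)
  pcr <- vapply(co, function(p) p$pcr, 0)
  # realized component counts per slide
  k <- vapply(co, function(p) length(label_components(p$ts$labels == 5L)),
              0L)
  pp <- planted_params()
  std_diff <- (mean(k[pcr == 1]) - mean(k[pcr == 0])) / pp$count_sd
  se <- sqrt(2 / 100)   # two groups of ~100, counts have sd ~ count_sd
  expect_equal(std_diff, cfg$effect_size, tolerance = 3 * se)
  # Mann-Whitney on the count feature separates the groups decisively
  p_mw <- stats::wilcox.test(k[pcr == 1], k[pcr == 0],
                             exact = FALSE)$p.value
  expect_lt(p_mw, 0.01)
})

test_that("null effect leaves no morphological group difference", {
  co <- generate_cohort(cohort_config(n_patients = 200, pcr_fraction = 0.5,
                                      effect_size = 0, clinical_effect = 0,
                                      seed = 23))
  pcr <- vapply(co, function(p) p$pcr, 0)
  k <- vapply(co, function(p) length(label_components(p$ts$labels == 5L)),
              0L)
  p_mw <- stats::wilcox.test(k[pcr == 1], k[pcr == 0],
                             exact = FALSE)$p.value
  expect_gt(p_mw, 0.01)
})

test_that("label layout fractions match the configured priors", {
  co <- generate_cohort(cohort_config(n_patients = 50, seed = 31))
  pp <- planted_params()
  fr_exc <- vapply(co, function(p) mean(p$ts$labels == 0L), 0)
  fr_tum <- vapply(co, function(p) mean(p$ts$labels %in% c(1L, 3L, 4L)), 0)
  fr_str <- vapply(co, function(p) mean(p$ts$labels %in% c(2L, 5L)), 0)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(fr_exc) - pp$excluded_fraction), 3 * se(fr_exc) + 0.002)
  exp_tum <- (1 - pp$excluded_fraction) * pp$tumor_of_tissue
  expect_lt(abs(mean(fr_tum) - exp_tum), 3 * se(fr_tum) + 0.002)
  expect_lt(abs(mean(fr_str) - (1 - pp$excluded_fraction - exp_tum)),
            3 * se(fr_str) + 0.002)
})

test_that("clinical effect shifts PR positivity for the pCR group", {
  co <- generate_cohort(cohort_config(n_patients = 400, pcr_fraction = 0.5,
                                      clinical_effect = 2, seed = 17))
  pcr <- vapply(co, function(p) p$pcr, 0)
  pr <- vapply(co, function(p) p$pr, 0)
  expect_gt(mean(pr[pcr == 1]), mean(pr[pcr == 0]) + 0.15)
  # percentages: zero iff negative, in [10, 100] otherwise
  pct <- vapply(co, function(p) p$pr_pct, 0)
  expect_true(all(pct[pr == 0] == 0))
  expect_true(all(pct[pr == 1] >= 10 & pct[pr == 1] <= 100))
})

test_that("cohort writer round-trips losslessly and deterministically", {
  co <- generate_cohort(cohort_config(n_patients = 3, seed = 8))
  d1 <- withr::local_tempdir()
  write_cohort(co, d1)
  expect_length(list.files(d1, pattern = "\\.png$"), 3L)
  clin <- utils::read.csv(file.path(d1, "clinical.csv"))
  expect_equal(nrow(clin), 3L)
  back <- read_cohort(d1)
  for (i in 1:3) {
    expect_identical(back[[i]]$ts$labels, co[[i]]$ts$labels)
    expect_equal(back[[i]]$ris_cm, co[[i]]$ris_cm, tolerance = 1e-12)
  }
  # write -> read -> write gives a byte-identical manifest
  d2 <- withr::local_tempdir()
  write_cohort(back, d2)
  m1 <- readLines(file.path(d1, "manifest.json"))
  m2 <- readLines(file.path(d2, "manifest.json"))
  expect_identical(m1, m2)
  # writing the same cohort twice gives identical CSV contents
  d3 <- withr::local_tempdir()
  write_cohort(co, d3)
  expect_identical(readLines(file.path(d1, "clinical.csv")),
                   readLines(file.path(d3, "clinical.csv")))
})

test_that("feature-level simulator plants the requested informative set", {
  sim <- simulate_feature_cohort(n = 100, n_features = 20,
                                 n_informative = 3, effect = 2, seed = 9)
  expect_equal(dim(sim$x), c(100L, 20L))
  expect_length(sim$informative, 3L)
  gap <- colMeans(sim$x[sim$y == 1, sim$informative]) -
    colMeans(sim$x[sim$y == 0, sim$informative])
  expect_true(all(abs(gap - 2) < 0.6))
  expect_identical(sim, simulate_feature_cohort(n = 100, n_features = 20,
                                                n_informative = 3,
                                                effect = 2, seed = 9))
})
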