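test_that("genotype simulation respects Hardy-Weinberg proportions and edge MAFs", {
  cc <- cohort_config(n_subjects = 10000, seed = 3, effect_tree = NULL,
                      maf = c(zero = 0, half = 0.5, mid = 0.3))
  g <- simulate_genotypes(cc)
  expect_true(all(g$zero == 0))
  het <- mean(g$half == 1)
  # HWE heterozygote fraction 2pq = 0.5; 5 MC standard errors
  expect_lt(abs(het - 0.5), 5 * sqrt(0.25 / 10000))
  hw <- hwe_test(g$mid)
  expect_gt(hw$p, 1e-3)
  expect_error(cohort_config(n_subjects = 5, effect_tree = NULL,
                             maf = c(x = 0.7)),
               "maf")
})

test_that("simulated loci pass an HWE screen across many seeds", {
  ok <- 0L
  for (s in 1:60) {
    cc <- cohort_config(n_subjects = 20000, seed = s, effect_tree = NULL,
                        maf = c(v = 0.3))
    p <- hwe_test(simulate_genotypes(cc)$v)$p
    if (p > 1e-3) ok <- ok + 1L
  }
  expect_gte(ok, 59L)
})

test_that("covariate margins match the configured cohort profile", {
  cc <- cohort_config(seed = 8)   # n = 3729
  cv <- simulate_covariates(cc)
  expect_equal(nrow(cv), 3729)
  expect_lt(abs(mean(cv$stage == "II") - 0.55), 0.03)
  expect_lt(abs(mean(cv$chemotherapy) - 0.91), 0.02)
  expect_true(all(cv$initiation_day >= cv$diagnosis_day))
  expect_true(all(cv$stage %in% c("I", "II", "III")))
  expect_true(all(cv$grade %in% c("I", "II", "III", "not graded")))
  one <- simulate_covariates(cohort_config(n_subjects = 1, seed = 1))
  expect_equal(nrow(one), 1)
  expect_false(anyNA(one))
})

test_that("event generation matches its closed forms", {
  # null effect: discontinuation times independent of genotype
  cc0 <- cohort_config(n_subjects = 20000, seed = 4, effect_tree = NULL,
                       maf = c(v1 = 0.3))
  g <- simulate_genotypes(cc0)
  cv <- simulate_covariates(cc0)
  ev <- simulate_events(cc0, g, cv)
  lat <- ev$latent_discontinuation_day - cv$initiation_day
  ks <- suppressWarnings(stats::ks.test(lat[g$v1 == 0], lat[g$v1 >= 1]))
  expect_gt(ks$p.value, 0.01)

  # single-leaf effect: empirical hazard ratio for g=1 vs g=0 ~ exp(beta)
  beta <- 0.4
  cc1 <- cohort_config(n_subjects = 50000, seed = 5,
                       effect_tree = list(leaves = "v1", theta = 1, beta = beta),
                       maf = c(v1 = 0.3))
  g1 <- simulate_genotypes(cc1)
  cv1 <- simulate_covariates(cc1)
  ev1 <- simulate_events(cc1, g1, cv1)
  lat1 <- ev1$latent_discontinuation_day - cv1$initiation_day
  # exponential rate MLE per genotype group
  rate <- function(x) 1 / mean(x)
  hr <- rate(lat1[g1$v1 == 1]) / rate(lat1[g1$v1 == 0])
  expect_lt(abs(hr - exp(beta)) / exp(beta), 0.10)

  # two-locus interaction tree: double-variant homozygotes vs reference ~ 4
  cc2 <- cohort_config(n_subjects = 50000, seed = 6)
  g2 <- simulate_genotypes(cc2)
  cv2 <- simulate_covariates(cc2)
  ev2 <- simulate_events(cc2, g2, cv2)
  lat2 <- ev2$latent_discontinuation_day - cv2$initiation_day
  hi <- g2$rs16947 == 2 & g2$rs3740065 == 2
  lo <- g2$rs16947 == 0 & g2$rs3740065 == 0
  hr2 <- rate(lat2[hi]) / rate(lat2[lo])
  expect_lt(abs(hr2 - 4), 0.5)

  # no censoring: only the administrative cutoff remains
  cc3 <- cohort_config(n_subjects = 50, seed = 7, ai_switch_rate = 0,
                       censor_rates = c(recurrence = 0, death = 0, emigration = 0))
  g3 <- simulate_genotypes(cc3)
  cv3 <- simulate_covariates(cc3)
  ev3 <- simulate_events(cc3, g3, cv3)
  expect_true(all(ev3$admin_censor_day == cv3$diagnosis_day + 1825))
  expect_true(all(is.na(ev3$ai_switch_day)))
  expect_true(all(is.na(ev3$recurrence_day)))
})

test_that("supply schedules follow the 6-monthly refill rule", {
  cc <- cohort_config(n_subjects = 2, seed = 1)
  cv <- data.frame(subject_id = c("A", "B"), initiation_day = c(30L, 30L),
                   diagnosis_day = 0L)
  ev <- data.frame(subject_id = c("A", "B"),
                   latent_discontinuation_day = c(400L, 30L),
                   ai_switch_day = NA_integer_, recurrence_day = NA_integer_,
                   death_day = NA_integer_, emigration_day = NA_integer_,
                   admin_censor_day = 1825L)
  sup <- simulate_supplies(cc, ev, cv)
  expect_equal(sup$dispense_day[sup$subject_id == "A"], c(30L, 212L, 394L))
  expect_equal(sup$dispense_day[sup$subject_id == "B"], 30L)
  expect_true(all(sup$days_supplied == 182L))
})

test_that("missingness injection is MCAR at the requested rate", {
  cc <- cohort_config(n_subjects = 1000, seed = 2, effect_tree = NULL,
                      maf = c(a = 0.2, b = 0.3, c = 0.4, d = 0.1, e = 0.25,
                              f = 0.35, g = 0.15, h = 0.45, i = 0.3, j = 0.2))
  g <- simulate_genotypes(cc)
  expect_identical(inject_missingness(g, 0), g)
  gm <- inject_missingness(g, 0.1, seed = 11)
  n_na <- sum(is.na(tampath:::geno_matrix(gm)))
  expect_lt(abs(n_na - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  # original untouched
  expect_false(anyNA(g))
})

test_that("cohort generation is fully deterministic given config and seed", {
  cc <- cohort_config(n_subjects = 300, seed = 17, missing_rate = 0.05)
  c1 <- simulate_cohort(cc)
  c2 <- simulate_cohort(cc)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$supplies, c2$supplies)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]])
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("with no genetic effect the per-variant Cox screen is centred on the null", {
  zs <- c()
  for (s in 1:12) {
    cc <- cohort_config(n_subjects = 1200, seed = 100 + s, effect_tree = NULL,
                        missing_rate = 0,
                        maf = c(a = 0.2, b = 0.3, c = 0.4, d = 0.15, e = 0.35))
    ch <- simulate_cohort(cc)
    oc <- derive_cohort_outcomes(ch$supplies, ch$events, ch$covariates)
    sc <- per_variant_screen(ch$genotypes, oc, covariates = NULL, shrink = FALSE)
    zs <- c(zs, sc$z)
  }
  # fraction rejected at 5% within binomial error of 0.05
  frac <- mean(abs(zs) > 1.96)
  expect_lt(abs(frac - 0.05), 0.05 / 2 + 3 * sqrt(0.05 * 0.95 / length(zs)))
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)))
})
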