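test_that("MAF computation counts alleles and flips orientation", {
  expect_equal(compute_maf(c(0, 1, 2, 0, 1))$maf, 0.4)
  expect_equal(compute_maf(c(0, 0, 0))$maf, 0)
  fl <- compute_maf(c(2, 2, 2, 1))
  expect_equal(fl$maf, 0.125)
  expect_true(fl$flipped)
  expect_equal(fl$raw, 0.875)
  expect_error(compute_maf(c(NA, NA)), "all-missing")
})

test_that("HWE chi-square matches hand calculations", {
  perfect <- c(rep(0, 81), rep(1, 18), rep(2, 1))
  hw <- hwe_test(perfect)
  expect_equal(hw$chi2, 0, tolerance = 1e-12)
  expect_equal(hw$p, 1)
  # counts (50, 20, 30): q = 0.4, expected (36, 48, 16)
  dev <- c(rep(0, 50), rep(1, 20), rep(2, 30))
  hw2 <- hwe_test(dev)
  expect_equal(hw2$chi2, 14^2 / 36 + 28^2 / 48 + 14^2 / 16, tolerance = 1e-10)
  expect_equal(hw2$chi2, 34.03, tolerance = 0.005)
  expect_lt(hw2$p, 1e-7)
  expect_equal(hwe_test(c(rep(0, 25), rep(1, 50), rep(2, 25)))$chi2, 0,
               tolerance = 1e-12)
  expect_warning(hwe_test(c(0, 0, 0)), "monomorphic")
})

test_that("MAF and HWE agree with brute-force allele counting", {
  set.seed(21)
  for (i in 1:400) {
    n <- sample(10:80, 1)
    g <- sample(0:2, n, TRUE, prob = c(0.5, 0.3, 0.2))
    if (stats::runif(1) < 0.3) g[sample(n, 2)] <- NA
    if (all(is.na(g)) || length(unique(stats::na.omit(g))) < 2) next
    expect_equal(compute_maf(g)$maf, brute_maf(g), tolerance = 1e-12)
    if (brute_maf(g) > 0) {
      expect_equal(suppressWarnings(hwe_test(g)$chi2), brute_hwe_chi2(g),
                   tolerance = 1e-10)
    }
  }
})

test_that("QC filtering drops by threshold and exclusion list, idempotently", {
  set.seed(2)
  n <- 600
  G <- data.frame(subject_id = as.character(1:n),
                  good = rbinom(n, 2, 0.3),
                  rare = rbinom(n, 2, 0.02),
                  rs1048943 = rbinom(n, 2, 0.2))
  # a locus wildly out of HWE
  G$bad_hwe <- c(rep(0L, 300), rep(2L, 300))
  q <- qc_filter(G, excluded_rsids = "rs1048943")
  expect_equal(sort(q$report$rsid), sort(c("good", "rare", "rs1048943", "bad_hwe")))
  expect_equal(q$report$status[q$report$rsid == "rare"], "fail_maf")
  expect_equal(q$report$status[q$report$rsid == "bad_hwe"], "fail_hwe")
  expect_true(q$report$status[q$report$rsid == "rs1048943"] %in%
                c("fail_amplification", "fail_hwe"))
  expect_equal(names(q$genotypes), c("subject_id", "good"))
  # idempotent
  q2 <- qc_filter(q$genotypes, excluded_rsids = "rs1048943")
  expect_identical(q2$genotypes, q$genotypes)
  expect_true(all(q2$report$status == "pass"))
})

test_that("imputation leaves observed data intact and respects dependence", {
  set.seed(3)
  n <- 300
  a <- rbinom(n, 2, 0.4)
  # no missing cells: all completed tables equal the input
  G0 <- data.frame(subject_id = as.character(1:n), a = a, b = rbinom(n, 2, 0.3))
  i0 <- impute_genotypes(G0, NULL, m = 3, seed = 1)
  for (tab in i0$completed) expect_equal(tab$a, a, ignore_attr = TRUE)

  # a missing cell at a locus perfectly correlated with another locus
  b <- a; b[1] <- NA
  G1 <- data.frame(subject_id = as.character(1:n), a = a, b = b)
  i1 <- impute_genotypes(G1, NULL, m = 50, cycles = 3, seed = 9)
  draws <- vapply(i1$completed, function(t) t$b[1], numeric(1))
  expect_gte(sum(draws == a[1]), 45)

  # independent locus at maf 0.5: draws follow the HWE marginal (1/4,1/2,1/4)
  x <- rbinom(n, 2, 0.5); x[5] <- NA
  G2 <- data.frame(subject_id = as.character(1:n), x = x, y = rbinom(n, 2, 0.3))
  i2 <- impute_genotypes(G2, NULL, m = 60, cycles = 3, seed = 4)
  d2 <- vapply(i2$completed, function(t) t$x[5], numeric(1))
  counts <- tabulate(d2 + 1, nbins = 3)
  expect_gt(stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.001)

  # near-total missingness still runs
  z <- rbinom(20, 2, 0.4); z[1:19] <- NA
  G3 <- data.frame(subject_id = as.character(1:20), z = z, w = rbinom(20, 2, 0.3))
  expect_silent(impute_genotypes(G3, NULL, m = 2, cycles = 1, seed = 5))
})

test_that("aggregation takes per-cell modes with ties toward fewer minor alleles", {
  G <- data.frame(subject_id = c("s1", "s2"), a = c(NA, 1L))
  fake <- list(
    completed = c(replicate(10, data.frame(subject_id = c("s1", "s2"),
                                           a = c(0L, 1L)),
                            simplify = FALSE),
                  replicate(35, data.frame(subject_id = c("s1", "s2"),
                                           a = c(1L, 1L)),
                            simplify = FALSE),
                  replicate(5, data.frame(subject_id = c("s1", "s2"),
                                          a = c(2L, 1L)),
                            simplify = FALSE)),
    missing_mask = matrix(c(TRUE, FALSE), 2, 1,
                          dimnames = list(NULL, "a")),
    genotypes = G, m = 50)
  class(fake) <- "imputation_set"
  agg <- aggregate_imputations(fake)
  expect_equal(agg$genotypes$a, c(1L, 1L))
  # 25/25 tie: broken toward the smaller genotype, flagged
  fake2 <- fake
  fake2$completed <- c(replicate(25, data.frame(subject_id = c("s1", "s2"),
                                                a = c(0L, 1L)),
                                 simplify = FALSE),
                       replicate(25, data.frame(subject_id = c("s1", "s2"),
                                                a = c(1L, 1L)),
                                 simplify = FALSE))
  agg2 <- aggregate_imputations(fake2)
  expect_equal(agg2$genotypes$a[1], 0L)
  expect_equal(agg2$n_ties, 1L)
  # m = 1: aggregated equals the single completed table
  fake3 <- fake; fake3$completed <- fake$completed[1]; fake3$m <- 1
  expect_equal(aggregate_imputations(fake3)$genotypes$a, c(0L, 1L))
})

test_that("imputation preserves marginal allele frequencies under MCAR", {
  cc <- cohort_config(n_subjects = 600, seed = 5, missing_rate = 0,
                      effect_tree = NULL,
                      maf = c(v1 = 0.3, v2 = 0.2, v3 = 0.45,
                              v4 = 0.1, v5 = 0.35, v6 = 0.25))
  gt <- simulate_genotypes(cc)
  gm <- inject_missingness(gt, 0.1, seed = 2)
  cv <- simulate_covariates(cc)
  agg <- aggregate_imputations(
    impute_genotypes(gm, cv, m = 10, cycles = 3, seed = 3))$genotypes
  for (v in paste0("v", 1:6)) {
    expect_lt(abs(compute_maf(agg[[v]])$maf - compute_maf(gt[[v]])$maf), 0.02)
  }
})
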