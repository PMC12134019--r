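#' Minor allele frequency of a genotype column
#'
#' Genotypes are minor-allele dosages in {0, 1, 2} (NA = missing). If the
#' computed frequency exceeds 0.5 the orientation is flipped (frequency
#' reported as `1 - raw`) and flagged.
#'
#' @param g Integer vector of genotypes.
#' @return List: `maf`, `flipped`, `n_missing`, `raw`.
#' @export
compute_maf <- function(g) {
  obs <- g[!is.na(g)]
  if (length(obs) == 0L) stop("all-missing genotype column")
  stopifnot(all(obs %in% 0:2))
  raw <- sum(obs) / (2 * length(obs))
  flipped <- raw > 0.5
  list(maf = if (flipped) 1 - raw else raw, flipped = flipped,
       n_missing = sum(is.na(g)), raw = raw)
}

#' One-degree-of-freedom Hardy-Weinberg chi-square test
#'
#' Compares observed genotype counts (AA, Aa, aa) with expectations
#' (p^2, 2pq, q^2) * n at the observed allele frequency.
#'
#' @param g Integer vector of genotypes ({0,1,2}, NA allowed).
#' @return List: `chi2`, `p`, `counts` (observed), `expected`.
#' @export
hwe_test <- function(g) {
  obs <- g[!is.na(g)]
  if (length(obs) == 0L) stop("all-missing genotype column")
  n <- length(obs)
  counts <- c(sum(obs == 0L), sum(obs == 1L), sum(obs == 2L))
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (q == 0 || q == 1) {
    warning("monomorphic column: HWE test degenerate")
    return(list(chi2 = 0, p = 1, counts = counts, expected = counts))
  }
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       counts = counts, expected = expected)
}

#' Filter variants on MAF, Hardy-Weinberg equilibrium and an exclusion list
#'
#' Produces a QC report row for every input variant and drops those failing
#' the MAF threshold, the HWE threshold, or named on the a-priori exclusion
#' list (loci dropped for HWE departure or poor minor-allele amplification).
#'
#' @param genotypes Genotype table (`subject_id` + rsid columns).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p_min Minimum HWE p-value (default 1e-3).
#' @param excluded_rsids Character vector of a-priori exclusions.
#' @return List: `genotypes` (passing columns only), `report` (data.frame:
#'   rsid, maf, flipped, hwe_chi2, hwe_p, n_missing, status).
#' @export
qc_filter <- function(genotypes, maf_min = 0.05, hwe_p_min = 1e-3,
                      excluded_rsids = character()) {
  rsids <- setdiff(names(genotypes), "subject_id")
  rows <- lapply(rsids, function(rs) {
    g <- genotypes[[rs]]
    mf <- compute_maf(g)
    hw <- suppressWarnings(hwe_test(g))
    status <- if (rs %in% excluded_rsids) {
      if (hw$p < hwe_p_min) "fail_hwe" else "fail_amplification"
    } else if (mf$maf < maf_min) "fail_maf"
    else if (hw$p < hwe_p_min) "fail_hwe"
    else "pass"
    data.frame(rsid = rs, maf = mf$maf, flipped = mf$flipped,
               hwe_chi2 = hw$chi2, hwe_p = hw$p, n_missing = mf$n_missing,
               status = status, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  keep <- report$rsid[report$status == "pass"]
  list(genotypes = genotypes[, c("subject_id", keep), drop = FALSE],
       report = report)
}
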