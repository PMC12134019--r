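#' Fit a Cox proportional-hazards model for one exposure
#'
#' Thin wrapper around [survival::coxph()] with the conventions used
#' throughout the pipeline: time in days since tamoxifen initiation, the
#' exposure entered as a single numeric term (minor-allele dosage), optional
#' adjustment covariates, and Efron's tie correction by default.
#'
#' @param time Numeric vector of follow-up times.
#' @param event 0/1 event indicators.
#' @param exposure Numeric exposure per subject.
#' @param covariates Optional data.frame of adjustment columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`: data.frame `terms` (term, coef, se,
#'   hr, ci_lo, ci_hi, z), `loglik` (at optimum), `ties`, `n`, `n_event`.
#' @export
fit_cox <- function(time, event, exposure, covariates = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(event) < 1) stop("no events")
  if (length(unique(exposure)) < 2L) stop("constant exposure")
  dat <- data.frame(.time = time, .event = event, exposure = exposure)
  form <- .time_formula("exposure")
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    dat <- cbind(dat, covariates)
    form <- .time_formula(c("exposure", names(covariates)))
  }
  fit <- survival::coxph(form, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-10, iter.max = 50))
  if (any(is.na(stats::coef(fit)))) {
    stop("non-convergence or aliased terms in Cox fit")
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(
    terms = data.frame(term = names(cf), coef = unname(cf), se = unname(se),
                       hr = exp(unname(cf)),
                       ci_lo = exp(unname(cf) - 1.96 * unname(se)),
                       ci_hi = exp(unname(cf) + 1.96 * unname(se)),
                       z = unname(cf) / unname(se), stringsAsFactors = FALSE),
    loglik = fit$loglik[length(fit$loglik)], ties = ties,
    n = length(time), n_event = sum(event)), class = "cox_fit")
}

.time_formula <- function(rhs) {
  stats::as.formula(paste("survival::Surv(.time, .event) ~",
                          paste(rhs, collapse = " + ")))
}

# adjustment design with the pipeline's reference categories
# (stage I, grade I, HER2 negative, mastectomy, cohabiting, employed)
screen_covariate_design <- function(covariates) {
  data.frame(
    age = as.numeric(covariates$age_years),
    stage = factor(covariates$stage, levels = c("I", "II", "III")),
    surgery = factor(covariates$surgery, levels = c("mastectomy", "lumpectomy")),
    radiotherapy = as.numeric(covariates$radiotherapy),
    chemotherapy = as.numeric(covariates$chemotherapy),
    grade = factor(covariates$grade, levels = c("I", "II", "III", "not graded")),
    her2 = factor(covariates$her2, levels = c("negative", "positive", "unknown")),
    cohabiting = as.numeric(covariates$cohabiting),
    employed = as.numeric(covariates$employed))
}

#' Per-variant adjusted Cox screen
#'
#' Fits one covariate-adjusted Cox model per variant, with the genotype as a
#' single numeric term (hazard ratio per additional minor allele), and
#' applies empirical-Bayes shrinkage across the screened log hazard ratios.
#'
#' @param genotypes Fully-imputed, QC-passed genotype table.
#' @param outcomes Outcome table from [derive_cohort_outcomes()].
#' @param covariates Covariate table; `NULL` for unadjusted models.
#' @param ties Tie handling for the Cox fits.
#' @param shrink Apply [eb_shrink()] across variants (default TRUE).
#' @return Data frame, one row per variant: rsid, n, events, coef, se, z,
#'   hr, ci_lo, ci_hi, shrunken coef/HR (if `shrink`), flag (empty or the
#'   fit error message).
#' @export
per_variant_screen <- function(genotypes, outcomes, covariates = NULL,
                               ties = "efron", shrink = TRUE) {
  rsids <- setdiff(names(genotypes), "subject_id")
  if (length(rsids) == 0L) {
    return(data.frame(rsid = character(), n = integer(), events = integer(),
                      coef = numeric(), se = numeric(), z = numeric(),
                      hr = numeric(), ci_lo = numeric(), ci_hi = numeric(),
                      flag = character(), stringsAsFactors = FALSE))
  }
  idx <- match(genotypes$subject_id, outcomes$subject_id)
  if (anyNA(idx)) stop("outcomes missing for some genotyped subjects")
  time <- outcomes$time_days[idx]
  event <- outcomes$event[idx]
  X <- if (is.null(covariates)) NULL else {
    cidx <- match(genotypes$subject_id, covariates$subject_id)
    screen_covariate_design(covariates[cidx, , drop = FALSE])
  }
  rows <- lapply(rsids, function(rs) {
    res <- tryCatch(fit_cox(time, event, genotypes[[rs]], X, ties = ties),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(rsid = rs, n = length(time), events = sum(event),
                 coef = NA_real_, se = NA_real_, z = NA_real_, hr = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, flag = res,
                 stringsAsFactors = FALSE)
    } else {
      tr <- res$terms[res$terms$term == "exposure", ]
      data.frame(rsid = rs, n = res$n, events = res$n_event, coef = tr$coef,
                 se = tr$se, z = tr$z, hr = tr$hr, ci_lo = tr$ci_lo,
                 ci_hi = tr$ci_hi, flag = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (shrink && sum(!is.na(out$coef)) >= 2L) {
    ok <- !is.na(out$coef)
    sh <- eb_shrink(out$coef[ok], out$se[ok])
    out$coef_shrunk <- NA_real_
    out$hr_shrunk <- NA_real_
    out$coef_shrunk[ok] <- sh$shrunken
    out$hr_shrunk[ok] <- exp(sh$shrunken)
    attr(out, "eb_mu") <- sh$mu
    attr(out, "eb_tau2") <- sh$tau2
  }
  out
}

#' Empirical-Bayes shrinkage of a set of log hazard ratios
#'
#' Semi-Bayes tempering of multiple comparisons without an externally set
#' prior: the grand mean is the precision-weighted mean of the coefficients,
#' the between-variant variance is the method-of-moments estimate
#' `max(0, var(coef) - mean(se^2))`, and each coefficient is pulled toward
#' the grand mean by the factor `tau2 / (tau2 + se^2)`.
#'
#' @param coef Numeric vector of per-variant log hazard ratios.
#' @param se Their standard errors.
#' @return List: `mu`, `tau2`, `shrunken` (same length as `coef`),
#'   `raw` (= `coef`), `se`.
#' @export
eb_shrink <- function(coef, se) {
  if (length(coef) < 2L) stop("need at least 2 variants to shrink")
  stopifnot(length(coef) == length(se), all(se > 0))
  w <- 1 / se^2
  mu <- if (all(!is.finite(w))) mean(coef) else
    sum(coef[is.finite(w)] * w[is.finite(w)]) / sum(w[is.finite(w)])
  tau2 <- max(0, stats::var(coef) - mean(se[is.finite(se)]^2))
  lambda <- ifelse(is.finite(se), tau2 / (tau2 + se^2), 0)
  list(mu = mu, tau2 = tau2, shrunken = mu + lambda * (coef - mu),
       raw = coef, se = se)
}
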