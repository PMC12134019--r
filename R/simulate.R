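#' Configuration for the synthetic pharmacogenetic cohort generator
#'
#' The defaults emulate the cohort the analysis is designed for: premenopausal
#' ER-positive breast cancer patients initiating adjuvant tamoxifen, followed
#' for 5 years from diagnosis with 6-monthly resupply, competing censoring by
#' aromatase-inhibitor switch (~47% of the cohort within 5 years), recurrence,
#' death and emigration, and an early-discontinuation burden of ~14%. The
#' default genotype effect is a two-locus multiplicative interaction tree on
#' rs16947 (CYP2D6) and rs3740065 (ABCC2) with parameters recovered from the
#' published genotype-combination hazard-ratio grid.
#'
#' @param n_subjects Cohort size (default 3729).
#' @param pathway A `pathway_graph`; MAFs default to its `expected_maf`.
#' @param maf Named vector of minor allele frequencies per rsid.
#' @param effect_tree `NULL` for no genetic effect, or a list with `leaves`
#'   (rsids), `theta` (one per leaf, each > -1/2) and `beta` (log-hazard
#'   scale pathway effect).
#' @param baseline_hazard Per-day rate of the latent decision to stop
#'   refilling tamoxifen, for a genotype at the reference level.
#' @param ai_switch_rate Per-day rate of switching to an aromatase inhibitor.
#' @param censor_rates Named per-day rates for `recurrence`, `death`,
#'   `emigration`.
#' @param followup_days Administrative window from diagnosis (default 1825).
#' @param supply_days Days supplied per dispensing (default 182).
#' @param initiation_delay Integer range (min, max) of days from diagnosis to
#'   tamoxifen initiation.
#' @param missing_rate Fraction of genotype entries set missing at random.
#' @param covariate_margins Named list of category probabilities for the
#'   clinical covariates (defaults reproduce the cohort's published margins).
#' @param seed Integer seed; per-stage substreams are derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 3729,
                          pathway = default_pathway(),
                          maf = NULL,
                          effect_tree = list(
                            leaves = c("rs16947", "rs3740065"),
                            theta = c(4.82, 3.17),
                            beta = 0.0180),
                          baseline_hazard = 1.50e-4,
                          ai_switch_rate = 4.45e-4,
                          censor_rates = c(recurrence = 4.0e-5,
                                           death = 3.5e-5,
                                           emigration = 2.0e-6),
                          followup_days = 1825,
                          supply_days = 182,
                          initiation_delay = c(14, 90),
                          missing_rate = 0.05,
                          covariate_margins = default_covariate_margins(),
                          seed = 1) {
  if (is.null(maf)) {
    maf <- stats::setNames(pathway$variants$expected_maf, pathway$variants$rsid)
  }
  stopifnot(n_subjects >= 1, all(maf >= 0 & maf <= 0.5),
            baseline_hazard >= 0, ai_switch_rate >= 0, all(censor_rates >= 0),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(effect_tree)) {
    stopifnot(length(effect_tree$theta) == length(effect_tree$leaves),
              all(effect_tree$theta > -0.5))
    miss <- setdiff(effect_tree$leaves, names(maf))
    if (length(miss)) {
      stop("effect tree leaves absent from the MAF map: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), pathway = pathway,
                 maf = maf, effect_tree = effect_tree,
                 baseline_hazard = baseline_hazard,
                 ai_switch_rate = ai_switch_rate, censor_rates = censor_rates,
                 followup_days = as.integer(followup_days),
                 supply_days = as.integer(supply_days),
                 initiation_delay = as.integer(initiation_delay),
                 missing_rate = missing_rate,
                 covariate_margins = covariate_margins,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default clinical covariate margins
#'
#' Category proportions for stage, grade, HER2, surgery, chemo-/radiotherapy
#' and age bands matching the source cohort's descriptive table; cohabitation
#' and employment, which that table does not report, default to plausible
#' Danish population values.
#'
#' @return Named list of probability vectors.
#' @export
default_covariate_margins <- function() {
  list(
    age_band = c("<40" = 0.153, "40-49" = 0.628, "50-55" = 0.219),
    stage = c(I = 0.2574, II = 0.5446, III = 0.1980),
    surgery = c(mastectomy = 0.4457, lumpectomy = 0.5543),
    radiotherapy = 0.5425,
    chemotherapy = 0.9070,
    grade = c(I = 0.2132, II = 0.5160, III = 0.2033, "not graded" = 0.0676),
    her2 = c(negative = 0.6305, positive = 0.1322, unknown = 0.2373),
    cohabiting = 0.75,
    employed = 0.70
  )
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Independent biallelic loci; minor-allele dosage is Binomial(2, maf).
#'
#' @param config A `cohort_config`.
#' @param seed Seed for this stage (defaults to a substream of `config$seed`).
#' @return Genotype table: `subject_id` plus one 0/1/2 column per rsid.
#' @export
simulate_genotypes <- function(config, seed = substream_seed(config$seed, "genotypes")) {
  maf <- config$maf
  if (any(maf < 0 | maf > 0.5)) stop("maf outside [0, 0.5]")
  n <- config$n_subjects
  m <- with_seed(seed, {
    vapply(maf, function(q) stats::rbinom(n, 2L, q), integer(n))
  })
  if (n == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(maf)))
  geno_table(m, subject_id = sprintf("S%05d", seq_len(n)))
}

#' Simulate clinical covariates
#'
#' Categorical covariates are drawn independently from the configured margins;
#' age is drawn uniformly within the sampled band. Day 0 is diagnosis;
#' tamoxifen initiation follows after a uniform delay.
#'
#' @inheritParams simulate_genotypes
#' @return Data frame of per-subject records.
#' @export
simulate_covariates <- function(config, seed = substream_seed(config$seed, "covariates")) {
  n <- config$n_subjects
  mg <- config$covariate_margins
  with_seed(seed, {
    band <- sample(names(mg$age_band), n, TRUE, mg$age_band)
    age <- ifelse(band == "<40", sample(30:39, n, TRUE),
           ifelse(band == "40-49", sample(40:49, n, TRUE),
                  sample(50:55, n, TRUE)))
    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      age_years = as.integer(age),
      stage = sample(names(mg$stage), n, TRUE, mg$stage),
      surgery = sample(names(mg$surgery), n, TRUE, mg$surgery),
      radiotherapy = stats::runif(n) < mg$radiotherapy,
      chemotherapy = stats::runif(n) < mg$chemotherapy,
      grade = sample(names(mg$grade), n, TRUE, mg$grade),
      her2 = sample(names(mg$her2), n, TRUE, mg$her2),
      cohabiting = stats::runif(n) < mg$cohabiting,
      employed = stats::runif(n) < mg$employed,
      diagnosis_day = 0L,
      initiation_day = as.integer(sample(config$initiation_delay[1]:config$initiation_delay[2],
                                         n, TRUE)),
      stringsAsFactors = FALSE)
  })
}

# per-subject log-hazard contribution of the configured effect tree
config_tree_scores <- function(config, genotypes) {
  et <- config$effect_tree
  if (is.null(et)) return(rep(0, nrow(genotypes)))
  miss <- setdiff(et$leaves, names(genotypes))
  if (length(miss)) stop("effect tree leaf missing from genotypes: ",
                         paste(miss, collapse = ", "))
  g <- as.matrix(genotypes[, et$leaves, drop = FALSE])
  tree_loghazard(list(leaves = et$leaves),
                 list(beta = et$beta, theta = et$theta), g)
}

#' Simulate latent discontinuation and censoring events
#'
#' The latent stop time (the day a subject ceases to refill tamoxifen) is
#' exponential with rate `baseline_hazard * exp(tree log-hazard)`; each
#' censoring cause is an independent exponential clock. All clocks start at
#' tamoxifen initiation; reported days are absolute (day 0 = diagnosis).
#'
#' @param config A `cohort_config`.
#' @param genotypes Genotype table from [simulate_genotypes()].
#' @param covariates Covariate table from [simulate_covariates()].
#' @inheritParams simulate_genotypes
#' @return Data frame with `latent_discontinuation_day` and the censoring-event
#'   columns (`ai_switch_day`, `recurrence_day`, `death_day`,
#'   `emigration_day`, `admin_censor_day`; NA where the cause never fires
#'   within 100 years).
#' @export
simulate_events <- function(config, genotypes, covariates,
                            seed = substream_seed(config$seed, "events")) {
  n <- config$n_subjects
  scores <- config_tree_scores(config, genotypes)
  init <- covariates$initiation_day
  horizon <- 36500  # cap clock draws far beyond follow-up
  draw <- function(rate) {
    if (rate <= 0) rep(NA_integer_, n)
    else {
      t <- ceiling(stats::rexp(n, rate))
      as.integer(ifelse(t > horizon, NA, t))
    }
  }
  with_seed(seed, {
    lat <- ceiling(stats::rexp(n, 1) / (config$baseline_hazard * exp(scores)))
    lat <- as.integer(pmin(lat, horizon))
    ai <- draw(config$ai_switch_rate)
    rec <- draw(config$censor_rates[["recurrence"]])
    dth <- draw(config$censor_rates[["death"]])
    emi <- draw(config$censor_rates[["emigration"]])
    data.frame(
      subject_id = covariates$subject_id,
      latent_discontinuation_day = init + lat,
      ai_switch_day = init + ai,
      recurrence_day = init + rec,
      death_day = init + dth,
      emigration_day = init + emi,
      admin_censor_day = covariates$diagnosis_day + config$followup_days,
      stringsAsFactors = FALSE)
  })
}

# earliest censoring day per subject (NA-safe)
earliest_censor_day <- function(events) {
  pmin(events$ai_switch_day, events$recurrence_day, events$death_day,
       events$emigration_day, events$admin_censor_day, na.rm = TRUE)
}

#' Simulate 6-monthly dispensing records
#'
#' Each subject is dispensed `supply_days` of tamoxifen at initiation and at
#' every `supply_days` interval thereafter, until the earlier of the latent
#' stop day and the earliest censoring event; a subject who stops simply
#' receives no further records.
#'
#' @param config A `cohort_config`.
#' @param events Event table from [simulate_events()].
#' @param covariates Covariate table (for initiation days).
#' @return Data frame of `subject_id`, `dispense_day`, `days_supplied`.
#' @export
simulate_supplies <- function(config, events, covariates) {
  stopifnot(identical(events$subject_id, covariates$subject_id))
  init <- covariates$initiation_day
  s <- config$supply_days
  stop_day <- pmin(events$latent_discontinuation_day, earliest_censor_day(events))
  # dispensings at init + k*s for k = 0, 1, ... while strictly before the
  # stop day; the initiation dispensing always occurs
  cnt <- ifelse(stop_day > init, floor((stop_day - init - 1) / s) + 1, 1)
  cnt <- pmax(as.integer(cnt), 1L)
  data.frame(subject_id = rep(events$subject_id, cnt),
             dispense_day = as.integer(rep(init, cnt) + (sequence(cnt) - 1L) * s),
             days_supplied = s, stringsAsFactors = FALSE)
}

#' Set genotype entries missing completely at random
#'
#' @param genotypes Genotype table.
#' @param missing_rate Fraction in [0, 1).
#' @param seed Integer seed.
#' @return A copy of `genotypes` with entries set to `NA`.
#' @export
inject_missingness <- function(genotypes, missing_rate, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0) return(genotypes)
  m <- geno_matrix(genotypes)
  with_seed(seed, {
    hit <- stats::runif(length(m)) < missing_rate
    m[hit] <- NA_integer_
  })
  geno_table(m, subject_id = genotypes$subject_id)
}

#' Generate a complete synthetic cohort
#'
#' Runs genotype, covariate, event and supply generation under named seed
#' substreams of `config$seed`, and applies genotype missingness.
#'
#' @param config A `cohort_config`.
#' @return List with `genotypes` (with missingness), `genotypes_true`
#'   (pre-missingness), `covariates`, `events`, `supplies`, and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  geno <- simulate_genotypes(config)
  cov <- simulate_covariates(config)
  ev <- simulate_events(config, geno, cov)
  sup <- simulate_supplies(config, ev, cov)
  geno_miss <- inject_missingness(geno, config$missing_rate,
                                  seed = substream_seed(config$seed, "missingness"))
  list(genotypes = geno_miss, genotypes_true = geno, covariates = cov,
       events = ev, supplies = sup, config = config)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             genotypes_true = file.path(dir, "genotypes_true.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             events = file.path(dir, "events.tsv"),
             supplies = file.path(dir, "supplies.tsv"))
  write_tsv_table(cohort$genotypes, paths["genotypes"])
  write_tsv_table(cohort$genotypes_true, paths["genotypes_true"])
  write_tsv_table(cohort$covariates, paths["covariates"])
  write_tsv_table(cohort$events, paths["events"])
  write_tsv_table(cohort$supplies, paths["supplies"])
  invisible(paths)
}
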