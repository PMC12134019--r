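#' End-to-end pipeline: simulate -> diary -> qc -> impute -> screen -> alps
#'
#' Runs the stages in dependency order under named substreams of a single
#' global seed, writing each stage's tables to `out_dir` and returning a
#' manifest with per-stage status, output paths and md5 checksums. Identical
#' config and seed yield identical files.
#'
#' @param config List of pipeline settings; see Details. Missing entries take
#'   the defaults.
#' @param out_dir Output directory.
#' @param seed Global seed (overrides `config$seed` if given).
#'
#' @details Recognized config entries: `cohort` (arguments to
#'   [cohort_config()]), `gap_days`, `carryover_cap_days`, `maf_min`,
#'   `hwe_p_min`, `m_imputations`, `impute_cycles`, `ties`, `kappa`,
#'   `omega`, `prior_iterations`, `posterior_iterations`, `max_leaves`,
#'   `stages` (character subset of simulate, diary, qc, impute, screen,
#'   alps, report).
#' @return Manifest list: `stages` (status per stage), `paths`, `checksums`,
#'   `seed`, `summary`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  defaults <- list(gap_days = 182L, carryover_cap_days = 182L,
                   maf_min = 0.05, hwe_p_min = 1e-3,
                   m_imputations = 50L, impute_cycles = 5L, ties = "efron",
                   kappa = 0.5, omega = 2.0,
                   prior_iterations = 300000L, posterior_iterations = 100000L,
                   max_leaves = 4L,
                   stages = c("simulate", "diary", "qc", "impute", "screen",
                              "alps", "report"))
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(stages = list(), paths = character(), seed = cfg$seed,
                   summary = list())
  add_path <- function(name, path) {
    manifest$paths[name] <<- path
    path
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- paste("error:", conditionMessage(res))
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[name]] <<- "ok"
    res
  }
  ccfg_args <- cfg$cohort %||% list()
  ccfg_args$seed <- substream_seed(cfg$seed, "cohort")
  ccfg <- do.call(cohort_config, ccfg_args)
  pathway <- ccfg$pathway

  cohort <- NULL
  if ("simulate" %in% cfg$stages) {
    cohort <- run_stage("simulate", function() {
      ch <- simulate_cohort(ccfg)
      paths <- write_cohort(ch, out_dir)
      for (nm in names(paths)) add_path(nm, paths[[nm]])
      ch
    })
  }
  outcomes <- NULL
  if ("diary" %in% cfg$stages) {
    outcomes <- run_stage("diary", function() {
      oc <- derive_cohort_outcomes(cohort$supplies, cohort$events,
                                   cohort$covariates, gap_days = cfg$gap_days,
                                   carryover_cap_days = cfg$carryover_cap_days)
      write_tsv_table(oc, add_path("outcomes", file.path(out_dir, "outcomes.tsv")))
      manifest$summary$n_events <<- sum(oc$event)
      manifest$summary$event_proportion <<- mean(oc$event)
      oc
    })
  }
  qc <- NULL
  if ("qc" %in% cfg$stages) {
    qc <- run_stage("qc", function() {
      excl <- pathway$variants$rsid[pathway$variants$excluded]
      q <- qc_filter(cohort$genotypes, maf_min = cfg$maf_min,
                     hwe_p_min = cfg$hwe_p_min, excluded_rsids = excl)
      write_tsv_table(q$report, add_path("variant_qc", file.path(out_dir, "variant_qc.tsv")))
      manifest$summary$n_variants_pass <<- sum(q$report$status == "pass")
      q
    })
  }
  geno_complete <- NULL
  if ("impute" %in% cfg$stages) {
    geno_complete <- run_stage("impute", function() {
      iset <- impute_genotypes(qc$genotypes, cohort$covariates,
                               m = cfg$m_imputations, cycles = cfg$impute_cycles,
                               seed = substream_seed(cfg$seed, "impute"))
      agg <- aggregate_imputations(iset)
      write_tsv_table(agg$genotypes,
                      add_path("genotypes_complete",
                               file.path(out_dir, "genotypes_complete.tsv")))
      manifest$summary$imputation_ties <<- agg$n_ties
      agg$genotypes
    })
  }
  screen <- NULL
  if ("screen" %in% cfg$stages) {
    screen <- run_stage("screen", function() {
      sc <- per_variant_screen(geno_complete, outcomes, cohort$covariates,
                               ties = cfg$ties)
      write_tsv_table(sc, add_path("screen", file.path(out_dir, "screen.tsv")))
      sc
    })
  }
  alps <- NULL
  if ("alps" %in% cfg$stages) {
    alps <- run_stage("alps", function() {
      prior_run <- run_chain(pathway, data = NULL,
                             iterations = cfg$prior_iterations,
                             seed = substream_seed(cfg$seed, "prior_chain"),
                             max_leaves = cfg$max_leaves, kappa = cfg$kappa,
                             omega = cfg$omega,
                             variants = setdiff(names(geno_complete),
                                                "subject_id"))
      post_run <- run_chain(pathway,
                            data = list(genotypes = geno_complete,
                                        outcomes = outcomes),
                            iterations = cfg$posterior_iterations,
                            seed = substream_seed(cfg$seed, "posterior_chain"),
                            max_leaves = cfg$max_leaves, kappa = cfg$kappa,
                            omega = cfg$omega, ties = cfg$ties)
      bf <- summarize_features(prior_run, post_run, pathway)
      write_tsv_table(bf$variants, add_path("bf_variants", file.path(out_dir, "bf_variants.tsv")))
      write_tsv_table(bf$concepts, add_path("bf_concepts", file.path(out_dir, "bf_concepts.tsv")))
      write_tsv_table(bf$trees, add_path("bf_trees", file.path(out_dir, "bf_trees.tsv")))
      tt <- top_trees(bf$trees)
      write_tsv_table(tt, add_path("top_trees", file.path(out_dir, "top_trees.tsv")))
      grids <- alps_hr_grids(tt, geno_complete, outcomes, ties = cfg$ties)
      jsonlite::write_json(grids, add_path("hr_grids", file.path(out_dir, "hr_grids.json")),
                           auto_unbox = TRUE, digits = NA)
      meta <- list(seed = cfg$seed, prior_iterations = cfg$prior_iterations,
                   posterior_iterations = cfg$posterior_iterations,
                   kappa = cfg$kappa, omega = cfg$omega,
                   max_leaves = cfg$max_leaves,
                   smoothing = "jeffreys (+1/2)/(n+1)",
                   prior_acceptance = prior_run$acceptance_rate,
                   posterior_acceptance = post_run$acceptance_rate)
      jsonlite::write_json(meta, add_path("alps_meta", file.path(out_dir, "alps_meta.json")),
                           auto_unbox = TRUE, digits = NA)
      list(prior = prior_run, posterior = post_run, bf = bf, top = tt,
           grids = grids)
    })
  }
  manifest$checksums <- tools::md5sum(manifest$paths[file.exists(manifest$paths)])
  if ("report" %in% cfg$stages) {
    run_stage("report", function() {
      rep <- report_run(out_dir)
      add_path("report_json", file.path(out_dir, "report.json"))
      add_path("report_txt", file.path(out_dir, "report.txt"))
      rep
    })
    manifest$checksums <- tools::md5sum(manifest$paths[file.exists(manifest$paths)])
  }
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# MAP-fitted 3x3 hazard-ratio grids for each two-leaf top tree
alps_hr_grids <- function(tt, genotypes, outcomes, ties = "efron") {
  two <- tt[tt$n_leaves == 2L, , drop = FALSE]
  grids <- list()
  for (id in two$feature) {
    leaves <- strsplit(id, "+", fixed = TRUE)[[1L]]
    fit <- tryCatch(fit_tree_params(list(leaves = leaves), genotypes, outcomes,
                                    ties = ties), error = function(e) NULL)
    if (is.null(fit)) next
    grids[[id]] <- list(leaves = leaves, beta = fit$params$beta,
                        theta = fit$params$theta,
                        grid = hr_grid(list(leaves = leaves), fit$params))
  }
  grids
}

#' Combined human- and machine-readable run report
#'
#' Reads the tables a completed pipeline run wrote into `dir` and emits a
#' per-variant summary (MAF, HWE p, screened raw and shrunken HR with CI,
#' Bayes Factor), the ten-concept Bayes Factor table, and the top-trees
#' table with their genotype hazard-ratio grids, as `report.json` and
#' `report.txt`.
#'
#' @param dir Directory of a completed [run_pipeline()] run.
#' @return The report list, invisibly.
#' @export
report_run <- function(dir) {
  need <- c("variant_qc.tsv", "screen.tsv", "bf_variants.tsv",
            "bf_concepts.tsv", "top_trees.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) stop("missing upstream output: ", f)
  }
  qc <- read_tsv_table(file.path(dir, "variant_qc.tsv"))
  sc <- read_tsv_table(file.path(dir, "screen.tsv"))
  bfv <- read_tsv_table(file.path(dir, "bf_variants.tsv"))
  bfc <- read_tsv_table(file.path(dir, "bf_concepts.tsv"))
  tt <- read_tsv_table(file.path(dir, "top_trees.tsv"))
  grids <- if (file.exists(file.path(dir, "hr_grids.json"))) {
    jsonlite::fromJSON(file.path(dir, "hr_grids.json"), simplifyVector = FALSE)
  } else list()

  variants <- merge(merge(qc[qc$status == "pass",
                             c("rsid", "maf", "hwe_p")],
                          sc[, intersect(c("rsid", "hr", "ci_lo", "ci_hi",
                                           "hr_shrunk"), names(sc))],
                          by = "rsid", all.x = TRUE),
                    stats::setNames(bfv[, c("feature", "bf")], c("rsid", "bf")),
                    by = "rsid", all.x = TRUE)
  report <- list(variants = variants,
                 concepts = bfc[, c("feature", "bf")],
                 top_trees = tt, hr_grids = grids)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- c("Pathway analysis run report", "===========================", "",
           sprintf("Variants passing QC: %d", nrow(variants)), "",
           "Per-variant summary (MAF, HWE p, screened HR, BF):",
           utils::capture.output(print(variants, row.names = FALSE)), "",
           "Pathway concept Bayes Factors:",
           utils::capture.output(print(report$concepts, row.names = FALSE)), "")
  if (nrow(tt) == 0L) {
    txt <- c(txt, "Top trees: none met BF >= 10 and posterior probability >= 0.01")
  } else {
    txt <- c(txt, "Top trees (BF >= 10 and posterior probability >= 0.01):",
             utils::capture.output(print(tt, row.names = FALSE)))
  }
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(report)
}
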