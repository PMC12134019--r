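#' Multiple imputation of missing genotypes by chained equations
#'
#' Each locus with missing values is modelled by a proportional-odds
#' regression of its genotype (0/1/2) on clinical covariates and the current
#' completed dosages at the other loci; missing cells are drawn from the
#' fitted multinomial. Each of the `m` completed datasets is produced by an
#' independent chain: fresh marginal initialisation followed by `cycles`
#' sweeps over the loci. Observed cells are never altered.
#'
#' Degenerate loci (fewer than two observed genotype levels, or a failed
#' proportional-odds fit) fall back to draws from the locus's observed
#' marginal distribution.
#'
#' @param genotypes Genotype table with missing entries (`subject_id` +
#'   rsid columns).
#' @param covariates Covariate table aligned by `subject_id`; `NULL` for
#'   genotype-only imputation.
#' @param m Number of completed datasets (default 50).
#' @param cycles Chained-equation sweeps per dataset (default 5).
#' @param seed Integer seed.
#' @return List of class `imputation_set`: `completed` (list of m genotype
#'   tables), `missing_mask`, `genotypes` (the input), `m`.
#' @export
impute_genotypes <- function(genotypes, covariates = NULL, m = 50,
                             cycles = 5, seed = 1) {
  G <- geno_matrix(genotypes)
  if (ncol(G) < 1L) stop("no variants to impute")
  mask <- is.na(G)
  if (any(rowSums(!mask) == 0L) && is.null(covariates)) {
    stop("subject with all loci missing and no covariates")
  }
  X <- if (is.null(covariates)) NULL else impute_design(covariates, genotypes$subject_id)

  marg <- apply(G, 2, function(g) {
    tab <- tabulate(g[!is.na(g)] + 1L, nbins = 3L)
    if (sum(tab) == 0L) tab <- c(1L, 1L, 1L)
    tab / sum(tab)
  })

  completed <- with_seed(seed, {
    lapply(seq_len(m), function(k) {
      Gk <- G
      # fresh marginal initialisation
      for (j in seq_len(ncol(Gk))) {
        nj <- sum(mask[, j])
        if (nj) Gk[mask[, j], j] <- sample(0:2, nj, TRUE, marg[, j])
      }
      if (any(mask)) {
        for (cyc in seq_len(cycles)) {
          for (j in seq_len(ncol(Gk))) {
            if (!any(mask[, j])) next
            Gk[mask[, j], j] <- draw_locus(Gk, X, j, mask[, j], marg[, j])
          }
        }
      }
      geno_table(Gk, subject_id = genotypes$subject_id)
    })
  })
  structure(list(completed = completed, missing_mask = mask,
                 genotypes = genotypes, m = m),
            class = "imputation_set")
}

# numeric design matrix of clinical predictors for the imputation models
impute_design <- function(covariates, subject_id) {
  idx <- match(subject_id, covariates$subject_id)
  if (anyNA(idx)) stop("covariates missing for some subjects")
  cv <- covariates[idx, , drop = FALSE]
  cols <- list()
  if ("age_years" %in% names(cv)) cols$age <- as.numeric(cv$age_years)
  if ("stage" %in% names(cv)) cols$stage <- match(cv$stage, c("I", "II", "III"))
  if ("grade" %in% names(cv)) {
    cols$grade <- match(cv$grade, c("I", "II", "III", "not graded"))
  }
  if ("chemotherapy" %in% names(cv)) cols$chemo <- as.numeric(cv$chemotherapy)
  if ("radiotherapy" %in% names(cv)) cols$radio <- as.numeric(cv$radiotherapy)
  if (length(cols) == 0L) return(NULL)
  as.matrix(as.data.frame(cols))
}

# draw missing genotypes at locus j from a proportional-odds model given the
# other loci (current completed values) and covariates
draw_locus <- function(Gk, X, j, miss_j, marginal) {
  pred <- cbind(Gk[, -j, drop = FALSE], X)
  obs <- !miss_j
  y <- droplevels(factor(Gk[obs, j], levels = 0:2))
  obs_lev <- as.integer(levels(y))
  n_miss <- sum(miss_j)
  if (nlevels(y) < 2L || ncol(pred) == 0L) {
    return(sample(0:2, n_miss, TRUE, marginal))
  }
  dat <- data.frame(pred[obs, , drop = FALSE])
  # drop constant predictors to keep polr well posed
  keep <- vapply(dat, function(v) stats::var(v) > 0, logical(1))
  if (!any(keep)) return(sample(0:2, n_miss, TRUE, marginal))
  dat <- dat[, keep, drop = FALSE]
  newdat <- data.frame(pred[miss_j, , drop = FALSE])[, keep, drop = FALSE]
  # proportional-odds first; multinomial logit as fallback (it degrades
  # gracefully under separation, e.g. a perfectly predictive co-locus)
  pr <- NULL
  fit <- tryCatch(
    suppressWarnings(MASS::polr(y ~ ., data = cbind(y = y, dat), Hess = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    pr <- tryCatch(
      suppressWarnings(stats::predict(fit, newdata = newdat, type = "probs")),
      error = function(e) NULL)
  }
  if (is.null(pr)) {
    fit <- tryCatch(
      suppressWarnings(nnet::multinom(y ~ ., data = cbind(y = y, dat),
                                      trace = FALSE, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      pr <- tryCatch(
        suppressWarnings(stats::predict(fit, newdata = newdat, type = "probs")),
        error = function(e) NULL)
    }
  }
  if (is.null(pr)) return(sample(0:2, n_miss, TRUE, marginal))
  if (is.null(dim(pr))) {
    # vector cases: one newdata row (probs across levels), or a two-level
    # response (binary predict returns P(second level))
    pr <- if (n_miss == 1L && length(pr) == length(obs_lev)) {
      matrix(pr, nrow = 1)
    } else if (length(obs_lev) == 2L) {
      cbind(1 - pr, pr)
    } else {
      return(sample(0:2, n_miss, TRUE, marginal))
    }
  }
  if (ncol(pr) != length(obs_lev)) return(sample(0:2, n_miss, TRUE, marginal))
  vapply(seq_len(n_miss), function(i) {
    p <- pmax(pr[i, ], 0)
    if (sum(p) <= 0) sample(0:2, 1L, TRUE, marginal)
    else obs_lev[sample.int(length(obs_lev), 1L, prob = p)]
  }, numeric(1))
}

#' Aggregate an imputation set into one completed dataset
#'
#' Each originally-missing cell is set to its modal genotype across the m
#' completed datasets, ties broken toward the smaller genotype (and flagged);
#' observed cells pass through unchanged.
#'
#' @param set An `imputation_set` from [impute_genotypes()].
#' @return List: `genotypes` (completed table), `n_ties` (tie-broken cells).
#' @export
aggregate_imputations <- function(set) {
  stopifnot(inherits(set, "imputation_set"), set$m >= 1)
  G <- geno_matrix(set$genotypes)
  mask <- set$missing_mask
  n_ties <- 0L
  if (any(mask)) {
    cells <- which(mask)
    draws <- vapply(set$completed, function(tab) geno_matrix(tab)[cells],
                    numeric(length(cells)))
    if (length(cells) == 1L) draws <- matrix(draws, nrow = 1)
    for (i in seq_along(cells)) {
      tab <- tabulate(draws[i, ] + 1L, nbins = 3L)
      best <- which(tab == max(tab))
      if (length(best) > 1L) n_ties <- n_ties + 1L
      G[cells[i]] <- min(best) - 1L  # ties toward smaller genotype
    }
  }
  list(genotypes = geno_table(G, subject_id = set$genotypes$subject_id),
       n_ties = n_ties)
}
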