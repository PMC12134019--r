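#' Metropolis-Hastings search over pathway-constrained interaction trees
#'
#' The chain moves over leaf sets (trees) drawn from the analyzed variants of
#' a pathway. Moves are add / drop / swap of a leaf, chosen uniformly among
#' the legal move types, with a proposal-ratio correction for reversibility.
#' Without data the chain targets the tree prior (size penalty x same-gene
#' affinity); with data, the target is prior x Laplace-approximated Cox
#' marginal likelihood of the tree. Feature probabilities (for variants,
#' pathway concepts and trees) are visit frequencies after burn-in, and
#' Bayes Factors are posterior odds over prior odds.
#'
#' @name alps_chain
NULL

#' Propose a structural move on a tree
#'
#' One of add / drop / swap, each with probability 1/3 where legal
#' (renormalized otherwise). The log proposal ratio accounts for the
#' forward and reverse move counts.
#'
#' @param leaves Character vector of current leaf rsids.
#' @param universe Character vector of all candidate variants.
#' @param max_leaves Maximum leaf count (default 4).
#' @return List: `leaves` (candidate), `log_q_ratio`, `move`.
#' @export
propose_move <- function(leaves, universe, max_leaves = 4L) {
  L <- length(leaves)
  pool <- setdiff(universe, leaves)
  legal <- c(add = L < max_leaves && length(pool) > 0L,
             drop = L > 1L,
             swap = length(pool) > 0L && L >= 1L)
  types <- names(legal)[legal]
  m <- length(types)
  if (m == 0L) return(list(leaves = leaves, log_q_ratio = 0, move = "none"))
  move <- types[sample.int(m, 1L)]
  n_legal <- function(L2, pool2) {
    sum(c(L2 < max_leaves && pool2 > 0L, L2 > 1L, pool2 > 0L && L2 >= 1L))
  }
  if (move == "add") {
    cand <- c(leaves, pool[sample.int(length(pool), 1L)])
    m2 <- n_legal(L + 1L, length(pool) - 1L)
    lqr <- (-log(m2) - log(L + 1L)) - (-log(m) - log(length(pool)))
  } else if (move == "drop") {
    cand <- leaves[-sample.int(L, 1L)]
    m2 <- n_legal(L - 1L, length(pool) + 1L)
    lqr <- (-log(m2) - log(length(pool) + 1L)) - (-log(m) - log(L))
  } else {
    out <- sample.int(L, 1L)
    inn <- pool[sample.int(length(pool), 1L)]
    cand <- c(leaves[-out], inn)
    lqr <- 0  # symmetric: same leaf count and pool size, same legal set
  }
  list(leaves = cand, log_q_ratio = lqr, move = move)
}

#' Run a prior or posterior chain over interaction trees
#'
#' Without `data`, the marginal-likelihood term is identically zero and the
#' chain samples the tree prior; with `data` (a list with `genotypes` and
#' `outcomes`), each proposed tree is scored by its Laplace-approximated log
#' marginal likelihood, memoized per canonical tree id and warm-started from
#' the current tree's MAP. The chain starts at a random single-leaf tree.
#'
#' @param pathway A `pathway_graph`.
#' @param data `NULL` (prior chain) or list(genotypes, outcomes).
#' @param iterations Total iterations.
#' @param seed Integer seed.
#' @param burn_in Iterations discarded before tallying (default 10%).
#' @param max_leaves Leaf-count cap (default 4).
#' @param kappa,omega Tree-prior parameters (see [tree_log_prior()]).
#' @param ties Tie correction for the marginal likelihoods.
#' @param thin_log Keep every `thin_log`-th chain record (default 1 = all).
#' @param variants Optional restriction of the variant universe (e.g. the
#'   QC-passed set), so a prior chain can match a posterior chain whose
#'   genotype table lost variants to QC.
#' @return List of class `alps_chain`: `tree_counts` (named visit counts
#'   post burn-in), `n_tallied`, `chain` (data.frame iteration / tree_id /
#'   accepted / log_ml), `acceptance_rate`, `ml_cache` (named log marginal
#'   likelihoods), `universe`, `settings`.
#' @export
run_chain <- function(pathway, data = NULL, iterations = 100000L, seed = 1L,
                      burn_in = floor(iterations / 10), max_leaves = 4L,
                      kappa = 0.5, omega = 2.0, ties = "efron",
                      thin_log = 1L, variants = NULL) {
  stopifnot(iterations >= 1L, burn_in >= 0L, burn_in < iterations)
  universe <- analyzed_variants(pathway)
  if (!is.null(variants)) universe <- intersect(universe, variants)
  use_data <- !is.null(data)
  if (use_data) {
    universe <- intersect(universe, setdiff(names(data$genotypes), "subject_id"))
    prep <- cox_prep(data$outcomes$time_days, data$outcomes$event)
  }
  if (length(universe) == 0L) stop("no analyzed variants available")

  # memoized marginal likelihood, warm-started from a parent tree's MAP
  ml_cache <- new.env(parent = emptyenv())
  fit_cache <- new.env(parent = emptyenv())
  get_ml <- function(leaves, warm_from = NULL) {
    id <- tree_id(leaves)
    if (!is.null(ml_cache[[id]])) return(ml_cache[[id]])
    init <- NULL
    k_new <- if (length(leaves) == 1L) 1L else 1L + length(leaves)
    if (!is.null(warm_from) && !is.null(fit_cache[[warm_from]])) {
      pf <- fit_cache[[warm_from]]
      # reuse beta; start new/kept phis at their previous values where the
      # leaf persists, 0 otherwise
      prev <- fit_cache[[warm_from]]
      init <- rep(0, k_new)
      init[1L] <- prev$x[1L]
      if (k_new > 1L && prev$k > 1L) {
        com <- intersect(leaves, prev$leaves)
        sl <- sort(leaves); sp <- sort(prev$leaves)
        for (v in com) {
          init[1L + match(v, sl)] <- prev$x[1L + match(v, sp)]
        }
      }
    }
    fit <- tryCatch(
      fit_tree_params(list(leaves = leaves), data$genotypes, data$outcomes,
                      ties = ties, init = init, prep = prep),
      error = function(e) NULL)
    if (is.null(fit)) {
      ml_cache[[id]] <- -Inf
      return(-Inf)
    }
    val <- as.numeric(log_marginal_likelihood(NULL, NULL, NULL, fit = fit))
    ml_cache[[id]] <- val
    fit_cache[[id]] <- list(x = fit$x, k = fit$k, leaves = leaves)
    val
  }

  with_seed(seed, {
    cur <- universe[sample.int(length(universe), 1L)]
    cur_id <- tree_id(cur)
    cur_lp <- tree_log_prior(list(leaves = cur), pathway, kappa, omega)
    cur_ml <- if (use_data) get_ml(cur) else 0
    ids <- character(iterations)
    acc <- logical(iterations)
    mls <- numeric(iterations)
    for (it in seq_len(iterations)) {
      prop <- propose_move(cur, universe, max_leaves)
      if (prop$move != "none") {
        lp2 <- tree_log_prior(list(leaves = prop$leaves), pathway, kappa, omega)
        ml2 <- if (use_data) get_ml(prop$leaves, warm_from = cur_id) else 0
        log_alpha <- (lp2 - cur_lp) + (ml2 - cur_ml) + prop$log_q_ratio
        if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
          cur <- prop$leaves
          cur_id <- tree_id(cur)
          cur_lp <- lp2
          cur_ml <- ml2
          acc[it] <- TRUE
        }
      }
      ids[it] <- cur_id
      mls[it] <- cur_ml
    }
    post <- ids[(burn_in + 1L):iterations]
    keep <- seq(1L, iterations, by = thin_log)
    structure(list(
      tree_counts = c(table(post)),
      n_tallied = length(post),
      chain = data.frame(iteration = keep, tree_id = ids[keep],
                         accepted = acc[keep], log_ml = mls[keep],
                         stringsAsFactors = FALSE),
      acceptance_rate = mean(acc),
      ml_cache = as.list(ml_cache),
      universe = universe,
      settings = list(iterations = iterations, burn_in = burn_in,
                      max_leaves = max_leaves, kappa = kappa, omega = omega,
                      ties = ties, seed = seed, with_data = use_data)),
      class = "alps_chain")
  })
}

#' Jeffreys-smoothed visit probability of a feature
#'
#' `(visits + 1/2) / (total + 1)` — never exactly 0 or 1, keeping odds
#' finite for never- and always-visited features.
#'
#' @param visits Visit count (scalar or vector).
#' @param total Total tallied iterations.
#' @return Probability in (0, 1).
#' @export
feature_probability <- function(visits, total) {
  stopifnot(total > 0)
  (visits + 0.5) / (total + 1)
}

#' Bayes Factor from posterior and prior feature probabilities
#'
#' The quotient of the posterior and prior odds.
#'
#' @param posterior_p,prior_p Probabilities in (0, 1).
#' @return `(posterior_p / (1 - posterior_p)) / (prior_p / (1 - prior_p))`.
#' @export
bayes_factor <- function(posterior_p, prior_p) {
  (posterior_p / (1 - posterior_p)) / (prior_p / (1 - prior_p))
}

# expand per-tree visit counts into per-variant and per-concept counts
expand_counts <- function(tree_counts, pathway) {
  ids <- names(tree_counts)
  leaf_list <- strsplit(ids, "+", fixed = TRUE)
  memb <- concept_membership(pathway)
  vars <- rownames(memb)
  v_counts <- stats::setNames(numeric(length(vars)), vars)
  c_counts <- stats::setNames(numeric(ncol(memb)), colnames(memb))
  for (i in seq_along(ids)) {
    lv <- intersect(leaf_list[[i]], vars)
    v_counts[lv] <- v_counts[lv] + tree_counts[i]
    if (length(lv)) {
      hit <- colSums(memb[lv, , drop = FALSE]) > 0
      c_counts[hit] <- c_counts[hit] + tree_counts[i]
    }
  }
  list(variants = v_counts, concepts = c_counts)
}

#' Bayes Factor summaries for variants, concepts and trees
#'
#' A variant feature is present in an iteration iff it is a leaf of the
#' current tree; a concept feature iff the tree contains at least one
#' variant mapped to that concept. Probabilities are Jeffreys-smoothed
#' visit frequencies; the tree table also carries the raw posterior
#' frequency (`pp_raw`) used for top-tree thresholding.
#'
#' @param prior_run `alps_chain` run without data.
#' @param posterior_run `alps_chain` run with data.
#' @param pathway The shared `pathway_graph`.
#' @return List of data.frames: `variants`, `concepts`, `trees`.
#' @export
summarize_features <- function(prior_run, posterior_run, pathway) {
  if (!identical(sort(prior_run$universe), sort(posterior_run$universe))) {
    stop("prior and posterior chains ran on different variant universes")
  }
  pe <- expand_counts(prior_run$tree_counts, pathway)
  qe <- expand_counts(posterior_run$tree_counts, pathway)
  np <- prior_run$n_tallied
  nq <- posterior_run$n_tallied

  mk <- function(ids, prior_counts, post_counts) {
    p0 <- feature_probability(prior_counts, np)
    p1 <- feature_probability(post_counts, nq)
    data.frame(feature = ids, prior_count = as.numeric(prior_counts),
               posterior_count = as.numeric(post_counts),
               prior_p = as.numeric(p0), posterior_p = as.numeric(p1),
               bf = as.numeric(bayes_factor(p1, p0)),
               stringsAsFactors = FALSE)
  }
  variants <- mk(names(pe$variants), pe$variants, qe$variants)
  concepts <- mk(names(pe$concepts), pe$concepts, qe$concepts)
  tree_ids <- union(names(prior_run$tree_counts), names(posterior_run$tree_counts))
  tp <- stats::setNames(numeric(length(tree_ids)), tree_ids)
  tq <- tp
  tp[names(prior_run$tree_counts)] <- prior_run$tree_counts
  tq[names(posterior_run$tree_counts)] <- posterior_run$tree_counts
  trees <- mk(tree_ids, tp, tq)
  trees$pp_raw <- trees$posterior_count / nq
  trees$n_leaves <- lengths(strsplit(trees$feature, "+", fixed = TRUE))
  list(variants = variants, concepts = concepts,
       trees = trees[order(-trees$bf), ])
}

#' Filter the tree table to the top identified trees
#'
#' Keeps trees with Bayes Factor at least `bf_min` and raw posterior
#' probability at least `pp_min`, sorted by BF descending.
#'
#' @param tree_bf Tree table from [summarize_features()].
#' @param bf_min BF threshold (default 10).
#' @param pp_min Posterior-probability threshold (default 0.01).
#' @return Filtered, sorted data.frame.
#' @export
top_trees <- function(tree_bf, bf_min = 10, pp_min = 0.01) {
  keep <- tree_bf$bf >= bf_min & tree_bf$pp_raw >= pp_min
  out <- tree_bf[keep, , drop = FALSE]
  out[order(-out$bf), , drop = FALSE]
}
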