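# Shared fixtures and independent oracles for the test suite.

# --- toy pathway: 3 variants in 2 genes (a, b in G1; c in G2) ---------------
toy_pathway <- function() {
  raw <- list(
    name = "toy",
    nodes = list(
      list(id = "G1", kind = "gene", label = "G1"),
      list(id = "G2", kind = "gene", label = "G2"),
      list(id = "phase_I", kind = "concept", label = "Phase I"),
      list(id = "a", kind = "variant", gene = "G1", minor_allele = "T",
           expected_maf = 0.3, excluded = FALSE),
      list(id = "b", kind = "variant", gene = "G1", minor_allele = "T",
           expected_maf = 0.3, excluded = FALSE),
      list(id = "c", kind = "variant", gene = "G2", minor_allele = "T",
           expected_maf = 0.3, excluded = FALSE)),
    edges = list(list("a", "G1"), list("b", "G1"), list("c", "G2"),
                 list("G1", "phase_I"), list("G2", "phase_I")),
    concepts = list(all = list(label = "all", ancestor = "phase_I"),
                    gene1 = list(label = "G1 activity", ancestor = "G1")))
  tampath:::pathway_from_list(raw)
}

# all legal trees (leaf sets) over a variant universe
enumerate_trees <- function(universe, max_leaves) {
  out <- list()
  for (L in seq_len(min(max_leaves, length(universe)))) {
    cb <- utils::combn(universe, L, simplify = FALSE)
    out <- c(out, cb)
  }
  out
}

# exact normalized tree prior by enumeration
enumerate_prior <- function(pathway, max_leaves, kappa = 0.5, omega = 2.0) {
  trees <- enumerate_trees(analyzed_variants(pathway), max_leaves)
  lp <- vapply(trees, function(lv) tree_log_prior(list(leaves = lv), pathway,
                                                  kappa, omega), numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  stats::setNames(p, vapply(trees, function(x) paste(sort(x), collapse = "+"),
                            character(1)))
}

# --- supply-diary brute force: day-by-day stock simulation ------------------
brute_force_outcome <- function(supplies, events, initiation_day,
                                gap_days = 182, carryover_cap_days = 182) {
  cw <- tampath:::censor_window(events)
  wend <- cw$window_end
  disp <- supplies$dispense_day
  supl <- supplies$days_supplied
  stock <- 0
  run <- 0L
  day <- initiation_day
  while (day < wend) {
    hit <- which(disp == day & disp < wend)
    for (h in hit) stock <- min(stock, carryover_cap_days) + supl[h]
    if (stock > 0) {
      run <- 0L
      stock <- stock - 1
    } else {
      run <- run + 1L
      if (run >= gap_days) {
        return(data.frame(time_days = day - initiation_day, event = 1L,
                          censor_reason = "none", stringsAsFactors = FALSE))
      }
    }
    day <- day + 1L
  }
  data.frame(time_days = wend - initiation_day, event = 0L,
             censor_reason = cw$cause, stringsAsFactors = FALSE)
}

# random one-subject supply/censoring fixture
random_diary_fixture <- function() {
  init <- sample(0:120, 1)
  nd <- sample(0:8, 1)
  disp <- sort(unique(c(init, init + sample(1:1700, nd, TRUE))))
  ev <- data.frame(ai_switch_day = NA, recurrence_day = NA, death_day = NA,
                   emigration_day = NA, admin_censor_day = 1825L)
  for (cause in c("ai_switch_day", "recurrence_day", "death_day")) {
    if (stats::runif(1) < 0.3) ev[[cause]] <- init + sample(1:1900, 1)
  }
  list(supplies = data.frame(dispense_day = disp,
                             days_supplied = sample(c(90L, 182L), length(disp), TRUE)),
       events = ev, initiation_day = init)
}

# --- allele-counting oracles ------------------------------------------------
brute_maf <- function(g) {
  obs <- g[!is.na(g)]
  alleles <- c(rep(0, 2 * sum(obs == 0)), rep(c(0, 1), sum(obs == 1)),
               rep(1, 2 * sum(obs == 2)))
  f <- mean(alleles)
  min(f, 1 - f)
}

brute_hwe_chi2 <- function(g) {
  obs <- g[!is.na(g)]
  n <- length(obs)
  q <- mean(obs) / 2
  p <- 1 - q
  e <- n * c(p^2, 2 * p * q, q^2)
  o <- c(sum(obs == 0), sum(obs == 1), sum(obs == 2))
  sum((o - e)^2 / e)
}

# --- Gauss-Hermite nodes/weights (Golub-Welsch) -----------------------------
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = (e$vectors[1, ])^2 * sqrt(pi))
}

# mode-centered adaptive Gauss-Hermite integration of the tree posterior
# (independent evaluation of the same integral log_marginal_likelihood
# approximates; the integrand is the exact unnormalized posterior)
quadrature_log_ml <- function(leaves, genotypes, outcomes, nodes = 20,
                              ties = "efron") {
  prep <- tampath:::cox_prep(outcomes$time_days, outcomes$event)
  g <- as.matrix(genotypes[, leaves, drop = FALSE])
  ft <- fit_tree_params(list(leaves = leaves), genotypes, outcomes, ties = ties)
  k <- ft$k
  S <- t(chol(solve(ft$curvature)))
  gh <- gauss_hermite(nodes)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(nodes)), k)))
  logf <- function(x) {
    th <- if (k == 1) 1 else exp(x[-1]) - 1
    P <- rep(1, nrow(g))
    for (l in seq_len(ncol(g))) P <- P * (1 + (if (k == 1) 1 else th[l]) * g[, l])
    tampath:::cox_pl(prep, x[1] * (P - 1), ties = ties)$ll +
      sum(stats::dnorm(x, log = TRUE))
  }
  vals <- apply(idx, 1, function(r) {
    z <- gh$nodes[r]
    p <- ft$x + sqrt(2) * as.numeric(S %*% z)
    logf(p) + sum(log(gh$weights[r]) + z^2)
  })
  vals <- vals[is.finite(vals)]
  M <- max(vals)
  M + log(sum(exp(vals - M))) + (k / 2) * log(2) +
    as.numeric(determinant(S)$modulus)
}

# small survival dataset for Cox micro-tests
random_micro_surv <- function() {
  n <- sample(4:8, 1)
  list(time = sample(1:10, n, TRUE), event = rbinom(n, 1, 0.7),
       x = sample(0:2, n, TRUE))
}

# grid-search maximizer of the Breslow partial likelihood for one exposure,
# vectorised over the beta grid (micro datasets only):
# ll(b) = sum_events [ b*x_i - log sum_{j in risk set} exp(b*x_j) ]
grid_search_cox <- function(time, event, x, step = 1e-4, lim = 5) {
  betas <- seq(-lim, lim, by = step)
  E <- exp(outer(betas, x))          # grid x subjects
  ll <- numeric(length(betas))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + betas * x[i] - log(rowSums(E[, risk, drop = FALSE]))
  }
  betas[which.max(ll)]
}
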