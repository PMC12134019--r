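#' Multiplicative gene-interaction trees
#'
#' An interaction tree is a set of leaf variants with per-leaf interaction
#' parameters theta and an overall pathway effect beta on the log-hazard
#' scale. A subject with minor-allele dosages g contributes the log hazard
#'
#'   beta * (prod_over_leaves(1 + theta_leaf * g_leaf) - 1)
#'
#' so the reference genotype (all g = 0) contributes 0 and, for two leaves,
#' the model expands to beta*theta1*g1 + beta*theta2*g2 +
#' beta*theta1*theta2*g1*g2 — main effects plus a product interaction. A
#' single-leaf tree fixes theta = 1, i.e. the contribution is beta * g.
#' Each theta must exceed -1/2 so leaf factors stay positive at g = 2.
#'
#' @name interaction_tree
NULL

# canonical identifier of a leaf set
tree_id <- function(leaves) paste(sort(leaves), collapse = "+")

#' Per-subject log-hazard contribution of a tree
#'
#' @param tree List with `leaves` (character rsids).
#' @param params List with `beta` and `theta` (one per leaf; ignored and
#'   fixed at 1 for single-leaf trees).
#' @param genotypes Numeric matrix (subjects x leaves, minor-allele dosage),
#'   a data.frame containing the leaf columns, or a vector for one subject.
#' @return Numeric vector of log hazards (0 at the reference genotype).
#' @export
tree_loghazard <- function(tree, params, genotypes) {
  L <- length(tree$leaves)
  g <- if (is.data.frame(genotypes)) {
    as.matrix(genotypes[, tree$leaves, drop = FALSE])
  } else if (is.matrix(genotypes)) {
    genotypes[, seq_len(L), drop = FALSE]
  } else {
    matrix(genotypes, nrow = 1)
  }
  if (anyNA(g)) stop("missing leaf genotype")
  theta <- if (L == 1L) 1 else params$theta
  stopifnot(length(theta) == L)
  P <- rep(1, nrow(g))
  for (l in seq_len(L)) P <- P * (1 + theta[l] * g[, l])
  params$beta * (P - 1)
}

#' Unnormalized log prior of a tree under the pathway
#'
#' Size penalty `kappa` per leaf beyond the first, times an affinity bonus
#' `omega` for every leaf pair sharing a pathway gene parent:
#' `(L - 1) * log(kappa) + n_shared_pairs * log(omega)`.
#'
#' @param tree List with `leaves`.
#' @param pathway A `pathway_graph` (for the leaf -> gene map).
#' @param kappa Size penalty per extra leaf (default 0.5).
#' @param omega Same-gene pair bonus (default 2).
#' @return Unnormalized log prior (scalar).
#' @export
tree_log_prior <- function(tree, pathway, kappa = 0.5, omega = 2.0) {
  L <- length(tree$leaves)
  genes <- pathway$variants$gene[match(tree$leaves, pathway$variants$rsid)]
  shared <- 0L
  if (L >= 2L) {
    tab <- table(genes)
    shared <- sum(choose(tab, 2))
  }
  (L - 1) * log(kappa) + shared * log(omega)
}

# unconstrained parametrization: x = (b, phi_1..phi_L), theta = exp(phi) - 1
# (single leaf: x = (b), theta fixed at 1)
tree_scores_x <- function(x, g) {
  L <- ncol(g)
  if (L == 1L) theta <- 1 else theta <- exp(x[-1L]) - 1
  P <- rep(1, nrow(g))
  for (l in seq_len(L)) P <- P * (1 + theta[l] * g[, l])
  list(s = x[1L] * (P - 1), P = P, theta = theta)
}

#' Maximum a posteriori fit of a tree's parameters
#'
#' Maximizes the ties-corrected Cox log partial likelihood of the tree's
#' subject scores plus independent standard-normal log prior densities on
#' beta and on each log(1 + theta). Single-leaf trees fix theta = 1 and fit
#' beta only. Optimization is compiled damped Newton with analytic gradient
#' and Hessian and eigenvalue-floored steps; two starting points are always
#' tried because the multiplicative model has a saddle at the origin and can
#' be multimodal, and a stationary point with non-positive curvature is
#' escaped along the most negative curvature direction.
#'
#' @param tree List with `leaves`.
#' @param genotypes Genotype table containing the leaf columns.
#' @param outcomes Data frame with `time_days`, `event` (>= 10 events).
#' @param ties Tie correction.
#' @param init Optional warm-start parameter vector (b, phi...).
#' @param prep Optional precomputed `cox_prep` structure.
#' @return List: `params` (list `beta`, `theta`), `x` (internal coordinates),
#'   `logpost` (log posterior at MAP), `ll` (partial likelihood term),
#'   `curvature` (k x k matrix), `k`, `convergence`.
#' @export
fit_tree_params <- function(tree, genotypes, outcomes, ties = "efron",
                            init = NULL, prep = NULL) {
  miss <- setdiff(tree$leaves, names(genotypes))
  if (length(miss)) stop("tree leaves absent from genotypes: ",
                         paste(miss, collapse = ", "))
  if (sum(outcomes$event) < 10) stop("fewer than 10 events")
  g <- as.matrix(genotypes[, tree$leaves, drop = FALSE])
  if (anyNA(g)) stop("missing leaf genotype")
  if (is.null(prep)) prep <- cox_prep(outcomes$time_days, outcomes$event)
  L <- ncol(g)
  k <- if (L == 1L) 1L else 1L + L
  gs <- g[prep$ord, , drop = FALSE]
  storage.mode(gs) <- "double"
  run_from <- function(start) {
    r <- tree_map_fit(gs, prep$ev_all, prep$grp_of_ev, prep$d,
                      prep$risk_starts, efron = (ties == "efron"),
                      init = start)
    if (!isTRUE(r$ok)) NULL else r
  }
  # x = 0 is a saddle of the multiplicative model (all gradients vanish at
  # beta = 0, theta = 0), so starts are kept away from it. Two starts are
  # always tried: the posterior can be multimodal, and a warm start must
  # never be the only one -- the fitted value is memoized by the chain, so a
  # silently bad warm fit would persist
  x0 <- if (!is.null(init) && length(init) == k) init else c(0.02, rep(0.05, k - 1L))
  if (abs(x0[1L]) < 1e-3) x0[1L] <- 0.02
  alt <- if (is.null(init)) c(-0.02, rep(0.05, k - 1L)) else c(0.02, rep(0.05, k - 1L))
  opt <- run_from(x0)
  opt2 <- run_from(alt)
  if (is.null(opt) && is.null(opt2)) stop("tree fit failed from both starts")
  if (is.null(opt) || (!is.null(opt2) && opt2$value < opt$value - 1e-9)) {
    opt <- opt2
  }
  # a stationary point with non-positive curvature is the saddle, not a
  # mode: push off it once and re-optimize
  if (k > 1L && min(eigen(opt$curvature, symmetric = TRUE,
                          only.values = TRUE)$values) <= 0) {
    opt4 <- run_from(opt$par + 0.1)
    if (!is.null(opt4) && opt4$value <= opt$value) opt <- opt4
  }
  x <- as.numeric(opt$par)
  theta <- if (L == 1L) 1 else exp(x[-1L]) - 1
  list(params = list(beta = x[1L], theta = theta), x = x,
       logpost = -opt$value, ll = opt$ll, curvature = opt$curvature, k = k,
       convergence = as.integer(opt$convergence))
}

#' Laplace-approximated log marginal likelihood of a tree
#'
#' `log p(data | tree) ~ logpost(MAP) + (k/2) log(2*pi) - 0.5 log det(H)`
#' where `H` is the curvature of the negative log posterior at the MAP and
#' `k` the number of free parameters (1 for a single leaf, 1 + L otherwise).
#' A singular curvature is ridged by 1e-6 and flagged.
#'
#' @inheritParams fit_tree_params
#' @param fit Optional precomputed result of [fit_tree_params()].
#' @return Scalar log marginal likelihood, with attribute `ridged` if the
#'   curvature needed regularization.
#' @export
log_marginal_likelihood <- function(tree, genotypes, outcomes, ties = "efron",
                                    init = NULL, prep = NULL, fit = NULL) {
  if (is.null(fit)) {
    fit <- fit_tree_params(tree, genotypes, outcomes, ties = ties,
                           init = init, prep = prep)
  }
  H <- fit$curvature
  ridged <- FALSE
  det_ok <- function(M) {
    ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    all(ev > 0)
  }
  if (!det_ok(H)) {
    H <- H + diag(1e-6, nrow(H))
    ridged <- TRUE
  }
  val <- fit$logpost + (fit$k / 2) * log(2 * pi) -
    0.5 * determinant(H, logarithm = TRUE)$modulus[1]
  attr(val, "ridged") <- ridged
  attr(val, "fit") <- fit
  val
}

#' Genotype-combination hazard-ratio grid of a two-leaf tree
#'
#' @param tree List with exactly two `leaves`.
#' @param params List with `beta` and `theta` (length 2).
#' @return 3x3 matrix of hazard ratios indexed by minor-allele dosages
#'   (g1 = rows 0..2, g2 = columns 0..2); cell (0,0) is exactly 1.
#' @export
hr_grid <- function(tree, params) {
  if (length(tree$leaves) != 2L) stop("hr_grid requires exactly 2 leaves")
  grid <- outer(0:2, 0:2, function(g1, g2) {
    params$beta * ((1 + params$theta[1] * g1) * (1 + params$theta[2] * g2) - 1)
  })
  out <- exp(grid)
  dimnames(out) <- list(g1 = 0:2, g2 = 0:2)
  out[1, 1] <- 1
  out
}

#' Recover (beta, theta1, theta2) from printed hazard-ratio grid cells
#'
#' Least squares in log space: minimizes the sum of squared differences
#' between `log(hr)` and `beta * ((1 + theta1*g1) * (1 + theta2*g2) - 1)`
#' over the supplied cells, from the fixed initialization beta = 0.01,
#' theta = 1 (deterministic).
#'
#' @param cells Data frame with columns `g1`, `g2`, `hr` (the reference cell
#'   (0,0) may be omitted; it carries no information).
#' @return List: `beta`, `theta` (length 2), `residual` (sum of squares).
#' @export
fit_grid_params <- function(cells) {
  cells <- cells[!(cells$g1 == 0 & cells$g2 == 0), , drop = FALSE]
  if (nrow(cells) < 3L || !any(cells$g1 >= 1 & cells$g2 >= 1)) {
    stop("under-identified cell set: need >= 3 non-reference cells including an interaction cell")
  }
  y <- log(cells$hr)
  obj <- function(p) {
    mu <- p[1] * ((1 + p[2] * cells$g1) * (1 + p[3] * cells$g2) - 1)
    sum((y - mu)^2)
  }
  grr <- function(p) {
    f1 <- 1 + p[2] * cells$g1; f2 <- 1 + p[3] * cells$g2
    mu <- p[1] * (f1 * f2 - 1)
    r <- mu - y
    2 * c(sum(r * (f1 * f2 - 1)),
          sum(r * p[1] * cells$g1 * f2),
          sum(r * p[1] * f1 * cells$g2))
  }
  opt <- stats::optim(c(0.01, 1, 1), obj, grr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  # polish with a second pass for near-exact round trips
  opt <- stats::optim(opt$par, obj, grr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  list(beta = opt$par[1], theta = opt$par[2:3], residual = opt$value)
}
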