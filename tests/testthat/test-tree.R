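test_that("tree log-hazard follows the multiplicative leaf form", {
  tr <- list(leaves = c("a", "b"))
  par <- list(beta = 0.018, theta = c(4.82, 3.17))
  expect_equal(tree_loghazard(tr, par, c(0, 0)), 0)
  expect_equal(tree_loghazard(tr, par, c(2, 2)), log(4.00), tolerance = 0.005)
  expect_equal(tree_loghazard(tr, list(beta = 0, theta = c(1, 2)), c(2, 1)), 0)
  # single leaf: theta fixed at 1, contribution beta * g
  expect_equal(tree_loghazard(list(leaves = "a"), list(beta = 0.3),
                              matrix(c(0, 1, 2), ncol = 1)),
               0.3 * c(0, 1, 2))
  expect_error(tree_loghazard(tr, par, c(NA, 1)), "missing")
})

test_that("two-leaf trees expand to main effects plus product interaction", {
  set.seed(5)
  for (i in 1:20) {
    beta <- rnorm(1, 0, 0.3)
    theta <- runif(2, -0.4, 4)
    g <- cbind(sample(0:2, 9, TRUE), sample(0:2, 9, TRUE))
    lh <- tree_loghazard(list(leaves = c("x", "y")),
                         list(beta = beta, theta = theta), g)
    expanded <- beta * theta[1] * g[, 1] + beta * theta[2] * g[, 2] +
      beta * theta[1] * theta[2] * g[, 1] * g[, 2]
    expect_equal(lh, expanded, tolerance = 1e-12)
  }
})

test_that("tree prior scores size and same-gene affinity", {
  pw <- toy_pathway()   # a, b in gene G1; c in G2
  expect_equal(tree_log_prior(list(leaves = "a"), pw), 0)
  expect_equal(tree_log_prior(list(leaves = c("a", "b")), pw),
               log(0.5) + log(2))
  expect_equal(tree_log_prior(list(leaves = c("a", "c")), pw), log(0.5))
  expect_equal(tree_log_prior(list(leaves = c("a", "b", "c")), pw),
               2 * log(0.5) + log(2))
  expect_equal(tree_log_prior(list(leaves = c("a", "c")), pw, kappa = 0.2,
                              omega = 3), log(0.2))
})

test_that("hazard-ratio grids are reference-anchored and structured", {
  par <- list(beta = 0.0180, theta = c(4.82, 3.17))
  gr <- hr_grid(list(leaves = c("a", "b")), par)
  expect_identical(gr[1, 1], 1)
  expect_true(all(gr > 0))
  expect_equal(gr[2, 2], 1.52, tolerance = 0.01)
  gr0 <- hr_grid(list(leaves = c("a", "b")), list(beta = 0, theta = c(1, 1)))
  expect_equal(unname(as.vector(gr0)), rep(1, 9))
  # theta2 = 0: no dependence on g2 at all
  grx <- hr_grid(list(leaves = c("a", "b")), list(beta = 0.1, theta = c(2, 0)))
  expect_equal(grx[, 1], grx[, 2])
  expect_equal(grx[, 1], grx[, 3])
  expect_error(hr_grid(list(leaves = "a"), par), "2 leaves")
})

test_that("grid-parameter recovery round-trips and flags under-identification", {
  set.seed(6)
  for (i in 1:10) {
    true <- list(beta = runif(1, 0.005, 0.2), theta = runif(2, 0.3, 5))
    gr <- hr_grid(list(leaves = c("a", "b")), true)
    cells <- expand.grid(g1 = 0:2, g2 = 0:2)
    cells$hr <- gr[cbind(cells$g1 + 1, cells$g2 + 1)]
    fp <- fit_grid_params(cells)
    expect_lt(fp$residual, 1e-8)
    pred <- hr_grid(list(leaves = c("a", "b")),
                    list(beta = fp$beta, theta = fp$theta))
    expect_equal(unname(as.vector(pred)), unname(as.vector(gr)),
                 tolerance = 1e-4)
  }
  flat <- data.frame(g1 = c(1, 0, 1), g2 = c(0, 1, 1), hr = 1)
  ff <- fit_grid_params(flat)
  predf <- hr_grid(list(leaves = c("a", "b")),
                   list(beta = ff$beta, theta = ff$theta))
  expect_equal(unname(as.vector(predf)), rep(1, 9), tolerance = 1e-4)
  expect_error(fit_grid_params(data.frame(g1 = c(1, 2), g2 = c(0, 0),
                                          hr = c(1.1, 1.2))),
               "under-identified")
})

test_that("single-leaf MAP essentially matches the conventional Cox fit", {
  cc <- cohort_config(n_subjects = 3200, seed = 44, missing_rate = 0,
                      effect_tree = list(leaves = "rs16947", theta = 1,
                                         beta = 0.2))
  ch <- simulate_cohort(cc)
  oc <- derive_cohort_outcomes(ch$supplies, ch$events, ch$covariates)
  ft <- fit_tree_params(list(leaves = "rs16947"), ch$genotypes, oc)
  fc <- fit_cox(oc$time_days, oc$event, ch$genotypes$rs16947)
  expect_lt(abs(ft$params$beta - fc$terms$coef), 0.02)
})

test_that("two-locus parameters are recovered from forward-simulated cohorts", {
  cc <- cohort_config(n_subjects = 50000, seed = 46, missing_rate = 0,
                      ai_switch_rate = 2e-4)
  g <- simulate_genotypes(cc)
  cv <- simulate_covariates(cc)
  ev <- simulate_events(cc, g, cv)
  # latent event times with administrative censoring only (engine-level check)
  lat <- ev$latent_discontinuation_day - cv$initiation_day
  oc <- data.frame(time_days = pmin(lat, 1795L),
                   event = as.integer(lat <= 1795L))
  ft <- fit_tree_params(list(leaves = c("rs16947", "rs3740065")), g, oc)
  est <- hr_grid(list(leaves = c("rs16947", "rs3740065")), ft$params)
  gen <- hr_grid(list(leaves = c("rs16947", "rs3740065")),
                 list(beta = 0.0180, theta = c(4.82, 3.17)))
  expect_true(all(abs(est / gen - 1) < 0.10))
})

test_that("the fitted curvature matches finite differences of the log posterior", {
  set.seed(33)
  n <- 400
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.25)
  t <- ceiling(rexp(n, 3e-3 * exp(0.1 * g1 * g2)))
  time <- pmin(t, 900); ev <- as.integer(t <= 900)
  G <- data.frame(subject_id = as.character(1:n), a = g1, b = g2)
  oc <- data.frame(time_days = time, event = ev)
  ft <- fit_tree_params(list(leaves = c("a", "b")), G, oc)
  prep <- tampath:::cox_prep(time, ev)
  f <- function(x) {
    th <- exp(x[-1]) - 1
    s <- x[1] * ((1 + th[1] * g1) * (1 + th[2] * g2) - 1)
    -(tampath:::cox_pl(prep, s)$ll + sum(stats::dnorm(x, log = TRUE)))
  }
  expect_equal(ft$logpost, -f(ft$x), tolerance = 1e-9)
  h <- 1e-4; k <- 3
  Hn <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    ei <- numeric(k); ei[i] <- h
    ej <- numeric(k); ej[j] <- h
    Hn[i, j] <- (f(ft$x + ei + ej) - f(ft$x + ei - ej) -
                   f(ft$x - ei + ej) + f(ft$x - ei - ej)) / (4 * h^2)
  }
  expect_equal(ft$curvature, Hn, tolerance = 1e-3, ignore_attr = TRUE)
  # gradient vanishes at the reported MAP
  gn <- vapply(1:k, function(i) {
    ei <- numeric(k); ei[i] <- 1e-6
    (f(ft$x + ei) - f(ft$x - ei)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(gn)), 1e-4)
})

test_that("Laplace marginal likelihood is exact against 1-D quadrature", {
  set.seed(5)
  n <- 20
  g <- rbinom(n, 2, 0.35)
  time <- sample(1:15, n, TRUE)
  event <- rbinom(n, 1, 0.7); event[1] <- 1
  G <- data.frame(subject_id = as.character(1:n), a = g)
  oc <- data.frame(time_days = time, event = event)
  lap <- as.numeric(log_marginal_likelihood(list(leaves = "a"), G, oc))
  prep <- tampath:::cox_prep(oc$time_days, oc$event)
  f <- Vectorize(function(b) exp(tampath:::cox_pl(prep, b * g)$ll +
                                   stats::dnorm(b, log = TRUE)))
  quad <- log(stats::integrate(f, -8, 8, rel.tol = 1e-10)$value)
  expect_lt(abs(lap - quad), 0.1)
  expect_error(log_marginal_likelihood(list(leaves = "a"), G,
                                       data.frame(time_days = time,
                                                  event = rep(0, n))),
               "events")
})

test_that("adding a pure-noise leaf pays an Occam penalty on average", {
  diffs <- c()
  for (s in 1:10) {
    cc <- cohort_config(n_subjects = 1500, seed = 500 + s, missing_rate = 0,
                        effect_tree = list(leaves = "rs16947", theta = 1,
                                           beta = 0.25),
                        maf = c(rs16947 = 0.34, noise = 0.3))
    ch <- simulate_cohort(cc)
    oc <- derive_cohort_outcomes(ch$supplies, ch$events, ch$covariates)
    m1 <- as.numeric(log_marginal_likelihood(list(leaves = "rs16947"),
                                             ch$genotypes, oc))
    m2 <- as.numeric(log_marginal_likelihood(list(leaves = c("rs16947", "noise")),
                                             ch$genotypes, oc))
    diffs <- c(diffs, m2 - m1)
  }
  expect_lt(mean(diffs), 0)
})
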