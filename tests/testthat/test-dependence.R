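test_that("intercept-only logistic fit recovers the log-odds closed form", {
  d <- tibble::tibble(target = c(rep(1, 3), rep(0, 97)), site1 = 0, site2 = 0)
  fit <- logistic_fit(d, target ~ 1)
  expect_equal(unname(coef(fit$fit)), log(3 / 97), tolerance = 1e-6)
  expect_equal(glance(fit)$deviance, -2 * (3 * log(0.03) + 97 * log(0.97)),
               tolerance = 1e-6)
})

test_that("separation and collinearity are detected", {
  d <- tibble::tibble(target = rep(c(0, 1), each = 20),
                      site1 = rep(c(0, 1), each = 20),
                      site2 = rbinom(40, 1, 0.5))
  expect_error(logistic_fit(d, target ~ site1), "separation")
  d2 <- tibble::tibble(target = rbinom(40, 1, 0.3), site1 = rep(0:1, 20))
  d2$site2 <- d2$site1
  expect_error(logistic_fit(d2, target ~ site1 + site2), "collinear")
})

test_that("two-predictor MLE matches a brute-force likelihood grid", {
  d <- simulate_site_design(300, beta0 = -1, beta1 = 1.2, beta2 = 0.8, seed = 55)
  fit <- logistic_fit(d, target ~ site1 + site2)
  est <- coef(fit$fit)
  ll <- function(b) {
    eta <- b[1] + b[2] * d$site1 + b[3] * d$site2
    sum(d$target * eta - log1p(exp(eta)))
  }
  # coarse-to-fine grid around a wide box
  best <- c(0, 0, 0)
  for (width in c(4, 1, 0.25, 0.05, 0.01)) {
    grid <- expand.grid(b0 = best[1] + seq(-width, width, length.out = 9),
                        b1 = best[2] + seq(-width, width, length.out = 9),
                        b2 = best[3] + seq(-width, width, length.out = 9))
    vals <- apply(grid, 1, ll)
    best <- as.numeric(grid[which.max(vals), ])
  }
  expect_equal(unname(est), best, tolerance = 5e-3)
  # deviance identity: -2 * loglik
  expect_equal(glance(fit)$deviance, -2 * ll(est), tolerance = 1e-8)
})

test_that("Wald odds-ratio intervals exponentiate the +/- 1.96 SE band", {
  d <- simulate_site_design(400, seed = 66)
  fit <- logistic_fit(d, target ~ site1 + site2)
  td <- tidy(fit)
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_equal(td$or_conf_low, exp(td$estimate - 1.96 * td$std_error))
  expect_equal(td$or_conf_high, exp(td$estimate + 1.96 * td$std_error))
})

test_that("stepwise selection rejects a collinear addition and keeps model 1", {
  set.seed(9)
  d <- simulate_site_design(500, seed = 77)
  d$site2 <- d$site1
  sel <- stepwise_select(d)
  expect_equal(sel$accepted, 1L)
  expect_equal(sel$steps$delta_x2[2], 0, tolerance = 1e-9)
  expect_equal(sel$steps$p_value[2], 1)
})

test_that("stepwise selection has the expected operating characteristics", {
  eff <- vapply(1:30, function(i) {
    stepwise_select(simulate_site_design(seed = 5000 + i))$accepted
  }, integer(1))
  expect_gte(mean(eff == 2L), 0.8)
  null <- vapply(1:30, function(i) {
    stepwise_select(simulate_site_design(beta1 = 0, beta2 = 0,
                                         seed = 6000 + i))$accepted
  }, integer(1))
  expect_gte(mean(null == 0L), 0.85)
})

test_that("tidy stepwise output is Table-shaped", {
  d <- simulate_site_design(800, seed = 88)
  sel <- stepwise_select(d)
  td <- tidy(sel)
  expect_true(all(c("model", "delta_x2", "p_value", "term", "estimate",
                    "odds_ratio", "accepted") %in% names(td)))
  expect_equal(sort(unique(td$model)), 0:3)
  expect_equal(unique(td$model[td$accepted]), sel$accepted)
})

test_that("fisher dependence labels the direction of site co-occurrence", {
  expect_equal(fisher_dependence(30, 5, 5, 30)$dependence, "overlap more")
  expect_equal(fisher_dependence(2, 28, 28, 2)$dependence, "overlap less")
  expect_equal(fisher_dependence(10, 10, 10, 10)$dependence, "none")
})

test_that("the gain/loss generator permits only single-step transitions", {
  r <- c(g1.0 = .1, g1.1 = .2, l1.0 = .3, l1.1 = .4,
         g2.0 = .5, g2.1 = .6, l2.0 = .7, l2.1 = .8)
  Q <- gainloss_generator(r, "dependence")
  expect_equal(rowSums(Q), setNames(rep(0, 4), rownames(Q)))
  expect_equal(Q["00", "11"], 0)   # double gains forbidden
  expect_equal(Q["01", "10"], 0)   # simultaneous swap forbidden
  Qi <- gainloss_generator(c(g1 = .2, l1 = .4, g2 = .1, l2 = .3), "independence")
  expect_equal(Qi["00", "10"], Qi["01", "11"])   # parallel rates tied
  expect_equal(Qi["10", "00"], Qi["11", "01"])
})

test_that("zero branch lengths reduce the likelihood to the root prior", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  states <- matrix("01", 1, 3, dimnames = list("g1", c("A", "B", "C")))
  ll <- ctmc_loglik(tr, states, c(g1 = 1, l1 = 1, g2 = 1, l2 = 1),
                    "independence")
  expect_equal(ll, log(0.25), tolerance = 1e-9)
})

test_that("independence likelihood factorizes into two 2-state chains", {
  set.seed(91)
  for (i in 1:20) {
    tr <- simulate_tree(sample(3:6, 1), mean_branch = 0.5, seed = 700 + i)
    rates <- c(g1 = runif(1, .1, 2), l1 = runif(1, .1, 2),
               g2 = runif(1, .1, 2), l2 = runif(1, .1, 2))
    st <- simulate_sites(tr, 30, rates, model = "independence",
                         dropout = 0.1, seed = 800 + i)
    m <- states_matrix(st)
    keep <- rowSums(!is.na(m)) >= 2
    m <- m[keep, , drop = FALSE]
    ll4 <- ctmc_loglik(tr, m, rates, "independence")
    m1 <- matrix(as.integer(substr(m, 1, 1)), nrow(m), ncol(m),
                 dimnames = dimnames(m))
    m2 <- matrix(as.integer(substr(m, 2, 2)), nrow(m), ncol(m),
                 dimnames = dimnames(m))
    ll2 <- prune2_loglik(tr, m1, rates["g1"], rates["l1"]) +
           prune2_loglik(tr, m2, rates["g2"], rates["l2"])
    expect_equal(ll4, ll2, tolerance = 1e-9)
  }
})

test_that("genes with fewer than two observed species are excluded", {
  tr <- simulate_tree(3, seed = 4)
  states <- rbind(g1 = c("00", "11", NA),
                  g2 = c("01", NA, NA))
  colnames(states) <- tr$tip.label
  rates <- c(g1 = 1, l1 = 1, g2 = 1, l2 = 1)
  ll_both <- ctmc_loglik(tr, states, rates, "independence")
  ll_first <- ctmc_loglik(tr, states[1, , drop = FALSE], rates, "independence")
  expect_equal(ll_both, ll_first)
})

test_that("MCMC chains are bit-reproducible and summaries well formed", {
  tr <- simulate_tree(3, mean_branch = 0.5, seed = 14)
  st <- simulate_sites(tr, 40, c(g1 = 1, l1 = 1.5, g2 = 0.5, l2 = 1),
                       model = "independence", seed = 15)
  fit1 <- mcmc_rates(tr, st, "independence", iterations = 3000, burnin = 500,
                     thin = 10, seed = 3)
  fit2 <- mcmc_rates(tr, st, "independence", iterations = 3000, burnin = 500,
                     thin = 10, seed = 3)
  expect_identical(fit1$samples, fit2$samples)
  expect_identical(fit1$log_harmonic_mean, fit2$log_harmonic_mean)
  expect_true(all(fit1$samples > 0 & fit1$samples <= fit1$r_max))
  td <- tidy(fit1)
  expect_true(all(td$q025 <= td$median & td$median <= td$q975))
})

test_that("the Bayes factor favours independence on independence data", {
  tr <- ape::read.tree(text = "((A:0.4,B:0.4):0.3,C:0.6);")
  st <- simulate_sites(tr, 120, c(g1 = 1, l1 = 1.5, g2 = 0.5, l2 = 1),
                       model = "independence", seed = 16)
  bf <- bayes_factor_dependence(tr, st, iterations = 12000, burnin = 3000,
                                thin = 20, r_max = 20, seed = 5)
  expect_lt(bf$log_bayes_factor, 2)   # no support for the richer model
})

test_that("stepping-stone estimate is finite and near the harmonic mean", {
  tr <- simulate_tree(3, mean_branch = 0.5, seed = 18)
  st <- simulate_sites(tr, 30, c(g1 = 1, l1 = 1, g2 = 1, l2 = 1),
                       model = "independence", seed = 19)
  ss <- stepping_stone(tr, st, "independence", n_rungs = 5,
                       iter_per_rung = 800, r_max = 20, seed = 6)
  expect_true(is.finite(ss$log_marginal))
  hm <- mcmc_rates(tr, st, "independence", iterations = 5000, burnin = 1000,
                   thin = 10, r_max = 20, seed = 7)
  expect_lt(abs(ss$log_marginal - hm$log_harmonic_mean), 25)
})
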