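test_that("state initialisation follows the midpoint recursion", {
  tr <- read_newick_text("(A:1,B:1);")
  expect_equal(initialize_state(tr, traits_for(tr, c(0, 2))), 1)
  tr3 <- read_newick_text(newick_3tip)
  expect_equal(initialize_state(tr3, traits_for(tr3, c(0.7, 0.7, 0.7))),
               c(0.7, 0.7))
  # finite likelihood at both ends of the sampler's support
  tr5 <- read_newick_text(newick_5tip)
  tt5 <- traits_for(tr5, c(2, -1, 0.5, 3, -2))
  init <- initialize_state(tr5, tt5)
  for (a in c(1.1, 2)) {
    ll <- augmented_loglik(tr5, tt5, init, stable_params(a, 0.5, init[1]))
    expect_true(is.finite(ll))
  }
})

test_that("PSRF matches its closed formula and flags degeneracy", {
  # identical constant chains: zero within-chain variance
  expect_warning(r <- psrf(list(rep(1, 100), rep(1, 100))), "variance")
  expect_identical(r, Inf)
  # separated means: plug into the formula directly
  set.seed(12)
  c1 <- rnorm(1000, 0, 1); c2 <- rnorm(1000, 10, 1)
  W <- mean(c(var(c1), var(c2)))
  B_n <- var(c(mean(c1), mean(c2)))
  expect_equal(psrf(list(c1, c2)), sqrt(((999 / 1000) * W + B_n) / W),
               tolerance = 1e-12)
  expect_gt(psrf(list(c1, c2)), 2)
  # well-mixed iid chains converge
  set.seed(13)
  expect_lt(psrf(list(rnorm(10000), rnorm(10000))), 1.01)
  expect_error(psrf(list(rnorm(100))), "2 chains")
  expect_error(psrf(list(rnorm(5), rnorm(5))), "10 draws")
})

test_that("identical inputs and seed give byte-identical posteriors", {
  sc <- scenario_spec(n_extant = 10, alpha_true = 1.7, c_true = 0.1, seed = 6)
  tr <- simulate_tree(sc)
  sim <- simulate_traits(tr, sc)
  f1 <- suppressWarnings(run_mcmc(tr, sim$traits, tiny_config(seed = 42)))
  f2 <- suppressWarnings(run_mcmc(tr, sim$traits, tiny_config(seed = 42)))
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$c, f2$c)
  expect_identical(f1$node, f2$node)
  f3 <- suppressWarnings(run_mcmc(tr, sim$traits, tiny_config(seed = 43)))
  expect_false(identical(f1$alpha, f3$alpha))
})

test_that("draw bookkeeping: equal run lengths, psrf fields, map estimate", {
  sc <- scenario_spec(n_extant = 8, seed = 14)
  tr <- simulate_tree(sc)
  sim <- simulate_traits(tr, sc)
  fit <- suppressWarnings(run_mcmc(tr, sim$traits, tiny_config(seed = 1)))
  lens <- vapply(fit$runs, function(r) length(r$alpha), integer(1))
  expect_equal(length(unique(lens)), 1L)
  expect_named(fit$psrf, c("alpha", "c", "root_state", "loglik"))
  # the Gelman-Rubin estimator can dip below 1 by O(1/n) sampling noise
  expect_true(all(fit$psrf[!is.na(fit$psrf)] >= 0.99))
  expect_equal(fit$map_estimate$loglik, max(vapply(fit$runs, function(r)
    r$map$loglik, numeric(1))))
  # the recorded maximum-posterior draw at least matches the best retained draw
  expect_gte(fit$map_estimate$loglik, max(fit$loglik) - 1e-9)
})

test_that("BM-constrained posterior mean of the root matches the GLS mean", {
  spec <- scenario_spec(n_extant = 50, birth = 0.08, death = 0.02,
                        alpha_true = 2, c_true = 0.12, root_true = -1, seed = 8)
  tr <- simulate_tree(spec)
  sim <- simulate_traits(tr, spec)
  fit <- suppressWarnings(run_mcmc(tr, sim$traits,
    chain_config(iterations = 20000, runs = 2, burnin_frac = 0.3, seed = 3,
                 alpha_fixed = 2)))
  gls <- bm_gls_root(tr, sim$traits)
  rs <- root_state_draws(fit)
  mcse <- mcse_batch(rs)
  expect_lt(abs(mean(rs) - gls$mean), 2 * mcse + 1e-3)
  # posterior root interval stays within the vicinity of the data range
  expect_gt(min(rs), min(sim$traits$logmass) - 2)
  expect_lt(max(rs), max(sim$traits$logmass) + 2)
})

test_that("free-alpha fits on Brownian data push alpha to the upper boundary", {
  meds <- vapply(1:5, function(s) {
    spec <- scenario_spec(n_extant = 100, birth = 0.08, death = 0.02,
                          alpha_true = 2, c_true = 0.1,
                          root_true = 0, seed = 20 + s)
    tr <- simulate_tree(spec)
    sim <- simulate_traits(tr, spec)
    fit <- suppressWarnings(run_mcmc(tr, sim$traits,
      chain_config(iterations = 15000, runs = 2, burnin_frac = 0.3,
                   seed = 30 + s)))
    median(fit$alpha)
  }, numeric(1))
  expect_true(all(meds > 1.8))
})

test_that("config validation refuses impossible settings", {
  expect_error(chain_config(iterations = 0), "positive")
  expect_error(chain_config(burnin_frac = 1), "burnin")
  expect_error(chain_config(psrf_target = 1), "exceed")
  expect_error(chain_config(alpha_fixed = 0.9), "alpha_fixed")
})
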