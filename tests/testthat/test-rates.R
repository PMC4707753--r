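# deterministic pseudo-posterior with known node states, for exercising the
# rate arithmetic without MCMC noise
fake_draws <- function(tree, tip_log, node_mat) {
  structure(list(tree = tree,
                 tip_values = stats::setNames(tip_log, tree$tip.label),
                 ntip = ape::Ntip(tree),
                 node = node_mat),
            class = "posterior_draws")
}

test_that("rate multipliers normalise to a unit median and scale as 1/t", {
  tr <- read_newick_text(newick_5tip)
  tips <- c(0.5, -0.5, 1.2, -0.9, 0.1)
  nodes <- matrix(rep(c(0, 0.3, 0.1, -0.2), each = 40), nrow = 40)
  dr <- fake_draws(tr, tips, nodes)
  prof <- branch_rate_multipliers(dr, tr)
  expect_equal(median(prof$edges$multiplier), 1, tolerance = 1e-12)
  expect_true(all(prof$edges$multiplier >= 0))
  # doubling one edge duration halves its raw rate (same increments)
  tr2 <- tr
  tr2$edge.length[3] <- 2 * tr$edge.length[3]
  prof2 <- branch_rate_multipliers(fake_draws(tr2, tips, nodes), tr2)
  expect_equal(prof2$edges$raw_rate[3], prof$edges$raw_rate[3] / 2,
               tolerance = 1e-12)
})

test_that("multipliers are invariant to a uniform shift of all log-masses", {
  tr <- read_newick_text(newick_5tip)
  tips <- c(0.5, -0.5, 1.2, -0.9, 0.1)
  set.seed(2)
  nodes <- matrix(rnorm(40 * 4, 0, 0.5), nrow = 40)
  m1 <- branch_rate_multipliers(fake_draws(tr, tips, nodes), tr)$edges$multiplier
  m2 <- branch_rate_multipliers(fake_draws(tr, tips + 3, nodes + 3),
                                tr)$edges$multiplier
  expect_equal(m2, m1, tolerance = 1e-12)
})

test_that("the time curve averages to the duration-weighted mean multiplier", {
  tr <- read_newick_text(newick_5tip)
  set.seed(3)
  nodes <- matrix(rnorm(40 * 4, 0, 0.5), nrow = 40)
  prof <- branch_rate_multipliers(fake_draws(tr, rnorm(5), nodes), tr)
  tc <- prof$time_curve
  lhs <- sum(tc$multiplier * tc$overlap) / sum(tc$overlap)
  rhs <- sum(prof$edges$multiplier * prof$edges$t_e) / sum(prof$edges$t_e)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(sum(tc$overlap), sum(tr$edge.length), tolerance = 1e-9)
})

test_that("the max-rate branch breaks ties toward the longer edge", {
  tr <- read_newick_text(newick_5tip)
  tips <- rep(0, 5)
  nodes <- matrix(0, nrow = 20, ncol = 4)
  dr <- fake_draws(tr, tips, nodes) # all increments zero: all-equal profile
  prof <- branch_rate_multipliers(dr, tr)
  mx <- max_rate_branch(prof, tr)
  expect_equal(mx$edge$t_e, max(tr$edge.length))
  # descendant tip set reported for the chosen edge
  expect_true(all(mx$descendant_tips %in% tr$tip.label))
})

test_that("a planted hundred-fold rate shift is recovered on Brownian data", {
  hits <- vapply(1:3, function(s) {
    spec0 <- scenario_spec(n_extant = 40, alpha_true = 2, c_true = 0.08,
                           root_true = 0, seed = 40 + s)
    tr <- simulate_tree(spec0)
    # plant on the stem of an internal clade of about ten tips
    ntip <- ape::Ntip(tr)
    inner <- (ntip + 2):(ntip + tr$Nnode)
    sizes <- vapply(inner, function(nd)
      length(stableasr:::.descendant_tips(tr, nd)), integer(1))
    node <- inner[which.min(abs(sizes - 10))]
    spec <- scenario_spec(n_extant = 40, alpha_true = 2, c_true = 0.08,
                          root_true = 0,
                          shift = list(node = node, fold = 100),
                          seed = 40 + s)
    sim <- simulate_traits(tr, spec)
    fit <- suppressWarnings(run_mcmc(tr, sim$traits,
      chain_config(iterations = 15000, runs = 2, burnin_frac = 0.3,
                   seed = 50 + s)))
    mx <- max_rate_branch(branch_rate_multipliers(fit), fit$tree)
    planted_child <- fit$tree$edge[sim$shift_edge, 2]
    mx$edge$child == planted_child
  }, logical(1))
  expect_true(all(hits))
})

test_that("under rate homogeneity no branch looks extreme", {
  spec <- scenario_spec(n_extant = 50, alpha_true = 2, c_true = 0.1,
                        root_true = 0, seed = 60)
  tr <- simulate_tree(spec)
  sim <- simulate_traits(tr, spec)
  fit <- suppressWarnings(run_mcmc(tr, sim$traits,
    chain_config(iterations = 15000, runs = 2, burnin_frac = 0.3, seed = 61)))
  prof <- branch_rate_multipliers(fit)
  expect_equal(median(prof$edges$multiplier), 1, tolerance = 1e-12)
  expect_true(all(prof$edges$multiplier < 30))
})

test_that("the rate-scaled tree stretches branches by their multiplier", {
  tr <- read_newick_text(newick_5tip)
  set.seed(5)
  nodes <- matrix(rnorm(40 * 4), nrow = 40)
  prof <- branch_rate_multipliers(fake_draws(tr, rnorm(5), nodes), tr)
  st <- rate_scaled_tree(prof, tr)
  expect_equal(st$edge.length, prof$edges$multiplier * tr$edge.length)
  # mismatch detection
  tr2 <- tr; tr2$edge.length[1] <- tr2$edge.length[1] + 1
  expect_error(branch_rate_multipliers(fake_draws(tr, rnorm(5), nodes), tr2),
               "match")
})
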