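test_that("augmented likelihood matches hand-computed Gaussian cases", {
  tr <- read_newick_text("(A:1,B:1);")
  p <- stable_params(2, 1, 0)
  expect_equal(augmented_loglik(tr, traits_for(tr, c(0, 0)), 0, p),
               2 * log(1 / sqrt(4 * pi)), tolerance = 1e-10)
  expect_equal(augmented_loglik(tr, traits_for(tr, c(1, -1)), 0, p),
               2 * (log(1 / sqrt(4 * pi)) - 1 / 4), tolerance = 1e-10)
})

test_that("augmented likelihood composes per-edge oracle densities", {
  tr <- read_newick_text(newick_5tip)
  tt <- traits_for(tr, c(0.4, -0.2, 1.1, -0.8, 0.3))
  nodes <- c(0.1, 0.5, 0.2, -0.3) # root, then internal nodes in ape order
  p <- stable_params(1.6, 0.8, 0.1)
  x <- c(tt$logmass, nodes)
  expected <- sum(vapply(seq_len(nrow(tr$edge)), function(e) {
    dx <- x[tr$edge[e, 2]] - x[tr$edge[e, 1]]
    log(oracle_stable_pdf(dx, 1.6, 0.8 * tr$edge.length[e]^(1 / 1.6)))
  }, numeric(1)))
  expect_equal(augmented_loglik(tr, tt, nodes, p), expected, tolerance = 1e-7)
})

test_that("likelihood errors name the offending component", {
  tr <- read_newick_text(newick_3tip)
  tt <- traits_for(tr, c(0, 0, 0))
  p <- stable_params(1.5, 1, 0)
  expect_error(augmented_loglik(tr, tt, c(0, NA), p), "node 5")
  expect_error(augmented_loglik(tr, tt, 0, p), "cover")
  expect_error(bm_marginal_loglik(tr, tt, -1, 0), "positive")
})

test_that("BM pruning equals the dense multivariate normal", {
  trees <- list(
    read_newick_text(newick_3tip),
    read_newick_text(newick_5tip),
    read_newick_text("((A:1,B:1,C:1):1,D:2);"), # polytomy
    read_newick_text(newick_fossil) # non-ultrametric
  )
  set.seed(9)
  for (tr in trees) {
    n <- ape::Ntip(tr)
    x <- rnorm(n)
    tt <- traits_for(tr, x)
    for (s2 in c(0.3, 1.7)) {
      rho <- 0.2
      V <- s2 * ape::vcv(tr)[tr$tip.label, tr$tip.label]
      dense <- -0.5 * t(x - rho) %*% solve(V) %*% (x - rho) -
        0.5 * determinant(V)$modulus[1] - n / 2 * log(2 * pi)
      expect_equal(bm_marginal_loglik(tr, tt, s2, rho), as.numeric(dense),
                   tolerance = 1e-8)
    }
  }
})

test_that("two tips joined at depth one reproduce the closed form", {
  tr <- read_newick_text("(A:1,B:1);")
  tt <- traits_for(tr, c(0, 0))
  expect_equal(bm_marginal_loglik(tr, tt, 1, 0), -log(2 * pi), tolerance = 1e-12)
})

test_that("the GLS phylogenetic mean maximises the BM root likelihood", {
  sc <- scenario_spec(n_extant = 12, fossil_fraction = 0.2, seed = 4)
  tr <- simulate_tree(sc)
  sim <- simulate_traits(tr, sc)
  g <- bm_gls_root(tr, sim$traits)
  x <- bind_traits(tr, sim$traits)
  V <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  Vi <- solve(V)
  one <- rep(1, nrow(V))
  direct <- as.numeric(t(one) %*% Vi %*% x / (t(one) %*% Vi %*% one))
  expect_equal(g$mean, direct, tolerance = 1e-8)
  # likelihood at the GLS mean beats nearby root values
  base <- bm_marginal_loglik(tr, sim$traits, 0.8, g$mean)
  expect_gt(base, bm_marginal_loglik(tr, sim$traits, 0.8, g$mean + 0.05))
  expect_gt(base, bm_marginal_loglik(tr, sim$traits, 0.8, g$mean - 0.05))
})

test_that("at alpha = 2 the augmented model marginalises to the BM likelihood", {
  # 3 tips: one free internal node besides the root; integrate it out
  tr <- read_newick_text(newick_3tip)
  tt <- traits_for(tr, c(0.6, -0.4, 0.9))
  cc <- 0.9; rho <- 0.1
  p <- stable_params(2, cc, rho)
  marg <- log(stats::integrate(function(v) {
    vapply(v, function(vi)
      exp(augmented_loglik(tr, tt, c(rho, vi), p)), numeric(1))
  }, -15, 15, rel.tol = 1e-9)$value)
  expect_equal(marg, bm_marginal_loglik(tr, tt, 2 * cc^2, rho),
               tolerance = 1e-4)

  # 4 tips, two free internal nodes: nested quadrature
  tr4 <- read_newick_text("((A:1,B:2):1,(C:1.5,D:0.5):2);")
  tt4 <- traits_for(tr4, c(0.2, -0.5, 1.0, 0.4))
  p4 <- stable_params(2, 0.7, -0.2)
  inner <- function(u) vapply(u, function(ui) {
    stats::integrate(function(v) vapply(v, function(vi)
      exp(augmented_loglik(tr4, tt4, c(-0.2, ui, vi), p4)), numeric(1)),
      -12, 12, rel.tol = 1e-8)$value
  }, numeric(1))
  marg4 <- log(stats::integrate(inner, -12, 12, rel.tol = 1e-7)$value)
  expect_equal(marg4, bm_marginal_loglik(tr4, tt4, 2 * 0.7^2, -0.2),
               tolerance = 1e-4)
})

test_that("compiled and reference likelihoods agree across parameter space", {
  set.seed(23)
  tr <- read_newick_text(newick_5tip)
  for (rep in 1:5) {
    x_tip <- rnorm(5, 0, 1.5)
    nodes <- rnorm(4, 0, 1.5)
    a <- runif(1, 1.06, 1.99)
    cc <- exp(runif(1, -2, 1))
    tt <- traits_for(tr, x_tip)
    p <- stable_params(a, cc, nodes[1])
    ll_grid <- augmented_loglik(tr, tt, nodes, p, method = "grid")
    ll_quad <- augmented_loglik(tr, tt, nodes, p, method = "quadrature")
    expect_equal(ll_grid, ll_quad, tolerance = 0.02)
  }
})
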