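# Shared fixtures and independent oracles.

# Independent characteristic-function inversion oracle for the symmetric
# stable density: adaptive quadrature (QAGI via stats::integrate) of
# (1/pi) Int_0^inf cos(zk) exp(-k^alpha) dk. Deliberately a different route
# from the package's composite Gauss-Legendre implementation.
oracle_stable_pdf <- function(x, alpha, scale = 1) {
  z <- abs(x) / scale
  f <- stats::integrate(function(k) exp(-k^alpha) * cos(z * k), 0, Inf,
                        rel.tol = 1e-11, subdivisions = 5000L)$value / pi
  f / scale
}

# small fixed trees
newick_3tip <- "((A:1,B:1):1,C:2);"
newick_fossil <- "((A:1,B:0.5):1,C:2);"
newick_5tip <- "(((A:1.2,B:0.8):0.6,C:1.9):0.7,(D:1.1,E:1.4):1.3);"

read_newick_text <- function(txt) {
  validate_time_tree(ape::read.tree(text = txt))
}

traits_for <- function(tree, logmass) {
  stopifnot(length(logmass) == ape::Ntip(tree))
  trait_table(stats::setNames(10^logmass, tree$tip.label))
}

# quick MCMC settings for structural tests (not statistical accuracy)
tiny_config <- function(seed = 1L, ...) {
  chain_config(iterations = 2000, runs = 2, burnin_frac = 0.5, thin = 2,
               seed = seed, ...)
}

# Monte-Carlo standard error by batch means
mcse_batch <- function(x, nbatch = 20L) {
  n <- length(x) %/% nbatch * nbatch
  bm <- colMeans(matrix(x[seq_len(n)], ncol = nbatch))
  stats::sd(bm) / sqrt(nbatch)
}
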