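#' MCMC run configuration
#'
#' Defaults mirror a standard production protocol for this model family:
#' 2,000,000 iterations, four independent runs, 10% burn-in, and a
#' potential-scale-reduction-factor target of 1.01. Scaled-down settings are
#' appropriate for simulation studies and tests.
#'
#' @param iterations iterations per run.
#' @param runs number of independent runs.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param burnin_frac fraction of iterations discarded (and used for proposal
#'   adaptation).
#' @param psrf_target convergence threshold on the Gelman-Rubin statistic.
#' @param alpha_fixed optional fixed stability index (2 for the
#'   Brownian-motion-constrained model); `NULL` samples alpha freely.
#' @param seed integer seed; every source of randomness in a fit derives from
#'   it.
#' @return a `chain_config` list.
#' @export
chain_config <- function(iterations = 2e6, runs = 4, thin = NULL,
                         burnin_frac = 0.10, psrf_target = 1.01,
                         alpha_fixed = NULL, seed = 1L) {
  if (iterations <= 0) stop("iterations must be positive")
  if (runs < 1) stop("need at least one run")
  if (burnin_frac < 0 || burnin_frac >= 1) stop("burnin_frac must be in [0, 1)")
  if (psrf_target <= 1) stop("psrf_target must exceed 1")
  if (!is.null(alpha_fixed) &&
      (alpha_fixed < ALPHA_MIN || alpha_fixed > 2))
    stop("alpha_fixed must lie in [", ALPHA_MIN, ", 2]")
  if (is.null(thin)) {
    # aim for ~1000 retained draws per run
    thin <- max(1L, floor(iterations * (1 - burnin_frac) / 1000))
  }
  structure(list(iterations = as.integer(iterations), runs = as.integer(runs),
                 thin = as.integer(thin), burnin_frac = burnin_frac,
                 psrf_target = psrf_target, alpha_fixed = alpha_fixed,
                 seed = as.integer(seed)),
            class = "chain_config")
}

#' Initialise latent node states
#'
#' Midpoint recursion: a post-order pass sets every internal node to the mean
#' of its children, then a pre-order pass smooths each non-root internal node
#' toward its parent. Gives a finite likelihood for any alpha in the sampler's
#' support.
#'
#' @param tree a `phylo` chronogram.
#' @param traits a `trait_table`.
#' @return numeric vector of internal-node states (root first, `ape` order).
#' @export
initialize_state <- function(tree, traits) {
  x_tip <- bind_traits(tree, traits)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  val <- c(unname(x_tip), rep(NA_real_, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  acc <- rep(0, nn); cnt <- rep(0L, nn)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (is.na(val[p]) && cnt[p] == 0L) val[p] <- 0 # placeholder
    acc[p] <- acc[p] + val[ch]; cnt[p] <- cnt[p] + 1L
    val[p] <- acc[p] / cnt[p]
  }
  pre <- rev(seq_len(nrow(po$edge)))
  for (e in pre) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (ch > ntip) val[ch] <- (val[ch] + val[p]) / 2
  }
  val[(ntip + 1):nn]
}

# moment initialisation of the dispersion from phylogenetic independent
# contrasts: sigma2_hat = mean squared contrast, c = sqrt(sigma2/2)
.init_c <- function(tree, x_tip) {
  sig2 <- tryCatch({
    bt <- ape::multi2di(tree, random = FALSE)
    bt$edge.length[bt$edge.length <= 0] <- DEGEN_EPS * 10
    mean(ape::pic(x_tip[bt$tip.label], bt)^2)
  }, error = function(e) NA_real_)
  if (!is.finite(sig2) || sig2 <= 0) {
    depth <- mean(ape::node.depth.edgelength(tree)[seq_along(x_tip)])
    sig2 <- max(stats::var(x_tip) / max(depth, 1e-6), 1e-8)
  }
  sqrt(sig2 / 2)
}

#' Fit the stable trait model by MCMC
#'
#' Metropolis-within-Gibbs over internal-node states (single-node random walks
#' plus periodic subtree shifts), the stability index alpha (reflected random
#' walk on `(ALPHA_MIN, 2]`, skipped when `alpha_fixed` is set) and the
#' dispersion c (random walk on log c). Priors: alpha uniform on the support,
#' log c uniform on `[-14, 7]`, node states improper flat. Proposal widths
#' adapt during burn-in only. Runs `config$runs` independent chains and
#' reports Gelman-Rubin PSRF for alpha, c, the root state and the
#' log-likelihood.
#'
#' @param tree a `phylo` chronogram.
#' @param traits a `trait_table` covering the tips.
#' @param config a [chain_config()].
#' @return a `posterior_draws` object: per-run draw matrices, pooled
#'   summaries, PSRF per scalar, the maximum-posterior draw, and a
#'   `converged` flag.
#' @export
run_mcmc <- function(tree, traits, config = chain_config()) {
  stopifnot(inherits(config, "chain_config"))
  tree <- validate_time_tree(tree)
  x_tip <- bind_traits(tree, traits)
  ntip <- ape::Ntip(tree)
  init_nodes <- initialize_state(tree, traits)
  c0 <- .init_c(tree, x_tip)
  alpha0 <- if (is.null(config$alpha_fixed)) 1.5 else config$alpha_fixed
  grid <- stable_grid()
  burn <- as.integer(floor(config$iterations * config$burnin_frac))
  opts <- list(iterations = config$iterations, burnin = burn,
               thin = config$thin,
               alpha_fixed = !is.null(config$alpha_fixed),
               alpha_min = ALPHA_MIN, logc_lo = -14, logc_hi = 7,
               subtree_every = 10L)

  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, config$runs)
  runs <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    set.seed(run_seeds[r])
    x0 <- c(unname(x_tip), init_nodes)
    # jitter the starting point per run so PSRF measures real mixing
    x0[(ntip + 1):length(x0)] <- x0[(ntip + 1):length(x0)] +
      stats::rnorm(length(init_nodes), 0, 0.1)
    a0 <- if (is.null(config$alpha_fixed)) {
      min(2, max(ALPHA_MIN, alpha0 + stats::runif(1, -0.2, 0.2)))
    } else config$alpha_fixed
    runs[[r]] <- cpp_run_chain(tree$edge, tree$edge.length, ntip, x0,
                               a0, c0 * exp(stats::runif(1, -0.3, 0.3)),
                               grid, opts)
  }

  scalar_chain <- function(name) lapply(runs, function(r) r[[name]])
  root_col <- 1L # root is the first internal node in ape order
  psrf_vals <- c(
    alpha = if (is.null(config$alpha_fixed)) psrf(scalar_chain("alpha")) else NA_real_,
    c = psrf(scalar_chain("c")),
    root_state = psrf(lapply(runs, function(r) r$node[, root_col])),
    loglik = psrf(scalar_chain("loglik"))
  )
  converged <- all(psrf_vals[!is.na(psrf_vals)] < config$psrf_target)
  if (!converged)
    warning("PSRF target ", config$psrf_target, " not met (max = ",
            round(max(psrf_vals, na.rm = TRUE), 4), ")")

  maps <- vapply(runs, function(r) r$map$loglik, numeric(1))
  best <- runs[[which.max(maps)]]$map

  out <- list(
    runs = runs,
    tree = tree, tip_values = x_tip, ntip = ntip,
    alpha = unlist(scalar_chain("alpha")),
    c = unlist(scalar_chain("c")),
    loglik = unlist(scalar_chain("loglik")),
    node = do.call(rbind, lapply(runs, `[[`, "node")),
    map_estimate = best,
    psrf = psrf_vals, converged = converged,
    model_tag = if (is.null(config$alpha_fixed)) "stable" else
      if (config$alpha_fixed == 2) "bm" else "stable_fixed",
    config = config,
    input_fingerprint = fingerprint_inputs(tree, traits)
  )
  class(out) <- "posterior_draws"
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws (", x$model_tag, " model): ",
      length(x$alpha), " draws from ", length(x$runs), " runs\n", sep = "")
  cat("  alpha: median", round(stats::median(x$alpha), 3),
      " c:", signif(stats::median(x$c), 3), "\n")
  rs <- root_state_draws(x)
  cat("  root (log10): median", round(stats::median(rs), 3),
      " [", round(stats::quantile(rs, 0.025), 3), ",",
      round(stats::quantile(rs, 0.975), 3), "]\n")
  cat("  PSRF:", paste(names(x$psrf), round(x$psrf, 4), collapse = "  "),
      "\n  converged:", x$converged, "\n")
  invisible(x)
}

#' Root-state posterior draws
#'
#' @param draws a `posterior_draws` object.
#' @param node internal-node index in `ape` numbering (defaults to the root).
#' @return numeric vector of posterior draws of that node's state (log10 kg).
#' @export
root_state_draws <- function(draws, node = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  col <- if (is.null(node)) 1L else as.integer(node) - draws$ntip
  if (col < 1L || col > ncol(draws$node)) stop("node ", node, " is not internal")
  draws$node[, col]
}

#' Summarise a node's posterior on the kg scale
#'
#' Back-transforms posterior quantiles of the log10-kg state; never averages
#' on the kg scale (which would be scale-inconsistent for skewed posteriors).
#'
#' @param draws a `posterior_draws` object.
#' @param node internal-node index (default root).
#' @param level credible level for the quantile interval.
#' @return list with `median_kg`, `ci_kg` (length 2) and the log10-scale
#'   equivalents.
#' @export
root_estimate <- function(draws, node = NULL, level = 0.95) {
  rs <- root_state_draws(draws, node)
  qs <- stats::quantile(rs, c((1 - level) / 2, 0.5, 1 - (1 - level) / 2),
                        names = FALSE)
  list(median_kg = back_transform(qs[2]),
       ci_kg = back_transform(qs[c(1, 3)]),
       median_log10 = qs[2], ci_log10 = qs[c(1, 3)])
}

# deterministic fingerprint of (topology, durations, trait values) so model
# comparisons can refuse mismatched fits
fingerprint_inputs <- function(tree, traits) {
  s <- paste(ape::write.tree(tree),
             paste(traits$species, signif(traits$logmass, 12), collapse = ";"))
  # small rolling hash; stable across sessions
  sum(cumsum(as.integer(charToRaw(s))) %% 97777L * 31L) %% 2147483647L
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance and
#' `B/n` the variance of chain means. Requires at least two chains of at least
#' ten draws. Degenerate chains (zero within-chain variance) return `Inf` with
#' a warning.
#'
#' @param chains list of numeric vectors (one per run) or a matrix with one
#'   column per run.
#' @return scalar PSRF, `>= 1` up to float noise.
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 10L) stop("need at least 10 draws per chain")
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W <= 0 || !is.finite(W)) {
    warning("zero within-chain variance; PSRF undefined (returning Inf)")
    return(Inf)
  }
  means <- vapply(chains, mean, numeric(1))
  B_over_n <- stats::var(means) # = B/n in the usual notation
  sqrt(((n - 1) / n * W + B_over_n) / W)
}
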