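# Likelihoods for trait evolution on a chronogram.
#
# The augmented likelihood treats internal-node states as latent variables:
# given values at every node, branch increments are independent symmetric
# stable draws whose scale follows the stability closure branch_scale().
# The Brownian-motion marginal likelihood (node states integrated out)
# is exact via Felsenstein pruning and serves as the analytic cross-check
# at alpha = 2, where sigma^2 = 2 c^2.

#' Parameter set of the stable trait model
#'
#' @param alpha stability index in `(ALPHA_MIN, 2]`.
#' @param c dispersion per Myr^(1/alpha), `> 0`.
#' @param root_state root trait value (log10 kg).
#' @return a `stable_params` list.
#' @export
stable_params <- function(alpha, c, root_state = 0) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 2)
    stop("alpha must be in (0, 2]")
  if (!is.numeric(c) || c <= 0 || !is.finite(c))
    stop("c must be finite and positive")
  if (!is.finite(root_state)) stop("root_state must be finite")
  structure(list(alpha = alpha, c = c, root_state = root_state),
            class = "stable_params")
}

# full node-value vector (tips then internals) from tips + augmented states;
# checks completeness and that the augmented root matches params$root_state
.full_state <- function(tree, traits, node_values, params = NULL) {
  ntip <- ape::Ntip(tree)
  x_tip <- bind_traits(tree, traits)
  if (length(node_values) != tree$Nnode)
    stop("node_values must cover all ", tree$Nnode, " internal nodes; got ",
         length(node_values))
  if (anyNA(node_values)) {
    bad <- which(is.na(node_values))[1] + ntip
    stop("missing value for internal node ", bad)
  }
  if (!is.null(params) &&
      abs(node_values[1] - params$root_state) > 1e-9)
    stop("augmented root value disagrees with params$root_state")
  c(unname(x_tip), unname(node_values))
}

#' Augmented log-likelihood under the stable model
#'
#' Sum over edges of the log stable density of the increment
#' `x[child] - x[parent]` with scale `branch_scale(c, t_e, alpha)`. Internal
#' node values (`node_values`, ordered root first as in `ape`) are part of the
#' state, so this is the joint density of tips and latent nodes given the root.
#'
#' @param tree a `phylo` chronogram.
#' @param traits a `trait_table` covering the tips.
#' @param node_values numeric vector of internal-node states (root first,
#'   `ape` node order).
#' @param params a [stable_params()] object.
#' @param method `"quadrature"` (accurate reference) or `"grid"` (the
#'   interpolated density the sampler uses).
#' @return log-likelihood (scalar).
#' @export
augmented_loglik <- function(tree, traits, node_values, params,
                             method = c("quadrature", "grid")) {
  method <- match.arg(method)
  x <- .full_state(tree, traits, node_values, params)
  t_e <- tree$edge.length
  if (any(t_e <= 0))
    stop("non-positive branch duration on edge ",
         paste(tree$edge[which(t_e <= 0)[1], ], collapse = "->"),
         " (collapse degenerate edges first)")
  dx <- x[tree$edge[, 2]] - x[tree$edge[, 1]]
  if (method == "grid") {
    return(cpp_stable_loglik(tree$edge, t_e, x, ape::Ntip(tree),
                             params$alpha, params$c, stable_grid()))
  }
  sc <- branch_scale(params$c, t_e, params$alpha)
  sum(vapply(seq_along(dx),
             function(i) stable_pdf(dx[i], params$alpha, sc[i], log = TRUE),
             numeric(1)))
}

#' Brownian-motion marginal log-likelihood (pruning algorithm)
#'
#' Exact Gaussian likelihood of the tip values with internal-node states
#' integrated out, conditioned on a fixed root state. Handles polytomies.
#' Equals the `alpha = 2` augmented model marginalised over node states when
#' `sigma2 = 2 c^2`.
#'
#' @param tree a `phylo` chronogram with >= 2 tips.
#' @param traits a `trait_table`.
#' @param sigma2 Brownian rate, (log10 kg)^2 per Myr, `> 0`.
#' @param root_state fixed root value (log10 kg).
#' @return log-likelihood (scalar).
#' @export
bm_marginal_loglik <- function(tree, traits, sigma2, root_state) {
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  msg <- .bm_prune(tree, bind_traits(tree, traits), sigma2)
  msg$loglik +
    stats::dnorm(msg$mean, root_state, sqrt(sigma2 * msg$vscale), log = TRUE)
}

#' Generalised-least-squares phylogenetic mean under BM
#'
#' The pruning message that reaches the root: its mean is the GLS phylogenetic
#' mean (the maximum-likelihood root state for any `sigma2`), and
#' `sigma2 * vscale` is its sampling variance.
#'
#' @param tree a `phylo` chronogram.
#' @param traits a `trait_table`.
#' @return list with `mean` and `vscale`.
#' @export
bm_gls_root <- function(tree, traits) {
  msg <- .bm_prune(tree, bind_traits(tree, traits), 1)
  list(mean = msg$mean, vscale = msg$vscale)
}

# Felsenstein pruning with sequential merging of child messages, so polytomies
# need no special casing. Returns the root message and the accumulated
# log-likelihood of all within-tree contrasts.
.bm_prune <- function(tree, x_tip, sigma2) {
  ntip <- length(x_tip)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  xhat <- c(unname(x_tip), rep(NA_real_, tree$Nnode))
  vhat <- c(rep(0, ntip), rep(NA_real_, tree$Nnode))
  ll <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    xv <- xhat[ch]; vv <- vhat[ch] + po$edge.length[e]
    if (is.na(xhat[p])) {
      xhat[p] <- xv; vhat[p] <- vv
    } else {
      vs <- vhat[p] + vv
      if (vs <= 0) stop("degenerate zero-variance contrast at node ", p)
      ll <- ll + stats::dnorm(xhat[p] - xv, 0, sqrt(sigma2 * vs), log = TRUE)
      xhat[p] <- (xhat[p] * vv + xv * vhat[p]) / vs
      vhat[p] <- vhat[p] * vv / vs
    }
  }
  root <- ntip + 1L
  list(mean = xhat[root], vscale = vhat[root], loglik = ll)
}
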