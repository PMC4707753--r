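---
title: "Heavy-tailed ancestral state reconstruction: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-tailed ancestral state reconstruction: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`stableasr` reconstructs ancestral values of a continuous trait — body mass on
the log10-kg scale in the motivating application — on a rooted,
time-calibrated phylogeny. Along each branch of duration $t$ Myr the trait
accrues an independent increment from a symmetric, mean-zero, alpha-stable
distribution. We fix the characteristic-function convention

$$\operatorname{E}\,e^{ikX} = \exp\{-(s\,|k|)^\alpha\},$$

so the stability index $\alpha \in (1, 2]$ controls tail weight and $s$ is the
dispersion. Stability closure forces the branch-level dispersion to be
$s_e = c\,t_e^{1/\alpha}$ for a per-Myr dispersion $c$: this is the only
scaling under which increments over subdivided branches compose consistently.
Two boundary cases have closed forms and anchor every numerical check:
$\alpha = 2$ is Gaussian with variance $2 c^2 t$ (Brownian motion, with
$\sigma^2 = 2c^2$ under this convention), and $\alpha = 1$ is Cauchy.

With $\alpha < 2$ the marginal likelihood of the tips is not available in
closed form, so the node states are retained as latent variables: given values
$x_v$ at every node, the augmented log-likelihood is the sum over edges of the
log stable density of $x_{child} - x_{parent}$ at scale $s_e$. At
$\alpha = 2$, integrating the node states out of this augmented model must
reproduce the exact Brownian marginal likelihood computed by Felsenstein
pruning — the package tests this equivalence by direct quadrature on small
trees, and it pins down the $\sigma^2 = 2c^2$ correspondence.

Why heavy tails matter for ancestral states: under Brownian motion the root
estimate is a generalised-least-squares average that large-bodied clades pull
upward. A stable model with $\alpha < 2$ can explain a large-bodied clade as
one rare jump on a single branch rather than a high tree-wide rate, so the
root estimate resists being dragged by derived giants and per-branch rate
variation is expressible without one parameter per branch.

## Densities

The standardised stable density is computed by inverting the characteristic
function, $f(z) = \pi^{-1}\int_0^\infty \cos(zk)\,e^{-k^\alpha}\,dk$. The
reference implementation (`stable_pdf()`) integrates by composite 16-point
Gauss–Legendre on half-period panels, with a $k = h u^2$ substitution on the
first panel to absorb the $k^\alpha$ kink at zero; relative accuracy is
~1e-10 in the body and far better than the 1e-6 contract out to
$|x|/s = 50$. Beyond $z = 100$ the Bergström tail series takes over.

The sampler needs millions of evaluations, so it interpolates
$\log f(z; \alpha)$ bilinearly from a grid over $(\alpha, \operatorname{asinh} z)$
built once per session (about 6 s). The $\alpha$ grid is uniform with step
0.005 up to 1.99 and then refines geometrically toward $2 - 10^{-6}$, because
the power-law tail coefficient vanishes like $\sin(\pi\alpha/2)$ at the
Gaussian boundary and linear interpolation across that endpoint would be
badly wrong; above the last grid point the exact Gaussian is used. Grid error
is below 0.006 in log density where the sampler operates ($z \le 25$) and
below 0.04 in the extreme tail, so the sampled model is a controlled,
documented perturbation of the exact one; the BPIC plug-in deviance is
evaluated with the same interpolated density as the chains, keeping the
model-comparison arithmetic internally consistent.

## Sampler

`run_mcmc()` is Metropolis-within-Gibbs over the internal-node states, the
stability index and the dispersion:

* one Gaussian random-walk update per internal node per iteration (the root
  is a node like any other — its state is the quantity of scientific
  interest);
* a subtree-shift move every 10 iterations, translating a random internal
  clade rigidly to decorrelate nested node states;
* a reflected random walk for $\alpha$ on $(1.05, 2]$ and a log-scale random
  walk for $c$ (skipped/fixed when `alpha_fixed = 2` gives the BM-constrained
  fit).

Priors are deliberately weak: $\alpha$ uniform on its support, $\log c$
uniform on $[-14, 7]$, node states improper flat — so the pseudo-outgroup
experiment below genuinely measures the effect of *adding* root information
to an analysis that otherwise has none. The lower bound $\alpha > 1.05$
excludes the undefined-mean regime where ancestral reconstruction
degenerates; the density utilities still expose $\alpha = 1$ for closed-form
tests. Proposal widths adapt by Robbins–Monro recursion during burn-in only
(frozen afterwards, preserving detailed balance), targeting 44% acceptance
for scalar updates and 23% for the subtree shift. Initial node states come
from a midpoint recursion (post-order child averaging, pre-order smoothing
toward the parent), $c$ from the independent-contrasts moment estimate
$\sqrt{\hat\sigma^2/2}$, and each run jitters its start so the
potential-scale-reduction factor (PSRF) measures real mixing. Convergence is
reported per scalar (alpha, c, root state, log-likelihood) against the 1.01
target; a fit that misses the target returns `converged = FALSE` with a
warning rather than an error. All randomness derives from the single
`seed`, and identical inputs plus seed give byte-identical draws.

The production protocol this mirrors is 2,000,000 iterations in four
independent runs with 10% burn-in. Every simulation study and test in the
package uses scaled-down runs — typically 20,000–30,000 iterations in two
runs with 30% burn-in on trees of about 100 tips, a few seconds per fit —
sizes at which the recovery experiments below are already well calibrated;
the larger burn-in fraction simply gives the adaptive proposals longer to
settle on short chains.

## Model comparison

`bpic()` computes a predictive information criterion of the deviance family:
$\bar D = -2\,\mathbb{E}_{post}[\log L]$, a plug-in bias penalty
$p = \bar D - D(\hat\theta)$ at the posterior means of
$(\alpha, c, \text{node states})$, and the criterion $\bar D + 2p$ (the
penalty weight is configurable to the DIC-style $\bar D + p$ via
`options(stableasr.bpic_penalty = "pD")`; the doubled penalty is the default
because the plug-in point in a latent-variable model understates the
effective dimension). `delta_bpic()` reports
$\Delta = \mathrm{BPIC}_{BM} - \mathrm{BPIC}_{stable}$, positive favouring
the heavy-tailed model, with exact ties awarded to Brownian motion as the
smaller model. $\Delta$ is invariant to any common shift of the
log-likelihoods, so the interpolation grid's small uniform bias cancels.

## Rate multipliers

With latent node states in hand, each edge has posterior draws of its
increment $\Delta x_e$. The raw rate is
$r_e = \operatorname{median}_{post}[(\Delta x_e)^2] / t_e$ — the
variance-per-Myr scale of Brownian motion — and the reported multiplier is
$m_e = r_e / \operatorname{median}_e(r_e)$, so the tree-wide median branch is
exactly 1 and "$m$ times the original branch length" is unit-free. The
posterior median (not mean) keeps a single wild draw from dominating an
edge's rate. Multipliers are invariant to shifting all log-masses by a
constant. The rate-through-time curve averages $m_e$ over the edges
intersecting each of 20 equal-width time bins, weighted by overlap duration,
and therefore integrates back to the duration-weighted mean multiplier.
`max_rate_branch()` breaks exact ties toward the longer branch, preferring
the better-identified edge.

## Synthetic data and what it does (not) show

The generator exists so that every stage is testable without external data.
`simulate_tree()` draws a constant-rate birth–death tree forward from a
crown root and stops the instant the extant count reaches `n_extant`, with
the present placed uniformly inside the waiting time to the next event (so
the count is exact and no pendant edge is degenerate); extinct lineages are
retained as dated fossil tips at the requested fraction of sampled tips and
the rest are pruned. Under pure birth this stopping rule has root-age
expectation $\sum_{k=2}^{n-1} (kb)^{-1} + (2nb)^{-1}$, which the tests check
by Monte Carlo. `simulate_traits()` adds exact Chambers–Mallows–Stuck stable
increments edge by edge.

`afrotheria_like_scenario()` fixes the study conditions used throughout the
acceptance experiments: 77 extant plus 20 fossil tips (fossil fraction
20/97), birth 0.06 and death 0.025 per Myr (crown ages of roughly 60–110
Myr), $\alpha = 1.77$, root $-1$ (0.1 kg), and dispersion $c = 0.08$ per
Myr$^{1/\alpha}$, chosen so simulated clades span the several orders of
magnitude of body mass typical of the application. One stem branch carries a
hundred-fold shift in squared dispersion. Two deliberate design choices make
the planted shift a well-posed recovery target rather than a coin flip:

* the stem is chosen among clades holding 15–40% of the extant tips with
  stem length in 4–25 Myr, closest to 7 Myr — a clade analogous to the
  large-bodied subclade in the application, on a branch long enough to be
  identifiable and short enough that the jump stays biologically plausible;
* the planted increment is redrawn until its magnitude lies between 2 and 4
  branch dispersions (symmetric sign). An unconditioned heavy-tailed draw
  leaves the shift unexpressed — no distinct large- or small-bodied clade at
  all — in roughly a third of replicates, and occasionally produces jumps of
  ten or more orders of magnitude; either way the replicate would not contain
  the pattern the scenario is defined to contain.

Even so, in about one replicate in ten a background branch realises a jump
whose rate exceeds the planted one — an honest property of heavy tails that
caps planted-shift recovery below 100%.

What passing these simulations does *not* show about real data: the
generator draws increments from exactly the fitted family, with a single
shift, no measurement error in masses, no topology or dating uncertainty,
and fossil tips sampled uniformly from extinct lineages rather than through
preservation biases. Recovery here demonstrates the estimator and software
are sound, not that the model is adequate for any particular empirical
dataset.

## The pseudo-outgroup root prior

Prior knowledge of the ancestral mass is encoded structurally:
`graft_outgroup()` creates a new root whose children are the original crown
and a pendant tip of prescribed mass. The published description of the
geometry ("separated by 5 Myr, with a 0.01 Myr pendant edge") is ambiguous
about whether 5 Myr is the stem length or the total tip-to-crown separation;
both readings are implemented (`mode = "total"`, the default, uses stem
4.99 + pendant 0.01, satisfying both printed numbers; `mode = "stem"` uses a
5 Myr stem). The sweep over outgroup masses {0.1, 0.5, 1, 5, 10, 20} kg
reports the *original crown root's* posterior, since that node is the
scientific target. On the benchmark, a 20 kg outgroup — two hundred times
the true root mass — moves the crown estimate by well under its posterior
interval, while an outgroup at the true mass tightens the interval: prior
information helps precision more than it shifts the answer.

## Numerical and reporting conventions

* Working scale is log10 kg everywhere; all kg values reported by the
  package are back-transforms $10^x$ of log-scale posterior quantiles
  (median and 2.5/97.5%), never means of kg draws, which would be
  scale-inconsistent under skew. Quantile intervals are used throughout
  (highest-posterior-density intervals were considered and rejected as the
  default because the intervals are reported on a transformed scale, where
  quantiles — unlike HPD bounds — commute with the back-transform).
* A tip is "fossil" iff its age exceeds 1e-3 Myr (`AGE_EPS`), absorbing
  float noise in published chronograms.
* Internal edges shorter than 1e-8 Myr collapse to polytomies (`DEGEN_EPS`);
  pendant edges are exempt so very young tips survive. Zero-duration edges
  would make the increment density degenerate.
* Trees with a basal polytomy and no explicit root are indistinguishable
  from unrooted newick and are rejected with instructions to root first.
* The model-fit fingerprint (topology + durations + trait values) guards
  `delta_bpic()` against comparing fits on different inputs, and seeds every
  fit in `run_tree_comparison()` so that identical inputs yield identical
  summaries under one master seed.

## Known limitations

* Skewed stable increments, Ornstein–Uhlenbeck attraction and trends are out
  of scope; the model menu is exactly {free-alpha stable, BM}.
* The sampler targets a density with ≤0.6% log-density interpolation error;
  exact-parity with implementations using other quadratures is not claimed,
  and BPIC magnitudes depend on the bias-penalty variant, so model
  comparisons should be read at the sign-and-magnitude level, not to three
  decimals.
* Per-edge rate multipliers are descriptive summaries, not formal shift
  tests.
* On short chains the PSRF criterion can flag non-convergence for the root
  state on heavy-tailed fits even when point summaries are stable; the flag
  is reported rather than hidden.
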