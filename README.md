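# stableasr

Bayesian ancestral state reconstruction of continuous traits on
time-calibrated phylogenies under a **symmetric alpha-stable model of trait
increments**, with Brownian motion as the `alpha = 2` special case.

## The problem

Reconstructing an ancestral body mass from extant species alone is fragile:
under Brownian motion (BM) the root estimate is a phylogenetically weighted
average that large-bodied descendant clades pull upward, and adding or
removing fossil tips can change both the estimate and its uncertainty. A
heavy-tailed increment model offers an alternative: if log-mass changes along
a branch of duration $t$ follow a symmetric, mean-zero stable law with index
$\alpha \in (1, 2]$ and branch dispersion $c\,t^{1/\alpha}$, then a
large-bodied clade can be explained by one rare jump on a single branch
instead of a high tree-wide rate. The package is aimed at phylogenetic
comparative analyses of this kind — its motivating case is afrotherian
mammals (tenrecs to elephants, six orders of magnitude of body mass, a rich
fossil record) — and provides:

* `phylo` I/O on chronograms with fossil tips: `read_time_tree()`,
  `prune_fossil_tips()`, `graft_outgroup()` (a dated pseudo-outgroup tip as a
  structural root prior), `read_traits()` (masses in kg, log10 working scale);
* exact and interpolated stable densities (`stable_pdf()`), augmented and BM
  marginal likelihoods (`augmented_loglik()`, `bm_marginal_loglik()`);
* a compiled Metropolis-within-Gibbs sampler over node states, `alpha` and
  `c` (`run_mcmc()`), with Gelman–Rubin PSRF convergence reporting;
* BPIC model comparison against the BM-constrained fit (`bpic()`,
  `delta_bpic()`);
* per-branch rate multipliers relative to the input chronogram and
  rate-through-time curves (`branch_rate_multipliers()`, `max_rate_branch()`);
* orchestration of multi-tree comparisons, fossil-inclusion contrasts and
  outgroup-mass sweeps (`run_tree_comparison()`, `fossil_contrast()`,
  `outgroup_sensitivity()`);
* a birth–death + stable-increment simulator with planted rate shifts
  (`simulate_tree()`, `simulate_traits()`, `afrotheria_like_scenario()`).

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 1
simulates the benchmark: a 97-tip chronogram (77 extant + 20 fossil tips,
root age ~75 Myr) with log-mass evolving at `alpha = 1.77` from a 0.1 kg
root and a planted hundred-fold rate shift on the stem of a 31-tip clade.
Steps 2–4 fit and summarise:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit.R
Rscript analysis/03_rates.R
Rscript analysis/04_outgroup_sweep.R
```

Step 2 prints the fossil-inclusion contrast (root medians with 95% quantile
intervals, back-transformed to kg, and the BPIC difference, positive
favouring the stable model):

```
total_evidence  stable 0.30 kg (0.09-0.97)  BM 0.13 kg (0.02-0.92)  dBPIC 108.0 -> stable
extant_only     stable 0.37 kg (0.04-4.14)  BM 0.02 kg (0.00-0.40)  dBPIC 85.3 -> stable
alpha (total evidence): 1.74 (1.45-1.93)
fossil contrast: median ratio 1.21, CI-width ratio 2.02, max-rate clade agrees: TRUE
```

Read: the heavy-tailed model is strongly preferred on both trees; its root
interval covers the true 0.1 kg on both; removing the 20 fossil tips moves
the point estimate only slightly (ratio 1.21) but doubles the interval width
— fossils buy precision, not a different answer. Step 3 identifies the
planted stem as the fastest branch:

```
total_evidence  max multiplier 1351.8x on edge 130->131 (31 descendant tips) - the planted stem
```

and step 4 shows the root prior barely matters: grafting a 20 kg
pseudo-outgroup (200x the true root mass) 5 Myr from the crown leaves the
crown estimate at 0.41 kg (0.12–3.57), inside the no-outgroup interval,
while an outgroup at the true 0.1 kg tightens the interval from
(0.10–1.02) to (0.07–0.43).

On your own data: `read_time_tree("tree.nwk")` + `read_traits("masses.csv")`
(columns `species,mass_kg`), then `run_mcmc()` with the default
`chain_config()` (2,000,000 iterations, 4 runs, 10% burn-in, PSRF target
1.01) and the same summary functions.

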