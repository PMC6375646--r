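---
title: "Mapping operator sequence to binding energy with Sort-Seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping operator sequence to binding energy with Sort-Seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A transcription-factor binding site (an *operator*) exerts its regulatory
effect through its binding energy. In a simple-repression promoter a
repressor bound over the RNAP site shuts transcription off, and a
statistical-mechanical treatment of the competition between RNAP, the
repressor, and the ~4.6 million nonspecific sites of the *E. coli*
genome gives the probability that RNAP occupies the promoter:

$$p_\mathrm{bound} = \frac{\tfrac{P}{N_{NS}} e^{-\beta\Delta\varepsilon_P}}
{1 + \tfrac{P}{N_{NS}} e^{-\beta\Delta\varepsilon_P}
   + \tfrac{2R}{N_{NS}} e^{-\beta\Delta\varepsilon_R}},$$

with all energies in units of $k_BT$ ($\beta \equiv 1$ throughout the
package; `kbt_to_kcal_per_mol()` converts, about 0.62 kcal/mol at 37 °C).
The factor 2 on the repressor copy number $R$ counts the two DNA-binding
heads of a LacI tetramer and is exposed as the `heads` parameter so
dimeric repressors can reuse the model. Expression is assumed
proportional to $p_\mathrm{bound}$, which holds in the weak-promoter
regime ($P \lesssim 1000$ for a lacUV5-like promoter); a test verifies
that the occupancy ratio and the closed-form fold-change

$$\mathrm{fold\text{-}change} =
\frac{1}{1 + \tfrac{2R}{N_{NS}} e^{-\beta\Delta\varepsilon_R}}$$

agree to within 5% in that regime.

The sequence dependence of $\Delta\varepsilon_R$ is modeled by an
**energy matrix**: an $L \times 4$ table of additive per-base
contributions. A linear energy model is only identified up to
per-position additive shifts and an overall scale, so matrices carry a
*gauge* (`reference`: wild-type entries pinned at 0; `position_mean`:
rows centered) and a *units* flag. Absolute energies come from the
decomposition
$\Delta\varepsilon_R = \alpha\,\varepsilon_\mathrm{mat} + \Delta\varepsilon_{wt}$,
where $\varepsilon_\mathrm{mat}$ is the arbitrary-unit matrix score,
$\alpha$ the scaling factor, and $\Delta\varepsilon_{wt}$ the measured
wild-type binding energy.

## What the generator emulates

`make_ground_truth_matrix()`, `mutagenize()` and `simulate_sorting()`
produce synthetic Sort-Seq experiments with the statistical structure
the inference assumes:

* a 21-bp operator mutagenized at 10% per base, uniformly over the three
  alternative bases (the average variant carries about 2 substitutions);
* additive binding energies; ground-truth matrices penalize most
  mutations (about 10% of entries are beneficial, as seen for strong
  operators), with a default mean single-mutant penalty of 2 kBT;
* expression proportional to $p_\mathrm{bound}$ times multiplicative
  log-normal cell-to-cell noise. The noise CV defaults to 0.3 — a
  typical flow-cytometry spread; the real assay's noise is not
  quantified, so tests sweep it;
* four sorting gates, each covering 15% of the expression histogram,
  evenly spaced from the bottom to the top of the distribution, with
  cells between gates discarded as in a FACS experiment.

The generator does not model PCR or transformation bottlenecks,
regrowth between sorting and sequencing, sequencing error, or
epistatic (non-additive) energy contributions. Passing recovery tests
on these simulations therefore demonstrates the estimators' correctness
under the model's own assumptions, not robustness to every artifact of
a wet experiment.

## Matrix inference

`mcmc_infer_matrix()` samples the free matrix cells (everything except
the reference sequence's entries, which are pinned at 0) with
Metropolis–Hastings. A proposal perturbs all free cells with
independent Gaussians; the acceptance probability is
$\min(1, 2^{N\Delta I})$ where $N$ is the total read count and $I$ the
mutual information between matrix scores and expression bins. The MI
estimator (`mutual_information()`) discretizes scores into equal-count
rank bins (default $\min(1000, N/50)$), which makes it invariant under
any strictly monotone transform of the scores — precisely the property
that lets an arbitrary-unit model be fit at all. Ties are broken by
record order after a seeded shuffle, so chains are bit-for-bit
reproducible. The public estimator subtracts a clamped Miller–Madow
bias term so that information-free data score near zero even with many
bins; the sampler itself uses the raw plug-in value, since acceptance
depends only on differences, for which the bias is essentially
constant.

Numerical choices:

* the chain starts at a count-weighted least-squares regression of bin
  index on one-hot-encoded sequence, which lands it near the
  informative region and makes short chains practical;
* the proposal step adapts toward a 20–40% acceptance rate during
  burn-in and is then frozen; defaults are 30000 recorded iterations
  after 10000 burn-in, the standard protocol, but the package's test
  suite uses 1000–2000 recorded iterations on $10^4$-variant
  simulations, where recovery already exceeds $r = 0.95$;
* the sign and scale of the matrix are diffeomorphic modes (invisible
  to rank-based MI), so the posterior mean is post-hoc oriented so that
  mutations penalize binding on average and normalized so the mean
  non-reference entry is 1 arbitrary unit;
* positions where the library shows fewer than two bases are flagged
  and their columns zeroed rather than letting them random-walk.

Replicate matrices come from `split_replicates()`, which partitions the
records into three equal groups, mirroring the replicate logic of the
original experimental analysis.

## Scaling to absolute units

Three routes are provided:

1. `infer_scaling_factor()` — single-parameter MCMC over $\alpha$
   feeding $p_\mathrm{bound}$, with the RNAP contribution fixed as an
   effective weak-promoter term. The rank-based MI estimator cannot see
   $\alpha$ at all (for fixed $\alpha$, $p_\mathrm{bound}$ is a
   monotone transform of the score), and a free-noise probit channel
   leaves a near-flat plateau at small $\alpha$ because standardized
   nearly-linear predictions are affine-invariant. The estimator
   therefore pins the channel noise width to the assay's fluorescence
   noise (the `noise_cv` argument, default 0.3, treated as a known
   property of the measurement): an ordered-probit likelihood on
   log-occupancy with free gate cutpoints, converted to bits per
   observation (`mutual_information_channel()`). With the scale
   anchored, $\alpha$ is sharply identified from both sides; synthetic
   recovery tests require agreement within 20%, and a flat-posterior
   diagnostic flags datasets whose bins carry no energy signal.
2. `scale_by_least_squares()` — ordinary least squares of known
   binding energies on matrix scores; exact on noiseless anchors and
   the preferred route when measured energies exist.
3. `scale_by_theoretical_penalty()` — matches the mean single-mutant
   entry to a theoretical average penalty, for architectures without a
   trusted thermodynamic model.

## Downstream analyses

* `base_probabilities()` maps energies to per-position Boltzmann
  probabilities $p_N = e^{-\varepsilon_N}/\sum_M e^{-\varepsilon_M}$,
  which are gauge-invariant; logos use the Schneider information
  content $2 + \sum_N p_N \log_2 p_N$ without small-sample correction
  (the probabilities come from a model, not from counted sites).
* `base_preference_test()` runs a Welch ANOVA across the four bases'
  replicate probabilities (gate $p < 0.01$) followed by Games–Howell
  pairwise comparisons; a base is declared preferred only if it beats
  every other base. The Games–Howell step is implemented here (Welch
  $t$, Welch–Satterthwaite df, studentized-range $p$ via `ptukey`)
  because no installed package provides it; exactly-degenerate
  replicate sets are treated as maximally significant.
* `fit_binding_energy()` fits the fold-change model to repressor
  titrations by one-parameter least squares (golden-section/parabolic
  search, robust for zero-residual data where derivative-based
  optimizers stall). The 95% CI is the linearized asymptotic interval
  — the original analysis does not state its regression machinery, so
  this conventional choice is documented rather than matched. A single
  data point is inverted algebraically.
* `induction_phenotypes()` returns leakiness and saturation as the
  analytic $c \to 0$ and $c \to \infty$ limits of the allosteric
  induction model (closed forms of the bracketed active fraction), and
  the EC50 by bracketed root-finding on log-concentration to a
  midpoint tolerance of $10^{-8}$ — verified against the midpoint
  definition rather than any closed form. LacI/IPTG defaults:
  $K_A = 139\,\mu M$, $K_I = 0.53\,\mu M$,
  $\Delta\varepsilon_{AI} = 4.5\,k_BT$, $n = 2$.
* `design_induction()` enumerates single (optionally double) mutants of
  the reference, predicts their energies, computes phenotypes and ranks
  by Euclidean distance to the requested targets (EC50 compared on a
  log scale, since it spans decades).
* `load_o1_mutant_energies()` ships the 26 measured O1 operator
  mutants (predicted and titration-measured energies) as a checksummed
  text fixture; mutation counts are recomputed from the sequences and
  validated, never trusted from labels.

## Worked example

```{r example}
library(sortseqthermo)

sim <- run_simulate(out_dir = "sim", n_variants = 1e4, seed = 1)
inf <- run_infer(sim$dataset_path, "inference", eps_wt = -15.3,
                 cfg = mcmc_config(n_iterations = 2000, n_burnin = 1000))
compare_matrices(inf$mean, sim$truth)

kbt <- to_kbt(inf$mean, alpha = inf$scaling$alpha, offset_wt = -15.3)
design_induction(kbt, targets = list(leakiness = 0.05,
                                     dynamic_range = 0.6))
```

## Known limitations

* Single-point (additive) models only: no pairwise or higher-order
  terms, and no insertions or deletions — matrices index aligned
  positions on one strand.
* The scaling-factor MCMC assumes the simple-repression thermodynamic
  model and a known assay noise scale; for architectures where neither
  holds, use the least-squares or theoretical-penalty routes.
* Joint inference of the RNAP-site matrix (which the original
  experimental design co-mutates) is out of scope; the RNAP term enters
  as a fixed effective parameter.
* Allosteric constants ($K_A$, $K_I$, $\Delta\varepsilon_{AI}$) are
  inputs, not fitted from Sort-Seq data, where they are degenerate.
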