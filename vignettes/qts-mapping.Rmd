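---
title: "Two-step mapping of additive, epistatic and gene-environment QTS effects in RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mapping of additive, epistatic and gene-environment QTS effects in RIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtsmap)
```

## The model

qtsmap maps quantitative trait SNPs (QTS) in recombinant inbred line (RIL)
populations phenotyped in several environments. The phenotype of line $k$
in environment $h$ is modeled as

$$
y_{hk} = \mu + \sum_i x_{ik} a_i + \sum_{i<j} x_{ik}x_{jk}\,aa_{ij}
       + e_h + \sum_i x_{ik}\,ae_{hi} + \sum_{i<j} x_{ik}x_{jk}\,aae_{hij}
       + \varepsilon_{hk},
$$

where $x_{ik} \in \{+1, -1\}$ codes the homozygote of the high- and
low-frequency allele (0 for a heterozygote, which fully inbred RILs do not
carry), $a_i$ is the additive effect of SNP $i$, $aa_{ij}$ the
additive-by-additive epistatic effect of a SNP pair, $e_h$ the environment
main effect, $ae_{hi}$ and $aae_{hij}$ the environment-specific deviations
of the genetic effects, and $\varepsilon_{hk}$ an i.i.d. normal residual.
All effects are in trait units. Environment interactions follow a
sum-to-zero convention, $\sum_h ae_{hi} = 0$ and $\sum_h aae_{hij} = 0$,
which makes $a_i$ the across-environment average effect.

Dominance is not modeled (a biparental RIL population has none), and no
kinship/polygenic random effect is included (a single biparental cross has
no population structure beyond what the cofactors capture).

## The two-step strategy

Testing every SNP and every SNP pair in the full mixed model is
computationally and statistically hopeless on dense marker data, so mapping
proceeds in two steps.

**Step 1 — GMDR screen** (`gmdr_screen()`). Every 1-, 2- (optionally
3-) locus model is scored by generalized multifactor dimensionality
reduction: lines are binned by their joint genotype, a cell is labeled HIGH
or LOW by the sign of its summed score residuals
$s_{hk} = y_{hk} - \hat\mu - \hat e_h$ (pooled over environments per line),
and the model is scored by 10-fold cross-validated testing balanced
accuracy, with empty or exactly-zero cells left unclassified. Models are
ranked by (accuracy, cross-validation consistency, marker order). Three
refinements matter on a dense map:

* *Parsimony.* A multi-locus model must beat its best sub-model's accuracy,
  and this filter is applied to the full enumeration before ranking.
  Without it, "passenger" pairs — a strong marker plus an irrelevant one,
  which inherit the strong marker's accuracy — occupy the entire top of the
  2-locus ranking.
* *Conditional screening.* Orders above 1 are screened on scores
  residualized for the retained single-locus candidates (`adjust = TRUE`),
  so the pair search targets interaction signal instead of re-finding
  additive loci through every linked shadow.
* *Locus clustering.* Markers within `clump_cM` (default 20 cM, genotype
  correlation about 0.45 at RIL linkage) count as one locus when models are
  deduplicated, and each retained locus is expanded into a candidate
  cluster of all map markers within `expand_cM` (default 15 cM). The scan
  then tests the true marker itself rather than whichever tightly linked
  neighbour happened to win the cross-validation lottery.

The screen returns the candidate clusters plus the cluster *pairs*
nominated by retained multi-locus models; only nominated pairs enter the
two-dimensional scan.

**Step 2a — scan with permutation thresholds** (`qts_scan()`). Each
candidate marker is tested by an F statistic for the locus's effects
jointly across environments: the model has per-environment intercepts
(absorbing $\mu$ and $e_h$), environment-specific slopes for the tested
term, and the other candidate clusters' representatives as background
cofactors — both their additive environment-specific slopes and the
nominated epistatic interactions. Cofactors within `exclusion_cM` (default
30 cM) of the tested term are excluded, as in composite interval mapping:
a tightly linked marker is a statistical proxy of the tested locus and
conditioning on it would erase the signal. With a single environment the
statistic reduces exactly to the classical cofactor-adjusted partial F.
Two-dimensional terms test the interaction columns ($aa$ + $aae$) of a
nominated cluster pair, after centering the pair on the local epistatic
peak within a `refine_cM` grid; the constituent markers' additive slopes
stay in both models so the test is specific to epistasis.

Experiment-wise thresholds at $\alpha = 0.05$ are computed separately for
the 1D and 2D families by permuting whole line phenotype profiles (a
line's values travel together, preserving the environment structure under
the null), recording each family's maximum F per permutation — the 2D
local refinement is repeated inside every permutation so the threshold
accounts for that selection — and taking the
$\lceil (B+1)(1-\alpha) \rceil$-th largest of the $B$ maxima.

**Step 2b — full-model MCMC** (`build_full_model()`, `fit_qts_mcmc()`).
All significant terms (clumped to one representative per locus) are
assembled into one hierarchical model; markers appearing only inside a
significant pair also receive additive terms, keeping the model
hierarchical. A Gibbs sampler draws from the posterior: $\mu$, $a$, $aa$
are fixed effects with vague normal priors ($10^6 \times$ the phenotype
variance); $e_h$, $ae$, $aae$ are random with one inverse-gamma variance
component per family ($\mathrm{IG}(0.01, 0.01)$), as is the residual.
Interaction families are sampled on sum-to-zero contrasts: the pooled main
effect column and its per-environment columns are exactly collinear, so
sampling all of them mixes arbitrarily badly, while the contrast basis is
full rank and the derived per-environment effects satisfy the sum-to-zero
convention exactly. Each effect is estimated by its posterior mean and
tested by $t = \text{mean}/\text{SD}$ with degrees of freedom set to the
chain's effective sample size minus one (Geyer initial-positive-sequence
estimate) — a conservative choice given that the draws are autocorrelated;
$-\log_{10} P$ is reported alongside.

## Heritability accounting

`partition_heritability()` attributes to every effect the empirical
variance of its fitted contribution over the realized design (all lines
$\times$ environments), divided by the total modeled variance — the sum of
all genetic component variances plus $\sigma^2_\varepsilon$ — times 100.
Environment main effects are excluded from both numerator and total, so
the reported heritabilities describe the genetic architecture rather than
the trial layout. The total is defined as the sum of the components, so
the accounting identity holds to machine precision; note that component
covariances (which are small for near-balanced RIL designs) are thereby
ignored rather than attributed.

The simulator solves $\sigma^2_\varepsilon$ from the same accounting:
given a target heritability $h^2$,
$\sigma^2_\varepsilon = V_G (1 - h^2)/h^2$ with $V_G$ the summed component
variances on the realized genotypes, so the realized heritability of each
replicate matches the target up to Monte Carlo error.

## The simulator and the benchmark scenarios

`sim_ril_genotypes()` generates fully inbred lines along a genetic map as
a first-order Markov chain per chromosome: the first marker is $\pm 1$
with probability 1/2 and each subsequent marker switches sign with
probability $R = 2r/(1+2r)$, the expected RIL recombination fraction at
fixation under repeated selfing, with $r$ the Haldane single-meiosis
fraction for the inter-marker distance. This is exact for all pairwise
expectations under no interference, without simulating whole-gamete
crossovers.

The benchmark layout used throughout the package's replicated studies is
3 chromosomes $\times$ 175 markers at 1 cM spacing (counts from the study
design; the map names marker counts, not lengths, so the 1 cM default is a
documented choice), two environments with fixed main effects $e = (1, -1)$
(fixed rather than random makes the variance accounting transparent; only
the spread matters to the pipeline, which absorbs $e_h$ in per-environment
intercepts), and two effect configurations (`qts_truth_reference()`):

* **large**: $a = (-3.24, -2.65, -1.77)$ at chr1:28, chr2:100, chr3:93
  with $ae_1 = (2.65, 4.05, 3.24)$ (and $ae_2 = -ae_1$), one epistatic
  pair chr2:44 $\times$ chr3:63 with $aa = 3.86$, $aae_1 = 4.47$;
* **small**: $a = (-0.79, -0.67, -0.40)$, $ae_1 = (0.63, 0.39, 0.32)$,
  $aa = 0.39$, $aae_1 = 0.17$ for the same positions.

Population sizes 100–200 and target heritabilities 0.5 and 0.7 span the
regimes of interest. `run_power_study()` simulates replicates (per-replicate
seeds are `seed + replicate`), runs the full pipeline on each, and counts a
true QTS as detected when a significant term lies within
`detect_window_cM` (default 2 cM) of it; at 1 cM marker spacing adjacent
markers differ in a handful of lines, so an exact-marker criterion would
measure a coin flip between statistically interchangeable neighbours.
Effect estimates are averaged over detecting replicates only, matching how
conditional power tables report estimates. The default study size in the
package's own acceptance checks is 50 replicates with a once-per-scenario
200-permutation threshold — chosen as the smallest study for which the
Monte Carlo error of a power estimate (about 5 percentage points at 87%
power) is clearly below the effects being measured.

What the generator does *not* emulate: missing genotypes or phenotypes,
residual heterozygosity, segregation distortion, non-normal residuals,
crossover interference, and real-data LD structure (the map is uniform).
Passing power studies therefore demonstrate the statistical machinery
under the stated generative model, not robustness to those features.

## Numerical choices

* Allele-frequency ties in the $\pm 1$ coding break lexicographically, so
  coding is deterministic across runs.
* GMDR cells whose training scores sum to exactly zero (tolerance
  $10^{-12}$) are unclassified and skipped in accuracy; folds with no
  classifiable test line are dropped from the mean with a warning.
* Cross-validation consistency counts the folds in which a combination
  attains the fold's best testing accuracy, ties to the lexicographically
  earlier combination.
* Rank-deficient scan terms (zero-variance or collinear markers) are
  skipped with F recorded missing; ranks come from pivoted QR.
* The 3-locus search keeps a bounded heap (default 5000) instead of the
  full enumeration, and the screen refuses outright when the requested
  search exceeds its evaluation budget (default $5 \times 10^7$).
* Gibbs chains default to 12,000 iterations, 2,000 burn-in, thinning 2;
  summaries are flagged when any genetic effect's effective sample size
  falls below 100.

## Known limitations

* Nominating a *weak* purely epistatic pair from $\sim 10^5$ candidate
  pairs by cross-validated accuracy is close to a lottery: the CV accuracy
  of a pair with $aa$ around 0.4 trait units (against residual SD around
  1.4) sits near the upper tail of the null accuracy distribution of the
  full pair search. Detection rates for such pairs are accordingly far
  below those of equally sized additive effects, and effect estimates
  conditioned on detection carry upward selection bias. Reported
  conditional estimates should be read with their `n_detected`.
* Power for weak additive QTS depends mostly on screen retention and the
  permutation threshold, and is therefore fairly insensitive to moderate
  changes in heritability; exact published-style power values for a given
  heritability convention can differ by several points from what any
  family-wise-corrected reimplementation produces.
* The scan's F test treats environment-specific slopes as fixed within
  each term's model and relies on the permutation threshold (not the
  parametric F distribution) for its significance decisions; the
  parametric p-values in the output are descriptive.

## A small worked example

```{r example, eval = FALSE}
library(qtsmap)

sc <- qts_scenario(n = 150, h2 = 0.7, truth = "large", reps = 1, seed = 42)
dat <- sim_scenario_replicate(sc, 43)

cand <- gmdr_screen(dat$G, dat$pheno, seed = 43)
scan <- qts_scan(dat$G, dat$pheno, cand, B = 200, seed = 43)
glance(scan)
autoplot(scan)

fit <- fit_qts_mcmc(dat$G, dat$pheno, build_full_model(scan), seed = 43)
summarize_architecture(fit, dat$G, trait = "simulated")
```
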