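---
title: "Modeling global patterns of epigenetic variation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling global patterns of epigenetic variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `globpat`, the
assumptions each stage makes, the defaults and why they were chosen, what
the synthetic-data generator does and does not emulate, and the numerical
and design decisions a maintainer would want written down.

## The stacked model

The core object is a hidden Markov model over non-overlapping 200 bp
genomic bins in which **every (individual, mark) ChIP-seq data set is a
separate observation dimension**. Given the hidden state ("global
pattern") of a bin, the D binary presence calls are conditionally
independent Bernoulli draws, so state *s* is fully described by its
emission vector `e[s, ]` — the probability of a presence call in each
track. Stacking differs from the per-individual (concatenated) convention
in that it yields **one** genome annotation shared by the whole cohort,
and in that the emission parameters, sliced per mark, form a per-individual
quantitative phenotype attached to each state. All downstream association
tests operate on those phenotypes; they never re-fit the model per subset
of individuals, because emissions are global parameters, not per-sample
estimates.

Assumptions worth keeping in mind:

* *Conditional independence across tracks given the state.* Violated in
  real data whenever two individuals share batch structure not captured by
  the state; the covariate-correction stage exists to soak up exactly that
  kind of shared technical variation before binarization.
* *A single state path for all individuals.* Genuinely individual-specific
  chromatin (e.g. a polymorphic enhancer) is representable only as a state
  whose emission vector is high in a subset of individuals — which is the
  point of the method, not a deficiency.
* *First-order Markov dependence along the genome*, chromosomes independent
  with a shared initial distribution.

## Fitting: Baum-Welch, initialization, convergence

Training is standard EM with a scaled forward-backward pass (per-position
normalization; the scaling constants reconstruct the log-likelihood
exactly). The inner loop is compiled (`src/fb.cpp`); the EM driver,
initialization and M-step are plain R. Emissions are clamped to
`[1e-6, 1 - 1e-6]` after every M-step so no observation can acquire zero
likelihood; initial and transition distributions are renormalized every
iteration and rows that receive no expected mass fall back to uniform.

**Initialization.** The default seeds the emission rows from k-means
centers of the observed call vectors, mapped affinely into `[0.2, 0.8]`
(`init = "kmeans"`); initial and transition distributions start uniform
with Dirichlet jitter. A fully random alternative (`init = "random"`,
emissions uniform on `[0.2, 0.8]`) is retained. The k-means default exists
because the likelihood surface of well-separated multivariate-Bernoulli
HMMs has wide, poor basins in which two true states merge while a third is
duplicated: on an 8-state, 20-track benchmark with emissions in
{0.05, 0.9}, uniform-random starts reached the dominant basin in roughly a
third of attempts, while k-means starts did so in the large majority; with
`restarts = 3` (each restart re-seeded) the best-of-restarts fit was
correct in every seeded trial the test suite runs. Restart selection is by
final log-likelihood, whose gap between basins is orders of magnitude
larger than within-basin variation.

**Convergence.** `tol` is the relative change in log-likelihood between
iterations (default `1e-4`, `max_iter = 200`). For parameter-recovery work
we recommend `1e-6`: with |logLik| in the 10⁵–10⁶ range a relative `1e-4`
can stop while parameters are still moving. The per-iteration trace is
returned so monotonicity is checkable; the test suite asserts it never
decreases beyond 1e-8 relative.

**Decoding** is per-bin posterior argmax ("most likely state"), ties broken
deterministically toward the smaller state id. A consequence surfaced by
the subset-decoding diagnostic: when a track subset renders two states
exactly indistinguishable, their posterior ties and *all* their mass
collapses onto the smaller id rather than splitting — the confusion matrix
shows a collapsed pair, not a smeared one.

## Preprocessing

**Quantile normalization** maps every track in a group (by default, all
tracks of one mark — marks differ grossly in genome-wide prevalence) onto
the cross-track mean of order statistics. Tied values receive the mean of
their tied quantile targets, so an all-tied track maps to the grand mean of
the targets. Two consequences are deliberate and documented rather than
bugs: with ties, (i) the *sorted* multiset of a normalized column is no
longer exactly the common target (tied entries were averaged), so exact
sorted-vector equality and idempotence hold verbatim only for tie-free
data; and (ii) tracks whose presence rate differs get their marginal
present bins mapped through "mixing zone" order statistics averaged across
tracks, which costs a few percent of detection at the binarization
threshold. Ranks within a track are always preserved exactly.

**Covariate correction** fits, per bin and per mark, a log-link Poisson
regression of the track values on standardized covariates (batched,
compiled IRLS; quasi-Poisson point estimates coincide with Poisson — the
quasi dispersion would only change standard errors, which are not used) and
removes the effect multiplicatively: `corrected = observed * exp(b0) /
fitted`. This keeps the count scale and non-negativity, which the
binarizer needs. Bins whose IRLS does not converge are retried with
`stats::glm.fit` and, failing that, left uncorrected with a warning;
all-zero bins stay zero.

Two identifiability caveats, verified by simulation and respected by the
test configurations:

* A covariate whose values align with the set of individuals active in a
  state is *confounded with biology at the bin level*: the per-bin fit will
  absorb real signal, and no per-bin method can avoid it. The end-to-end
  calibration test therefore draws covariates orthogonalized against the
  activity architecture — the well-posed case. With real covariates
  (sequencing depth, sex, RSC) this is an assumption, not a guarantee.
* Because the null-effect slope estimate has sampling noise of order
  `(Σ_d μ_d x_d²)^(-1/2)` per bin, the *worst-case* relative change under a
  truly null covariate is far above a few percent at cohort-scale track
  counts; the "correction changes nothing under the null" property is
  checked on the mean relative change (≤ 5 %), not the maximum.

**Binarization** uses a Poisson background: per track, λ is the genome-wide
mean of the corrected signal (genome-wide rather than per chromosome — a
deliberate choice; per-chromosome rates would make calls incomparable
across chromosomes), and the call threshold is the smallest integer c with
`P(Pois(λ) ≥ c) ≤ 1e-4`, forced to at least 1. The threshold search is a
`qpois` jump plus a verification walk, and the test suite checks it against
brute-force tail summation for λ ∈ {0.5, 1, 5, 20}. The model is only
*calibrated* — calls ≈ latent presence — when per-track presence is sparse
(roughly ≤ 15 % of bins) and signal exceeds the threshold comfortably;
real histone marks live in that regime, and so do the generator
configurations used for end-to-end tests (presence ≈ 0.12, signal rate 60
vs background 1). With dense presence the track mean swallows the signal
and the threshold lands inside the signal distribution; this is a property
of the background model itself, worth knowing before applying it to
broad marks.

## The synthetic-data generator

`simulate_truth()` realizes a first-order Markov state path (uniform
initial state; stay probability `self_transition`, default 0.9; jumps
uniform over the other states, so the stationary distribution is uniform)
and a true emission matrix, by default a block architecture in which each
state is "active" (p_on = 0.9) in a subset of individuals and background
(p_off = 0.05) elsewhere, concordant across marks. `simulate_counts()`
gates a two-rate Poisson on the Bernoulli presence draw: rate
`lambda_high` (default 20) where present, `lambda_low` (default 1)
otherwise, times `exp(Σ β_j x_j)` for per-track covariates. Defaults were
chosen once to mirror a desk-scale version of a real cohort — 20–75
individuals, 1–3 marks, 200 bp bins, tens of thousands of bins — and to
sit near the boundary of the binarization-calibrated regime so that tests
can probe both sides of it deliberately.

Planted effects live at the level the analysis tests them:

* gQTLs shift the **presence probability** of a state by `shift` per
  dosage unit (clamped to [0, 1]), not the counts — emissions are the
  phenotype downstream, so the truth must act there.
* Expression links are linear in a state's per-individual emission vector;
  planted genes' TSS are placed inside bins of their target state so that
  TSS-proximal geometry is realizable.
* Phenotype plans shift chosen states' presence probability in case
  individuals.
* Interval annotations are sampled per bin with weights solved from the
  requested base-level fold (`w = f(1−q)/(1−fq)` at target fraction `q`),
  erroring when `f·q ≥ 1` — the fold is then geometrically impossible.

What the generator does **not** emulate — and hence what green tests do not
certify about real data: mappability and blacklist artifacts, fragment-size
effects, linkage disequilibrium (SNPs are independent), population
structure (so genotype PCs are optional and default off), copy-number or
GC covariates acting non-multiplicatively, and continuous gradations of
chromatin state (the truth is a hard state path). Real emission parameters
also vary continuously across individuals; two-valued architectures make
Spearman-based diagnostics pessimistic, because within a tied block the
rank order between two refits is pure noise. The robustness diagnostic
therefore uses continuous architectures (`runif(0.1, 0.9)`), where
per-chromosome refits match at median ρ ≈ 0.99; with two-valued
architectures the same refits agree in parameters to ~0.01 yet cap at
ρ ≈ 0.75.

## Association machinery

All linear associations (gQTL, expression, modules, proteins, eQTL) run
through one residualize-then-correlate OLS kernel that is algebraically
identical to per-pair `lm()` (checked in tests) but runs as three matrix
products. Bonferroni for gQTLs is `5e-8 / (m·k)` — the genome-wide level
divided by the number of emission phenotypes; the family size and
threshold are recorded on every result. Model selection counts significant
**(SNP, state, mark) triples** (unique-SNP counts are also reported per
k), ties to the smaller k. Replication keeps each SNP's **minimum p over
nonsingleton states** (the per-SNP reduction is unstated upstream;
minimum-p is this package's documented choice) and compares the collection
against a seeded Uniform(0,1) reference sample of 10⁵ draws with a
two-sided Mann-Whitney U test. The eQTL overlap draws `n_perm` SNP sets
matched to the gQTL set's MAF composition in 5-percentage-point bins
(sampling with replacement, with a warning, only when a bin is exhausted)
and reports the fraction of permutations with strictly fewer significant
eQTLs; with all-null expression the counts degenerate to zero and the
percentile to 0, so null-calibration checks use a background in which
every gene carries weak genetic signal.

Mann-Whitney U tests use exact enumeration of all `choose(n, n_case)`
label assignments (two-sided by distance from the null mean) when either
group has fewer than 8 members, and the tie-corrected normal approximation
otherwise; both branches are cross-checked against `stats::wilcox.test`.
The min-p permutation adjustment recomputes all per-state p-values for
each label shuffle — vectorized by the observation that the emission ranks
never change, only the group indicator — and defines the adjusted p as
the fraction of null minima **strictly below** the observed p. Strict
"more significant than" can yield an exact 0, so the add-one smoothed
estimate `(1 + count) / (1 + n_perm)` is reported alongside; `n_perm`
defaults to 1000. The logistic check reports non-convergence (including
fitted-probability saturation, the perfect-separation symptom) instead of
a Wald p.

Distance profiles use exactly `2·span/window` windows (10,000 at the
±500 kb / 100 bp defaults), assign each window the pattern of the 200 bp
bin containing its midpoint (unambiguous for 100 bp windows), sign
distances by strand (upstream negative), and skip windows beyond
chromosome ends with per-distance denominators adjusted. Averaging is per
distance bin; the per-gene × per-state correlation matrix is attached for
per-(distance, state) breakdowns. Enrichment counts **bases**, not bins;
partially overlapping bins contribute their overlapping bases, and the
two-sided binomial p sums the probabilities of all outcomes no more
probable than the observed one, located by bisection on both flanks of the
mode so genome-scale base counts stay cheap (verified against
`binom.test`). BH families are one per external annotation source per
model. Mark-pair correlation summarizes over **all** states (not only
high-signal ones — an undocumented upstream detail resolved here in favor
of using everything).

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run seeded synthetic studies at
the sizes the methods need to show their behavior on one CPU in a few
minutes: 10⁵ bins × 20 tracks for recovery and annotation accuracy, 10⁴
null tests for calibration, 50 full pipeline replicates for gQTL power, a
{5, …, 30} state grid for selection, 100 repeats × 500 permutations for
family-wise error, and 100 MAF-matched permutations for the eQTL overlap.
Every random draw descends from a single seed (`--seed` in the acceptance
script; per-stage streams derived arithmetically in the generator), so
every number is bit-reproducible.

## Known limitations

* Emission-phenotype association treats fitted emissions as error-free
  observations; their estimation noise (shrinking with state occupancy) is
  not propagated into the test statistics.
* The per-bin covariate correction cannot distinguish covariate effects
  from biology aligned with the covariate (see above); this is inherent,
  not implementation-specific.
* Greedy state matching is not optimal assignment; it can cascade a single
  bad early match. It is used because it is the established convention for
  this diagnostic, and the unmatched remainder is reported rather than
  dropped.
* The HMM assumes homogeneous transition dynamics genome-wide; no
  position-specific or distance-decay transitions.
* Binarization calibration degrades for dense (broad) marks, as discussed.
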