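---
title: "Methods: retrospective validation of generative models with retromol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrospective validation of generative models with retromol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Given a project bioactivity table — compounds, pXC50 potencies, and
(sometimes) synthesis dates — can a generative model trained only on the
project's *early* chemistry propose the actives the project reached *late*?
`retromol` operationalizes this as a time-split evaluation: order the
project along a time axis, cut it into stages, partition compounds into
activity regions, and score any generated compound set against the late
actives.

## The time axis

**Dated mode.** When synthesis dates exist, compounds are sorted by date
(ties by input order) and split after user-chosen cumulative counts
(e.g. 500 and 1000 for a 1500-compound project). Date-based staging is the
ground truth this package prefers whenever dates are available.

**Pseudo-time mode.** Public bioactivity collections have publication
batches, not project dates. The pseudo-time axis substitutes a potency-
anchored ordering:

1. a hashed linear-path structural fingerprint per compound (default:
   paths up to 7 bonds, 1024 bits);
2. PCA to 3 components, each score column scaled to unit variance;
3. a second PCA of the 4-column matrix [3 standardized scores, pXC50] to
   3 components;
4. the Euclidean distance of every compound, in the second score space, to
   the compound with the lowest pXC50 (ties broken by smallest input row).

Sorting by ascending distance orders the project from its least-potent
starting point outward jointly in chemistry and potency. Stages are the
first 50%, next 25% and final 25% of that ordering, with floor-based
cumulative cuts so counts are reproducible for any n (n = 7 gives 3/2/2).

Three numerical decisions here were genuinely open and are worth recording:

* *"Normalized" PCA components* are interpreted as unit-variance scaling of
  the stage-1 score columns before pXC50 is appended. Without it the
  relative scale of fingerprint scores and potency would be an accident of
  the fingerprint length. A `standardize_scores` flag exposes the choice.
* *pXC50 enters the second PCA unscaled* (native log-molar units), so a
  one-log potency difference means the same thing in every project;
  `standardize_pxc50` exists but is off by default.
* PCA is SVD-based and deterministic up to component sign; distances are
  sign-invariant, so the ordering carries no RNG dependence. Rank-deficient
  inputs (e.g. all-identical structures) raise an error naming the
  deficiency rather than silently padding components.

The proprietary fragment-dictionary fingerprint used upstream is not
reimplemented; the hashed path fingerprint is a declared substitute and
bit-level agreement is not claimed.

## Activity classes and regions

Classes cut pXC50 at thresholds (6, 7, 8) by default — (7, 8, 9) suits very
potent series — with half-open bins [t, t') so a compound at exactly 6.0 is
*middle*: every value has exactly one class. Regions then combine stage and
class: α = early ∧ ≥ middle (the fine-tuning material), β = middle/late ∧
≤ middle, γ = middle/late ∧ ≥ high (the rediscovery reference). Early-stage
low-activity compounds belong to no region. Two focus-set rules are
provided because the source material describes α both as "over middle
activity" and as "above-average activity": the default
(`above_mean_early`) keeps early compounds strictly above the early-stage
mean pXC50, matching how the activity model's positive class is defined.

## Metrics

Validity, uniqueness, novelty and rediscovery form a funnel over a
generated list: valid = parses and sanitizes; unique = distinct canonical
non-isomeric SMILES (first occurrence kept); novel = unique structures
absent from the training reference (defaults to pre-training corpus ∪ focus
set); rediscovered = unique valid structures exactly matching γ-region
canonical SMILES, each γ compound counted once, with the *evaluated list
size* as denominator (so a top-100 cut uses 100). All identity matching is
on canonical non-isomeric SMILES after de-salting (largest fragment by
heavy-atom count, ties by lexicographically smallest canonical SMILES) —
no scaffold or fuzzy matching.

aSNN is the mean over query molecules of the maximum Tanimoto similarity to
a reference set, on Morgan fingerprints (radius 2, 2048 bits by default).
It is directional by construction; the package never symmetrizes it. The
conventional 0.3 "similar" cutoff annotates reports and never filters
computation. Stratified tables report one aSNN per (stage ∈ {middle, late},
activity class) cell with at least one member; empty cells are absent, not
zero.

## The activity scorer

All early-stage compounds, labelled active iff pXC50 strictly exceeds the
early-stage mean (exactly-mean is inactive), train a 100-tree random forest
of depth ≤ 20 on ECFP6 bits (radius 3, 1024). The 70/30 split is
*stratified* — the upstream description does not say, but stratification
prevents degenerate test sets on imbalanced projects and is recorded in the
model metadata; balanced accuracy on the held-out 30% is the model metric.
Scoring returns the active-class probability; unparseable molecules score
`NA`, never 0, so they rank last in top-k selection instead of masquerading
as confident negatives.

## Cluster predictivity

k-means (k = 10) on ECFP6 bit vectors with k-means++ seeding under a
mandatory recorded seed, Lloyd iterations on the squared-Euclidean
objective (Tanimoto-medoid clustering is a non-goal). Per cluster, α/β/γ
members are counted (`none` excluded) and the verdict is: predictive iff
α > 0 and γ > β; unpredictive iff α > 0 and γ < β; otherwise indeterminate —
the source rule covers only strict inequalities, so the γ = β tie and
α = 0 both land in the third bucket. Representatives are the member nearest
the cluster mean and the highest-pXC50 member (ties by input row).

## The baseline generator

The framework needs a generator exposing fit / focus / sample / NLL. A
desk-scale order-3 Markov chain over SMILES tokens fills the contract:
bracket atoms, two-letter halogens and `%nn` ring labels are atomic tokens;
additive smoothing (0.01 pseudo-counts) is applied at query time so any
string over the training alphabet has finite NLL (reported in nats);
focusing interpolates each context's distribution toward the focus corpus
with weight λ, falling back to the prior for contexts the focus corpus
never saw. Order 3 and smoothing 0.01 keep sampling non-trivially valid
while remaining desk-scale; the model is deliberately weak — its role is to
exercise the evaluation machinery and the per-region NLL diagnostics, not
to compete with neural engines. An external engine implementing the same
four-function contract can replace it without touching the framework.

## The synthetic project simulator

The simulator emulates what the analysis assumes about real projects:
congeneric series, potency rising with time, all four activity classes
populated. Chemistry is template substitution — two scaffold chemotypes,
each with two substitution sites and a small substituent alphabet, so every
product is valid by construction (validated once at spec construction).
Potency follows

    pXC50 = base + substituent_effect + drift * u + N(0, noise_sd)

with u ∈ [0, 1] the position in synthesis order, base 5, drift 1,
noise_sd 0.4 (wide enough to straddle class boundaries and produce
realistic class mixing), and a latent target base + 3.2 u driving
substituent selection. The two regimes plant the similarity structure that
separates public from in-house data: *public-like* keeps mid/late actives
on the early scaffold while low-potency excursions move to the second
scaffold (so aSNN(α,γ) > aSNN(α,β)); *in-house-like* swaps the roles (the
project jumps scaffold to reach potency, as happens when off-target or ADME
pressure forces a series change). Chemotype is assigned from the realized
activity class, and the rule admits a 3% exception rate — kept deliberately
small because a directional nearest-neighbour metric saturates once even a
handful of cross-series actives leak into a region. Regime checks label
public-like projects by pseudo-time and in-house-like projects by date,
mirroring how each kind of dataset is processed in practice.

What the simulator does **not** emulate: real SAR landscapes (effects are
additive by construction), assay heteroscedasticity, multi-objective
optimization pressure, human batch effects in registration order, or the
scale of real projects. A green regime-separation test therefore
establishes that the pipeline detects a planted similarity structure — not
that it would reach the same numbers on any particular real dataset.

## Reproducibility and budgets

All randomness flows through named seeds (`scorer`, `kmeans`, `generator`)
recorded in every output; the pipeline manifest lists each artifact with a
SHA-256 hash, and two runs under the same configuration produce identical
manifests. Chemistry and random-forest primitives run in a batched
`python` subprocess (RDKit, scikit-learn) with per-string session caching;
everything else is base R plus jsonlite/yaml/digest. Tests and the
acceptance script run on one CPU well inside their budgets by using
80–120-compound fixtures and a few hundred samples; the defaults
(5000 samples, top-100/500) remain the production configuration.

## Known limitations

* Rediscovery is exact-match on canonical non-isomeric SMILES; a generator
  producing a late active's stereoisomer or salt gets no credit (and
  stereochemistry is stripped throughout).
* The random-forest scorer object references a session-scoped pickle; it is
  re-trained (cheaply, seeded) rather than shipped across sessions.
* Only on-target potency is modelled; the stratification has no notion of
  the multi-parameter objectives that drive real series changes, which is
  precisely the gap the in-house-like regime caricatures.
* The Markov baseline's validity is low by design; conclusions about
  neural-engine behaviour require plugging such an engine into the
  generator contract.
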