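---
title: "Identifying keystone species from cross-sectional microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying keystone species from cross-sectional microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keystones)
```

## The problem

A dysbiotic gut community differs from a healthy one not only in which
species are over- or under-represented, but in how the members interact.
Species whose interactions hold the community together — keystone species —
are attractive intervention targets: adding or removing a few of them can
drag the whole community back toward a healthy composition, where broad
interventions fail. This package identifies such targets from
*cross-sectional* 16S-style abundance tables for a diseased and a healthy
("normal") group: it infers a dynamic model of the community from the two
cross sections, simulates microbial interventions in that model, and selects
the smallest species combination whose joint intervention best restores the
normal composition.

## The model

Community dynamics are modeled with the generalized Lotka–Volterra (gLV)
system

$$\frac{dx_i}{dt} = x_i\Big(r_i + \sum_j a_{ij}\, x_j\Big),$$

where $x_i$ is the abundance of taxon $i$, $r_i$ its intrinsic growth rate,
and $a_{ij}$ the per-unit effect of taxon $j$ on taxon $i$'s per-capita
growth. Every diagonal entry $a_{ii}$ is negative (self-limitation), which
is required for bounded dynamics, and $x_i = 0$ is absorbing: an extinct
taxon stays extinct unless an intervention reintroduces it.

### Identification from cross sections

A cross section contains no time derivatives, so the model is identified
through a steady-state assumption: every sample is treated as an
(approximate) equilibrium of one shared gLV model — different hosts sit at
different equilibria because they harbor different sub-assemblages and
experience different environments. At an equilibrium, every taxon present
satisfies $0 = r_i + \sum_j a_{ij} x_j$. These constraints determine each
row $(r_i, a_{i\cdot})$ only up to a positive scale, so the self-limitation
is normalized to $a_{ii} = -1$ and row $i$ is estimated from the samples
where taxon $i$ is present as the regression

$$x_i \;\sim\; r_i + \sum_{j \in N(i)} a_{ij}\, x_j,$$

ridge-penalized on the standardized slopes (default penalty 0.01; the
intercept is unpenalized). $N(i)$ is the set of taxa allowed to act on
$i$ — and including *all* of them jointly in the row fit is what adjusts
each putative interaction for the measured confounders (the backdoor
criterion of graphical causal models, realized as covariate adjustment).

$N(i)$ comes from a compositionality-aware co-occurrence prior: SparCC
basis correlations (Dirichlet-resampled log-ratio variance decomposition,
median of 20 resamples, iterative exclusion of the strongest pair above
|rho| = 0.1 for up to 10 rounds) with a permutation test — each taxon's
counts shuffled independently across samples, 1000 permutations, add-one
p-values — and pairs at p ≤ 0.01 enter the prior. The permutation statistic
is the single-pass basis correlation without the exclusion refinement: on
permuted data with few taxa the exclusion step intermittently degenerates
the basis-variance solve and clips correlations to ±1, which corrupts the
tail of the null; the observed statistic is computed identically so the
test remains exchangeable.

After the fit, every supported directed edge $j \to i$ is itself
permutation-tested (source abundances shuffled within the samples used for
row $i$, the row refit, 1000 permutations), edges with p > 0.01 are
dropped, and fit–test–prune iterates until the edge set is stable. The edge
set never grows, so the iteration terminates. Orientation deserves a
caveat: the permutation test measures association strength given the
adjustment set, so both directions of a strongly interacting pair often
survive; pair-level discovery is well-calibrated (tested), but individual
edge directions are only partially identifiable from cross sections.

### Hub species

Species importance in the fitted directed, signed network is scored with
HITS on the absolute-weight adjacency (power iteration to an L2 change
below 1e-10, at most 1000 iterations; hub and authority vectors have unit
Euclidean norm). The *hub* score — out-influence — is the quantity of
interest. Hub significance uses a permutation null, by default shuffling
edge weights over the fixed topology; a full random-rewiring null is
available (`null = "rewire"`), and is the appropriate choice when the
question is whether the topology itself concentrates influence (a
unit-weight star is invariant under weight shuffling). Species with
p ≤ 0.01 are called hubs. Degree heterogeneity is summarized by the
R² of the log–log least-squares fit of the degree distribution.

## Dynamic intervention simulation (DIS)

An intervention clamps target taxa — a sustained press perturbation, not a
pulse: removal clamps to 0, addition clamps to the taxon's normal-group
mean abundance. The default mode follows the differential direction
(Wilcoxon rank-sum on relative abundances, BH-corrected at FDR ≤ 0.05):
elevated in disease → remove, depleted → add. The clamped system is
integrated from the diseased baseline with a fixed-step RK4 integrator
(dt = 0.05, t_max = 1000, convergence when the derivative max-norm falls
below 1e-8; negative excursions floored at zero; compiled in C++). A
fixed-step scheme was chosen over adaptive stepping for bit-reproducibility;
an independently coded adaptive integrator (`deSolve::lsoda`) is kept as a
cross-check and agrees with RK4 on intervention scores to better than 1e-6
on the test communities.

The intervention score (IS) is the fractional reduction of the weighted
Bray–Curtis distance to the normal reference, computed on relative
profiles:

$$d(u, v) = \frac{\sum_i w_i\,|u_i - v_i|}{\sum_i w_i\,(u_i + v_i)},
\qquad
IS = \frac{d(x^{base}, x^{ref}) - d(x^{post}, x^{ref})}{d(x^{base}, x^{ref})}.$$

The weights are the HITS hub scores of the *normal* network (normalized,
then floored with a uniform 0.01 so no taxon has zero weight — the floor is
applied after normalization so the score is invariant to rescaling the
weights), which rewards interventions that restore topologically important
species. Clamped targets are excluded from the distance sums so a clamp
cannot trivially inflate its own score; IS is 1 at full recovery, 0 at no
effect, negative when the community moves further away. The reference
profile is the normal group's mean relative abundance — observed data
rather than a fitted equilibrium, which is robust to model misfit; the
diseased baseline is the fitted diseased model's steady state reached from
the diseased group's mean profile, so that post-intervention changes are
attributable to the intervention and not to residual model drift.

## Keystone selection

The combination intervention score (CIS) of a target set is the IS of the
simultaneous intervention on all its members. Selection is greedy forward
search: each step adds the candidate with the largest marginal CIS gain
(ties broken by the larger single-species IS, then lexicographically).
When the best single-candidate gain is negligible (≤ 0.05), all remaining
pairs are tried and the better of the best single and the best pair is
taken — interventions on mutually antagonistic species often only pay off
jointly (removing one of two blooming competitors merely releases the
other). Selection stops when the CIS exceeds 0.9 (strictly), when neither
a single nor a pair has positive gain, or at `max_k` species. A backward
elimination pass (`backward_eliminate`) then drops members whose removal
costs less than 1e-6 CIS, to a fixed point. The candidate pool defaults to
every taxon surviving the coverage filter, not just hubs.

Two caveats are worth stating. First, greedy search carries no optimality
guarantee; on six-taxon communities with exhaustive enumeration as the
oracle it reaches at least 95% of the optimal CIS in 19 of 20 random
scenarios, the failure being a case that requires a three-subset lookahead.
Second, because clamped targets leave the distance support, adding a target
changes the metric as well as the dynamics; the elimination tolerance of
1e-6 therefore only removes members whose contribution is exactly
dynamical no-ops (e.g. removal clamps on already-extinct taxa) unless a
looser tolerance is requested.

## The synthetic test bed

All power and recovery claims are calibrated on a planted-truth generator,
not on real data:

* **Community** (`generate_glv_community`): random support at connectivity
  0.15, off-diagonal strengths $\sim N(0, 0.3^2)$, $a_{ii} = -1$, target
  equilibrium $x^* \sim$ log-normal(0, 0.5); growth rates are set to
  $r = -A x^*$ so the interior equilibrium is feasible by construction,
  and draws are rejected until it is locally stable. Over 20 seeds at 20
  species, at least half the first draws are accepted.
* **Disease** (`perturb_to_disease`): the highest-out-degree taxa are the
  planted drivers; their growth rates are shifted (bloom, or depletion —
  never to extinction) with all interactions intact, escalating until the
  diseased equilibrium sits at Bray–Curtis distance > 0.2 from normal.
  Accepted scenarios keep every driver at ≥ 0.2% relative abundance in the
  diseased state: a driver below the detection (and coverage-filter)
  horizon would be an unaddressable ground truth. Drivers act through
  unchanged interactions because that is the regime in which clamping them
  back can restore the community at all.
* **Cross sections** (`sample_cross_section`): under the default
  `noise = "equilibrium"`, each sample draws a random sub-assemblage (each
  taxon colonizes with probability 0.8), multiplies growth rates by
  log-normal environmental noise (CV 0.3), and is integrated to its own
  equilibrium; proportions are then drawn as multinomial counts at depth
  10,000. Assemblage variation is essential: with pure observation noise
  (`noise = "observation"`, also provided) taxa are independent across
  samples and the steady-state constraints carry no information — sign
  recovery degrades to chance. Real data have further structure the
  generator does not emulate (chimeras, primer and copy-number bias,
  taxonomy misassignment, overdispersion beyond multinomial), so passing
  tests demonstrate correctness of the machinery under the model's own
  assumptions, not field performance.
* **Truth** (`exhaustive_truth`): brute-force CIS of every subset up to a
  budget, scored through the same code path but integrated with
  `deSolve::lsoda`, serving as the selection oracle.

Default cohort sizes mirror a realistic discovery study (16 normal / 22
diseased samples, 20 taxa for the test bed). At that scale the
permutation-tested prior at p ≤ 0.01 recovers only a handful of
interactions — a power statement about small cohorts, not a defect — yet
the planted drivers appear among the top-5 selected keystones (at least 2
of 3) in 19 of 20 seeded replicates, because the intervention scoring
itself carries most of the discriminating signal. Compositional closure is
a second documented limit: at very small communities (3 taxa, two degrees
of freedom after closure) the row-wise regression is only consistent on an
absolute-abundance scale, which the generator exposes via
`output = "absolute"`; interaction-sign recovery there is ~95% pooled over
20 seeded communities.

## Numerical choices and edge cases

* Pseudocount 1 on counts before any log or Dirichlet step (configurable);
  SparCC needs at least 4 taxa; constant taxa get zero correlations with a
  warning and p = 1 on all their pairs.
* Add-one permutation p-values everywhere: the smallest attainable p with
  1000 permutations is 1/1001, so downstream FDR arithmetic never sees 0.
* Rows with fewer than 3 positive samples are fit as pure self-limitation
  (with a warning); constant regressors are dropped from a row fit.
* The integrator errors out when any abundance exceeds 1e6 (unstable
  model) rather than returning a spurious state.
* Test problem sizes: 6–20 taxa, 16–150 samples, 100–1000 permutations,
  20-seed harnesses — chosen so each property is measured at the smallest
  scale at which it is meaningful.

## Limitations

Everything rests on the steady-state reading of cross-sectional data; the
method cannot distinguish a community far from equilibrium. Edge
orientation is only partially identifiable, total (absolute) abundance is
unobserved so all dynamics are fit on compositions, and permutation tests
at p ≤ 0.01 have limited power at cohort sizes of a few dozen samples. The
intervention score is one defensible choice among several (the metric is
isolated behind `intervention_score`, so weighted Euclidean or cosine
variants can be swapped in), and greedy-plus-elimination subset search is a
heuristic, not an exact optimizer.
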