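---
title: "Predicting segregation variance in autotetraploid crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting segregation variance in autotetraploid crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrasegvar)
```

## The problem

In clonal breeding of autotetraploid, highly heterozygous crops such as
potato, each bi-parental cross produces an F1 family whose members
segregate and are then propagated vegetatively. Choosing which crosses
to make — and how large to grow each family — depends not only on the
expected progeny mean but also on the *segregation variance*: the
genetic variance among the F1 progenies of one cross. Estimating it by
simulating large progeny sets per cross is possible but costly when
thousands of candidate crosses must be ranked; estimating it from small
field families is noisy. `tetrasegvar` computes it in closed form from
three inputs a genomic-selection programme already has:

* parental genotypes — phased haplotypes (four 0/1 homolog rows per
  marker) or, as a fallback, unphased allele dosages (0–4);
* a genetic map (Morgan or cM);
* additive marker effects (e.g. from rrBLUP), consumed as given.

## The model

Write the progeny genotypes of the cross P1 × P2 at *p* biallelic
markers as the *n × p* dosage matrix $X_{P1 \times P2}$ and the additive
effects as $\beta$. The additive segregation variance is the quadratic
form

$$\sigma^2_{P1 \times P2} = \beta^{T}\, \mathrm{var}(X_{P1 \times P2})\, \beta .$$

Everything therefore reduces to the progeny dosage covariance matrix.
Under tetrasomic inheritance with purely bivalent pairing (no double
reduction) and no crossover interference, each parent's two-locus
segregation is fully described by 36 possible gametes in three classes —
both chromatids parental (2P, probability $(1-c)^2/6$ each), one
parental one recombinant (1P1R, $c(1-c)/12$), both recombinant (2R,
$c^2/6$) — where $c$ is the recombination fraction between the loci.
Crossing two parents gives $36 \times 36 = 1{,}296$ progeny genotype
combinations; taking expectations over that product measure collapses to
closed forms:

* off-diagonal (two loci A, B):
  $\mathrm{cov}(x_A, x_B) = \big\{\tfrac13 \sum_h (A_h^{P1} B_h^{P1} +
  A_h^{P2} B_h^{P2}) - \tfrac1{12}(x_A^{P1} x_B^{P1} +
  x_A^{P2} x_B^{P2})\big\}\,(1 - 2c)$ — the parental linkage-phase
  "bracket" attenuated linearly in $(1-2c)$;
* diagonal:
  $\mathrm{var}(x_A) = \tfrac13(x_A^{P1} + x_A^{P2}) -
  \tfrac1{12}\big[(x_A^{P1})^2 + (x_A^{P2})^2\big]$, which depends only
  on dosages.

Both are implemented (`cov_phased()`, `var_locus()`) *and* re-derived
exhaustively at test time from the enumerated 1,296-row table
(`cov_brute_force()`); the suite checks agreement to 1e-12 over all
$2^8$ two-locus phasings per parent and a grid of $c$. Because the
covariance vanishes at $c = 0.5$, loci on different chromosomes never
co-vary and the matrix is block-diagonal by chromosome:
`build_cov_blocks()` never materialises the full $p \times p$ matrix,
and `predict_crosses()` accumulates $\beta^T M \beta$ per chromosome
(with a per-chromosome precomputation of the attenuation-weighted
$\beta\beta^T$ kernel so that many crosses reuse it).

Three prediction modes share this machinery:

* **phased** — the full formula above;
* **unphased** — phase unknown, LD unusable: the off-diagonals are set
  to 0 and only `var_locus()` terms remain
  ($\sigma^2 = \sum_m \beta_m^2\,\mathrm{var}(x_m)$);
* **double reduction** — a separate closed form
  $\{\cdot\}\,(1 - \tfrac43 c)(1 + 2\alpha_A)$ valid under *complete*
  quadrivalent pairing with the locus order centromere–A–B. It is
  deliberately exposed as its own mode with a bounded
  $\alpha \in [0, 1/6]$ (the classical quadrivalent maximum; the source
  derivation does not state a range, so the bound is our flagged
  convention). Note that at $\alpha = 0$ it does *not* reduce to the
  bivalent formula for $c > 0$: the pairing model differs, and the two
  attenuations $(1-2c)$ vs $(1-\tfrac43 c)$ agree only at $c = 0$. Its
  assumptions are rarely met in real meioses; we treat the mode as an
  exploratory upper bound and do not use it in the validation study.

## The forward simulator

`simulate_family()` is the validation arm: per chromosome the four
homologs are partitioned uniformly at random into two bivalents (three
equiprobable pairings) and each bivalent transmits one chromatid,
starting from a random member of the pair. Crossovers on the
transmitted chromatid are generated as a Poisson process of rate 1 per
Morgan. This is mathematically identical to the marker-interval Markov
walk with Haldane switch probabilities $c = \tfrac12(1 - e^{-2\Delta d})$
(Poisson increments over disjoint intervals are independent, and the
switch probability over an interval is the probability of an odd count),
but costs O(1) random draws per chromatid instead of one per interval —
this is what keeps 5,000-progeny families affordable. The inner loop is
C++ (as in the established forward simulators in this field), drawing
from R's RNG so every run is reproducible under `set.seed()`.
Correctness is certified at the level that matters: simulated two-locus
gamete frequencies are tested against the exact 36-cell table (1e6
gametes at $c \in \{0.05, 0.2, 0.4\}$, every cell within three
Monte-Carlo standard errors), not by cytological bookkeeping.

## Estimators and the finite-family correction

From a family's true genetic values the package computes:

* **M1** — the sum over chromosomes of the sample variance of
  per-chromosome genetic values; ignores covariance between QTL on
  different chromosomes, mirroring the block-diagonal prediction;
* **M2** — the sample variance of the total genetic values;
* **cov_total** — the effect-weighted inter-chromosome sample
  covariance. The double sum over chromosome pairs is restricted to
  *distinct* chromosomes with each unordered pair counted twice; that is
  the convention under which `m2 = m1 + cov_total` holds exactly, and it
  is enforced by computing cov_total as the off-diagonal mass of the
  covariance matrix of per-chromosome genetic-value sums (an O(n ·
  n_chrom²) aggregation; the literal marker-pair double loop is kept
  internally as a test oracle). All sample statistics use the n−1
  divisor — the identity test fails under the n divisor, which guards
  the convention.

In an equilibrium (infinite) family, unlinked loci are independent and
cov_total is 0. In real families of 10–40 progenies, drift generates
sizeable LD between unlinked loci — measurable as `r2_unlinked()`, whose
null scale is $1/(n-1)$ — and the closed-form prediction drifts from
small-family estimates. `finite_prediction()` adds the observed
cov_total of a progeny sample to the phased prediction
($\sigma^2_{phased-finite} = \sigma^2_{phased} + \mathrm{cov_{total}}$),
which the tests show improves the correlation with M2 at family size 15.

## The synthetic study and what it does (not) show

`synth_parents()` generates the founder panel for all tests: each
homolog allele is an independent Bernoulli(0.5) draw, positions uniform
on chromosomes of 1 Morgan. Defaults are a desk-scale stand-in for a
real resequencing panel — 100 parents, 12 chromosomes (potato's
chromosome number and roughly its per-chromosome map length), 200
markers/chromosome (2,400 total instead of ~49k; density mainly affects
runtime, not the moment structure, because predictions and simulations
agree marker-by-marker), 2,000 QTL with gamma(shape 2, scale 0.2)
effect sizes, i.e. mean effect 0.4 and positive sign. The scenario
runner fixes effect sizes across the runs of a study and re-draws QTL
positions each run, and samples crosses from the 4,950-cross
half-diallel.

What the synthetic panel does *not* emulate: population structure and
realistic allele-frequency spectra, LD among founders, genotyping error,
non-additive gene action, double reduction (the simulator is purely
bivalent), and estimated-rather-than-true marker effects. Passing tests
therefore validate the internal consistency of derivation, enumeration
and simulation under the stated meiotic model — they do not certify
performance on empirical breeding data, where phasing quality, family
size and trait architecture dominate.

The family-size distribution across crosses is `"uniform"` (all equal)
or `"gamma"`; the gamma shape is not specified by the study design we
replicate, so we default to shape 2 (matching the effect-size gamma) and
scale to the target mean, flooring drawn sizes at 2 so every family
supports a sample variance. This convention is deliberately prominent:
change `size_shape` to explore others.

## Numerical choices

* Recombination fractions from Haldane's function on map-distance
  differences; `c = 0` (co-located markers) is allowed and such markers
  are not merged.
* Enumeration and closed forms in double precision; no symbolic
  algebra. The oracle-equivalence tolerance is 1e-12.
* The quadratic form can round off to tiny negatives on monomorphic
  input; values in (−1e-9, 0) are clamped to 0 with a warning, anything
  more negative raises an error (the true progeny covariance matrix is
  positive semidefinite, so a large negative means inconsistent inputs).
* Missing genotype calls are rejected (complete matrices after QC are
  assumed); multi-allelic markers and ploidies other than 4 are out of
  scope.
* Scenario seeds: run *r* of a scenario uses `seed + r - 1`, so any
  single run can be reproduced in isolation.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run, by choice, at desk scale:
the oracle equivalence sweeps all 256 two-locus phasings against
enumeration; simulator fidelity uses 1e6 gametes per linkage level; the
headline concordance check uses 50 crosses of 5,000 progenies on the
default panel (PCC between M1 and the phased prediction ≥ 0.99 in the
large-family limit); the qualitative scenario-grid check uses three
family sizes × two distributions × two family numbers × 10 runs. The
90-scenario, 30-run full grid is available through `build_grid()` +
`run_grid()` for users who want the complete factorial.

## Known limitations

Additive effects only — dominance (plausibly large in potato) and
epistasis are not part of the derivation, so predictions for strongly
non-additive traits will be biased. The double-reduction mode inherits
strong assumptions (complete quadrivalents, centromere–locus order) and
has no simulation counterpart here. Marker-effect estimation itself
(rrBLUP, Bayes A) is upstream of this package: effects are inputs, and
their quality bounds the quality of any prediction built on them.
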