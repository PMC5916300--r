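---
title: "Methods: apportioning quadratic entropy across nested reef scales"
author: "reefQE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: apportioning quadratic entropy across nested reef scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefQE)
```

## The model and its assumptions

The package targets a three-level nested sampling design: coral colonies
within reef sites, sites within atolls, atolls within an archipelago,
with integer individual counts per (colony, species) cell and an
unbalanced layout (unequal numbers of sites per atoll and colonies per
site). Diversity is measured by Rao's quadratic entropy
$QE(p) = \sum_{ij} d_{ij} p_i p_j$, which needs only a species
dissimilarity matrix $d$ and relative abundances $p$; it extends the
Gini–Simpson index ($d_{ij} = 1$ for $i \ne j$) and inherits its
robustness to under-sampling of rare species, because common species
dominate the quadratic form.

**Even-weighted pooling.** Abundance vectors are averaged, not
abundance-weighted, up the hierarchy: a site's vector is the plain mean
of its colonies' within-colony relative abundances, and so on upward.
Every unit therefore carries the same weight at its level regardless of
how many individuals or subunits it contains — the property that makes
the decomposition well behaved under an unbalanced design. With these
weights the decomposition

$$\gamma = \alpha_{\text{colony}} + \beta_{\text{colonies|sites}}
  + \beta_{\text{sites|atolls}} + \beta_{\text{atolls}}$$

is exactly additive by telescoping: each beta is the difference between
the QE of a pooled vector and the mean QE of its constituent vectors.
The test suite asserts additivity to $10^{-10}$ on 1,000 random
unbalanced datasets. Beta components are guaranteed non-negative only
when $d$ is Euclidean-embeddable; `is_euclidean()` reports the minimal
eigenvalue of the doubly centred $-d^2/2$ matrix so users can check
(e.g. apply a square-root transform) before interpreting small negative
betas as structure.

## Null models and SES

No published description fixes the randomization scheme for each scale,
so the following scale-specific nulls are this package's documented
choice. Each breaks structure *only* at the tested level, holding both
coarser and finer structure fixed:

* **colonies within sites** — pool the individuals of each site and deal
  them back to that site's colonies at random, preserving colony totals
  (a multivariate-hypergeometric split);
* **sites within atolls** — shuffle colonies, with their contents, among
  the sites of their atoll, preserving per-site colony counts;
* **atolls** — shuffle whole sites, with their colonies, among atolls,
  preserving each atoll's site count.

One candidate formulation — relabelling whole-site profiles among sites
within an atoll — is a pure relabelling under even weights: the beta
statistic is invariant, the null has zero variance, and the test is
degenerate. The colony-shuffling null above is the weakest randomization
that actually perturbs the statistic while remaining exchangeable under
neutral assembly; this is the design deviation recorded in the project
ledger.

`SES = (obs − mean(null)) / sd(null)`; positive SES = units more
differentiated than the null (clustering within units), negative =
over-dispersion. p-values are two-sided on the distance from the null
mean, with the +1 correction, so they are never 0. When the null has
zero variance the SES is reported as `NA` — never silently coerced to 0.

**Discreteness and calibration.** Permutation p-values are conservative
for discrete statistics. This bites hardest at the atoll scale of small
designs: with 2 atolls and 3 sites each there are only 10 distinct
site-to-atoll partitions, so the reported p can never fall below ~0.1.
The acceptance suite therefore checks type-I calibration with the
standard randomized (tie-broken) rank — exactly uniform under
exchangeability — and separately verifies that the reported conservative
p never rejects more than nominally. The same construction is used to
check the Maddison–Slatkin null, whose Fitch-step statistic takes only a
handful of values.

## Distances

* **Gower** (mixed traits): quantitative traits contribute
  $|x_i - x_j| / R_t$ with $R_t$ the observed range *of the supplied
  species-mean table* (not a global constant); nominal traits contribute
  0/1; missing values drop the trait for that pair with weight
  renormalization; equal weights by default. Species-level means enter
  the distances — within-species variation is used by the signal
  statistics, not by QE.
* **p-distance** (per gene): proportion of differing sites among sites
  where both sequences have an unambiguous base (A/C/G/T); gaps, N and
  IUPAC ambiguity codes are removed pairwise. No model correction — the
  raw proportion is the definition used. The concatenated variant pools
  difference and site counts across genes, so species missing a gene
  contribute no sites for it.
* Whether to halve distances before QE differs between conventions;
  `halve_distances` is exposed and **off** by default, documented rather
  than guessed.

## Phylogenetic signal

`blomberg_k()` implements the K ratio with the GLS phylogenetic mean;
K = 1 exactly on a star tree, and the permutation p is one-tailed on
large K (signal = relatives more similar than chance). The
measurement-error variant profiles the GLS mean analytically and
maximizes the likelihood of the species means under
$N(\hat a 1,\ \sigma^2 C + \mathrm{diag}(m))$ over $\log \sigma^2$ in a
bracket of $[10^{-8}, 10^{8}] \times \mathrm{var}(\bar x)$ (tolerance
$10^{-10}$), with $m_i = s_i^2 / n_i$; singleton species receive the
pooled within-species variance, with a logged message. K is then
computed with $C + \mathrm{diag}(m)/\hat\sigma^2$. The `sigma` field
reports $\hat\sigma^2$, the ML Brownian rate: published tables in this
literature print a "σ" described only as variation around K after
controlling for intraspecific variation, which is ambiguous between a
rate, a variance, and a dispersion of K; this package commits to the
rate and documents the choice here. Per-atoll K prunes the tree to the
atoll's pooled species and refuses to test fewer than 4 species.

The discrete test counts minimum state changes with Hartigan's
generalization of the Fitch rule (exact on multifurcations) and compares
against state shuffles preserving frequencies; p is one-tailed on few
steps.

## The fecundity trait

Egg volume uses a prolate spheroid, $V = (\pi/6) L S^2$: two axes are
measured, and the unmeasured third axis is taken equal to the short one.
Adjusted fecundity is egg count rescaled by relative egg volume,
$n \cdot V / \bar V$ — egg number in units of average-sized eggs, which
is dimensionless and hence invariant to volume units. The authoritative
adjustment formula lives in supplementary material that is not available
here; this stand-in is dimensionally sensible, isolated in a single
function so it can be swapped, and flagged as a documented choice.
Interpolation to unmeasured species fits
$\log(\text{fecundity}) \sim \log(\text{body size})$ by least squares:
with at most a handful of measured species a GAM is under-determined, so
the smoother appears only in the diagnostic report (and only when there
are enough females), never in the interpolation itself.

## The synthetic world

The generator's defaults state the world the tests run in: 4 atolls,
4–8 sites per atoll, 2–4 colonies per site (the unbalanced field
design), 20 individuals per colony (field collections averaged ~16
individuals per colony; rounded to 20), a lognormal(0, 1) species
abundance distribution, 20 species, a Brownian body-size-like trait
(rate 1, intraspecific SD 0.25, 5 individuals per species) and a 4-state
symmetric Mk habitat-like trait. Assembly regimes:

* **neutral** — every colony is a multinomial draw from the shared SAD,
  independent of traits and phylogeny;
* **filtering** — each unit at the configured level draws a normal
  environmental optimum (spread × trait SD) and species weights are
  Gaussian-downweighted by trait distance to it (niche width h × trait
  SD);
* **limiting similarity** — sequential colony assembly where an
  arriving individual's species weight is penalized by
  $\exp(-\text{repulsion} \cdot \max\text{similarity to residents})$.

Per-gene distance matrices for the robustness harness are noisy
perturbations of scaled patristic distances, not sequence simulations —
sufficient to probe how the PQE grid degrades with distorted
evolutionary information, but not a substitution-model test. What a
green test establishes, and what it does not: the calibration and power
experiments validate the null models and the direction of inference
under the generator's idealized world (multinomial sampling, one trait
driving assembly, no spatial autocorrelation beyond the design, no
detection error). They do not validate field conclusions: real data add
unmodelled dominance structure, gene-specific rate variation, and
sampling effort gradients.

## Numerical choices

* Exact symmetry of every distance matrix is enforced at construction
  (`(D + t(D))/2`, zero diagonal); QE refuses matrices with missing
  entries on the support of `p`.
* Covariance inversions use `solve()` with a logged $10^{-10}$ diagonal
  jitter fallback; the ME likelihood uses Cholesky factorization and
  returns a penalty value on factorization failure, so the scalar
  optimizer stays inside the positive-definite region.
* Seeds are mandatory for every stochastic operation; each routine
  snapshots and restores the global RNG state, so seeded runs are
  bit-reproducible and composable. Derived stage seeds are small fixed
  offsets of the master seed.
* Counts are integers by contract — the colony-reallocation null is
  defined on individuals, so fractional abundances are rejected at I/O.
* `n_perm` defaults to 999 (tests use 99–199 where only calibration, not
  resolution, matters — scaled down to keep the suite inside its time
  budget).

## Known limitations

* The sites-within-atolls and atolls nulls shuffle intact subunits, so
  with very few subunits the conservative p is coarse (see
  discreteness note above); designs with ≥ 4 atolls are advisable before
  interpreting atoll-level p-values.
* Abundance-weighted (non-even) pooling is reserved, not implemented.
* No model-corrected genetic distances, no Pagel's λ, no
  ancestral-state reconstruction beyond Fitch counts, and no sequence
  alignment or tree inference: trees and alignments are inputs.
* The Holm-corrected significance column emitted by the pipeline is an
  extension, clearly labelled; the primary grid is uncorrected at
  α = 0.05, matching the presentation conventions of this literature.
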