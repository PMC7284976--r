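---
title: "Strain-group deconvolution from MLST coverage: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-group deconvolution from MLST coverage: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmlst)
```

## Overview

`mgmlst` estimates the relative abundances of strain population groups of
one bacterial species inside a microbiome sample. It rests on two ideas:

1. MLST allele catalogues and labelled reference strains ("learning
   samples") already encode which alleles characterize which strain
   groups, so a handful of housekeeping genes suffices as a reference —
   no genome panel is needed.
2. A community's per-locus allele relative abundances, discretized to 100
   allele copies, look exactly like the genotype of a single ploidy-100
   admixed individual, so supervised admixture inference returns the
   group mixture proportions directly.

This vignette documents the model, its tunable parameters, the numerical
conventions, what the simulator does and does not emulate, and known
limitations.

## From coverage to a ploidy-100 profile

**Marker SNPs.** Considered alleles at a locus are those used by the
learning set plus the locus's *default allele*. A marker SNP for allele
$a$ is a (position, base) pair at which $a$ differs from *every* other
considered allele. This is the strictest definition that a brute-force
scan can verify, and it makes each marker's frequency an unbiased read of
its allele's abundance. An allele with no such position cannot be
resolved by the scheme and is rejected outright rather than silently
dropped. The default allele carries no markers: it is defined as the sink
for all unexplained coverage, mirroring the convention of treating
unmarked mass as the most common (RT1-type) allele in *P. acnes*
schemes.

**Presence filters.** A marker is *present* when its relative abundance
at the marker position is at least `min_freq` (default 0.01) **and** it
is supported by at least `min_reads` reads (default 4). Frequencies use
the total read depth at the position as the denominator. Both filters are
inclusive at the boundary; zero-depth positions give frequency 0 and an
absent call. Raising either threshold can only remove presence calls,
never add them.

**Allele abundance.** An allele is present only when all of its markers
are present. Its abundance is summarized from its marker frequencies by
the **minimum** (default). The minimum is conservative — it never assigns
more mass to a non-default allele than its weakest marker supports — at
the cost of a small downward bias under sampling noise (the minimum of
several noisy unbiased estimates sits below the truth by roughly half a
standard error per extra marker). The residual $1 - \sum_a \hat f_a$ goes
to the default allele. A mean summarizer is available via
`infer_allele_abundance(..., method = "mean")` for deeply sequenced
samples where the bias matters more than robustness. Residuals slightly
below zero (to $-0.10$) are clamped with a warning and the vector
renormalized; anything lower indicates inconsistent marker calls and is
an error.

**Ploidy encoding.** Abundances map to `round(f * 100)` copies with
half-away-from-zero rounding. Rounding can leave 99 or 101 copies; the
repair inserts one missing copy (99) or removes one copy from the most
abundant allele, ties broken toward the lowest allele ID (101). Larger
discrepancies cannot arise from a simplex under these rules, but a
largest-remainder fallback guarantees an exact-100 result for any input.
The same repair applies when simulated communities are assembled from
target fractions, with the tie rule operating on group labels in sorted
order. Missing copies are `NA` internally and `-9` in STRUCTURE-format
exports.

## The supervised admixture model

Let $k = 1..K$ index population groups, $l$ loci, $j$ alleles, and let
$n_{klj}$ count the learning allele copies (100 per strain per locus;
missing copies contribute nothing). For one test sample with allele
copies $\{a\}$:

$$p_{kl\cdot} \sim \mathrm{Dirichlet}(\lambda + n_{kl\cdot}), \qquad
  z_a \mid q \propto q_k\, p_{kl,\mathrm{allele}(a)}, \qquad
  q \sim \mathrm{Dirichlet}(\alpha + m),$$

where $m_k$ counts copies assigned to group $k$. The sampler sweeps these
three conditionals; copies of the same allele at a locus are
exchangeable, so assignments are drawn as one multinomial per (locus,
allele) — a sweep costs $O(\sum_l K J_l)$ regardless of ploidy. The
posterior mean of $q$ over retained sweeps is the reported composition,
with a batch-means Monte-Carlo standard error (50 batches).

Design choices where the design was genuinely open:

- **Frequency prior.** Population allele frequencies get independent
  $\mathrm{Dirichlet}(\lambda = 1)$ priors per (group, locus). A
  correlated-frequency prior (the F-model familiar from population
  structure software) is deliberately not implemented: learning counts
  are in the hundreds to thousands per group and dominate any prior, so
  the added machinery would change nothing measurable here. The
  `sample_freqs = FALSE` fast mode fixes frequencies at their posterior
  means instead of resampling them.
- **Admixture concentration.** $\alpha$ is fixed at $1/K$ by default; a
  single supervised sample gives $\alpha$ little to identify, and $1/K$
  keeps the implied prior mass on $q$ constant as $K$ changes.
  `update_alpha = TRUE` enables a Metropolis random-walk update of a
  common $\alpha$ under a Uniform$(0, 10]$ prior for users who want it
  inferred.
- **Missing data.** Missing copies are simply excluded from both the
  learning counts and the assignment step.

**Run acceptance.** Before a run's results count, every learning strain
is re-inferred as if it were a test sample, with its own 100 copies per
locus subtracted from the learning counts (leave-own-copies-out), and is
correct when the argmax of its posterior-mean $q$ equals its label. Runs
with accuracy below 0.8 — i.e. *more than* 20% misassigned — are
discarded: 13 of 62 misassigned (21.0%) rejects a run, 12 of 62 (19.35%)
does not. Reclassification uses shortened chains (a tenth of the main
settings, floored at 200/500 sweeps), since only an argmax is needed.
Runs launch with seeds `seed + i` until the configured number of accepted
runs (default 20) is collected, capped at `max_attempts` (default 100);
per-sample results are the arithmetic mean over accepted runs (median by
option). Finally the merge map folds groups that represent one ribotype
(e.g. clade IA-1 and clade IB-3 forms of RT1) into reporting groups.

Default chain settings are 25,000 burn-in plus 125,000 retained sweeps.
Because the collapsed sweep is cheap, these defaults are affordable, but
all fidelity experiments in this package's tests use scaled settings —
burn-in 2,000, 10,000 retained sweeps, 5 accepted runs — chosen because
on group-distinctive synthetic schemes the posterior is sharply
concentrated and longer chains change the estimates only in the fourth
decimal.

## What the simulator emulates — and what it does not

`generate_synthetic_scheme()` builds a scheme shaped like a curated
*P. acnes*-style learning set: 6 groups × 4 loci × 10 strains per group
by default, every group with its own allele at every locus, at least
`snp_divergence = 2` private positions per allele, and one minority
within-group variant allele per group. This guarantees marker derivation
succeeds and curation removes nothing — by construction, the generated
learning set is already clean.

Communities are assembled by sampling members uniformly with replacement
from the target groups' strains; Set B targets come from a flat Dirichlet
over reporting groups (the maximal-entropy reading of "randomly
generated" compositions), and Set C ships six fixed clinically shaped
target vectors (dominant group 0.5–0.9 plus minors) in
`inst/extdata/setc_synthetic_targets.tsv` — synthetic stand-ins, not
measured clinical compositions. `community_to_pileup()` draws
per-position depths from a Poisson and bases from the member-weighted
allele distribution with a uniform substitution error;
`community_to_sam()` writes locus-spanning reads for the alignment path.

What passing these simulations shows: the encoding, the sampler, the
acceptance rule and the merging are correct, and compositions are
recovered essentially exactly when alleles separate groups cleanly. What
they do not show: performance under real-world complications —
amplification bias, homopolymer or quality-correlated sequencing errors,
strains whose allelic profiles straddle groups, novel alleles absent from
the catalogue (which this method, like any reference-based method,
misattributes to known groups), or uneven coverage across loci. The
clinical-sample behavior of the approach cannot be certified by these
tests.

## Numerical conventions and degenerate inputs

- Coordinates are 0-based half-open everywhere; SAM's 1-based positions
  are converted at the boundary. Mapping-quality filtering defaults to 0
  (all mapped reads); upstream identity filtering is not re-checked.
- Consensus-profile ties during curation resolve to the smallest allele
  ID; ambiguity excludes a strain when any *other* group's consensus
  matches its profile at least as well as its own.
- Learning-set curation recomputes consensus profiles from the strains
  given to it, so curating an already-curated set is a no-op.
- A sample allele carried by no group's learning copies has zero
  likelihood everywhere when $\lambda = 0$ and raises an error naming the
  locus; the default $\lambda = 1$ absorbs it smoothly.
- Degenerate Pearson inputs (an exactly constant composition vector)
  return a flagged `NA` rather than a number; cohort comparisons on
  zero-variance groups report $p = 1$ with a warning. The cohort test is
  a two-sided Mann–Whitney U by default (a t-test by flag) — appropriate
  for small-sample compositional fractions — with per-group reporting and
  no multiplicity correction.

## Problem sizes used in the packaged experiments

The fidelity experiments (tests and `scripts/acceptance.R`) use the
default synthetic scheme (6 groups, 4 loci, 60 learning strains), 6
Set A communities, 20 Set B communities and 6 Set C communities at
burn-in 2,000 / 10,000 retained sweeps / 5 accepted runs; the quadrature
cross-check uses $K = 2$, one locus, ploidy 4, 60,000 sweeps. These sizes
were chosen so the whole suite is a desk-scale experiment while leaving
Monte-Carlo error an order of magnitude below the effects being checked.

## Known limitations

- Alleles must be pre-aligned and equal-length; indel-bearing alleles and
  internal alignment are out of scope.
- The method cannot discover new strain groups: unseen allele
  combinations are forced onto the known groups.
- The min-of-markers abundance summarizer biases non-default alleles
  slightly downward at moderate depth, inflating the default allele
  correspondingly; use deeper coverage or the mean summarizer when this
  matters.
- Unsupervised choice of $K$, linkage between loci, and sequence-type
  reconstruction (as opposed to group proportions) are non-goals.
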