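---
title: "Methods: dating serial red-plastid endosymbioses"
author: "rhodochron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating serial red-plastid endosymbioses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodochron)
```

## The scientific question

Complex red algal-derived plastids occur in four distantly related
eukaryote groups — cryptophytes, ochrophytes, haptophytes and myzozoans —
whose host phylogeny does not track the plastid phylogeny. Serial
endosymbiosis models (the "rhodoplex" framework) explain this by a single
secondary uptake of a red alga followed by tertiary and quaternary
transfers between hosts. Such a chain is only possible if every donor
lineage overlapped in time with its recipient. `rhodochron` implements the
computational layer of this chronological test: it turns 95% highest
posterior density (HPD) age intervals from Bayesian relaxed-clock dating
into per-transfer feasibility windows under an explicit scenario, plus the
supporting machinery (prior densities, trace summaries, an EGT screen,
compositional site stripping) and a synthetic-data generator that makes
every stage testable without the original multi-gene dataset.

## Transfer windows

A lineage's *availability window* runs from the older 95% HPD bound of the
node that opens its stem (the crown node's parent) down to the younger 95%
HPD bound of its crown node — the span during which a plastid could have
been acquired along the stem. For a transfer `donor -> recipient` the
feasibility window is the pairwise intersection,

```
older   = min(donor.older,  recipient.older)
younger = max(donor.younger, recipient.younger)
```

and the transfer is feasible iff `older >= younger`. Windows are computed
*pairwise only*: the realized time of an earlier transfer is deliberately
not propagated into later donor windows, because the published interval
table this engine reproduces is itself built from pairwise intersections
(each event uses the full stem window of its donor). Ordering is assessed
separately.

`sequential_feasibility()` asks whether the chain admits a weakly
age-decreasing assignment of one event time per window. We implement the
exact (global) semantics by a greedy pass — place each event as old as its
window and its predecessor allow — rather than the weaker pairwise
consecutive-overlap check, because the pairwise condition is necessary but
not sufficient on chains of three or more events; the report still itemises
pairwise violations since they are the interpretable diagnostic. The
envelope of a scenario is the span from the oldest event bound to the
youngest, the total period over which the serial transfers unfolded.

Bounds are carried at full precision; comparisons against published
integer tables use `round_half_away()` (round half away from zero).
Infeasible windows report a negative *overlap deficit* (`younger - older`)
to aid diagnosis rather than erroring.

## Calibration prior densities

Four fossil-calibration prior families are provided, matching the
sensitivity analyses of node-dating practice. For bounds `tL < tU` (Ma):

* **Soft-bound uniform** — constant density on `[tL, tU]` carrying mass
  0.95, with 2.5% of prior mass beyond each bound (`cdf(tL) = 0.025`,
  `cdf(tU) = 0.975`). The exact functional form of the tails is not
  dictated by the contract, only their mass and continuity; we use a
  power-law decay below `tL` (which respects the age-zero boundary) and an
  exponential decay above `tU`, each matched for density continuity at the
  bound. Only the tail-mass and continuity contracts are treated as
  normative.
* **Skew-normal** — shape `alpha = 10`, location anchored at `tL` (the
  "literal" reading of the fossil record: minima close to the true node
  age), and scale `beta` solved by root-finding so that
  `cdf(tU) = 0.975` to within 1e-8. The CDF uses Owen's T function
  evaluated by quadrature; sampling uses the exact
  `delta|U0| + sqrt(1-delta^2) U1` representation.
* **Truncated Cauchy** (short tail `c = 0.1`, long tail `c = 10`; offset
  `p = 0`, left mass `pL = 0.01`) — a Cauchy with location `tL(1+p)` and
  scale `c*tL`, truncated at `tL` and carrying mass `1 - pL`, continued
  below `tL` by a power-law soft minimum carrying `pL`. The density is
  proper, so the default sampler is the exact inverse CDF; a `ceiling`
  argument (e.g. a 3200 Ma root maximum) is available where downstream
  consumers need bounded draws.

All numeric quantile inversions use bisection/`uniroot` to at least 1e-8
relative tolerance. The 97.5% prior quantiles order as skew-normal
&le; uniform &le; short-tailed Cauchy &le; long-tailed Cauchy for a shared
calibration, which mirrors the qualitative ordering of posterior medians
reported for these families.

Calibration tables use Min/Max vocabulary; the package's interval
vocabulary is strictly older/younger, and `read_calibration_table()` maps
Min to the interval's younger bound. Minimum-only Proterozoic clades
receive a default maximum of 1900 Ma.

## Posterior summaries

`hpd_interval()` returns the shortest contiguous window over the sorted
samples containing `ceiling(mass * n)` samples — the ceiling guarantees at
least the nominal empirical coverage — with ties on width broken towards
the smallest younger bound so output is deterministic. `summarize_trace()`
emits per-node mean/median/HPD rows plus analysis-level medians; because it
is ambiguous whether "median ages" across analyses are medians of node
means or node medians, both are computed and labelled.
`compare_chronograms()` matches internal nodes across two dated trees by
tip-set bipartitions and reports the fraction of nodes shifted strictly
younger (ties count as unshifted), the mean shift among shifted nodes, and
median age/HPD-width differences. `clocklikeness_rank()` orders genes by
root-to-tip path-length variance only; the additional bipartition-support
filter used by some gene-selection tools is intentionally omitted and
documented as a simplification.

## The EGT screen

Endosymbiotic gene transfer (EGT) leaves a topological signature: in an
affected marker gene the recipient group branches with the donor rather
than with its vertical sister. The screen labels every tip with its
taxonomic group and, in each bootstrap tree, finds every *maximal*
label-pure clade (a pure clade contained in a larger pure clade of the same
label is not counted). Each such clade contributes weight 1 (regardless of
tip count — the unit of observation is the clade) to its label's row: the
label composition of its sister group, with mixed sisters credited in
proportion to tip counts. Rows are normalized to sum to 1. Maximal pure
clades are re-identified independently in every bootstrap tree, since
bootstrap replicates need not contain the ML tree's clades. A focal label
is flagged `non_vertical_dominant` when its top sister differs from the
expected vertical sister with frequency at or above a configurable
threshold (default 0.5; no published numeric criterion exists for
"dominant", so the default is a design choice). Input trees are treated as
rooted; unrooted input is an error unless midpoint rooting is requested.

## Compositional site stripping

The alignment-level heterogeneity statistic is

```
H = sum over taxa t, residues r of (f[t, r] - mean_r f[., r])^2
```

over gap-free per-taxon compositions. A site's score is
`H(full) - H(without the site)`, computed incrementally from the count
matrix. The underlying published tool names no formula, so this
sum-of-squared-deviations reconstruction is a documented choice; only the
behavioural properties are treated as normative (identical rows give
`H = 0` and zero scores; a planted discordant site ranks first; stripping
reduces `H`). Because a site can *dilute* heterogeneity, scores may be
slightly negative; ranking is unaffected (ties break by site index).
`strip_sites()` removes `floor(fraction * n_sites)` top-ranked sites so the
requested fraction is never exceeded.

## The synthetic-data generator

The generator's defaults are the study conditions the analyses assume:

* **Dated trees** — birth-death trees conditioned on a root age; non-root
  node ages are i.i.d. draws from the conditioned age density (closed-form
  inverse CDF, exposed as `bd_age_cdf()`), topology built by uniform
  lineage splitting.
* **Branch rates** — mean rate 0.02625 replacements/site per 100 Myr, a
  Gamma(shape 2, rate 2) hyperprior on the rate-variance parameter (prior
  mean 1), and a 100 Ma time unit. Both clock models use mean-preserving
  log-normal parameterisations (the `-sigma2/2` corrections), so the two
  models are comparable at the same `mu`. The autocorrelated model is
  geometric Brownian motion along branches; the uncorrelated model draws
  each branch independently. The parent-child rate-correlation contrast
  (autocorrelated `r > 0.3` vs uncorrelated `|r| < 0.1`) is asserted with
  `sigma2` fixed at its hyperprior mean, because pooling trees with
  different drawn `sigma2` values induces spurious correlation through the
  shared `-sigma2/2` shift.
* **Posterior traces** — each node receives a replicate-specific posterior
  location (log-normal error at the stated coefficient of variation) and
  samples are drawn around it with the same dispersion; this two-level
  construction is what makes 95% HPDs cover the truth at the nominal rate.
  Parent-older-than-child ordering is enforced by rejection, erroring when
  the budget is exhausted.
* **EGT genes** — the transfer is implanted by pruning the recipient clade
  and regrafting it as sister to the donor clade. Bootstrap replicates are
  emulated by random rooted NNI moves with a per-internal-branch
  probability `epsilon` (default bootstrap sample size 1000, matching an
  ultrafast-bootstrap sample), chosen over sequence resampling because the
  screen consumes trees and `epsilon` gives direct control of topological
  noise.
* **Biased alignments** — unbiased taxa draw i.i.d. from base frequencies;
  biased taxa draw from a mixture tilted toward a designated residue
  subset.

What the generator does *not* emulate: site-heterogeneous substitution
processes, rate variation across sites, alignment error, and the dating
samplers themselves. Passing tests therefore demonstrate the correctness
of the implemented statistics and engines on data with the assumed
structure, not the field behaviour of the upstream inference tools.

## Problem sizes used by the test suite

The packaged tests run the round-trip serialization property on 1000
random chronograms; HPD oracle equivalence on samples up to 10^4; HPD
coverage on 500 synthetic posteriors of 2000 samples; the EGT exhaustive
oracle on trees of up to 12 tips; positive/negative EGT controls with 200
bootstrap replicates per gene at `epsilon = 0.1`; and the rate-correlation
contrast on about 3000 pooled parent-child branch pairs from 40 simulated
40-tip trees. These sizes were chosen so the full property battery
exercises each contract at meaningful scale while the suite stays quick to
run routinely.

## Known limitations

* The scenario engine consumes printed or derived HPD bounds; it does not
  recompute posteriors, so its conclusions inherit whatever biases the
  upstream dating run had.
* The stem-opening convention (parent's older HPD bound) is one defensible
  mapping of "stem lineage" onto tree nodes; published donor windows are
  therefore shipped as fixtures rather than recomputed from any particular
  tree.
* The sister-group screen cannot detect EGT when *all* markers of a
  lineage were replaced — there is no conflicting vertical signal left.
* `validate_calibrations()` checks marginal bound consistency and
  ancestor-descendant compatibility; it does not model the joint
  truncation of nested calibrations, which is a property of the dating
  samplers.
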