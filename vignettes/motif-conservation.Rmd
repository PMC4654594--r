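---
title: "Methods: scoring the conservation of degenerate RNA motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring the conservation of degenerate RNA motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifcons)
```

`motifcons` asks whether a short degenerate RNA element — the kind a Puf
protein binds in a 3' UTR — is retained across a phylogeny more often than
random sequence would allow. This vignette explains the models, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical decisions taken where the
procedures leave room.

## Motifs and their permutation null

A motif is an ordered list of positions, each a non-empty subset of
{A,C,G,T}; `U` is transliterated on input and `N` in a sequence matches
nothing. A *collection* of alternative motifs (always equal length here)
matches when any member does. The null family used everywhere is the set
of *position permutations*: reorderings of the positions, applied jointly
to all members of a collection so that shared structure between the
alternatives is preserved. Permutations keep composition and information
content, so they retain the statistical texture of the motif while
destroying its biological identity. Reorderings that reproduce an
identical collection — including the original — are excluded; for
`UGUA[ACU]AUA` (symbol multiset 3×U, 3×A, 1×G, 1×[ACU]) that leaves
8!/(3!·3!) − 1 = 1119 permutations. When more permutations exist than are
requested, a seeded uniform sample without replacement is drawn (100 by
default in the conservation pipeline).

In `derive_regex()` a base enters a position when its frequency is
*strictly* above 10%; a base at exactly 10% is excluded. The strictness
follows the defining phrase "more than 10%"; ties at the boundary are
deliberate exclusions, not accidents of floating point (frequencies are
ratios of counts).

## The conservation score

For one ortholog set, every species is called present (1) if any
ortholog's UTR matches the collection, absent (0) if orthologs exist but
none match, and missing if the species has no ortholog. Missing species
are pruned from the tree, suppressed degree-2 nodes having their branch
lengths summed. On the pruned tree the score is computed bottom-up:

* a leaf's proportion `P` is its call;
* an internal node with children X1, X2 has
  `CS = P(X1)·S(X1) + P(X2)·S(X2)`, where `S(X)` is X's stem branch plus
  the total branch length beneath X, and the node's own proportion is
  `P = CS / (S(X1) + S(X2))`.

`CS` at the root is the weighted sum of branch lengths over which the site
is inferred present: 0 when absent everywhere, the pruned tree's total
branch length when present everywhere, monotone under absent→present
flips. The recursion assumes a descendant's stem branch is occupied in the
same proportion as its subtree — the stem is *included* in `S(X)`, which
is what makes the two-leaf example `(A:0.3,B:0.7)` with both present score
exactly 1.0, and the three-leaf example `((A:0.2,B:0.2):0.1,C:0.5)` with
A,B present score 0.5.

Two degenerate cases need decisions. A subtree of total length zero makes
`P` a 0/0; we fall back to the subtree's leaf-call average, which is the
limit of the recursion as the lengths shrink symmetrically. Polytomies are
not defined by the two-descendant recursion; they error unless
`resolve = TRUE` resolves them arbitrarily with zero-length internal
branches (which, by the same limit argument, is neutral for the score). A
tree whose root trifurcates is treated as a polytomy even though `ape`
regards it as an unrooted binary tree — the recursion needs a root.

### Permutation FDR

Scores alone have no scale: longer trees give bigger scores, and AT-rich
compositions give more chance matches. The null is therefore empirical:
the same ortholog sets re-scored with each of `m` permuted motifs. For a
set A,

FDR(A) = (mean over permutations of #{sets with permuted CS ≥ CS(A)}) /
#{sets with real CS ≥ CS(A)}.

The denominator is at least 1 (A itself). The raw ratio can exceed 1 and
is retained (`fdr_raw`); the reported `fdr` caps at 1. The conserved set
is everything with FDR ≤ the threshold, *inclusive*, default 0.01.

For gene groups collapsed into one unit (paralogous genes encoding one
histone type, say), presence is any-member-any-ortholog, the unit is
scored normally, and an empirical p-value `(1 + #{perm CS ≥ CS}) / (m+1)`
is reported — unless even the maximum achievable score (present in every
scored species) could not reach significance against the permuted scores,
in which case the unit is reported "not tested" rather than quietly
non-significant.

## Pairwise screen

The two-species test classifies shared ortholog sets into a 2×2 table
(match in both / one / neither) and computes the one-tailed hypergeometric
`P(X ≥ n_both)`. Because related species share composition and ancestry,
the raw p is not trusted; the real motif's p is ranked against the p of
every permutation, ties counted against the real motif
(rank = 1 + #{perm p ≤ real p}) — a conservative convention, chosen here
because the tie rule is not otherwise specified. Significance requires
both a Bonferroni-corrected p < 0.05 (the factor is the number of species
pairs in the surrounding screen, exposed as an argument) and empirical
p < 0.01 (top 1%). With fewer than 100 permutations the top-1% rule cannot
be met and the result is flagged underpowered instead of silently failing.

## Mutual-information 10mer discovery

Binding specificity is characterised as the set of anchored 10mers
(`UGUA` + 6 free positions, 4096 candidates) that discriminate an in-group
of UTRs from an out-group. Each round scores every candidate by the mutual
information (in bits) of the 2×2 table (group membership × match), keeps
the best, and masks every UTR the kept 10mer matches *in either group* —
"accounted for" is read as matched-by-a-kept-10mer regardless of group, so
no UTR contributes to two selections. Ties in MI break to the
lexicographically smallest candidate (a deterministic, documented choice).
The search stops at 250 rounds or when no candidate has positive MI.

The keep-count comes from a ROC-style curve of cumulative TPR/FPR in
selection order: the local slope dFPR/dTPR is estimated by least squares
over a centred 11-point window, and the kept set ends just before the
first point whose slope exceeds 1 — false positives accumulating faster
than true positives. A window with no TPR variation has slope +∞ (cutoff
fires) unless FPR is also flat (slope 0, e.g. the all-zero-FPR prefix,
where everything is kept). The written description of this rule admits a
second reading — cut where cumulative FPR exceeds cumulative TPR — which
is exposed as `rule = "fpr_gt_tpr"`; neither is privileged, and `override`
forces an exact count for deliberately stricter cutoffs. Kept 10mers are
grouped as connected components of the Hamming-distance-1 network (an
automated stand-in for grouping a network layout by eye, which is the one
place this package replaces a manual step with an algorithm), optionally
merging components whose derived regexes agree at all but one free
position.

## Dependence models

Whether two proteins' sites co-occur beyond chance is asked three ways.

**Stepwise logistic regression.** Nested models 0–3 (constant; + site 1;
+ site 2; + interaction) are fit by `glm(family = binomial)` — the
standard tool for the job — and each addition is tested by the deviance
drop against χ² with df equal to the added estimable terms. Forward
selection stops at the first addition with p ≥ 0.05. Aliased (collinear)
additions contribute zero deviance and are rejected; quasi-separated fits
are tolerated inside the stepwise path (deviances remain defined) but
`logistic_fit()` errors on separation when called directly. Reported
intervals are Wald: exp(β ± 1.96 SE).

**Fisher dependence.** A 2×2 Fisher exact test over the gene set, with a
direction label (overlap more / less / none). The two-tailed p follows the
sum-of-small-probabilities convention; the reported odds ratio is the
sample cross-product ratio, with the conditional-exact CI from the
standard test. Note the two-tailed p bounds the one-tailed hypergeometric
p only on the enrichment side; on the depletion side the one-tailed p
approaches 1 and the inequality reverses.

**Gain/loss CTMC.** Paired presence states {00, 01, 10, 11} evolve by a
single-step chain: simultaneous changes of both sites have rate zero. The
dependence model frees all 8 gain/loss rates; the independence model ties
parallel rates (4 free). The likelihood is Felsenstein pruning with
matrix exponentials, pattern-compressed over genes; leaves missing both
sites are ambiguous (sum over states); genes observed in fewer than two
species are excluded. The root distribution is uniform over the four
states by default (`root = "stationary"` is available) — the classical
tool's default is not documented, so this is an explicit choice. Under
independence the 4-state likelihood factorises exactly into the two
2-state chain likelihoods, which the tests verify to 1e-9 against an
independent 2-state pruning implementation.

Rates are sampled by random-scan Metropolis–Hastings with multiplicative
lognormal proposals (the y/x Hastings term included), uniform priors on
[0, `r_max`] (default 100; the prior bound is a configuration, not an
estimate), and proposal scales adapted only during burn-in so the
post-burn-in chain is a valid fixed-kernel sampler. Marginal likelihoods
use the harmonic-mean estimator for comparability with the classical
discrete-trait workflow, with
`log BF = 2(log HM_dep − log HM_indep)`; the harmonic mean's instability
is acknowledged, and a stepping-stone estimator is provided as a clearly
labelled alternative (`stepping_stone()`). Chains are bit-reproducible
given a seed.

## The synthetic-data generator

The generator produces exactly what the pipeline consumes: a rooted binary
tree with i.i.d. exponential branch lengths (leaves `sp1..spN`),
binding-site histories simulated *exactly* (Gillespie waiting times, no
discretisation) under the same 2- or 4-state generators the inference
uses, i.i.d. per-(gene, species) ortholog dropout producing missing calls,
and UTR sequences with one concrete realization of the motif planted at a
uniform offset wherever a site is present (non-overlapping when two
factors are present). With scrubbing on, accidental background matches are
re-drawn before planting, so absence means zero matches — the clean
setting used in unit tests. With scrubbing off, background matches occur
at the i.i.d. rate (≈ 0.023 expected matches per 500-nt UTR for the Puf3
element at uniform composition), the realistic setting used for
calibration studies.

The **reference conservation study** (`simulate_conservation_study()`)
fixes the conditions under which the pipeline's closure is demonstrated:
12 species, 600 ortholog sets of which 120 carry the conserved site,
500-nt UTRs (the 500-nt-downstream-of-stop convention), uniform base
composition, scrubbing off, 5% dropout. Conserved genes gain the site on
the stem of one clade and retain it under loss rate 0.2 (gain 0.05 allows
regain); background presence follows a low-gain chain (gain 0.01, loss 1,
stationary ≈ 1%). Two of these choices deserve justification:

* *Uniform composition.* At fungal-like 36% GC the AT-rich background
  inflates the chance match rate of an AT-rich motif to ≈ 8% per UTR, and
  permuted motifs (same composition) then produce score nulls that swamp a
  12-leaf study. Uniform composition gives the analytic ≈ 2.3% rate and is
  the stated low-background regime. Real genomes are the AT-rich case —
  which is why the method needs the permutation FDR at all, and why
  passing this closure study says the machinery is correct, not that any
  particular genome will separate this cleanly.
* *The clade must dominate the tree.* Under the score recursion a single
  chance match on a long-stem leaf propagates part-way up the tree, so the
  null tail reaches roughly the longest root-to-leaf path. A clade-wide
  site is only separable when the clade's branch length is a large share
  of the total; the study therefore places the gain on a clade holding
  about two-thirds of the tree's branch length, redrawing the random tree
  (deterministically from the seed) when no such clade exists. On 12-leaf
  trees with exponential branch lengths this is a real constraint; on the
  large, deeply sampled phylogenies the method is meant for, the conserved
  lineage naturally spans most of the tree.

What the generator does **not** emulate: indels and alignment error,
lineage-correlated ortholog loss (dropout is i.i.d.), compositional
heterogeneity along the UTR, motif turnover within a UTR (sites moving
while presence is retained), and any coupling between site presence and
expression. Passing the closure study demonstrates the statistics and the
plumbing under the model's own assumptions — no more.

Other defaults worth knowing: `simulate_site_design()` uses intercept
−3.5 (a realistic target prevalence of ≈ 3%) with site effects β1 = 3,
β2 = 1 on the logit scale; MCMC tests and the acceptance script use a
balanced 4-taxon tree with branches 0.3–0.4 at rates near 1, the regime
where absolute rates are identifiable (on saturated branches only the
gain/loss ratio is), with a prior box `r_max = 20` matched to that scale.

## Problem sizes and numerical notes

The shipped studies are sized for a single CPU: the closure study scans
600 × 12 UTRs for 101 motifs (a couple of minutes, dominated by regex
scanning), stepwise selection runs 100 + 100 replicates of n = 1000
(seconds), MCMC uses 50k iterations for rate recovery and 20k per model
for the Bayes factor (tens of seconds each, via eigen-decomposition
matrix exponentials with a Padé fallback and pattern compression).
Scores are vectorised across ortholog sets by grouping identical
missingness patterns, so each pruned tree is traversed once per pattern
rather than once per gene. Offsets in all match tables are 0-based;
output TSVs carry a comment header saying so.
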