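---
title: "Methods: annotating, scanning and dating a promoter-resident DNA transposon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating, scanning and dating a promoter-resident DNA transposon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference chain

`tecoopt` implements the chain of evidence by which a transposable element
(TE) can be shown to have donated a transcription-factor binding site to a
gene promoter:

1. **Element annotation.** A candidate repeat is characterized de novo:
   terminal inverted repeats (TIRs), the target-site duplication (TSD) left
   by cut-and-paste insertion, open-reading-frame content, and the terminal
   `YARNG` motif shared by P-superfamily DNA transposons. A decision table
   turns these features into a classification; a TIR-bearing, TSD-flanked
   element with no substantial ORF is a *non-autonomous class II* element.
2. **Copy counting.** A BLASTN-like seed-and-extend search counts genomic
   copies under the conventional repeat filter: identity at least 85% over
   at least 85% of the query length.
3. **Binding-site scanning.** A position weight matrix (PWM) is scanned
   over both strands; each hit's *weight* is the summed natural-log
   log-odds and its p-value is the exact tail probability of that score
   under the background model, computed by dynamic-programming convolution.
   Expected hit counts give observed/expected enrichment ratios.
4. **Promoter comparison.** The two paralogous promoters are globally
   aligned; large alignment gaps become indel *regions*, and each region's
   genomic copy number decides whether it was inserted into its carrier
   (repetitive) or lost from the other paralog (single copy).
5. **Insertion dating.** Kimura-2-parameter (K2P) distances on third codon
   positions feed a neighbor-joining tree, which is linearized under a
   molecular clock and calibrated at a node of known age. The element's
   divergence from its family consensus, divided by the calibrated rate,
   dates the insertion; the date is then ordered against the gene
   duplication node.

Every stage can be exercised on synthetic data with known ground truth; the
generators are first-class, tested package functions.

# Models and assumptions

## K2P distances and their uncertainty

For a pairwise comparison with transition proportion $P$ and transversion
proportion $Q$ over $L$ sites (pairwise deletion of gaps and ambiguity
codes),

$$ d = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q), $$

with the delta-method standard error
$\mathrm{se}^2 = [c_1^2 P + c_3^2 Q - (c_1 P + c_3 Q)^2]/L$ where
$c_1 = 1/(1-2P-Q)$, $c_2 = 1/(1-2Q)$, $c_3 = (c_1+c_2)/2$. The analytic SE
is used rather than a bootstrap; the test suite verifies that the empirical
spread of simulated estimates matches it within 10%, and that both $d$ and
the SE agree with `ape::dist.dna(model = "K80", variance = TRUE)` to
near machine precision.

The published anchor values are reproduced exactly by this machinery: a
1316-site comparison at $d = 0.034$ with ts:tv 2:1 has SE 0.005, and a
1024-site comparison at $d = 0.010$ has SE 0.003 (three decimals).

The ts:tv split behind a given divergence is not identifiable from $d$
alone; simulations use an instantaneous ratio of 2:1 (`kappa = 2`),
exposed as a parameter. At the small distances relevant here the SE is
insensitive to this choice.

## Clock linearization and calibration

`nj_tree()` delegates Saitou–Nei neighbor joining to `ape::nj` and then
clamps negative branch lengths to zero, transferring the deficit to the
sibling edge. `linearize_and_calibrate()` roots on the outgroup and
re-estimates node heights under a strict clock by tip-count-weighted
averaging: each internal node's height is the mean over its descendant tips
of the node-to-tip path length. The **root is special**: rooting on an
outgroup cannot locate the root along the stem edge, and tip-count
weighting there would let the species-rich side dominate. The root height
is therefore the unweighted mean of its two child-side path means, which is
invariant to where the stem edge was split. Without this correction the
calibrated rate is biased low by roughly the tip-count imbalance (a factor
of about two in the six-taxon scenario), inflating all ages.

This weighted averaging is a deliberate lightweight alternative to the full
ordinary-least-squares linearization; on clock-simulated six-taxon data the
recovered node ages are unbiased within simulation noise (duplication
10 MY recovered at ~10.5 on average, rate 0.004 recovered within ~4%).

Ages scale linearly with the calibration age, so ordering verdicts are
invariant under re-calibration (tested).

## Insertion dating and the ordering verdict

Element-versus-consensus divergence accrues on a single lineage, so the
age point estimate is $t = d_\mathrm{elem}/r$ (not $d/2r$), with interval
$(d_\mathrm{elem} \pm z\,\mathrm{se})/r$ clipped at zero and $z = 2$ by
default. The insertion is placed on the branch of the host lineage's root
path whose age interval contains the point estimate. The verdict against a
reference node (the gene duplication) is *younger* only when the whole
interval lies below the reference age, *older* only when it lies wholly
above, and *indistinguishable* otherwise.

This interval rule is deliberately conservative. Note its consequence: for
a 1316-bp element whose true insertion (8 MY) postdates a duplication
(10 MY) by only 2 MY, the K2P standard error (~0.005 at these divergences)
makes the $z=2$ upper bound straddle the reference in a large fraction of
replicates, so the conservative verdict is frequently *indistinguishable*
even though the point estimate sits below the duplication and its interval
covers the true age. A point-placement comparison would order the events
"correctly" more often, but would not express uncertainty; the package
reports both the interval verdict and the branch placement so users can
make either argument explicitly.

## PWM scores and exact p-values

Log-odds are natural-log (so a printed $\ln p$ of $-11.492$ corresponds to
a p-value of $1.0\times 10^{-5}$ at two significant figures):
$\mathrm{lo}_{b,j} = \log\frac{c_{b,j}+\alpha_b}{\sum_b c_{b,j} + \sum_b \alpha_b} - \log \pi_b$,
with the per-column pseudocount mass $\alpha$ defaulting to
$\max(0.5,\ 0.01\times \text{column total})$, split across bases in
proportion to the background $\pi$. The p-value of a score is the exact
tail probability of the column-independent background score distribution,
computed by convolving per-column distributions on a discretized grid
(default $10^{-3}$ natural-log units, round-to-nearest; worst-case
log-score error is grid $\times$ width / 2). The test suite checks the DP
against exhaustive $4^w$ enumeration for widths up to 6 at a $10^{-5}$
grid, with query thresholds placed midway between achievable scores so the
comparison is exact.

Expected hit counts are
$E = (\text{length} - w + 1)\cdot \Pr(S \ge \text{threshold}) \cdot (\text{strands})$,
and overlapping hits are all reported (no greedy masking), matching how
motif-prediction tools count sites.

## Seed-and-extend homology search

Exact `word_size` (default 11) seeds on both strands are clustered by
alignment diagonal (tolerating indel drift up to a band derived from
`x_drop`) and then by subject position, so tandem copies seed separate
extensions. Each cluster is extended by an *optimal local alignment* of
the query against the padded subject window (match +1, mismatch −2, gap
open −5, extend −2, megablast-style), rather than by a greedy x-drop walk;
`x_drop` controls the window padding. Within the seeded window this is by
construction the Smith–Waterman optimum, which the tests confirm against
an independently written dense DP oracle. Copy counting keeps hits with
identity ≥ 85% over ≥ 85% of the query (inclusive thresholds, with a
`strict_gt` switch), collapsing overlapping passing hits to the
best-scoring one.

Because local alignment trims mismatch-dense ends, a decoy sequence whose
full-length identity is just below the threshold can occasionally pass the
filter over a slightly shorter aligned span — this is faithful to how
BLASTN behaves and is visible in the acceptance suite as a rare borderline
event in the decoy-rejection property.

## Promoter comparison

Global alignment uses affine gaps (+1/−1, open −4, extend −0.5) so that
large indels stay contiguous. Gap runs of at least `min_region_len`
(default 200 bp — published analyses of this kind ignore small indels, the
smallest reported region being ~315 bp) become regions; runs in the same
row separated by fewer than `join_dist` (default 50) aligned columns are
merged first, and a merged region's *length* is the summed gap length
(the amount of carrier-exclusive DNA) while its interval spans the full
carrier range. Promoters are assumed written 5′→3′ with the transcription
start site at the 3′ end; regions are numbered with Roman numerals from
the TSS-proximal end outward. Region boundaries are reported as raw
alignment-gap boundaries, without refinement against repeat termini.

Origin classification uses genomic copy number alone: at least
`min_copies_for_repeat` (default 2) copies → insertion into the carrier;
exactly one copy (the region's own locus) → loss from the other paralog;
zero copies → ambiguous. Outgroup synteny evidence is out of scope and
this limitation is deliberate.

# The synthetic-data generators

The generators emulate the study conditions and serve as ground truth:

- `evolve_sequence_k2p()` mutates sites independently with the exact K2P
  substitution probabilities for the target distance, making the estimator
  consistent by construction (verified at $L = 10^5$).
- `plant_element_copies()` inserts independently diverged copies flanked by
  fresh random TSDs, screening the host base adjacent to each insertion so
  the duplication cannot accidentally extend by one base.
- `generate_promoter_pair()` plants indel regions into a shared backbone;
  the default region specification (Y-carried 2348, 315, 598, 496 bp and
  A-carried 728 bp on a 5350-bp backbone) mirrors the published region
  table, giving a ~9.1-kb Y-analog promoter.
- `simulate_duplication_scenario()` evolves codon-structured sequences
  (first/second positions frozen, third positions neutral) along a
  five-species history — outgroup split 95 MY (the calibration), congener
  20 MY, crown clade 5 and 4 MY — with a gene duplication at 10 MY on the
  crown stem and an element instantiated on the duplicate lineage at 8 MY.
  The default rate is 0.004 substitutions/site/MY: the value implied by an
  element-consensus divergence of ~0.034 accrued on one lineage since an
  insertion shortly after a ~10 MYA duplication, which also reproduces the
  published 0.034 ± 0.005 scale on a 1316-bp element.
- `plant_motif_instances()` overwrites windows with exact site copies on
  recorded strands.

Each generator draws from a private stream seeded from (seed, operation
name), so outputs are byte-reproducible and adding a generator never
perturbs existing fixtures.

What the generators do **not** emulate: indel evolution inside elements,
rate heterogeneity across sites or lineages (in particular, an accelerated
duplicate lineage would bias the duplication date, which the package
reports but does not correct), GC-content structure beyond a single knob,
nested insertions arising spontaneously, and alignment error (coding
alignments are simulated gap-free). Passing tests therefore demonstrate
correctness of the algorithms under the stated models, not robustness to
every feature of real genomes.

# Numerical and design choices

- **Coordinates** are 1-based, closed, plus-strand throughout the user
  surface (the R/Bioconductor convention); BED input is converted on read.
  TSS-relative biology-style positions (e.g. −2132) convert through
  `tss_to_index()`, with no position zero.
- **Case and alphabet**: input is upper-cased; `U` and non-IUPAC characters
  are rejected rather than coerced.
- **TSD matching is exact** (the reported duplications are exact octamers);
  tie-breaking takes the longest qualifying duplication, and TIR search is
  anchored at the element termini only.
- **ORF threshold**: 100 codons separates "no open reading frame" from
  incidental micro-ORFs when classifying autonomy; translation uses the
  standard code with no initiator-codon special-casing.
- **Consensus ambiguity**: ties at the 50% threshold emit the minimal IUPAC
  code covering the tied bases, because downstream distance estimation
  excludes ambiguity codes pairwise; columns with gap fraction at or above
  the threshold are dropped.
- **Degenerate inputs** raise typed errors early: saturated K2P distances,
  all-zero PWM columns, ragged alignments, out-of-bounds intervals,
  insufficient TSD flanks, calibration nodes at zero height.
- **Problem sizes**: the shipped tests run the full suite at desk scale —
  2000-replicate K2P spread checks, 50-seed copy-number recovery on ~12-kb
  genomes, 20-seed end-to-end dating with 1000-codon alignments, promoter
  alignments up to ~9 kb — chosen so the whole suite completes in a few
  minutes on one core.

# Known limitations

- Copy counting is desk-scale (simple hash seeding; no genome index, no
  E-values, no translated search).
- Clock linearization is the weighted-averaging scheme above, not the full
  OLS system, and assumes a strict clock.
- Region origin calls rest on copy number only; single-copy regions cannot
  be distinguished from very recent single-copy insertions without
  outgroup synteny.
- The dating interval propagates only the element-divergence SE; rate
  uncertainty from the calibration is not propagated (it is small relative
  to the element SE at the scales above, but not zero).
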