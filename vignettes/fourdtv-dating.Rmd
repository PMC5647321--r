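---
title: "Dating whole-genome duplications from 4dTv distributions: models and methods"
author: "paleoploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating whole-genome duplications from 4dTv distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoploid)
```

## The statistic and its model

For a pair of homologous coding sequences, 4dTv is the proportion of
four-fold degenerate sites whose third-position bases differ by a
transversion. A site enters the count only if (i) neither codon contains a
gap or ambiguity, (ii) both codons belong to a four-fold degenerate family
(CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN under the standard code), and
(iii) the two codons agree at their first two positions. Condition (iii) is
a deliberate, conservative convention: when the first two positions differ,
the third position's degeneracy class can differ between the two genes, and
the site's neutrality is no longer guaranteed. The cost is a smaller site
count, which matters for short genes (see *Numerical behaviour* below).

Because a transversion changes the purine/pyrimidine class and the class
process under any Kimura-type two-parameter (K2P) model is a symmetric
two-state Markov chain with flip rate 2β, the expected 4dTv of a pair with
total divergence τ (in units of β·t summed over both lineages) is

$$Q(\tau) = \tfrac12\left(1 - e^{-4\tau}\right),$$

independent of the transition/transversion ratio κ and of the ancestral
base composition (two-state symmetric chains forget their root state).
`tau_for_target_4dtv()` inverts this curve, τ = −log(1 − 2x)/4, so
simulations can be parameterised directly by target 4dTv values. The
statistic saturates at 0.5; values near saturation carry almost no time
information. By default the raw proportion is reported, which is the scale
on which peak positions like 0.042 are conventionally quoted;
`compute_4dtv(..., correct = TRUE)` applies the two-state correction
−log(1 − 2Q)/2 for users who want additivity at deeper divergences.

## From gene pairs to dated events

The pipeline estimates event times in four stages.

**Pairing and alignment.** Candidate homolog pairs (a BLAST-like hit
table) are aligned codon-aware: proteins are aligned globally
(Needleman–Wunsch, BLOSUM62, affine gaps, open 11 / extend 1 in matrix
units, via Biostrings) and the alignment is back-translated, so gaps occur
only in whole codons. Internal stop codons translate to `*` and are aligned
like any residue — evolved or misannotated sequences are data, not errors.
Pairwise global alignment stands in for the multiple aligners used in
large-scale studies; for the pairwise statistic computed here the
difference is immaterial.

**Syntenic chaining.** Hits are converted to anchors in *gene-rank*
coordinates (0-based order of gene starts along each chromosome), which
makes gap penalties independent of gene length and intergenic distance.
Chains must advance strictly in both genomes, in the same or inverted
orientation, with at most `max_gap` skipped genes per genome between
consecutive anchors (default 10); a chain scores
`n_anchors × anchor_score − gap_penalty × skipped genes` (defaults 10
and 1). The best chain is found by dynamic programming, removed, and the
process repeats — a greedy extraction of non-overlapping chains; chains
with fewer than `min_anchors` (default 5) are dropped. These defaults are
in the range common to collinearity tools; all are exposed in
`chain_params()`. Tie-breaking is deterministic (earlier start, then longer
chain). One known limitation: when two different chains attain exactly the
same score, the tie-break depends on which genome is "A", so anchor-set
anti-symmetry under swapping the genomes is guaranteed only when the
optimum is unique; the optimal score itself is always symmetric.

**Block aggregation.** Each block's 4dTv is the *median* of its anchors'
defined pair values (mean available via `agg = "mean"`). The median is
robust to the occasional mis-paired anchor, at the price of a small
downward bias for discrete data discussed below.

**Density, peaks, clock.** Block values are smoothed with a Gaussian KDE on
a 512-point grid over [0, max + 3·bandwidth]; `bandwidth = "auto"` is
Silverman's rule (`bw.nrd0`). Peaks are interior local maxima whose
prominence — height minus the higher of the two flanking minima, each
flank taken to the adjacent local maximum or grid end — reaches
`min_prominence` (default 0.05) of the maximum density. Taking the
*higher* flank means a mode that barely rises above a neighbouring
shoulder is discarded, and a near-flat density yields no peaks at all.
Peak positions are reported at grid resolution without parabolic
refinement; with 512 grid points the discretisation is below 10⁻³ 4dTv
for typical ranges, well under the other uncertainties. Given an anchor
(x₀, t₀) — an ortholog peak of known age — the clock rate is
r = x₀/(2 t₀) per lineage, and any peak x dates to t = x/(2r). The factor
2 is required for the standard published anchor pairs to be mutually
consistent: anchoring at (0.27, 46.7 Mya) dates a 0.16 peak to 27.67 Mya
and anchoring at (0.16, 27.9 Mya) dates a 0.27 peak to 47.08 Mya, each
within 1% of the other printed value — the residual being rounding of the
printed peak positions. No clock rate is assumed by default; dates are
only produced from an explicit user-supplied anchor, because published
paralog-peak dates (e.g. ≈7.8 Mya for a 0.042 peak) imply a slightly
different rate (≈2.69×10⁻³/My) than either printed ortholog anchor,
presumably from unrounded peak positions.

## The simulator: what it emulates and what it does not

`build_genome_set()` generates the study conditions the analysis assumes.
An ancestral gene set (ATG + uniform sense codons + stop) is run through an
ordered event list, deepest first: *speciation* events split off outgroup
genomes that evolve independently to the present; *WGD* events replicate
every focal lineage into 2 or more subgenome copies, each copy then
independently lost with probability `loss_prob` — so a retained paralog
pair occurs with probability (1 − loss)². The canonical scenario
(`allohexaploid_events()`) is an allohexaploid: two outgroup speciations at
4dTv 0.27 and 0.16, and one triplicating hybridization/WGD event at 0.042,
so all three subgenome pairs share one divergence level — a modelling
choice, since only the peaks themselves are observable. Divergence is
parameterised directly in β·τ units; calendar time never enters the
simulator, keeping it free of any clock assumption.

Sequence evolution is site-independent K2P (default κ = 2) on nucleotides.
There is no selection, no codon model, no indels, no rate variation among
sites or lineages, and no gene conversion; collinearity is perfect except
for losses, and the hit table is emitted from truth (optionally with 5%
uniform-random decoy hits to exercise chaining noise tolerance) rather than
from an actual similarity search. Passing tests on this generator therefore
validates the *statistical machinery* — site identification, counting,
chaining, mode recovery, clock arithmetic — not robustness to biological
complications such as rate heterogeneity, fractionation bias, or tandem
arrays. Evolved sequences may contain internal stop codons; they are
deliberately not repaired, since only third positions of intact four-fold
codons are read.

Determinism: every gene, branch and loss decision draws from an RNG
substream derived by a stable hash of the root seed and the gene/branch
identifier, so outputs are byte-identical for a given configuration and
seed and independent of evaluation order.

## Numerical behaviour and problem sizes

Pair-level 4dTv is a ratio k/n₄ of small integers. Two consequences shape
the defaults used in validation:

* **Quantisation and median bias.** With n₄ four-fold sites per pair, pair
  values live on a lattice of spacing 1/n₄, and the median of a handful of
  such values is biased low by roughly (1/3)/n₄ (the mode–median offset of
  a low-mean binomial). At 100-codon genes (n₄ ≈ 45 usable sites at shallow
  divergence) this bias is ~0.007 — material against a ±0.01 recovery
  band. Validation runs therefore use 300-codon genes (n₄ ≈ 130,
  bias ≈ 0.003).
* **KDE sample size.** Silverman bandwidths computed from fewer than ~20
  block values are small enough to resolve individual lattice clumps,
  splitting one mode into several. Validation runs use 40 blocks
  (600 genes at 15 genes per chromosome). A Monte-Carlo check of this
  estimator design (40 block medians of 12 pairs each, n₄ = 131) gives a
  mode estimate with mean ≈ 0.040 and sd ≈ 0.003 around a true 0.042.

The end-to-end recovery test simulates one WGD at expected 4dTv 0.042 with
600 genes × 300 codons, κ = 2, 10% copy loss, runs the full pipeline with
default chaining and auto bandwidth, and requires the highest-prominence
peak within 0.042 ± 0.01; at these sizes the run takes well under a minute
on one CPU. Deep divergences are noisier: at 4dTv 0.27, conditioning on
identical first two codon positions discards ~73% of four-fold codons, so
ortholog-level fixtures use longer genes (200 codons) and a fixed 0.025
bandwidth to display the three-peak structure cleanly.

Degenerate inputs are defined away rather than patched: pairs with zero
four-fold sites are flagged undefined and excluded; blocks with no defined
pair value are excluded from dating; densities require ≥ 2 values;
saturated corrections (Q ≥ 0.5) and saturated p-distances (p = 1) are
flagged undefined.

## Family statistics

Domain over-representation uses the exact hypergeometric upper tail
(`stats::phyper`): the probability of drawing ≥ k domain-positive genes in
n draws from a universe of N genes with K positives. The default universe
is the *union* of focal and background genomes (the focal genome's genes
are part of N and K), which is the standard one-set-versus-union
convention; a background-only universe is available via
`background = "others"`. Counting is per gene, not per domain hit. Raw
p-values are reported by default, with Benjamini–Hochberg adjustment behind
a flag, since single-domain tests need no correction. Expansion profiles
histogram within-family amino-acid p-distances (bin 0.02) and report the
fraction below 0.05 — a recently expanded family (e.g. post-WGD) shows an
excess of near-zero distances. The qPCR utility implements
2^−ΔΔCt exactly and exists so the expression arithmetic used alongside
such analyses is covered by tests.

## Design choices that were genuinely open

* **Four-fold site convention** (both codons four-fold *and* identical
  first two positions): chosen over the laxer "third position of a
  four-fold codon in either gene" because it never counts a site whose
  degeneracy differs between the pair; conventions differ between
  published pipelines and the choice is not always stated.
* **No multiple-hit correction by default**: peak positions around
  0.04–0.27 are conventionally quoted as raw proportions; the correction
  is monotone, so peak *ordering* and clock consistency are unaffected,
  and it is available behind a flag.
* **Median block aggregation**: robustness to a single bad anchor pair was
  judged worth the small discreteness bias, which the problem-size
  guidance above keeps negligible.
* **Greedy chain extraction**: optimal single chains with greedy removal
  (rather than a global multi-chain optimisation) matches common practice
  and keeps the oracle-checkable invariant "first chain = provably optimal
  chain".
* **Adjacent-valley prominence**: flanking minima are taken to the
  neighbouring local maximum rather than walked to the nearest higher
  point; the latter assigns any global maximum a prominence equal to its
  full height and would report a "peak" on an essentially flat density.
* **Hexaploidy as one triplicating event**: three subgenomes with a single
  paralog divergence level reproduces a unimodal paralog peak; scenarios
  with two nested duplications are expressible with two `wgd` events if
  needed.

## Known limitations

Peak positions are grid-resolution estimates without refinement or
confidence intervals; Silverman bandwidth over-smooths strongly multimodal
distributions (fix the bandwidth explicitly when displaying multi-peak
structure); the simulator's idealisations listed above; chaining
anti-symmetry under genome swap is only guaranteed for unique optima; and
printed enrichment p-values from real multi-genome studies are not
reproducible without the underlying annotations, so only the test's
mathematics, not those published values, is validated here.
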