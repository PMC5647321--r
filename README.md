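# paleoploid

Dating polyploidization and speciation events from the transversion rate at
four-fold degenerate sites (4dTv).

## The problem

Allopolyploid plant genomes — such as hexaploid weeds formed by
hybridization of a tetraploid and a diploid donor — carry the traces of
their origin in the divergence of duplicated genes. For a pair of homologous
coding sequences, the **4dTv** statistic is the fraction of four-fold
degenerate third codon positions (codon families CTN, GTN, TCN, CCN, ACN,
GCN, CGN, GGN) that differ by a transversion. Because any base at these
sites is synonymous, they evolve approximately neutrally, and because
transversions are a symmetric two-state class process, the expected 4dTv of
a pair with total divergence τ (in transversion-rate time) is

    Q(τ) = (1 − e^(−4τ)) / 2,

rising from 0 and saturating at 0.5. A whole-genome duplication (WGD)
deposits thousands of paralog pairs at one divergence, so the distribution
of 4dTv over syntenic gene pairs shows a peak per event; under a molecular
clock with per-lineage rate r (4dTv/My), a peak at position x dates its
event to

    t = x / (2 r)   million years ago (Mya),

the factor 2 because both lineages accumulate divergence. Calibrating r from
an ortholog peak of known age converts every peak to an absolute date.

`paleoploid` implements this workflow end to end, for users who want a
self-contained, testable reimplementation of the classic 4dTv dating
pipeline: codon-aware pairwise alignment, four-fold site identification and
4dTv computation; dynamic-programming chaining of homology anchors into
collinear syntenic blocks (the DAGchainer-style stage); Gaussian-KDE peak
detection and two-lineage clock dating; gene-family statistics
(hypergeometric domain enrichment, amino-acid p-distance expansion
profiles, qPCR 2^−ΔΔCt fold changes); and a Kimura-two-parameter
allopolyploid genome simulator that generates CDS FASTA, GFF3, homology
hits and a ground-truth divergence table, so the entire pipeline is
validated against known truth without external data.

## Worked example

Fit the dating model to 4dTv values with one paralog and two ortholog
modes, anchoring the clock at the deeper ortholog peak (0.27 ⇒ 46.7 Mya):

```r
library(paleoploid)
set.seed(1)
x <- c(rnorm(200, 0.042, 0.01),   # paralog pairs from a recent WGD
       rnorm(150, 0.16,  0.02),   # orthologs to a closer outgroup
       rnorm(120, 0.27,  0.03))   # orthologs to a deeper outgroup
fit <- wgd_dating(x, anchor_4dtv = 0.27, anchor_mya = 46.7)
fit
#> 4dTv peak dating
#>   470 values, bandwidth 0.02475, 3 peak(s)
#>   position height prominence date_mya
#> 1  0.04244  6.426     4.6400    7.341
#> 2  0.16336  4.110     2.2569   28.256
#> 3  0.26907  2.546     0.6937   46.539
```

The three detected modes sit at 4dTv ≈ 0.042, 0.16 and 0.27; under the
calibrated clock (rate 0.27/(2·46.7) ≈ 2.89×10⁻³ 4dTv/My) they date to
≈ 7.3, 28.3 and 46.5 Mya — the WGD and the two speciations. `coef(fit)`
returns the peak positions, `plot(fit)` draws the density with dated peaks.

The same result from raw inputs, via the pipeline (here on simulated data;
real CDS/GFF3/hit files can be supplied through the `inputs` entry):

```r
res <- run_pipeline(list(
  seed = 42, outdir = "run1",
  simulate = list(n_genes = 120, codons_per_gene = 150, kappa = 2,
                  events = list(list(kind = "wgd",
                                     tau = tau_for_target_4dtv(0.042))),
                  loss_prob = 0.1, genes_per_chromosome = 15)))
res$dating$peaks
#>     position   height prominence
#> 1 0.04298978 70.49569  38.768160
#> 2 0.03391542 36.89445   5.166921
```

The dominant (highest-prominence) peak recovers the simulated WGD's
expected 4dTv of 0.042. The run directory holds every intermediate table
(per-pair 4dTv, syntenic blocks, density, peaks) plus a JSON manifest of
parameters and checksums; identical config + seed reproduces identical
bytes. A thin command-line wrapper for each stage is installed at
`inst/cli/paleoploid.R`.

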