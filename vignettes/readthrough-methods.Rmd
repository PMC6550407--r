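---
title: "Methods: testing whether stop-codon read-through is error or adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing whether stop-codon read-through is error or adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readthroughr)
```

## The scientific question

Ribosome profiling shows ribosomes dwelling in 3'UTRs of many eukaryotic
genes: the ribosome occasionally fails to terminate at the canonical stop
codon and translates on until the next in-frame stop. Two hypotheses compete.
Under the *adaptive* hypothesis this read-through is a regulated mechanism
that diversifies the proteome; under the *error* hypothesis it is molecular
noise held down by purifying selection whose strength scales with how often a
transcript is translated. The two hypotheses make different, testable
predictions, and this package implements the full statistical battery that
separates them:

1. **Rates vs expression.** If read-through is an error, selection against it
   intensifies with mRNA abundance, so the per-translation read-through rate
   should *decrease* with expression.
2. **Motif avoidance.** Stop-codon contexts known to leak (TGACA, TGACT —
   TGA followed by C, then A or T) should be depleted in highly expressed
   genes, both component-wise and combinatorially.
3. **No conservation signature.** The translated extension (region 1) should
   show no excess interspecific sequence conservation, no avoidance of
   frame-shifting indels, and no length conservation relative to a never-
   translated control segment (region 2), once detection bias is controlled.
4. **Harm mitigation.** Because a hydrophobic extension peptide destabilizes
   the protein, selection should lower the hydrophobicity of region-1
   peptides in genes where read-through actually occurs.

## Regions and the read-through rate

For each gene, **region 1** is the transcript segment between the canonical
(first) stop codon and the second in-frame stop codon in the 3'UTR, and
**region 2** the segment between the second and third in-frame stops. Both
are taken in the CDS frame, exclude the bounding stop codons (the extension
peptide is what is translated), and are cut at 300 nt downstream of the
canonical stop; a region cut by the cap is flagged `truncated_at_cap`.
Coordinates are 1-based inclusive throughout, with an empty region encoded as
`end = start - 1`.

The per-gene read-through rate is the ribosome-profiling RPKM (reads per
kilobase per million mapped reads) of region 1 divided by that of the coding
region. Expression is always taken from *mRNA-seq* RPKM of the coding region,
so the rate (ribo-seq) and the expression (mRNA-seq) never share counting
noise.

**Detection bias and supergene rates.** Low rates are only observable in
well-expressed genes, which by itself manufactures a negative rate-expression
correlation. The debiasing device is binning: genes are ranked by mRNA RPKM
and packed into 10 bins of (near) equal *total* RPKM, and each bin's rate is
computed as the ratio of summed region-1 RPKM to summed CDS RPKM — a single
"supergene" — rather than a mean of noisy per-gene ratios. Because a gene is
never split, exact equality of bin totals is impossible; each gene is
assigned to the bin containing its cumulative-RPKM midpoint, which guarantees
every bin total is within one gene's RPKM of the ideal share. Bin
uncertainty is the SD of the supergene rate over 1,000 bootstrap resamples of
the bin's genes (a single-gene bin has bootstrap SD exactly 0). The
rate-expression trend is summarized by Spearman's rank correlation across
bins; with only 10 bins the two-sided P uses the exhaustive permutation
distribution for n < 10 and the t approximation for n >= 10. Published
analyses sometimes attach astronomically small P-values to a perfect rank
ordering of ten bins; no 10-point rank test can produce them, and this
package reports the honest small-sample value instead.

**Fraction of read-through removed by selection.** Read-through in the
lowest-expression bin is essentially invisible to selection, so its rate
approximates the intrinsic error rate r_low; the highest bin's rate r_high is
what selection tolerates. The fraction removed is (r_low - r_high) / r_low.
With the published yeast bin rates (0.0398, 0.0111) this is 72.1%, and with
the fly rates (0.04069, 0.01318) it is 67.6%.

## Motif composition tests

Each gene contributes a stop-codon context: the stop codon itself and the two
following nucleotides, with expression on the log2(RPKM + 1) scale (the +1
keeps zero-RPKM genes defined). Genes whose 3'UTR is shorter than 2 nt are
excluded and counted. Genes are split into expression tertiles of equal gene
count (remainder to the lower bins; ties broken by gene id).

Within a bin, the frequency of a motif expected under independent use of its
three components is the product of the component frequencies. The
combinatorial test permutes each component column independently across the
bin's genes (exactly preserving component margins) 10,000 times; the deficit
P is the fraction of shuffles whose motif count is *at or below* the observed
count. Because ties count toward the P-value and counts are discrete, this P
is conservative (stochastically larger than uniform under the null) — the
effect fades as the expected count grows, which is why the calibration tests
use bins large enough for an expected count near 80. Genome-level tests are
the Mann-Whitney U (two-sided, tie-corrected normal approximation) comparing
expression of motif carriers vs non-carriers, and Fisher's exact test
(two-sided, point-probability method) on TGA usage in the top 20% of genes by
expression vs the rest.

## Conservation of the post-stop regions

Inputs are pairwise alignments of the stop-codon neighborhood (50 nt upstream
of the stop to at most 300 nt downstream) between a reference species and a
close relative. QC retains an alignment only if (a) the three reference stop
columns are gap-free in both species and the partner's bases there form some
stop codon (not necessarily the same one), and (b) identity over the 36
columns immediately upstream of the stop is at least 88%, counting gapped
columns as mismatches (the conservative reading of "the last 36
nucleotides").

Per gene and region the package computes: percent identity at aligned
non-gapped sites; identity split by codon position (frame anchored at the
first region-1 reference residue and tracked on reference residues, so
partner gaps cannot shift the frame) — under protein-level constraint
positions 1-2 should beat position 3; indel events as maximal per-sequence
gap runs, assigned to the region containing their first gap column, with the
frame-shifting fraction being the share of events whose length is not a
multiple of 3; and absolute and relative length differences |L_A - L_B| and
|L_A - L_B|/(L_A + L_B). Genes with a capped region 1 are excluded from
length statistics (their length is censored) but kept for identity.

Group comparisons use a one-tailed bootstrap: both groups are resampled
independently, and the P-value is the fraction of replicates whose statistic
difference contradicts the alternative, ties counting against the strict
alternative (two identical constant groups give P = 1). For the frameshift
fraction, genes — not events — are the resampling unit and the fraction is
recomputed from each resample's pooled events. Expression-matched controls
pair every read-through gene with the nearest non-read-through gene on each
side of it in the expression ranking (mean of the two; edge genes use the
single available neighbor) and apply a paired two-tailed t-test on raw
identities (no arcsine transform; the choice is logged here so users can
transform upstream if preferred).

**The adaptive verdict.** The pipeline calls a dataset "adaptive-like" only
when *both* signals point the same way: read-through genes show excess
region-1 conservation *and* a deficit of frame-shifting indels, each at
one-tailed bootstrap P < 0.05. Requiring multiple concordant signals reflects
how functional read-through candidates are actually triaged and makes the
false-positive rate of the verdict roughly the product of the two tests'
levels rather than their sum.

## Hydrophobicity

Peptides are conceptually translated (standard code) from the last 16 codons
of the CDS, region 1, and region 2; a trailing partial codon from a capped
region is dropped, and proteins shorter than 16 residues use the whole
protein (flagged). The hydrophobic fraction is the share of residues in
{G, A, V, I, L, M, F, Y, W}. Group means are unweighted means of per-gene
fractions with bootstrap standard errors over genes, and the one-tailed
bootstrap P tests whether read-through genes have the *lower* region-1
hydrophobicity. Capped regions are included and flagged.

## What the synthetic generator emulates

`synthetic_truth()` fixes the study conditions; `generate_genes()`,
`generate_rt_calls()`, `generate_ortholog_pairs()` and
`apply_hydrophobicity_shift()` realize them deterministically from a master
seed (streams are split per stage, so enabling one stage never perturbs
another's draws).

* **Expression**: log-normal RPKM, meanlog 2, sdlog 1.5 — median ~7 RPKM
  with a realistic 3-4 decade dynamic range.
* **True read-through rate**: r(e) = r0 (1 + e)^(-b) with r0 = 0.04, b = 0.2.
  The intrinsic rate equals the published low-bin scale (~0.04) and the
  decay gives a high-bin rate on the order of 0.01, matching the observed
  contrast; b = 0 is the constant-rate null world.
* **Transcripts**: stop-free CDS of 300-3000 nt (uniform over whole codons),
  stop codon and +1/+2 bases drawn from tertile-specific component
  probabilities (TGA and +1 C frequencies decline with expression, mirroring
  the observed component trends), and a 60-400 nt 3'UTR of uniform ACGT —
  giving an in-frame stop probability of 3/64 per codon and hence mean
  region-1 lengths of ~60 nt, the observed scale.
* **Counts**: mRNA and ribo-seq counts are Poisson with intensities
  proportional to expression (x2 translation factor for ribo-seq; library
  sizes 2e7), and region-1 ribo intensity is the CDS intensity times the true
  rate times the length ratio. No overdispersion knob in this version — a
  documented simplification.
* **Read-through calls**: a gene is called when its region-1 ribo count
  exceeds 4 reads, reproducing the detection bias (calls enrich for high
  expression and long region 1).
* **Orthologs**: the partner species is derived by i.i.d. substitutions
  (0.10/site, uniform among the three alternatives) and indels (0.01/site,
  geometric lengths with mean 3). In the *error world* those rates apply
  everywhere; in the *adaptive world* region 1 of called genes has its
  substitution rate multiplied by 0.5 and indels there forced in-frame with
  probability 0.5.
* **Hydrophobicity shift**: region-1 codons of called genes (sparing the
  first codon, which carries the +1/+2 context) are swapped from
  hydrophobic- to hydrophilic-encoding sense codons with the probability that
  lowers the expected hydrophobic fraction by 0.1.

What the generator does **not** model: overdispersed counts, codon-usage
bias, UTR composition structure, alignment-tool artifacts (alignments are
emitted with their true gap structure rather than re-estimated), CpG or
context-dependent substitution, and shared phylogenetic history across genes.
Passing tests therefore demonstrate that the statistics recover known truth
under idealized sampling — not that real libraries satisfy the Poisson or
i.i.d. assumptions.

## Numerical and design choices

* Coordinates are 1-based inclusive; a zero-length region has
  `end = start - 1`. The annotation's `cds_end` is the position of the last
  stop-codon base.
* Binning ties are broken by gene id everywhere, making every ranking
  deterministic.
* Genes with zero measured CDS ribo RPKM contribute to neither supergene
  sum; missing region-1 RPKM contributes 0 to the numerator.
* All bootstrap and shuffle routines take a seed and are reproducible; the
  pipeline derives per-stage and per-bin substreams from one master seed so
  adding a bin or toggling a stage leaves other results untouched.
* Bootstrap P-values are reported with resolution 1/n_boot and never as 0 by
  fiat; ties count against the strict alternative.
* Degenerate inputs: constant expression still bins (flagged); empty
  regions translate to empty peptides and are excluded from that source's
  comparison; an alignment whose reference stop sits within 36 columns of
  the window edge fails QC rather than being scored on a short window.

## Problem sizes used in the test suite

The suite regenerates everything at run time: oracle checks use 100-1,000
random small instances per operation; calibration uses 200 seeds with
5,000-gene bins and 300 shuffles (expected motif count ~80, where the
discrete conservativeness of the deficit P is negligible); recovery uses the
full default of 3,000 genes and 10 bins over two seeds; world discrimination
uses 20 seeds per world at 800 genes with a call threshold of 2 so both gene
groups are well populated; the hydrophobicity shift check uses 200 genes per
group drawn from a 2,500-gene simulation. These sizes are the package's
chosen trade-off between statistical resolution and a test suite that runs
in minutes.

## Known limitations

* The supergene estimator is consistent for the expression-weighted mean of
  the true rate over a bin's genes with nonzero region-1 length — genes whose
  second stop immediately follows the first contribute expression to the
  denominator but can never contribute read-through signal.
* The shuffle-deficit P is conservative for small expected motif counts.
* The built-in ortholog generator emits true alignments; with real data the
  aligner's gap placement adds error the QC step only partially absorbs.
* Only pairwise (two-species) conservation is supported, by design.
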