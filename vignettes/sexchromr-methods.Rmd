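---
title: "Models and methods behind sexchromr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexchromr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexchromr)
```

# Scope

`sexchromr` implements the computational chain used to characterise a
young X/Y chromosome pair from a female reference genome and genetic
crosses: anchoring genetic-map markers to the assembly, Marey-map
construction and segmentation of the recombination landscape,
reconstruction of Y-linked gametolog coding sequences from pedigree
segregation, codon-level divergence estimation with a per-branch
decomposition, allele-specific expression bias, and windowed genome
composition scans.  Because the real sequencing data behind such studies
are far beyond desk scale, every analysis stage is paired with a forward
simulator that generates inputs with the same statistical structure and
records the ground truth, so each stage is validated by parameter
recovery rather than by re-processing raw reads.

This vignette documents the models, the defaults and why they were
chosen, the numerical decisions, and what the simulations do and do not
establish about real data.

# Marker anchoring and Marey maps

Genetic-map markers derived from transcriptome sequencing are located in
the genome by local alignment.  `anchorMarkers()` keeps hits with
identity strictly above 97% and alignment length strictly above 100 bp;
because a transcript marker typically yields one hit per exon, all
passing hits of a marker on its modal chromosome are collapsed to the
minimum start coordinate, which marks the gene start.  Where a marker
has passing hits on several chromosomes, the chromosome with the most
passing hits wins, with summed alignment length as tie-break; this rule
is a package decision, made because multi-chromosome markers are rare
and genuinely ambiguous ones should not anchor anywhere.

A Marey map plots genetic position (cM) against physical position (bp);
its local slope is the recombination rate.  Raw transcriptome-derived
maps contain marker-order noise, so `buildMareyMap()` fits a monotone
non-decreasing curve by isotonic least-squares regression
(`stats::isoreg`), the mildest smoothing consistent with the fact that
genetic distance cannot decrease along a chromosome.  Markers deviating
from the fit by more than a configurable threshold (default 2 cM) are
flagged, never removed — an outlying marker may indicate an assembly
problem, which is information.

`recombinationRate()` slides a window (default 10 Mb, step 2 Mb) along
the chromosome and estimates the rate as the range of fitted cM of the
markers inside divided by their bp span.  The window is deliberately
much wider than the 1 Mb windows used for density scans: a slope
estimate needs enough markers per window, and at a few hundred markers
per chromosome a 10 Mb window is the smallest that keeps most windows
informative.  Windows with fewer than two markers get `NA` and are
interpolated from neighbours for segmentation only.

## Segmentation and boundary refinement

`segmentRegions()` classes windows with rate below 0.25 cM/Mb as
suppressed — the threshold is configurable; 0.25 encodes "approximately
zero" on a scale where active distal recombination runs at ~2 cM/Mb —
and takes the longest contiguous suppressed run covering (or nearest
to) the chromosome midpoint, of at least `min_run` windows, as the
pericentromeric region.  Coarse boundaries come from interpolating the
windowed rate profile to the level halfway between the suppressed level
and the adjacent distal plateau; a window centred exactly on a sharp
rate change has half the plateau rate, so this crossing is unbiased at
window resolution.

Window-level estimates cannot do better than a few Mb, because any
window straddling the boundary mixes the two regimes and because marker
gaps in the rarely recombining centre leave windows empty.  When the
Marey map is supplied, each boundary is therefore refined by segmented
regression on the raw marker cM values around the coarse boundary: a
linear ramp meeting a constant plateau, continuous at the breakpoint,
fitted by least squares over a grid of candidate breakpoints.  On maps
simulated at the package's study-like geometry (370.6 Mb chromosome,
2 cM/Mb distal arms of 25.6 and 15 Mb, 400 markers) this localises both
boundaries to well under 1 Mb for marker noise up to 0.5 cM, where
window-midpoint rules err by 4–8 Mb.  The refinement assumes an
approximately flat plateau; with substantial central recombination the
breakpoint estimate degrades gracefully toward the coarse one.

The pseudoautosomal boundary is reported (`pseudoautosomalBoundary()`)
as the distal-p/pericentromeric boundary, together with the interval
between the last pseudoautosomal and the first sex-linked marker, so
that agreement between the two definitions can be checked rather than
assumed.

# Reconstructing Y-linked gametologs

In a two-generation cross, a Y-linked variant is transmitted from
father to every son and to no daughter.  `classifySites()` applies this
segregation rule to per-site allele depths: the mother must be
homozygous (minor-allele fraction below 0.1, a sequencing-error floor),
the father must carry a second allele B absent from the mother, every
genome-sequenced son with depth ≥ 5 must carry B, and no daughter with
depth ≥ 5 may carry B — one carrying daughter is a hard reject.  An
allele counts as *carried* with ≥ 2 supporting reads making up ≥ 5% of
the site depth, so isolated sequencing errors cannot toggle a call.
For transcriptome-sequenced sons the rule is relaxed to 80% of
informative sons, because Y copies are less expressed than their X
gametologs and can drop out of RNA data entirely; the tolerance (20%)
and the RNA-specific path exist precisely so that Y-silenced genes do
not silently lose their diagnostic sites.  At least 80% of progeny must
be informative at the site, and in multi-family data the rule must hold
in every informative family.

`partitionReads()` then assigns read pairs: a pair is Y when every
diagnostic site it overlaps shows the Y allele (at least one site), X
when every site shows the X allele, ambiguous on conflict or third
alleles, and uninformative without overlap; a mate inherits its pair's
bin.  `buildConsensus()` piles up Y-assigned reads over the coding
sequence and calls the majority base where depth ≥ 3 and the majority
fraction exceeds one half; ties and low-depth positions become `N`.
Consensus-over-known-CDS replaces de-novo assembly of Y reads: the goal
is the Y gametolog coding sequence for divergence analysis, coding
coordinates are known from the X gene models, and repetitive non-coding
regions are excluded anyway.

Because nearly every read pair in a diverged gene overlaps some
diagnostic site, positions far from any Y-SNP are rare; they surface as
`N` runs and are masked from divergence counting, which keeps the
consensus-based dS estimate essentially unbiased at the divergences the
package targets (2–15%).

# Codon substitution model

`ng86()` implements the Nei–Gojobori (1986) unweighted pathway method.
Synonymous sites are counted per codon as one third of the synonymous
single-base changes, with changes creating stop codons counted as
nonsynonymous so that S + N equals three per codon exactly; sites are
averaged over the two sequences.  Differences at multiply-substituted
codons are averaged over all minimal mutational pathways that avoid
stop codons (falling back to all pathways when none avoids them), and
proportions are corrected with the Jukes–Cantor transform
d = −(3/4)·ln(1 − 4p/3).  A proportion at or beyond 3/4 raises a
saturation error rather than returning a fabricated distance.  The
pathway table is verified in the test suite against an independent
brute-force enumeration over all orderings for all 61 × 61 sense codon
pairs.

NG86 with Jukes–Cantor correction stands in for maximum-likelihood
branch models: at divergences of ~0.12 and below the two agree closely,
and the counting estimator is self-contained and exactly testable.
Branch-specific rates come from the additive three-point decomposition
(`branchDecompose()`): on ((X,Y),outgroup),
b_X = (d_XY + d_X,OG − d_Y,OG)/2 and so on, separately for the
synonymous and nonsynonymous classes, clamped at zero; per-branch
ω = dN_b/dS_b is reported as `NA` (never 0 or ∞) when dS_b is zero.
Shared-branch noise cancels in the decomposition, so the Y-branch
estimate is driven by Y-branch substitutions only.  Since per-gene ω is
a ratio of noisy counts, across-gene means carry a small Jensen-type
upward bias (about +0.02 at 500 codons and the package's default
divergences); consumers comparing regions through the paired test
(`pairedOmegaTest()`) are unaffected because the bias is shared.

`codonAlign()` aligns triplets in a frame-preserving way: translate,
globally align peptides (Needleman–Wunsch, BLOSUM62, affine gaps via
`Biostrings::pairwiseAlignment`), back-thread to codons, and mask gap
or ambiguous codons from counting.  Genes whose frame contains internal
stops are skipped.  Universal genetic code only.

# Expression bias

Expression input is allele-resolved counts — from the simulator or from
diagnostic-SNP read assignment — not a full quantifier.  After
counts-per-million normalisation, `biasSummary()` reports per-gene
female:male log2 bias of total (X+X vs X+Y) expression and the Y share
of male expression; `xyExpressionTest()` is a two-sided paired t-test
of X against Y copy CPM within males, and `regionBiasCompare()` runs
Welch two-sample t-tests of log2 bias between regions (Welch because
region variances genuinely differ when Y degeneration differs).  For a
gene whose Y copy is expressed at a fraction δ of one X copy, the
expected log2 bias is log2(2/(1+δ)); the simulator's recovery tests
check exactly this analytic limit.

# Genome composition scans

`densityWindows()` uses the printed 1 Mb window / 0.2 Mb step scheme,
counting gene starts per window (genes/Mb) or percent of window bp
covered by merged intervals (TE%).  `compareChromosomes()` tests the
focal chromosome's window values against each autosome with the
two-sided Mann–Whitney–Wilcoxon test and Holm step-down adjustment
across comparisons.  Overlapping windows are autocorrelated, and the
rank tests treat windows as exchangeable units, exactly as the printed
analysis does; a non-overlapping scheme (step = window) is available
for conservative testing.

# The simulators

`simulateGametologTriplets()` evolves a random stop-free ancestral CDS
along ((X,Y),OG).  A proposal picks a uniform site and a uniform
alternative base and is accepted with relative rate 1 if synonymous, ω
if nonsynonymous, 0 if it creates a stop.  The proposal count per
branch is set analytically so the expected number of accepted
synonymous events equals the target dS times the ancestral synonymous
site count — per-gene divergence stays stochastic, as in real data,
rather than being rejection-forced to the target.  The X and Y branches
each carry half the X:Y target; the outgroup branch carries the
remainder of the X:outgroup target.  Realized per-branch event counts
are recorded as truth.

`simulateCross()` builds a family in which the father carries the
reference X and the Y haplotype, the mother two X haplotypes (one with
extra neutral heterozygous SNPs at 0.002/bp), sons Y plus a maternal X,
daughters the paternal X plus a maternal X.  Paired-end reads
(150 bp, 400 bp inserts, flat 0.002 per-base error) are drawn per
haplotype; site observations and the read–site overlap table are
derived from those same reads, so alignment is by construction and the
pipeline runs without an external aligner, while FASTQ and a minimal
VCF 4.2 (`GT:AD:DP`) writer are provided for interoperability.  The
default design is two parents, 5+5 genome-sequenced F1 at 20×, and
25+25 transcriptome-sequenced F2 whose Y-copy depth is scaled by the
gene's Y expression — the coverages are stand-ins chosen as typical for
such crosses, since the underlying study designs rarely print them.
RNA-scaled Y depth is what exercises the classifier's dropout
tolerance.

`simulateGeneticMap()` integrates a piecewise-constant rate function
(distal arms at 2 cM/Mb, centre at 0 by default, geometry 25.6 Mb +
330 Mb + 15 Mb on a 370.6 Mb chromosome) and adds Gaussian cM noise
(default 0.25 cM); markers are placed with density proportional to rate
plus a floor of 0.25 cM/Mb-equivalent, so the rarely recombining centre
is sparsely but non-trivially covered — with no floor at all, boundary
estimation would be limited by multi-Mb marker gaps, which real
transcript-derived maps do not show because genes exist in
pericentromeric regions too.  The emitted hit table contains passing
hits at the true positions, extra higher-start exon hits, and
controlled proportions of sub-threshold hits to exercise the anchoring
filters.

`simulateExpression()` draws negative-binomial counts (dispersion 0.1)
per allele copy with lognormal gene-level means, two X copies for
females, X plus δ-scaled Y for males, and a common library size —
equal-depth libraries keep the analytic bias limits exact; real
libraries vary in depth, which CPM absorbs.

## What the simulations do not show

The generators emulate the statistical structure the analyses rely on,
not sequencing reality: no indels or structural variants, no
recombination within genes, a flat error profile with no quality-score
structure, no mapping ambiguity (alignment is by construction), no
reference bias, and codon-level evolution without rate heterogeneity
among sites or lineages.  Passing recovery tests therefore demonstrates
that the estimators are correct and well-calibrated under their stated
assumptions — not that those assumptions hold in any particular real
data set.  In particular, real Y reconstruction contends with
paralogous mapping and repeat-rich flanks that the simulator never
produces.

# Numerical and design notes

* Coordinates are 0-based half-open internally; 1-based inclusive in
  all text formats (hit tables, VCF).
* All randomness flows from the caller's RNG (`set.seed`); identical
  seeds give byte-identical outputs, including FASTQ.
* Ties in consensus calling yield `N`; ties in modal-chromosome
  anchoring resolve by summed alignment length, then name order.
* ω is `NA` whenever the corresponding dS is zero.
* Degenerate paired tests (all differences zero) report t = 0, p = 1
  instead of erroring.
* Problem sizes in the tests (e.g. 150 genes × 500 codons for
  divergence recovery, 400 markers for segmentation, 25 samples per sex
  for expression) were chosen as the smallest sizes at which the
  recovery tolerances are comfortably non-trivial — large enough that
  sampling noise does not dominate the quantity under test, small
  enough to run on a laptop in minutes.

# Known limitations

The branch decomposition assumes additive distances; for very short Y
branches with ω ratios of small numbers, per-gene ω is unstable (the
package reports it as `NA` only when dS is exactly zero, and leaves
outlier handling to the aggregation step, which reports per-statistic
n).  The segmentation assumes a single central suppressed region per
chromosome; chromosomes with several suppressed blocks report only the
run covering the midpoint as pericentromeric.  The classifier requires
the mother to be homozygous at a site, so Y-SNPs coinciding with
maternal heterozygosity are unrecoverable by design — in simulations
this is bookkept by the truth table, in real data it costs a small,
divergence-independent fraction of sites.
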