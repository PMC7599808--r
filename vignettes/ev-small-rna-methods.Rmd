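---
title: "Methods: small RNA profiling of stem cells and their EVs"
author: "evsmallrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling of stem cells and their EVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evsmallrna)
```

## The analysis problem

Mesenchymal stem cells (bone-marrow derived BMSCs and adipose derived
ASCs) secrete extracellular vesicles (EVs) whose small RNA cargo differs
sharply from the parental cells: cells are dominated by ~22 nt miRNAs,
while EVs carry a large population of tRNA-derived small RNAs (tsRNAs) —
halves of 30–40 nt produced by cleavage in the anticodon loop of mature
tRNAs, and shorter fragments of 17–26 nt. During osteoblastic
differentiation (day 0 to day 7 of induction) both the class composition
and the per-feature expression of this cargo change. The package
implements the complete downstream analysis of such an experiment —
2 cell types × {cells, EVs} × {D0, D7} × 3 donors — as tested R code,
validated end to end on simulated reads with known ground truth and on
the published result tables shipped as text fixtures.

## The annotation cascade

Reads are assigned hierarchically, each read to the first stage with any
hit:

1. **tRNA**, ungapped end-to-end, at most 1 mismatch;
2. **miRNA**, 0 mismatches, tolerating an untemplated 3′ tail of 1–3
   A/T bases (miRNAs carry enzymatic 3′ A/U additions that are absent
   from the reference);
3. **rRNA**, **mRNA**, **other small RNA**, **genome**, each at most 1
   mismatch.

Putting tRNA first keeps tRNA halves — which can contain miRNA-length
subsequences — from being absorbed by later classes. The miRNA stage
uses a smallest-tail rule: the shortest tail length `t` such that the
read minus its last `t` bases matches a mature miRNA exactly. A terminal
A/T that continues the template is therefore counted as templated, never
as a tail. Within a stage, ties are resolved deterministically: fewest
mismatches, then smallest reference start, then lexicographically
smallest reference name; each read is counted exactly once (no
fractional multi-mapping — the tie rule is this artifact's documented
choice). Alignment is ungapped and sense-strand only, which is adequate
because small RNA reads derive from the annotated strand of mature
transcripts; the genome stage is represented by decoy sequences in the
synthetic setting, with identical cascade semantics to a real genome
backend. The inner matcher is compiled (Rcpp) and is verified in the
test suite against an exhaustive R enumeration of every
stage/reference/offset/tail combination.

## tsRNA typing

A tRNA-mapped read of length ≥ 30 anchored within 1 nt of the 5′ end is
a 5′ half; anchored within 1 nt of the 3′ (CCA) end, a 3′ half. The 1 nt
anchor tolerance accommodates ragged ends; strict 0-only anchoring is
brittle and nothing in the source material mandates it. Reads of 17–26
nt are fragments. The published classes do not tile the 27–29 nt range;
those reads are classified as fragments (operationally "shorter than
30 nt"), and reads ≥ 30 nt anchored at neither end are flagged
`nonstandard`. Isoacceptor tables report counts and percentages of all
tRNA-mapped reads with a majority-vote dominant type (ties prefer
halves). Coverage profiles accumulate per-position depth and a
100-percentile-bin meta-profile across tRNAs of different lengths; raw
depth is reported (the published coverage figure does not state a
normalisation; per-position depth divided by library size can be derived
trivially from the output).

## Differential expression

The DE engine is a deliberately transparent negative-binomial Wald test,
not a call to an existing DE package, so that every reported number is
reproducible by hand:

- **Size factors**: median-of-ratios over features with positive counts
  in every sample, rescaled to geometric mean 1. The test suite checks
  them against DESeq2's implementation (an independent oracle, never the
  implementation) to 1e-10.
- **Abundance filter**: features with raw counts below 50 in *every*
  sample are excluded before testing (boundary inclusive: one sample at
  50 keeps the feature).
- **Per feature**: normalized group means μ_D7, μ_D0; a
  method-of-moments dispersion α = max(1e-8, (s² − μ)/μ²) computed on
  the normalized counts of both groups pooled;
  log2FC = log2((μ_D7 + 0.5)/(μ_D0 + 0.5)) (the 0.5 pseudocount keeps
  fold changes finite when one group is zero; positive values mean
  higher at D7); a delta-method standard error from the NB variance of
  the group means; a two-sided p from the normal reference; BH
  adjustment across the tested features of the contrast.
- **Contrasts** run independently within each (cell type, compartment)
  stratum, unpaired across day — four separate contrasts, BH applied
  per contrast and feature level. Donor pairing is not modelled; the
  design reports contrasts separately exactly as the tables do.
- **Significance rules**: miRNAs |log2FC| ≥ 1 and raw p < 0.05; tsRNAs
  BH-adjusted p < 0.05 together with |log2FC| ≥ 1. The raw-vs-adjusted
  asymmetry between the two feature levels is reproduced as published,
  not harmonised.

Two properties of this estimator matter for interpretation. First,
pooling the dispersion across groups (rather than around group means)
makes the test mildly conservative: an observed group difference
inflates the pooled variance, so the null rejection rate at p < 0.05
sits near 0.02–0.04 for 3 vs 3 samples rather than exactly 0.05, and
p-values are approximately but not perfectly uniform (KS distance
~0.04–0.09 at 500 features). Second, there is no dispersion shrinkage
toward a fitted trend, so per-feature fold-change estimates are unshrunk
and exact replication of published per-miRNA log2FC values (which came
from the deposited raw sequencing data) is explicitly out of scope; the
test instead demonstrates recovery of planted effects (log2FC = 2 at
mean 1000 recovered within ±0.2).

## The read simulator

The simulator is first-class, tested code: it defines the conditions
under which the pipeline is validated.

- **References**: random sequences at GC ≈ 0.5, screened so that no
  17-mer (the shortest simulated insert) occurs in two references. This
  makes every read's true class, reference and coordinates recoverable
  without ambiguity, which is what permits exact (100%) recovery
  checks. tRNAs are 73–90 nt, end in CCA, and carry the anticodon of
  their isoacceptor label (Gly-GCC, Val-AAC, …) centred in a 7 nt
  anticodon loop at a realistic position (loop start 30–36).
- **Reads**: miRNA reads are full mature sequences, tailed with 1–3 A/T
  bases with probability 0.25; tRNA halves cut the mature tRNA at a
  uniform position inside the anticodon loop, keep the 5′ or 3′ piece
  (the 3′ piece retains the CCA end) and clamp the free end into the
  30–40 nt window; fragments are internal 17–26 nt substrings;
  background reads are random substrings of the class references.
  Inserts read through into the TruSeq small-RNA 3′ adapter
  (`TGGAATTCTCGGGTGCCAAGG` — the library kit's adapter; the exact
  trimming parameters used in the original study are unstated, so this
  default is recorded as an assumption and is configurable). Qualities
  are a constant Q36 with substitution errors at the configured rate
  dropped to Q12 — a deliberately simple, testable noise model.
- **Study conditions**: per-sample class compositions encode the
  published class percentages — cells ~56–63% miRNA at both days;
  BMSC-EVs 52% tRNA / 10% miRNA at D0 shifting to 14% tRNA / 28% miRNA
  at D7; ASC-EVs 47% tRNA at both days with miRNA 12% → 8% — plus a
  small per-donor log-normal jitter (sd 0.05) standing in for donor
  variability. EV libraries concentrate their tRNA reads on Gly-GCC,
  Glu-CTC and Gly-CCC (cells on Gly-GCC, Val-AAC, Val-CAC), mirroring
  the published isoacceptor dominance, which is what lets unsupervised
  clustering of tsRNA profiles separate compartments.

What the simulator does **not** emulate: per-feature biological day
effects within a feature level (the day effect is a class-composition
effect, which size-factor normalisation removes at the feature level —
so a simulated experiment is approximately null for the DE engine, and
DE power/calibration are validated by dedicated count-level NB
simulations instead); UMIs; paired-end reads; tRNA modification-induced
misincorporations; 5′ isomiR variation; pre-tRNA leader/trailer
fragments. Passing recovery tests therefore demonstrates the
correctness of the pipeline's logic under unambiguous references, not
its accuracy on real, repeat-rich genomes.

Recovery is reported as two distinct quantities: *mapping sensitivity*
(the fraction of reads assigned their true class and reference — 100%
at zero error rate, but bounded above by the mismatch budget once
errors are simulated: a 30–40 nt read carries ≥2 substitutions with
probability ~1% at a 0.5% per-base error rate and then cannot map
anywhere) and *typing accuracy* (the fraction of tRNA-annotated reads
whose half/fragment type matches the simulator's truth, which stays at
~100% because any read that maps at ≤1 mismatch maps at its exact true
coordinates under collision-free references).

## Preprocessing choices

Mean Phred ≥ 20 and N fraction ≤ 0.1 (conventional defaults; the
original processing thresholds are unstated), adapter located by best
overlap of ≥ 10 bases with mismatch rate ≤ 0.1 (fewest mismatches,
leftmost on ties), insert length window 15–45 nt bracketing all species
of interest (17–26 nt fragments, ~22 nt miRNAs, 30–40 nt halves). Reads
with no detectable adapter are retained when already within the window —
discarding untrimmed reads would lose fully-inserted long tsRNA reads —
and dropped otherwise. Every input read lands in exactly one tally
(conservation is asserted in code).

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open throughout. RNA is represented in the
DNA alphabet (U→T), matching sequencer output. PCA uses
log2(normalized + 1) on the 500 most variable features with per-feature
centering (the published transform is unstated; this is the documented
stand-in), and fixes the SVD sign by making the loading of the most
variable feature non-negative, so coordinates are reproducible.
Clustering uses average-linkage on Euclidean distances of the same
transform. All-zero features are reported with NA p-values and excluded
from BH. Empty annotation lists, empty FASTQ files and all-zero
histograms are valid inputs with defined outputs.

## Problem sizes

The shipped analysis scripts simulate 24 libraries of 5,000 reads; the
validation suite uses 12 libraries of 10,000 reads for recovery checks,
500-feature NB simulations for calibration, and 200 reads × 20
references for the exhaustive oracle comparison — sizes at which every
property is exercised while the whole suite stays fast. All simulations
are seeded; identical configurations produce byte-identical FASTQ and
truth tables.

## Known limitations

Ungapped alignment cannot represent indel sequencing errors; the
mismatch budget (≤1) applies uniformly to background and genome stages
(whether the original pipeline did the same is unstated); dispersion is
per-feature method-of-moments with no information sharing, so small
baseMean features have noisy fold-change standard errors; and the
published headline detection counts (e.g. numbers of miRNAs detected
per compartment) derive from the deposited raw sequencing data, which
this package deliberately does not require.
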