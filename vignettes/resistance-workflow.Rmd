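---
title: "Methods: dose-response, synergy, fusion detection and copy-number analysis in metresist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response, synergy, fusion detection and copy-number analysis in metresist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metresist)
```

`metresist` implements the computational workflow used to characterise a
cell-line model of acquired resistance to a targeted kinase inhibitor: how
resistant the cells are (dose-response), whether a drug combination defeats
the resistance (Bliss synergy), what genomic lesion causes it
(fusion-transcript detection from RNA-seq read pairs, copy-number
segmentation), and the matrix preprocessing used for protein-array
readouts. Every stage has a matching synthetic-data generator with recorded
ground truth, so each analysis can be validated as a recovery experiment.
This vignette documents the models, conventions and numerical choices.

## Viability and dose-response

Raw plate counts are converted to tumour-cell growth inhibition (TGI)
after baseline adjustment: with $b$ the mean of the day-1 (seeding-time)
untreated wells and $u$ the mean of the endpoint untreated wells,

$$\mathrm{TGI}(x) \;=\; 1 - \frac{x - b}{u - b}.$$

TGI is 0 for a well growing like untreated cells, 1 at growth stasis
(endpoint signal equal to the seeding baseline), above 1 for net cell kill
and below 0 for growth stimulation. The cytotoxic (>1) and stimulated
(<0) tails are retained in dose-response fitting but clipped to $[0,1]$
before Bliss arithmetic, which requires probabilities. A plate whose
adjusted untreated signal $u-b$ is not positive is rejected as degenerate
rather than producing sign-flipped scores.

Dose-response curves use the four-parameter logistic in its
rising-with-dose form,

$$\mathrm{TGI}(x) \;=\; L + \frac{U - L}{1 + (\mathrm{IC}_{50}/x)^{h}},
\qquad h > 0,$$

with the IC50 defined at the inflection (relative IC50), so the fitted
curve passes through $(L+U)/2$ exactly at $x=\mathrm{IC}_{50}$. Fitting
minimises squared error with the IC50 parameterised on the log10-dose
scale, under box constraints $L \in [-0.5, 1]$, $U \in [0, 1.5]$,
$h \in (0, 10]$ and IC50 between the lowest dose / 100 and the top dose
× 100, from three deterministic starting points (half-effect crossing,
dose-range midpoint, one decade below the top with a steeper slope). The
multi-start is cheap and makes the fit reproducible without stochastic
restarts; replicate wells are averaged (unweighted) before fitting, since
no replicate-variance model is attempted.

Two situations are reported as a censored bound rather than a number, in
the field's "> top dose" style: a fitted span $U-L$ below `min_span`
(default 0.2 TGI units — below that the curve carries no usable
inflection) and a fitted IC50 beyond the top tested dose. The reported
bound is the top dose of the ladder. The recovery tests require noiseless
refits to return the generating IC50 within 0.1%, and plates with 5% well
noise to recover it within 10% on average over 20 seeds.

Dose ladders are plain geometric series (`top / fold^(i-1)`); the standard
designs are nine 4-fold steps from 10 µM (bottom ~153 pM) and five 4-fold
steps from 10 µM (bottom ~39 nM). Concentrations are carried in molar
throughout and only formatted to pM/nM/µM for display, avoiding unit
mix-ups between stages.

## Bliss independence and ΔBLISS

For single-agent inhibitions $A$ and $B$ (clipped to $[0,1]$), the Bliss
expectation is $E = A + B - AB$, and the synergy score of a combination
cell is $\Delta = \max(0,\; \mathrm{obs} - E)$: 0 for additivity, 1 for
maximal synergy. The subtraction order is fixed by the score's defined
range (0 additive → 1 synergistic); the unfloored signed excess is kept in
a companion matrix so antagonism (negative excess) remains visible. The
single-agent inhibitions entering $E$ are the measured zero-dose edges of
the same plate, not fitted curves — the edges are the experiment's own
single-agent assay.

The "maximal synergy" dose window takes the largest upper-right block of
the dose grid in which every cell reaches at least 90% of the maximal
ΔBLISS and reports its boundary as exclusive lower bounds — the highest
tested dose *below* the block, the convention behind statements like
"maximal synergy above 39 nM of drug A". When several blocks qualify, the
one covering the most grid cells (then the lower drug-A bound) is chosen.
An all-additive surface returns an empty window.

The combination simulator supports three interaction models: exact Bliss
additivity; a *rescue* model (flat single agents, full response above
configurable dose gates) emulating a resistant clone killed only by the
combination — which by construction drives ΔBLISS to its ceiling of 1 —
and a mild antagonism model (`0.8 · max(A,B)`) used to exercise the signed
excess. The rescue model is a deliberately stylised artifact: it generates
surfaces with known ΔBLISS structure and says nothing about the biology of
why a combination works.

## Fusion detection from paired-end reads

The fusion workflow runs entirely in transcript coordinate space (1-based,
inclusive, sense strand): reads are mapped to a wild-type transcript set,
discordant pairs nominate a partner pair, supporting reads are assembled,
and the junction is localized by exact matching.

**Mapping.** The mapper is intentionally toy-scale, sufficient for
error-free or low-error synthetic libraries: exact 20-mer seeds taken from
both ends of each read are looked up in a k-mer index, and each candidate
placement is extended without gaps, soft-clipping whatever does not match
(the best contiguous block scores matches +1 / mismatches −3 and must keep
its mismatch rate below 4%). Any read with at least 20 contiguous bases on
one side of a junction is seeded by at least one of its two end seeds, so
junction-spanning reads map to one partner with a clipped tail. Both
orientations are tried and mate 2 is normalised to the transcript's sense
strand. A read keeps its unique best placement; ties across locations are
flagged multi-mapped and excluded from pair counting (tallied separately),
as are unmapped mates. Pre-aligned input in a minimal SAM dialect (`@SQ`
header; QNAME/FLAG/RNAME/POS/MAPQ/CIGAR with M and S operations only) can
substitute for the built-in mapper.

**Discordant pairs.** A chimeric pair has its two mates uniquely mapped to
two different transcripts. Counts per unordered transcript pair, sorted
descending, nominate the fusion candidate; wild-type-only libraries must
produce zero chimeric pairs (error-free reads), which the specificity
tests enforce.

**Assembly.** Supporting reads (both mates of every chimeric pair, plus
soft-clipped reads on the candidate partners) are assembled with a minimal
de Bruijn strategy: k-mers (default k = 31) form a graph whose maximal
unambiguous paths are emitted as contigs. Because all input reads are
sense-normalised and come from one junction neighbourhood, error-free
input yields a single contig reconstructing the region. No coverage-based
tip/bubble cleaning is attempted — with error-free defaults there are no
tips or bubbles; with `error_rate > 0` the assembler is exercised only in
stress tests.

**Junction localization.** The contig is split into a prefix exactly
contained in the 5′ partner and a suffix exactly contained in the 3′
partner, maximising total matched length with at least 25 anchoring bases
per side. Substring containment is monotone in the split position, so the
optimum is found by two binary searches rather than scanning every split;
a property-based test checks exact agreement with the brute-force
all-splits oracle. When junction-flanking bases are shared by both
partners the split slides without changing the fusion sequence: the
5′-most split is reported, along with the `homology_interval` giving the
number of equivalent alternatives. Coordinates are reported as J5 (last
retained base of the 5′ partner) and J3 (first retained base of the 3′
partner), so the fusion sequence is `prefix(tx5, J5) + suffix(tx3, J3)`
and its length is `J5 + (L3 − J3 + 1)`.

**Reading frame.** Given CDS annotations, the junction is in frame when
the retained 5′ coding length `J5 − cds_start5 + 1` and the skipped 3′
length `J3 − cds_start3` are both whole codons; the fusion protein then
spans residues 1 to `(J5 − cds_start5 + 1)/3` of the 5′ partner and
`(J3 − cds_start3)/3 + 1` to the annotated end of the 3′ partner. The
synthetic annotation places the CDS offsets so the canonical architecture
(J5 = 2006, J3 = 1202) is in frame with a 593 + 386 residue product.

**Coverage.** RBM (reads per base per million reads) is per-base coverage
× 10⁶ / total library reads — total reads, not mapped reads, so the
normaliser is independent of mapping quality. Region folds are ratios of
mean RBM over an interval with a pseudocount (default 0.1 RBM) guarding
empty regions; the acceptance-style fold comparisons use pseudocount 0.

## Copy-number segmentation

Probe-level log2 ratios are segmented by recursive binary segmentation: the
split minimising within-segment squared error is accepted when its cost
reduction exceeds a BIC-style penalty $2\hat\sigma^2\log n$, with
$\hat\sigma$ estimated from the median absolute successive difference
divided by 0.954 — successive differencing cancels the piecewise-constant
mean and the median resists inflation by the true jumps. Segments keep at
least 5 probes; a numerically tiny penalty floor prevents float noise from
splitting exactly-constant tracks. Noiseless piecewise-constant tracks are
recovered exactly.

Fold change is $2^{\overline{\log_2}}$, so a log2-ratio-2 segment is a
4-fold amplification. Under probe noise, binary segmentation occasionally
represents one amplified region as two adjacent elevated segments;
`amplified_regions()` therefore merges consecutive segments with fold ≥ 2
(halfway in log space between neutral and 4-fold) and reports the
probe-weighted mean — the readout a copy-number analyst would quote for
the region.

Breakpoints between adjacent segments are placed midway between the
flanking probes. A breakpoint strictly inside a gene span is reported with
the exons immediately 5′ and 3′ of it in transcription order (strand
aware: flipping the strand swaps which genomic exon plays the 5′ role); a
breakpoint exactly on an exon edge belongs to the adjacent intron, and one
inside an exon body is flagged `in_exon`.

## Protein-array preprocessing

Analyte × sample intensity matrices are median-centered per analyte (axis
exposed, since centering per sample is equally defensible) and clipped
into the conventional $[-3, 3]$ heatmap display range. The range operation
is saturation, not affine rescaling: the bounds are display-oriented, and
clipping keeps in-range values — and therefore their contrasts — exactly
as centered. It is idempotent by construction.

## What the synthetic data does and does not emulate

The generators reproduce the *structure* of the study's data: 75-base
paired-end reads with ~250 ± 30 inserts drawn from transcripts in
proportion to molar abundance × effective length; sigmoidal viability with
multiplicative lognormal well noise (unit mean, configurable CV);
checkerboard combination matrices with zero-dose edges; piecewise-constant
log2 tracks with Gaussian probe noise. Error-free reads are the default:
the statistics under test (pair counts, junction coordinates, coverage
folds) concern fusion evidence, not aligner robustness; a uniform
substitution `error_rate` exists for stress tests only. Not modelled:
base-quality scores, positional/GC coverage bias, PCR duplicates, spliced
genomic alignment, array probe-affinity effects, plate spatial artifacts.
Consequently, passing recovery tests demonstrates correctness of the
statistics on clean data of realistic shape — not performance on real
libraries.

Two generator choices deserve explanation:

* **Background transcript.** The read simulator's study conditions include
  a transcriptome-like background transcript at high abundance alongside
  the two fusion partners. In a real library the partner transcripts are a
  tiny fraction of reads, so adding a fusion barely changes the
  denominator of the per-million normalisation. In a minimal three-
  transcript library the fusion's own mass dilutes everything and a
  20-fold region excess is arithmetically unreachable (the achievable fold
  tops out below 2). The background restores the real-data regime.
* **Calibrated fusion abundance.** Expected interior per-base coverage of
  a transcript is proportional to its molar abundance (fragments ∝
  abundance × effective length; per-base coverage ∝ fragments / effective
  length). `calibrate_fusion_abundance()` solves exactly, including the
  dilution term, for the fusion abundance whose expected retained-region
  RBM fold equals a stated target, so simulated folds are predictable from
  first principles rather than tuned.

## Problem sizes and reproducibility

The test suite runs its recovery experiments at deliberately modest sizes —
a few thousand read pairs for end-to-end fusion recovery, 50,000 pairs per
library for coverage folds, 480-probe tracks over 20 seeds — sizes at
which the statistics under test are already stable. The acceptance script
(`scripts/acceptance.R`) uses 20,000 pairs for junction recovery and
200,000 pairs per library for the coverage fold. Every stochastic step
takes an explicit seed; all generators are deterministic given one, and
the pipeline report is bit-reproducible under a fixed seed.

## Known limitations

* The mapper has no gapped or spliced alignment and assumes low divergence;
  it is not a replacement for a production aligner on real data, and the
  minimal-SAM entry point exists precisely so external alignments can be
  substituted.
* The assembler resolves one junction neighbourhood at a time; repetitive
  sequence shared between partners beyond the homology interval, or
  multiple co-expressed fusion isoforms, are out of scope.
* Binary segmentation reports no per-breakpoint significance (no
  permutation p-values); the penalty controls the expected false-split
  rate only loosely.
* IC50s are relative (inflection) IC50s; no absolute-IC50 or GI50/LC50
  decomposition is attempted.
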