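---
title: "Motif-anchored footprint profiling of ChIP-exo data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-anchored footprint profiling of ChIP-exo data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exofootprint)
library(GenomicRanges)
```

## The signal and the model

ChIP-exo adds a lambda exonuclease digestion step to chromatin
immunoprecipitation: the enzyme chews 5'→3' along each strand until it is
blocked, and a protein cross-linked to the DNA is such a block. The 5'-most
base of a sequenced read therefore marks a *boundary of protection* at near
base-pair resolution. Around a genuinely bound recognition sequence this
produces a characteristic strand-specific signature: a pile-up of
forward-strand 5' ends a fixed distance upstream of the protein, and a
mirror pile-up of reverse-strand 5' ends the same distance downstream — a
*coherent peak-pair*. Published estimates place the exonuclease stop 5–6 bp
upstream of the protein:DNA cross-link point, so the peak-pair spacing
reads out cross-link geometry, e.g. one cross-link per monomer of a
dimeric factor.

`exofootprint` operationalizes this as follows:

1. **Scan** bound regions (ChIP-seq peaks) for motif matches, either with a
   position weight matrix (PWM) at an exact match p-value threshold, or
   with a degenerate IUPAC consensus constrained at selected positions.
2. **Index** read 5' ends per chromosome, strand and base.
3. **Extract** a window of `flank` bp beyond each motif match,
   orientation-normalized to the motif strand (minus-strand sites are
   position-reversed and strand-swapped), into a sites × positions ×
   strand matrix.
4. **Aggregate** the matrix into a footprint profile (per-position sums for
   each strand) and compare it against profiles obtained with
   column-permuted motifs.

All coordinates are handled as `GRanges` (1-based, closed) inside R; BED
input and output is converted at the boundary, so files on disk follow the
0-based half-open BED convention.

## Motif scores and exact match p-values

A PWM column holds base probabilities after pseudocount regularization: a
total pseudo-mass of 0.01 per column (split by background frequency) is the
default, which keeps log-odds finite without visibly distorting
well-determined columns. A window of the motif length scores
$\sum_i \log_2(p_i(b_i)/q(b_i))$ against the background $q$ (uniform by
default, overridable by a genome-composition estimate).

The threshold for a match p-value $p$ is computed *exactly*: per-column
log-odds are snapped to a lattice of $10^{-3}$ bits and the full score
distribution under i.i.d. background is obtained by dynamic programming
(convolution over columns). The scanner compares window scores on the same
lattice, so "score ≥ threshold" and "background tail mass ≤ p" agree
without Monte-Carlo error; tests verify the tail against exhaustive
enumeration of all $4^L$ sequences for small $L$. The lattice rounding
perturbs any single score by at most $L/2 \times 10^{-3}$ bits, negligible
against per-column log-odds of order 1.

Degenerate consensus scanning is exact string matching: *constrained*
positions must match their IUPAC code, *anti* positions (the
"strike-through" bases of an in-silico mutated consensus) must mismatch it,
and all other positions are free. The 15-bp glucocorticoid receptor
binding sequence `nGnACAnnnTGTnCn` used throughout the examples is
self-complementary at its eight constrained positions, so every match is
found on both strands at the same coordinates — consensus scans therefore
report all matches and leave overlap handling to the caller, whereas PWM
scans resolve overlapping same-motif hits greedily (higher score wins,
plus strand on ties) to avoid double-counting reads in profiles.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p` | 1e-4 | PWM match p-value (exact background tail) |
| `flank` | 30 bp | window beyond the motif ends; single-factor footprints span roughly 30 bp around the recognition sequence |
| `n_perm` | 50 | column permutations for the null; resolves empirical p-values down to 1/51 ≈ 0.02 at desk-scale cost |
| `min_mapq` | 1 | BAM mapping-quality filter |
| `dedup` | FALSE | exonuclease stops legitimately stack at identical 5' positions, so deduplication would erase signal; exposed for degenerate libraries |
| `pseudocount` | 0.01/column | PWM regularization |
| `k`, `n_init` | 4, 10 | k-means clusters and restarts |

## The permutation control and the coverage p-value

For each of `n_perm` seeded column permutations (the identity permutation
is rejected and resampled — an unshuffled control is not a control), the
regions are rescanned at the same match p-value. The background score
distribution is invariant under column permutation, so the same threshold
applies and match abundance stays comparable. Each permuted hit set yields
a profile normalized to mean coverage per site per position; the envelope
(median and interquartile range per position) is drawn under the observed
profile, and the *coverage p-value* compares the observed total normalized
coverage against the permuted totals with the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$, which is never
0 and never exceeds 1. Motif libraries are ranked by ascending p-value,
then descending enrichment (observed over median null); a motif with zero
matches is flagged and ranked last. A machine-readable *coherence* flag
records whether the forward-strand maximum lies strictly left of the
reverse-strand maximum. No multiple-testing correction is applied by
default — the analysis ranks motifs, it does not threshold them — but
Benjamini–Hochberg adjustment is available.

Two properties of this control are worth knowing. First, a permuted motif
that happens to match *inside a bound region* near the true site captures
real footprint reads, which makes the null conservative; this is by
design — composition-matched nulls should be allowed to sit in bound
chromatin. Second, if many binding sites are textually *identical*, a
column permutation compatible with a shifted copy of that one sequence
matches every site at once and can reach observed-level coverage. Real
binding sites are heterogeneous draws from the motif, which breaks this
degeneracy; the simulator's `plant = "sample"` mode reproduces that
heterogeneity and is the setting under which ranking is validated.

## The simulator and what it does (not) emulate

`sim_config()` describes a single-chromosome i.i.d. background genome with
non-overlapping peaks and one motif instance planted at each peak center on
a random strand. Reads are generated per site: each read draws a
cross-link offset and protected strand from a weighted mixture (mirrored
for minus-strand sites), draws an exonuclease stop distance (default 5–6
bp, uniform), places its 5' end that distance *upstream of the cross-link
on the protected strand's own 5'→3' axis* (smaller coordinate on the
forward strand, larger on the reverse), and extends 3'-ward. Uniform
background reads are added at `background_rate` per bp. Every read carries
a truth record (originating site, offset, stop).

Defaults are chosen as realistic study conditions and then left alone:
peaks are 200 bp wide — a typical ChIP-seq peak span, and deliberately
much wider than the motif, because in motif-sized peaks every chance match
of a permuted motif would sit on top of the true footprint and the control
would be meaningless; 500 peaks; 20 reads per site (Poisson); background
0.001 reads/bp; read length 36; cross-link mixture with a dominant outer
pair at ±8 bp (70%) and a minor inner pair at ±3 bp (30%), echoing the
nested peak-pairs expected when either of two monomers of a dimeric factor
cross-links. With symmetric offsets ±c and fixed stop s, the aggregated
forward-strand profile peaks at $-(c+s)$ and the reverse at $+(c+s)$
exactly; this closure property pins down every sign convention in the
package and is asserted in the tests.

The simulator does **not** model sequencing errors, mappability, PCR
duplication, fragment-length variation, nucleosomes, or cooperative/tethered
binding. Passing tests on simulator output therefore demonstrates the
correctness of the bookkeeping (coordinates, strands, orientation
normalization, statistics) and the behaviour of the method under its own
generative assumptions — not performance on real libraries with their
position-dependent biases.

## Numerical and design choices

* **Anchor**: the site anchor is `start + floor(L/2)` on the forward
  genome, and relative coordinates are motif-oriented. For odd motif
  lengths the window is symmetric and the pipeline is exactly invariant
  under reverse-complementing the genome and mirroring reads; for even
  lengths the mirrored anchor shifts by one base (the center falls between
  bases) — profiles remain internally consistent but even-length mirror
  runs are offset by 1 bp.
* **Overlapping site windows** each receive full counts; no read ownership
  is assigned. Footprints are per-site quantities.
* **Windows containing N** are skipped rather than scored (log-odds would
  be undefined).
* **Zero-hit permutations** contribute an all-zero profile and are flagged
  in the log, keeping the envelope defined.
* **Heatmap row order** is descending total window count ("most occupied"
  first), matching how top sites are selected for clustering.
* **k-means** runs on the concatenated forward+reverse rows, each site
  vector scaled to unit total by default so occupancy does not dominate
  shape; `stats::kmeans` (Hartigan–Wong) with seeded restarts provides the
  optimization and does not produce empty clusters. With one-sided
  cross-linking, sites bound in opposite orientations produce mirror-image
  vectors and are separated essentially perfectly at k = 2.
* **Determinism**: every stochastic step takes a seed; pipeline runs derive
  all sub-seeds from one master seed recorded in the manifest, so a rerun
  with the same manifest is bit-identical.

## Validation problem sizes

The test suite validates against brute-force oracles (naive rescoring,
nested-loop recounts, exhaustive sequence enumeration) on small instances,
and against planted truth on moderate ones: 2,000 sites for footprint
geometry, 200 replicate null simulations (n_perm = 50) for coverage
p-value calibration, 20 replicate runs for ranking discrimination against
5 permuted decoys, 500 sites for orientation clustering, and 1,000
seeded 505-site subsamples for the unbiasedness of `subsample_profile()`.
These sizes give the binomial/KS bounds used in the tests comfortable
power while keeping a full run at desk scale.

## Known limitations

* The coverage statistic is the whole-window, both-strand total; a
  center-weighted variant may discriminate better for very wide windows
  but is not the default.
* Empirical p-values saturate at 1/(n_perm+1); ranking many strong motifs
  may produce ties resolved by enrichment.
* Paired-end input is treated as independent single-end reads (with a
  warning); ChIP-exo libraries are typically single-end.
* Scanning is restricted to supplied regions; whole-genome scans are out
  of scope.
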