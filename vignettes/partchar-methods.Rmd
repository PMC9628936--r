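---
title: "Methods: imaging-based DNA part characterization with tagged long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging-based DNA part characterization with tagged long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partchar)
```

## The measurement problem

Characterizing regulatory DNA parts — promoters and ribosome-binding
sites (RBSs) — means attaching a number to each part that predicts how
strongly it drives expression. The classical route (clone one part, grow
liquid cultures, measure single cells on a flow cytometer) scales poorly.
partchar implements an alternative, high-throughput route:

1. **Combinatorial assembly.** Parts are assembled into a reporter
   circuit by one-pot Golden Gate cloning, so one reaction yields a
   library of part combinations.
2. **Plate-level phenotyping.** Colonies are photographed on the plate in
   two fluorescence channels. The measurement circuit expresses GFP under
   the part combination being measured and RFP from a fixed cassette, so
   the GFP/RFP ratio of a colony is an expression readout normalized for
   colony growth.
3. **Pooled genotyping.** Each picked colony is amplified with a
   forward x reverse pair of 7 bp barcode tags, all amplicons are pooled
   and sequenced as long reads, and reads are demultiplexed back to their
   colony and aligned against every possible construct to call each
   colony's genotype.
4. **Relative units.** Joining phenotype to genotype by colony index
   gives per-part mean intensities, expressed relative to a standard
   circuit as relative promoter units (RPU) or relative RBS units (RRU).

Every stage consumes and produces ordinary tabular data (tibbles and
TSVs), so the pipeline is equally usable as a set of composable functions
or through `run_pipeline()`.

## Colony intensity

For a matched colony the intensity is

$$I = \frac{\bar g \cdot A_g}{\bar r \cdot A_r},$$

where $\bar g, \bar r$ are the mean background-subtracted green and red
channel values over the segmented region and $A_g, A_r$ the region areas
in the two channel images. "Channel value x size" is interpreted as mean
x area, i.e. the *integrated* channel signal, which makes $I$ a ratio of
integrated GFP to integrated RFP; a `stat = "sum"` option computes the
sum directly. Because both channels share the colony's geometry, $I$ is
insensitive to colony size and to any common exposure factor — both
properties are asserted in the test suite.

### Segmentation choices

The detector estimates the background with a large-kernel (radius 31 px)
median filter, subtracts it, smooths with a 1 px Gaussian, thresholds,
labels connected components, declumps touching colonies with a
distance-transform watershed, and filters regions by minimum area
(30 px) and circularity ($4\pi A/P^2 \ge 0.6$).

The default threshold is *noise-based*: 3.5 robust noise SDs (plane MAD)
above the corrected background, with an absolute floor of 8/255. We do
not use Otsu's method by default: Otsu assumes foreground and background
populations of comparable mass, and on a plate where a few bright
colonies dominate the histogram it places the threshold far above dim
colonies, silently dropping them (we observed recall dropping to ~40% on
synthetic plates with a log-uniform brightness spread). Otsu remains
available via `detect_params(threshold_method = "otsu")` for densely
covered plates.

Saturation: pixels at the top of the 8-bit range are counted per region;
regions with more than 5% saturated pixels are flagged and excluded from
part aggregation by default, since a clipped GFP signal biases the ratio
downward.

## Tags and demultiplexing

Tag sets are designed greedily over the $4^7$ candidate space: shuffled
candidates are accepted when they keep a minimum pairwise Levenshtein
distance (Levenshtein rather than Hamming because long-read errors are
indel-rich), contain no homopolymer run longer than 3, and are not
self-complementary. A Hamming sphere-packing bound rejects infeasible
requests up front. The design function defaults to distance 3 — the
textbook choice that tolerates one edit per tag — but the pipeline's own
fixtures use distance 4, which is comfortably feasible for 7-mers and,
at realistic error rates, is what keeps misassignment below 1% (at
distance 3 we measured ~1.1%: badly damaged tag ends occasionally sit
closer to a wrong tag than to their own). 8 forward and 12 reverse tags
address 96 colonies; with 24 device barcodes the capacity is 2304.

Demultiplexing searches each read end, in both orientations, by
semi-global edit distance and assigns a read only when exactly one
declared pair is the strict best match on both ends; every tie is
reported as `ambiguous` rather than guessed. With tag-only matching and
a budget of `max_edit = 1` per tag, the triangle inequality guarantees
that a read whose tags carry at most one error each can never be
misassigned (distance to any wrong tag is at least $3 - 1 - 1 = 1 >$
would-be margin); this is proven on exhaustively mutated fixtures in the
tests.

That guarantee has a cost: at realistic long-read error rates (~8%/base)
the probability that *both* 7 bp tags carry at most one error is only
about 0.81, capping the assignment rate. When the constant primer
binding sites are supplied (`binding_fwd`, `binding_rev`), the
demultiplexer therefore matches each tag together with its binding-site
context — the full tag primer, which is what was physically attached.
Errors landing in the shared context shift all candidates equally and
cannot flip a ranking, so the tag-region budget keeps its meaning; the
total budget becomes `max_edit` plus the 97.5% binomial quantile of
context errors at an assumed worst-case 10%/base. In simulation at 5%
substitutions + 3% indels with 96 distance-4 pairs this yields ~94%
assignment at ~0.8% misassignment; a `min_margin` argument tightens the
winner-margin requirement for applications that prefer purity over
yield (margin 2 gives ~0.1% misassignment at ~72% assignment).

The search window is anchored at the read terminus (pattern length +
budget + 3 bases). Scanning deeper into the read admits spurious
matches — with 12 candidate tags and a 35-base window, the expected
number of chance sub-threshold hits per end approaches 0.5, which we
measured as ~25% misassignment; anchoring eliminates this.

## Genotyping

The reference set is the cartesian product of all parts per slot in
circuit order (promoter–RBS–CDS–terminator) flanked by the binding
sites. Each demultiplexed insert is locally aligned (affine gaps:
match +2, mismatch −3, gap open −5, extend −2; both strands; banded,
band = 0.2 x read length + 30) against candidate constructs ranked by a
shared 11-mer prescreen (`top_k = 5` candidates by default, `top_k = 0`
forces exhaustive alignment). The aligner is implemented in C++ and
tracks the query span of the best local path, giving the *query
coverage* — aligned read bases over read length — without a traceback.
Reads below 95% query coverage are discarded; the definition is
read-relative, so a read truncated to 90% of its construct still passes,
while random sequence does not.

Per colony bin, coverage-passing reads are tallied per construct. The
most-supported construct (the *primary mapped reference*) is the
genotype call, and two purity scores gate it:

$$\mathrm{score}_1 = \frac{\text{primary count}}{\text{total reads}},
\qquad
\mathrm{score}_2 = \frac{\text{primary} - \text{second}}
{\text{primary}},$$

with QC passing when total reads > 15, score1 > 0.4 and score2 > 0.65.
Two definitional choices are deliberate and exposed rather than silent:
"second" is the read count of the second-most-supported *reference
within the bin* (a bin-purity measure), not secondary alignments of a
single read; and score1's denominator counts *all* reads assigned to the
bin, including coverage-failed ones, so score1 reflects mapping success
as well as purity. `genotype_bins()` documents both; the thresholds are
arguments.

For pooled plasmid libraries, `call_reads(circular = TRUE)` doubles each
reference so reads spanning the circular origin align contiguously.
`profile_library()` turns passing calls into combination and per-slot
marginal ratios, optionally with a Spearman rank correlation against the
input molar ratios of the assembly reaction. Note that rank correlation
is only informative when the expected ratios are distinct: with heavily
tied inputs (e.g. one skewed slot, one uniform slot) within-tie ordering
is random and the statistic degrades for purely combinatorial reasons.

## Relative units

The part strength is the mean colony intensity over 3-20 QC-passing
colonies of the circuit in which only that part differs from the
standard circuit, and the relative unit is

$$\mathrm{RPU\ or\ RRU} = \frac{\text{mean part intensity}}
{\text{mean standard-circuit intensity}},$$

so the standard part itself is exactly 1 and all units are free of the
common fluorescence scale. A variant convention that divides by
(standard − part) is retained behind
`relative_unit(convention = "typeset")` purely for auditability: it is
singular at the standard circuit and is not used anywhere in the
package. Standard circuits are measured per strain; strain comparisons
(`strain_comparison()`) are rank-based and therefore insensitive to
strain-specific scale factors.

## The synthetic data generator

Since no raw plate images or reads are deposited with this kind of
experiment, the package ships a generator that emulates both
acquisitions with exact ground truth:

* **Plates** (`simulate_plate()`): non-overlapping colonies with radii
  drawn in 6-12 px, rendered as flat discs with a 2 px Gaussian-soft rim
  *outside* the nominal radius — so the disc mean equals the programmed
  level exactly — plus flat background (10/255), additive Gaussian pixel
  noise (sd 3/255 by default) and 8-bit quantization with clipping
  warnings.
* **Reads** (`simulate_tagged_reads()`): tag + binding site + amplicon +
  binding site + revcomp(tag), with iid per-base substitutions (5%),
  insertions (1.5%) and deletions (1.5%) — a realistic R9-era total of
  8% — and each read reverse-complemented with probability 0.5. The
  empirical error rate of the sequenced library in the motivating
  experiments is not reported, so the default is a choice, exposed in
  `read_sim_config()`. Read ids encode the full ground truth for test
  oracles.
* **Demo bundles** (`make_demo()`): one-slot-varied characterization
  circuits cycled over colonies, with colony GFP =
  base x promoter strength x RBS strength x lognormal colony noise
  (CV 6%, matching the 5-8% colony-to-colony spread typical of plate
  assays) and constant-mean RFP. Part strengths are drawn log-uniformly
  over half a decade either side of the standard.

Everything is deterministic given explicit seeds; no global RNG state is
touched (`with_seed` scoping).

What the generator does *not* emulate — and hence what green tests do
not certify on real data: optical vignetting and flat-field error,
out-of-focus colonies, colony shape irregularity, PCR chimeras, strand
bias, and quality-correlated (rather than iid) base errors. The
detection and demultiplexing margins on real data should be validated
against a hand-labelled plate and a known-genotype pool respectively.

## Numerical and scale choices

* Problem sizes in the test suite and acceptance script: 512-960 px
  plates with 40-96 colonies, 96 tag pairs, 30-105 reads/colony
  (2.9k-10k reads), and 20,000 reads for library profiling — sizes at
  which every stage completes in seconds to ~1 minute on one CPU while
  leaving multinomial noise small relative to the tested tolerances.
* Coordinates are 0-based, origin top-left, x = column, y = row; all
  intensities are on the 8-bit camera scale.
* Colony matching across channels and pick assignment are greedy
  closest-first one-to-one matchings with a 10 px default tolerance;
  ties break by smaller distance, then lower record id.
* Alignment score ties between constructs pick the lowest construct id
  and set an `ambiguous` flag.
* Degenerate inputs are first-class: blank images yield empty tables
  (not errors), bins with zero passing reads yield `NA` genotypes that
  fail QC, constant-size colony sets report an undefined size-bias
  correlation, and division guards name the offending colony.

## Limitations

The k-mer prescreen (`top_k`) trades a vanishing risk of missing the
true construct for a ~4x speedup; exhaustive alignment is one argument
away. The sphere-packing feasibility check for tag design is an upper
bound, not an achievability proof, so near-bound requests fail in the
greedy phase with the achieved count. Query coverage, not identity, is
the read filter — a high-error read that aligns end-to-end passes, which
matches the intended use (construct identity, not variant calling).
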