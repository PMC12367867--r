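---
title: "Designing and evaluating annealing-inhibition blocking primers"
author: "primerblockr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating annealing-inhibition blocking primers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerblockr)
```

## The problem

Molecular diet analysis of a hematophagous predator — the motivating system
is sea lamprey (*Petromyzon marinus*) feeding on Great Lakes fishes — uses
vertebrate-universal primers to amplify a short mitochondrial 12S marker
from gut or fecal DNA. Because the predator's own tissue dominates the
extract, most amplicons (and most sequencing reads) are predator-derived,
drowning out the host/prey signal the study is after. An
**annealing-inhibition blocking primer** is an unextendable oligonucleotide
that binds the predator template across the universal primer's binding site
and into a predator-specific region; its physical presence excludes the
universal primer from the predator template while leaving host templates
untouched. This package designs such blockers from a reference alignment
and quantifies how well a blocker works from qPCR traces and from amplicon
read tables.

## Design model

The design rests on a single discriminative feature: a region where the
target carries sequence that the rest of the community lacks. In a gapped
community alignment this shows up as a run of columns in which the target
is non-gap while (nearly) all non-target records are gapped.
`findDiscriminativeGap()` scans for maximal runs of at least `minLen`
columns where at least `gapFrac` of the non-targets are gapped; in the
motivating system that window is a 23-column target-specific insertion
immediately downstream of the universal primer's footprint.

Two genuinely open choices were settled as follows:

* **Which side carries the insertion.** An alignment "gap between the
  target and the others" can mean either a target insertion or a shared
  non-target insertion. The primary mode assumes the target is the inserted
  one (the configuration that makes a blocker possible at this locus); the
  mirrored criterion is available via `mode = "nontarget_insert"`.
* **Non-target gap fraction.** `gapFrac` defaults to 0.9 rather than 1.0,
  so a few non-target species sharing the insertion (e.g. congeners of the
  target) do not hide the window. `minLen` defaults to 15 columns with the
  23-column window as the documented exemplar.

Blocker candidates are enumerated on the target's sense strand, in the same
orientation as the forward universal primer: every candidate's 5' end lies
inside the primer footprint with a 3'-terminal overlap of `minOverlap` to
`maxOverlap` bases (default 6–10), and its length is either in
`[lenMin, lenMax]` or in an explicit `lengths` set (the worked panel uses
34 and 36 bases, chosen to span the insertion). The universal primer is
first prepended to every record with `appendPrimerToAlignment()` — it binds
all community members, so this adds no gap columns and simply shifts design
coordinates by the primer length; degapping an appended record returns
primer + input sequence.

Candidate specificity is scored per non-target as the count of mismatching
or gapped columns over the candidate footprint (a gap counts as a
mismatch, so a candidate spanning the insertion scores at least the
insertion width against every species lacking it), plus a 3'-weighted
variant in which the five 3'-terminal columns count double, since terminal
mismatches disrupt annealing most. Ranking is deterministic: larger
minimum non-target mismatch count first, then melting temperatures inside
the configured band, then shorter candidates, then leftmost start.

## Melting temperature

`nnTm()` implements the unified nearest-neighbor stack parameters with the
non-self-complementary initiation terms, an entropic monovalent-salt
correction of 0.368 cal K^-1 per phosphate times ln[Na+], and

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ + R \ln (C_T/4)} - 273.15$$

with `saltmM = 50` and `oligoUm = 0.25` as frozen defaults. Those two
defaults were calibrated once against the published panel values (63.8 °C
for the 34-mer, 65.8 °C for the 36-mer); the model reproduces them at
63.94 / 65.92 °C and the defaults were left untouched. Two caveats are
documented deliberately:

* 3' end modifications (C3 spacer, inverted dT) and purification grades
  are synthesis annotations only; no thermodynamic adjustment is applied,
  matching vendor practice of quoting identical Tm across modifications at
  equal length.
* Extending an oligo by G or C *almost* always raises the predicted Tm,
  but not strictly: replacing an A/T terminal penalty changes both
  enthalpy and entropy, and on GC-rich oligos the predicted Tm can dip by
  a few hundredths of a degree. The package's property tests therefore
  assert monotonicity only up to a 0.05 °C trace.

## qPCR evaluation

The cycle threshold is the fractional cycle at which baseline-normalized
fluorescence (delta-Rn) first reaches a fixed threshold, default 0.063 —
the instrument setting of the motivating evaluation — linearly interpolated
between the bracketing cycles. Linear (not log-linear) interpolation is the
contract: at a threshold placed in the near-exponential region the two
agree to well under a tenth of a cycle, and linear is the simpler, exactly
testable rule. Input is assumed already normalized; no baseline subtraction
is attempted.

Suppression is quantified as \(2^{\Delta C_t}\), assuming perfect per-cycle
doubling; `foldSuppression(ctBlocked, ctUnblocked)` exponentiates the Ct
difference of a blocked/unblocked pair. When aggregating replicates the
package exponentiates the mean Ct difference (matching the printed
arithmetic of the motivating study) and also reports per-replicate folds.
A blocked reaction that never crosses the threshold is reported as
"suppressed beyond quantification" with the lower bound
\(2^{(\text{maxCycle} - C_t^{\text{unblocked}})}\), not as an error.

Melt curves are reduced to the temperature of the maximum of −dF/dT
(central differences after a 3-point moving average; ties to the lowest
temperature), and `classifyShift()` calls a blocked mixed-template product
predator-like or host-like by its distance to the two single-species
baselines, with a 0.5 °C ambiguity margin.

## Read processing and statistics

The amplicon pipeline is deliberately small but complete:

1. **Merge** (`mergePairs()`): the reverse mate is reverse-complemented and
   the longest suffix/prefix overlap with at most 2 mismatches (minimum 10
   bases — unstated upstream, chosen to forbid spurious 1-base overlaps)
   is kept. The output is the overlap region *only*; with 2 × 150 reads
   and ≤ 107-base amplicons both mates span the template, so trimming to
   the overlap recovers exactly the amplicon and discards read-through.
   Disagreements resolve to the higher-quality base; quality ties become
   `N`.
2. **Filter** (`filterReads()`): drop merged reads longer than 107 bases
   or containing a homopolymer run above 8. "Large homopolymer" is
   unquantified upstream; 8 is a common amplicon-pipeline default and is
   configurable.
3. **Dereplicate** (`dereplicate()`), optionally dropping uniques below a
   count floor. Dropping singletons (`minCount = 2`) is the standard
   pseudo-denoising shortcut used for the large simulated runs below; note
   it removes proportionally more reads from rare templates (their error
   variants are almost all singletons), so quantitative recovery checks
   run with `minCount = 1`.
4. **Classify** (`classifySeq()`): nearest references by global-alignment
   identity with bootstrap rank confidence — the fraction of resamples of
   query positions in which the top hit is unambiguous at a rank and
   agrees with the full-data call; assignment is the deepest rank at or
   above the 80% cutoff. This is a deliberate, documented stand-in with
   transparent semantics, not a re-implementation of any published
   classifier. Its tie handling is what produces the biologically expected
   family-level calls for a query one base away from several confamilial
   references.
5. **Cluster** (`clusterOtus()`): single-linkage at an alignment-based
   mismatch-fraction cutoff. The upstream description states both a 97%
   and a 99% similarity threshold; the contradiction is left unresolved
   and the cutoff is an explicit parameter, default 0.03.

Chimera removal is out of scope and logged as an explicit no-op stage.

Blocker effectiveness over an OTU table (`OtuExperiment`, a
SummarizedExperiment whose `colData` pairs each blocked sequencing sample
with the unblocked control of the same DNA template) is assessed by paired
t-tests on raw counts (`d = unblocked − blocked`; no rarefaction or
compositional normalization, matching the motivating study's direct use of
counts), Holm's sequential Bonferroni within each taxon's family of tests,
and the stated decision rule: a blocker is effective iff it significantly
reduces predator reads and no host taxon is significantly reduced —
significant host *increases* are expected and do not disqualify.

## The simulators

`simulateCommunity()`, `simulateQpcr()`, `simulateMelt()` and
`simulateReads()` generate all three input kinds with known ground truth,
bit-reproducibly under a mandatory seed. Default study conditions: a
12-species community over an 84-base shared region plus a 23-base
target-specific insertion (so the target amplicon is 107 bases — the
longest the pipeline's own length filter admits, mirroring a reference set
spanning 89–107 bases), 8% per-base interspecific divergence, 2 × 150
reads with 0.001 per-base substitution errors (no indels — a documented
simplification that keeps merge and filter behavior analyzable), and
mixtures such as 90:10 predator:host. Blocking is modeled as dividing the
predator's template proportion by a single effective `suppressionFold`
before multinomial read sampling, the template-level counterpart of the
\(2^{\Delta C_t}\) interpretation. The qPCR simulator calibrates its
logistic midpoint against the package's own interpolated Ct definition, so
noise-free round trips are exact rather than carrying the ~0.09-cycle
convexity bias of a purely analytic placement.

What the simulators do **not** emulate: PCR-cycle-resolved amplification
stochasticity, chimeras, indel errors, instrument-specific quality
profiles, or taxon-specific amplification bias. Passing the simulation
checks therefore demonstrates that the pipeline arithmetic and statistics
recover a known truth under idealized noise — not that any particular
wet-lab run will.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own benchmark sizes: communities of 10–12 species,
alignments of a few hundred columns, 4,000-read unit-test libraries and
two 50,000-read-pair end-to-end libraries; the exhaustive alignment oracle
battery uses 200 random pairs of up to 8 bases. The center-star aligner is
intended for a few hundred short sequences (the scale of a curated
single-marker reference set) and is quadratic in their number; larger
datasets are out of scope. Alignment scoring defaults to match +1,
mismatch −1, gap −2 with linear gaps — adequate for short rRNA fragments —
with `N` scored as a universal mismatch and ambiguity codes other than `N`
rejected at parse time. All coordinates are 0-based half-open. Traceback
ties prefer diagonal, then a gap in the second sequence, then the first,
making every alignment deterministic.

## Known limitations

* Elongation-arrest blocker design, hairpin/self-dimer thermodynamics and
  multiplex compatibility are not modeled; the 10:1 blocker:primer
  concentration recommendation is emitted as guidance metadata only.
* The classifier and clusterer are transparent toy implementations; for
  production community analysis use a full amplicon pipeline and bring the
  resulting OTU table back here for the blocker statistics.
* Suppression estimates inherit the perfect-doubling assumption; primer
  dimers or efficiency above 100% in real reactions bias \(2^{\Delta C_t}\).
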