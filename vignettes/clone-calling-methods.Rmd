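---
title: "Calling clones from barcoded long-read libraries: models and choices"
author: "BarcodeClones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling clones from barcoded long-read libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Multiplexed assays of variant effect (MAVEs) read out pooled libraries of
mutagenized clones through short DNA barcodes embedded in the construct.
Before a screen can be scored, each barcode must be mapped to the genotype
of the clone that carries it. Long high-fidelity (HiFi) amplicon reads cover
the barcode(s) and the full open reading frame in a single molecule, but
three failure modes corrupt a naive barcode-to-genotype dictionary:

1. **Sequencing errors in the barcode** make one clone look like several.
2. **Non-unique barcodes** — the same barcode sequence picked up by two or
   more clones with different genotypes.
3. **PCR crossover chimeras** — recombinant molecules joining the 5' part of
   one clone to the 3' part of another during amplification.

`BarcodeClones` addresses all three: it clusters reads by barcode
*similarity* and genotype *coherence*, calls per-clone consensus barcodes
and error-filtered genotypes with protein consequences, and uses dual
flanking barcodes to flag non-unique barcodes and putative chimeras.

## The procedure

**Extraction.** Each read is aligned to the reference amplicon semi-globally
(read global, reference ends free) with affine gap penalties (match +1,
mismatch −4, gap open −6, gap extend −1), in both orientations;
`Biostrings::pairwiseAlignment` provides the dynamic program, and the
degenerate `N` stretches marking barcode regions match any read base at full
match score. From the alignment we take the barcode sequence(s) with
per-base qualities and the *candidate variants* — every mismatch or gap
outside the barcode regions, adjacent same-type columns merged, indels
left-aligned. Reads whose minimum barcode basecall quality falls below Q62
are discarded: on real instruments such reads are enriched for
multi-occupancy wells whose signal mixes two molecules. A read at exactly
Q62 is kept.

**Seed clustering.** Reads sharing an identical (virtual) barcode form a
group. Within a group, candidate variants seen in only one read *and* below
Q50 are set aside as putative errors; a graph then joins two reads if both
are wild-type after filtering or if their filtered variant sets have a
Jaccard index of at least 0.2. Connected components — including singletons —
become seed clusters.

**Merging.** Cluster pairs whose members' barcodes lie at minimum edit
distance *ed* are considered for merging, for *ed* = 1 up to 2. A candidate
merge is accepted only if (a) after re-filtering errors on the pooled
cluster both sides are wild-type or their remaining variant sets reach the
Jaccard threshold, (b) no pair of member barcodes exceeds the maximum edit
distance, and (c) the sizes are sufficiently divergent,
|log2(size1/size2)| > *ed* — the situation expected when a small satellite
cluster holds reads of a large clone with extra barcode basecalling errors.
Note that (c) makes equal-sized clusters unmergeable across distinct
barcodes; that is the rule's literal form and we keep it. Within an *ed*
level candidates are processed in a fixed order (descending combined size,
then lexicographic consensus-barcode pair, then smallest member read id) and
each level is iterated to fixpoint before the next; levels are not
revisited. Candidate pairs are discovered with a symmetric-deletion barcode
index and verified by exact edit distance, so the optimized path returns
exactly what an all-pairs scan would.

**Consensus and translation.** Each final cluster yields a clone call: the
plurality member barcode per region (ties by summed quality, then
lexicographic), the error-filtered nucleotide genotype, and per-codon
protein consequences under the standard code (synonymous `p.H2=`, missense
`p.M1I`, nonsense `p.K3Ter`, frameshift `p.K3fs`, in-frame
`p.K3del`/`p.K3ins`; variants outside the ORF are non-coding). Substitutions
hitting one codon are applied jointly. Compound indels are reported per
event together with a clone-level net-frame annotation. Frameshift-length
indels whose left-aligned position sits at the 5' end of a homopolymer run
of length ≥ 4 (the run start or the base before it) are annotated, because
long-read indel artifacts concentrate there.

**QC.** Barcode groups with one clone are `unique`; multi-clone groups are
`non_unique_remediable` when the dominant clone holds strictly more than two
thirds of the group's reads, else `non_unique`. With dual barcodes, chimera
detection anchors on one flank: clones with identical anchor barcodes,
overlapping genotypes (identical sets, non-empty intersection, or both
wild-type — the latter annotated `wt_only`) and *entirely different* other
flanks (edit distance above the merge limit, so nothing clustering could
conflate) form chimera sets, maximal under transitive closure. A crossover
molecule shares its upstream barcode with one parent and its downstream
barcode with the other, so the default `direction = "both"` anchors on each
flank in turn; a one-flank detector inevitably misses crossovers that land
5' of all of one parent's variants (for a Poisson(λ) mutation load and a
uniform crossover point the miss probability of the upstream-only detector
is (1 − e^{−λ})/λ ≈ 0.32 at λ = 3, against ≈ e^{−λ} ≈ 0.05 for the
two-flank detector). The classical upstream-only analysis remains available
and is what the chimera/non-unique cross-tabulation uses; its
non-uniqueness arm comes from a re-clustering with virtual barcodes
disabled, since only then does the comparison measure what a single-barcode
design would have seen.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `minBcQual` | Q62 | minimum per-base barcode quality to keep a read |
| `maxEd` | 2 | maximum barcode edit distance for merging |
| `jaccardMin` | 0.2 | genotype-coherence threshold |
| `varQualMin` | Q50 | quality arm of the error filter |
| `homopolymerMin` | 4 | run length for frameshift-context annotation |
| `useVirtual` | TRUE | concatenate dual barcodes into one identifier |

Q62, the merge limit of 2 and the Jaccard threshold of 0.2 are the
method's published operating points. Q50 for the error filter is our
choice: comfortably above the quality of raw miscalls yet below the
consensus-quality range of correct HiFi basecalls; it is exposed as a
tunable. The barcode-quality statistic is the minimum by default (the
strictest reading); `bcQualStat = "mean"` is available.

## Indel-quality policy

An indel has no basecall of its own, and within a homopolymer run its gap
placement is ambiguous: every placement across the run scores identically,
and the aligner's choice routinely lands on a *correct* high-quality copy of
the repeated base while the erroneous low-quality base is absorbed as a
match. Naively taking the inserted-base or flanking-base quality therefore
lets single-read artifacts through a filter that drops only *single-read
and low-quality* candidates. We instead score an indel by the minimum read
quality over its **ambiguity span**: the event's read bases (or gap flanks),
extended across the maximal equal-base read runs at its boundaries, plus one
further base each side. Multi-base substitution events and mismatches at
the very ends of the alignment — both typically re-encodings of
indel-containing regions — are widened similarly (±2 and ±4 bases), and
difference events separated by at most two matching columns share the
minimum quality of their joint span. Finally, indels abutting a degenerate
barcode region are assigned to the barcode side: `N` matches every base, so
in-region and boundary placements tie, and such events are barcode noise
rather than template variants (their bases join or leave the extracted
barcode string instead). These rules are conservative for real variants —
a clone's true variant is supported by every read of the clone and survives
on support alone — and in simulation they raise exact-genotype recovery
from roughly 50–85% to ≥ 95% without touching the published filter rule.

## The simulator

`simulateLibrary()` generates the study conditions end to end: clones with
uniform-random barcodes (25 nt per region), a Poisson(3) per-clone mutation
load placed uniformly over the ORF (70% SNV / 15% insertion / 15% deletion,
indel lengths 1–3), lognormal reads per clone (median ≈ 10), HiFi-like
per-base error rates (substitution 10⁻³, insertion and deletion
2.5 × 10⁻⁴ each — the regime of circular-consensus reads), indel rates
multiplied 5× inside homopolymer runs of length ≥ 4, a 2% per-read chance of
one barcode error, planted non-unique barcodes (a later clone re-using an
earlier clone's barcodes with a different genotype), and chimeric templates
formed before read errors by joining clone A up to a uniform ORF crossover
point to clone B beyond it, so the upstream barcode comes from A and the
downstream barcode from B. Qualities are anti-correlated with error status
(correct ≈ N(90, 3), erroneous ≈ N(25, 8), clamped to [3, 93]); barcode
errors draw from a 70/30 low/high mixture, the high component (≈ N(75, 5))
modelling systematic consensus miscalls that pass the Q62 filter — without
it the read filter would remove every barcode error and the edit-distance
merge phase would never be exercised. Read orientation is randomized 50/50.
Everything is a deterministic function of the seed, to the byte.

What the simulator does *not* model: instrument kinetics, context-dependent
substitution spectra, true multi-occupancy well signals (only their
low-quality-barcode footprint), chimeras of more than two parents, and
recombination hotspots. Passing the recovery tests therefore demonstrates
the algorithmic machinery under the stated error phenomenology, not
instrument-grade realism.

## Numerical and degenerate-input choices

Left-alignment normalizes indel representations before any set comparison;
the Jaccard index of two empty variant sets is defined as 1 (two wild-type
reads agree); the remediable threshold is a strict inequality, so a clone
with exactly two thirds of a group's reads is not remediable; equal-size
clusters never merge (|log2 1| = 0); cluster ordering and all tie-breaks
use byte-order (`radix`) string comparison, making runs locale-independent
and byte-reproducible; an empty FASTQ yields a complete zero-count report;
chimera detection on a single-barcode layout is an explicit error rather
than a silent no-op; start-codon substitutions are reported as ordinary
code-table changes (`p.M1L`), with no start-lost special-casing. The alignment score floor is a fraction (0.25) of read
length; reads under it are dropped as `unaligned`.

## Problem sizes used in the shipped tests

The test-suite simulations are sized for a laptop-class run: the recovery
study uses 100 clones at ~10 reads each (~1,000 reads, ~600 bp amplicon);
the crossover study uses 800 clones at ~5 reads each with 5% chimeric
templates (~4,300 reads); clustering correctness is checked against a
brute-force reference on 200 random micro-libraries of up to 50 reads.

## Known limitations

Recurrent sequencing errors — the same miscall in two or more reads of a
clone — are retained by design, because the published filter drops only
single-read low-quality candidates; at HiFi error rates this leaves a few
percent of clones with one false variant, and it is the dominant remaining
error mode in simulation. Criterion (c) means a clone sequenced at similar
depth to an error satellite cannot absorb it. The upstream-only chimera
analysis misses crossovers with no genotype overlap toward their upstream
parent; the two-flank default mitigates but cannot remove the blind spot
when a crossover product overlaps neither parent's variant set. Frame
restoration by compensating indels is annotated (net frame) but protein
consequences are still reported per event.
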