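---
title: "Models and conventions in nickrepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions in nickrepair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nickrepair)
```

`nickrepair` analyzes the repair outcomes of site-specific DNA lesions —
two-ended breaks from Cas9 or I-SceI, and nicks from the Cas9 nickases
D10A and H840A that replication converts into one-ended breaks — as read
out by two single-copy reporters and by junction PCR assays. This
vignette documents the models, the coordinate and canonicalization
conventions, the synthetic-data generator, and the numerical choices, in
the order a user meets them.

## Reporters and coordinates

All coordinates are 0-based, half-open, on the Watson strand; conversion
to 1-based happens only at IO boundaries (BED via `rtracklayer`).

The **SCR reporter** carries a 5'-truncated GFP (`TrGFP`) and a full GFP
interrupted by an 18-bp I-SceI site (`ISceGFP`), separated by two
artificial RFP exons (B upstream of A). A break in `ISceGFP` repaired by
short-tract gene conversion off the sister's `TrGFP` yields GFP+RFP−
cells; long-tract conversion duplicates the exon B/A cassette
(GFP+RFP+), a repeat-directed tandem duplication whose span is the
distance between the allelic positions of the break in the two repeats.
The default geometry makes that span exactly 10,000 bp, emulating the
~10-kb spacing of the reporter construct this assay family uses; a
scaled-down geometry (used in the faster tests) is configured through
`scr_reporter_config()` and exercises the same arithmetic. The construct
is *parameterized*, not transcribed from a database record, so the
package builds with no downloads; `read_reporter()` accepts externally
supplied FASTA/BED.

The relevant fork for LTGC/TD-visible products is fixed per reporter
(`origin_direction_for_ltgc = "rightward"`): only one-ended breaks from
the rightward fork can duplicate the cassette, so leftward-fork events
produce no reporter-visible product.

The **NHEJ reporter** expresses GFP only after reframing: translation
initiates at a strong Kozak ATG (`Koz-ATG`) that sits out of frame with
the GFP coding sequence by a 34-bp frameshift. The promoter, spacer and
trailing pad are synthesized from A/C only, which guarantees no start or
stop codon exists — or can be created at an indel junction — outside the
intended ones; this is what makes the rule-based frame test below
*exactly* equal to a translation simulation on this construct.

## Strand and collision logic

The D10A nickase cuts the strand paired with the sgRNA (the complement
of the PAM strand); H840A cuts the displaced strand (the PAM strand).
A nick collapses a replication fork as a "lead" collapse when the nicked
strand is that fork's leading-strand template and as a "lag" collapse
otherwise. The leading-strand template of a rightward-moving fork is
fixed, by convention, as the Crick strand. These two rules generate the
full 8-row truth table (`collision_table()`), which is symmetric under
jointly mirroring the PAM strand and the fork direction. sgRNA-to-PAM
assignments are data (`inst/extdata/sites.yaml`), not constants.

## Frame-restoration rule

An indel at the NHEJ-reporter cut restores GFP when

1. its net size `c` satisfies `c mod 3 == 2` — i.e. gains of 2, 5, 8, …
   bp or losses of 1, 4, 7, … bp (the signed form `3n − 1`); the 34-bp
   frameshift is `3n + 1`, so only this congruence class cancels it —
   provided the event stays in the spacer and leaves the GFP CDS intact;
   or
2. it alters any nucleotide of the Koz-ATG start codon, in which case
   scanning initiates at the native, in-frame GFP ATG.

`frame_restored()` implements the local rule these two clauses are
special cases of: rebuild the mutated sequence upstream of the GFP
coding body, require the codon feeding the body to be ATG, and require
the first upstream ATG to sit in frame with it. The general form is
needed because a junction can *reconstitute* a start codon — a deletion
can splice an upstream `A` onto the `TG` of a broken ATG, or the Kozak
`A` onto the GFP `TG` — and whether GFP is restored then depends on the
frame of the reconstituted codon, not merely on which codon was hit.
The rule is checked exhaustively against an independent ORF-scanning
oracle (`translation_reports_gfp()`: translate from the first ATG, score
the peptide for containing full-length GFP) for all deletions of
1–100 bp and all C-only insertions of 1–30 bp at every position of a
compact test construct. Insertions in the exhaustive scan are C-only
because an arbitrary inserted sequence can itself contain a start codon,
which the local rule does not model; its domain is indels whose inserted
bases do not create new ATGs.

## Microhomology and canonical junction calls

A deletion's microhomology is defined by **placement ambiguity**: the
number of distinct same-length deletions producing the identical product,
minus one. This equals the length of the longest match between the
sequence 5' of the left-aligned deletion and the 3' end of the deleted
segment, and is verified against brute-force enumeration over random
sequences. Within a locus, calls are left-aligned; the discarded
information is preserved as the `ambiguity_window`.

Compound events (deletion plus untemplated insertion) are normalized in
two steps by `canonical_event()`: *shrink* — inserted bases identical to
the deleted boundary bases are matched out, yielding the minimal
representation — then *slide* to the leftmost equivalent placement. At
two-sided fusion junctions (translocations, TD fusions) a zero-loss
junction can still carry MH; `junction_mh()` counts placements there,
and ambiguous bases are attributed to the upstream partner (locus A; the
GFP side of a TD fusion), i.e. the junction is placed right-maximally.

The aligner is `Biostrings::pairwiseAlignment` (global, affine gaps)
with match +2, mismatch −11, gap open 12, gap extension 1. The mismatch
penalty is deliberately high relative to gap costs so that a compound
indel is never re-expressed as a run of substitutions, while isolated
sequencing errors still align as substitutions (one or two adjacent
substitutions remain cheaper than a gap pair). Reads whose aligned
columns fall below 80% identity are `unaligned`; indel operations
separated by ≤5 matched bases merge into one event; merged events that
both delete and insert, or multiple distant events, are `complex`.
"Edited" excludes substitution-only reads, which at amplicon scale are
indistinguishable from sequencing error. The deletion size bins are
1–10, 11–80 and ≥81 bp (the third bin is forced by the first two).

## Translocation quantification

Junction reads between two loci come in four orientation types (which
side of each cut the read carries, F/R per locus). The caller tests each
read, in both orientations, against the four fusion templates, so calls
are invariant under reverse-complementation. Relative levels are
translocation reads / control-amplicon reads / transfection efficiency;
the assay's fixed 10:1 volume mixing of translocation and control PCRs
is treated as a design constant that cancels in fold changes, so levels
are reported as measured. Chimeras with untemplated junction insertions
are counted as translocations (flagged, excluded from `precise_join`).

## TD product classification

The invasion and termination amplicons of a GFP−RFP+ clone are windows
around `ISceGFP`. Classes: 1 — amplicon identical to the reference
(intact I-SceI site); 2 — a single indel whose canonical placement lies
within ±10 bp of the break (window configurable; the assay itself states
no numeric window, so "at the break point" is operationalized here);
3 — a chimeric fusion retaining only the amplicon sequence on the
break-proximal side, joined at an MH to reporter sequence upstream of
exon B (invasion) or upstream of `ISceGFP` (termination).

For INV3, `processed_len` counts reference bases between the break and
the last base matching `ISceGFP` before the fusion (right-maximal
placement), and `entry_distance` is the allelic break position minus the
fusion target (positive = upstream; negative values are entries between
the allelic position and exon B). `td_span = break − entry`, so INV3
spans shift from the 10,000-bp repeat span by exactly the entry
distance. INV2×TER2 clone pairs carrying the identical canonical indel
are flagged `shared_indel_with_ter` — the signature of two-round strand
invasion copying one pre-mutated template into both junctions.

## FACS metrics

`normalize_frequency` = (sample rate − background rate) / transfection
efficiency, clamped at zero with a warning (small-count noise can push
the corrected value below zero; clamping beats erroring in a pipeline).
LTGC bias is defined as `LTGC / (STGC + LTGC)` — the long-tract share of
gene-conversion events; the term is used in the field without a printed
formula, so the definition is fixed here and carried in all outputs.
Wild-type-relative scaling divides by the wild-type mean × 100. The
strand-asymmetry report computes per-(site, nickase) mutant/wild-type
folds from replicate means, assigns each to its collision class, and
compares classes by a paired two-tailed t test when the same sites
contribute to both classes (the D10A/H840A pairing), unpaired otherwise.

## Synthetic data: what it emulates, and what it does not

Every generator takes an explicit seed and restores the caller's RNG
state; identical seed + configuration gives byte-identical FASTQ/FASTA/
CSV output. Truth tables record each read's event in the *same* canonical
convention the callers report, so recovery comparisons are exact string
and coordinate equality.

* Amplicon libraries: class mixture over unedited / deletion / insertion
  / complex; deletion sizes from a two-component law (geometric, mean
  4 bp, plus a resection tail shifted to 11 bp, mean 30 bp) emulating
  the short-indel versus resection contrast seen in junction spectra —
  the parametric form is a stand-in, not a fit to any empirical
  distribution; `mh_bias` is the probability that a deletion's placement
  is drawn from the MH-bearing placements of its size at the cut.
* Compound (delins) events are constrained so their canonical
  decomposition is unique (≥3 bp lost, inserted bases differing from the
  bases they would mismatch-align to, non-zero net size). Without these
  constraints a delins can be *mathematically identical* to a
  substitution run or a different indel, and "truth" would be ill-posed.
* Sequencing noise is substitution-only (no simulated sequencer indels),
  so indel truth stays unambiguous — a documented limitation relative to
  real libraries. FASTQ qualities are constant Q40 placeholders. Real
  data also contain PCR chimeras, primer artifacts and coverage bias,
  none of which are modeled; passing truth-recovery tests therefore
  demonstrates correctness of the calling logic, not robustness to every
  real-world artifact.
* Translocation libraries: control-read fraction
  `1/(1 + volume_ratio × trans_abundance)` mirrors the volume-mixing
  design; per-side resection is geometric; a configurable fraction of
  junctions is precise.
* TD clones: INV3/TER3 entry points are *selected* among positions whose
  natural junction ambiguity equals the MH length drawn from the entry
  law (falling back to shorter MH when no position offers the drawn
  length — long MH is rare in random sequence, as in a real reporter).
  Entry windows are restricted to non-GFP sequence upstream of exon B
  and clipped to the 8.1–11.9-kb span band the full-scale assay
  resolves; with the default geometry this makes all INV3 spans fall in
  8–12 kb, with repeat-directed spans at exactly 10 kb.
* FACS counts are multinomial; transfected cells (probability = the
  transfection efficiency) acquire reporter events at the true
  frequencies, all cells show background events, and a parallel
  background sample is drawn — making the downstream normalization
  unbiased by construction.

## Problem sizes and numerical tolerances

Stochastic checks in the test suite use fixed seeds and 3-SD bands from
the corresponding binomial/multinomial oracle. Truth-recovery runs use
10,000-read libraries, 5,000–20,000-read translocation libraries and
120–200-clone TD sets; the exhaustive frame scan uses a compact
(~360-bp) construct so the full deletion × position grid stays cheap
while exercising every regime of the rule (promoter, Koz-ATG, spacer,
CDS, trailing pad). The type-I-error check of the t-test wrapper uses
2,000 null simulations.

## Known limitations

* The junction caller assumes pre-merged single-amplicon reads; no
  paired-end merging or UMI handling.
* Substitution-only "editing" is invisible by design.
* Translocation discovery is restricted to a configured locus pair (as
  in a PCR design); no genome-wide search, no reciprocal-product
  pairing.
* Mechanism labels for TD classes (INV1/INV2 ↦ two-round-invasion
  consistent, INV3 ↦ MH-mediated) are structural classifications, not
  causal claims.
* A compound event whose inserted bases happen to match internal
  deleted-region sequence can admit several score-equal alignments; the
  generator avoids emitting such events, but on arbitrary real reads the
  reported decomposition is one member of the equivalence class.
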