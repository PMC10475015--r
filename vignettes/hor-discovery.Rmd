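---
title: "Discovering tandem higher-order repeats: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering tandem higher-order repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(horseq)
```

## The problem

Large tandem repeats dominate several regions of mammalian genomes.  In the
best-studied cases -- centromeric alpha satellite, and the ~1.6 kb NBPF
(Olduvai) repeats of human chromosome 1q -- the primary repeat unit (the
*monomer*) is itself organised into a *higher-order repeat* (HOR): a few
distinct monomer types (m1, m2, m3, ...) repeat as a block, and the
block-to-block divergence (often below 5%) is an order of magnitude smaller
than the divergence between the monomer types (~20-30%).  For the NBPF
repeats the canonical HOR is a 3mer, m1-m2-m3, about 4.8 kb long; its copy
number in tandem arrays differs sharply between humans (and Neanderthals)
and the other great apes, which makes reliable HOR annotation interesting
well beyond repeat biology.

`horseq` implements the complete discovery-and-annotation chain for this
class of structure, plus a simulator that plants HOR arrays with exact
ground truth so that every stage can be tested quantitatively without
touching multi-hundred-Mb assemblies.

## The repeat spectrum

The entry point is a frequency-domain picture of a sequence,
`grm_histogram()`.  For every K-length window over `{A,C,G,T}` (windows
containing N are skipped) the start-to-start distances between *consecutive*
occurrences of that window are pooled into a histogram over 1..`max_length`.
A tandem repeat of unit L makes most of its K-strings recur at exactly L, so
the histogram spikes at L; an HOR of order 3 built from three diverged
monomer types makes most K-strings unique to one type, recurring at 3L, while
the minority of K-strings conserved across types recur at L and 2L.  The
characteristic fingerprint of a 3mer HOR on a ~1.6 kb monomer is therefore a
dominant peak near 4.8 kb with sub-peaks near 1.6 and 3.2 kb
(`validate_hor_signature()`).

Choices that matter:

* **K (default 12).**  K must be long enough that random recurrences are
  rare (a 12-mer has a 1/16.8M vocabulary, so a 2 Mb sequence produces only
  a thin background) and short enough that a few K-strings survive in all
  monomer types despite ~25% inter-type divergence.  K is configurable
  (4-64; above 32 a slower string-keyed path is used) and recorded in run
  manifests.
* **Distances are start-to-start** of consecutive occurrences, which reads
  the repeat period off directly.
* **N handling.**  Windows containing N are excluded; inter-occurrence
  distances above `max_length` (default 20 kb) are dropped, so assembly
  gaps cannot create phantom long-range periods.
* **Memory.**  The histogram is accumulated in a single streaming pass,
  bounded by the number of distinct K-strings present, so 10 Mb segments
  are unproblematic on a laptop.

`grm_detect_peaks()` merges histogram bins within a relative radius
(default ±3%, because indel jitter in the repeat period scales with length)
around local maxima and reports the modal length.  A merged peak must exceed
`min_count` (default 5) **and** a prominence threshold: its merged mass must
be at least `min_prominence` (default 3) times the mass expected over the
merge window from the local ±20% background density.  The prominence filter
exists because relative-radius merging applied to the flat random background
of a Mb-scale sequence would otherwise fabricate a "peak" at any queried
length, and the HOR-signature test could never return false.

## From spectrum to monomer families

`locate_tandem_regions()` turns near-constant K-string recurrence into
regions: maximal runs of consecutive occurrences whose spacings lie in a
unit range with coefficient of variation at most 0.1, with at least
`min_copies` occurrences; overlapping runs with compatible units merge.
`extract_repeat_copies()` then segments a region at successive occurrences
of its key K-string.  Two practical points:

* The segmentation **phase is arbitrary** -- a key occurring 300 bp into the
  planted monomer yields copies rotated by 300 bp.  All downstream logic is
  phase-consistent, and comparisons against reference units are made with
  `rotational_divergence()`, which scores a sequence against all rotations
  (and optionally the reverse complement) of another.
* Fragments outside `[0.8, 1.25]` of the unit length are discarded: shorter
  ones are terminal partials, longer ones are fusions created when a
  mutation destroyed an intervening key occurrence.  Without the upper
  filter, fused double-units would contaminate the copy set.

Copies are compared all-against-all (`divergence_matrix()`) with unit-cost
Levenshtein distance normalised by the longer length -- symmetric, and
penalising truncations; indels count single, consistent with the
edit-distance scan.  `cluster_families()` takes the connected components of
the graph with an edge wherever divergence is *strictly* below the threshold
(default 5%) -- single linkage.  Because chaining can join copies whose
direct divergence exceeds the threshold, each family reports its
`max_intra_divergence`, making violations of the stricter clique reading
visible.  Families are labelled m1, m2, ... in order of first occurrence and
then re-labelled to HOR phase (`relabel_by_hor_phase()`): successor votes
between adjacent same-strand hits identify the dominant cycle, and the most
common copy-opening family becomes m1.  Ties keep positional labels with a
warning.

`build_consensus()` star-aligns members to the medoid (global pairwise
alignments), drops insertions relative to the medoid, and majority-votes
each column over `{A,C,G,T,-}`; a gap majority deletes the column, ties
between bases resolve alphabetically, and a base beats a tied gap.  For five
copies at 2% substitution divergence this recovers the generating sequence
to well under 1%, and the member-to-consensus mean divergence never exceeds
the mean pairwise divergence (asserted in tests).

**HOR-first refinement.**  An exact key only recovers the monomer types it
is conserved in.  At ~25% inter-type divergence only a handful of 12-mers
survive in all types, so key-based segmentation alone can, depending on the
mutation realisation, yield a single rotated type.  Discovery therefore
refines in two steps, mirroring the classic HOR-first formulation: the
largest seed family's consensus is scanned over the sequence as an anchor;
anchor-to-anchor spans close to `hor_order` units are cut into `hor_order`
equal sub-units (minus-strand anchors are processed on the reverse
complement); and the pooled sub-unit copies are re-clustered.  The sub-unit
phase, like the segmentation phase, is conventional.

## Scanning and assembly

`scan_monomers()` searches each consensus and its reverse complement against
the sequence with a semi-global (infix) unit-cost edit distance, base by
base, computed by Myers' bit-parallel algorithm over 64-row blocks (the
pattern is padded with wildcard rows to a word multiple; because adjacent
end-distances differ by at most one, the padding shifts the end-distance
profile without changing it, so the sweep stays exact).  N matches nothing,
on either side.  Candidate loci are local minima of the end-distance
profile with divergence (edits / consensus length) at most `max_divergence`;
for each, the alignment start is recovered by a reverse dynamic program.
Candidates from all families and strands are then accepted greedily by
ascending divergence, then start, then family order; a candidate
overlapping an accepted hit by at most 10% of its consensus length is
trimmed to abut it, larger overlaps are rejected.  Accepted hits never share
a base, and each locus keeps only its best family.

* **`max_divergence` = 0.15** by default: comfortably above intra-family
  drift (<5%, plus archaic drift of a few tenths of a percent) and far
  below inter-family divergence (~25%), so family assignment is effectively
  unambiguous.  It is configurable and recorded in output metadata.
* Hit spans come from the alignment (indel-aware), not a fixed window.
* Hits with more than `max_n_fraction` (default 10%) N content are dropped.

`find_assembly_gaps()` reports maximal N-runs strictly longer than a cutoff
(default 2 kb), the standard map of assembly gaps.

`hor_assemble()` chains two grouping passes.  Hits are traversed in genomic
order with maximal minus-strand blocks reversed, so rows read m1-m2-m3 in
gene orientation while coordinates stay forward-strand; a new HOR copy
starts when the family label fails to strictly increase, the strand changes,
or the gap exceeds `intra_copy_gap_tol` (default 400 bp, a quarter monomer).
The strict label-increase rule is the minimal rule reproducing both
successive canonical triples and variant rows such as m1-m3.  Copies whose
gaps stay within `array_gap_tol` (default 10 kb, about two canonical HOR
lengths -- the quantification of the visual "blank space" between arrays)
form tandem arrays; an array is *prominent* when it contains two adjacent
canonical copies.  `count_report()` tabulates per-array and total counts,
listing prominent arrays and scattered groups separately, with optional
user-supplied gene labels (never inferred) applied positionally to the
prominent arrays.  `render_scheme()` / `render_scheme_svg()` draw the
aligned scheme -- one row per copy with its 1-based start, family-coloured
boxes in fixed columns, a `*` (text) or bold (SVG) flag for
reverse-complement copies, and blank separation between arrays -- and
`align_panels()` lays several assemblies side by side with anchor arrays
co-linear.

Internally all coordinates are 1-based closed (the native convention of the
R/Bioconductor containers used for I/O); BED export converts to 0-based
half-open, GFF3 stays 1-based, and schemes print 1-based starts.

## The synthetic genomes

`generate_genome()` plants arrays and N-gap runs into a random background.
Monomer families derive from a shared random ancestor by independent
substitution, with the rate solved so the expected pairwise divergence hits
the target and redrawn until every measured pairwise divergence is within
±20% of it.  Planted copies receive per-base substitutions (uniform over the
three alternatives) and single-base indels -- the simplest model satisfying
the divergence regime the method assumes.  Minus-strand arrays are emitted
as the reverse complement of their concatenated rows, with forward-strand
truth coordinates.  The defaults are the regime the method targets:
1600 bp monomers, 25% inter-family divergence, 2% substitutions plus 0.5%
indels per planted copy (an intra-array divergence consistent with the
"copy divergence below 5%, an order of magnitude under monomer divergence"
description of the HOR regime; no direct measurement of NBPF intra-array
rates was available, so the alpha-satellite analogy sets the default), on a
2 Mb background.

Preset scenarios plant the published per-assembly HOR-copy layouts of
chromosome 1 at desk scale: `t2t_like_scenario()` (arrays of
19/15/14/13/5/9 copies, 64 of 75 canonical, two arrays on the minus strand,
one 2.5 kb N-gap), `hg38_like_scenario()` (22/13/10/14, 52 of 59
canonical), `neanderthal_like_scenario()` (16/13/12/17, 39 of 58) and
`chimp_like_scenario()` (scattered monomers, no canonical HOR).  Details the
published account does not fix were chosen once: variant rows are spread
evenly inside each array, cycle through the patterns m1-m3, m1-m2 and m1
(all opening with m1, so planted row boundaries coincide with the
label-increase rule), and per-array variant allocations are
[3,2,2,2,0,2], [3,2,1,1] and [5,5,4,5] respectively; arrays sit ~300-500 kb
apart.  The analysis scripts and the acceptance script additionally share
one homologous monomer panel across assemblies, drifting it by 0.5%
(archaic) and 1% (chimp) substitutions, and scan every genome with the
human panel, as a real cross-assembly comparison does.

What the simulator does *not* emulate -- and hence what passing tests do not
show about real data: flanking gene structure and exons, hybrid
half-domains, segmental duplications that partially repeat array context,
assembly collapse or expansion of arrays, and sequencing-error profiles.
Real-genome runs also face scale (a chromosome 1 is two orders of magnitude
larger; the scanner streams and the spectrum is memory-bounded, so this is
time, not memory).

## Problem sizes and determinism

The shipped analyses and tests run on 1-2.4 Mb genomes with 151-213 planted
monomers per hominin-like assembly; a full analysis chain (spectrum,
discovery, scan, assembly) takes seconds to a few tens of seconds per
genome on one core.  Every stochastic step flows through explicit seeds
(`family_spec`, `genome_spec`, `mutate_seq`); scenario builders decouple the
family stream from the background stream, and identical configuration and
inputs produce byte-identical artifacts (checksummed in the run manifest).

## Known limitations

* Families are defined by single-linkage components; a divergence drift
  across a long array could chain families that a clique rule would split
  (the reported `max_intra_divergence` exposes this).
* Discovery fixes one segmentation phase globally; assemblies whose arrays
  genuinely carry different HOR phases would be reported in the reference
  phase.
* Hybrid monomers (half one type, half another) are not called; a hybrid
  either matches one family within the divergence budget or is left
  unannotated.
* The scanner reports non-overlapping best hits; overlapping repeat
  structures (e.g. nested duplications of partial monomers) are outside its
  model.
* Count recovery is exact under the simulated regime; on real assemblies
  the thresholds (`max_divergence`, gap tolerances) are the operative
  dials and are surfaced in every report manifest.
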