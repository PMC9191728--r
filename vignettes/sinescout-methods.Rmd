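---
title: "sinescout: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sinescout: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model each
stage assumes, the tunable parameters with their defaults and rationale,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.  It states no
empirical result that the test suite does not itself compute.

## 1. The element model

A tRNA-head SINE is modelled as

```
5'  [lead] [A box, 11 bp] [spacer] [B box, 11 bp] [head linker] [body] [tail]  3'
      |<------------------- tRNA-like head ------------------->|
```

flanked in the genome by a 10–15-bp target-site duplication (TSD) on each
side.  Four criteria define a reported family: length at least 150 bp, an
RNA polymerase III type-2 promoter, at least three genomic copies, and
TSD-flanked insertions.  The distance from the element's 5′ end to the A
box (`tss_offset`) is a *measured* quantity; the pipeline never assumes the
eleven-nucleotide value observed in cockroach SINEs, it reports whatever
the consensus shows.

## 2. Promoter scanning

The canonical motifs are `TRGYNNARNNG` (A box) and `RGTTCRANTCC` (B box).
Parameters:

* `max_mismatch_per_box = 1` — functional SINE promoters rarely carry more
  than one substitution per box; raising this floods the anchor set.
* `spacing_bounds = c(25, 70)` bp between A-box end and B-box start —
  deliberately a little wider than the canonical ~30–60 to tolerate the
  approximation in that range.
* `N` in the genome never matches any motif position.

Scanning is vectorized (per-position mismatch profiles via byte lookup
tables), runs on both strands, and reports *all* A/B pairings; overlapping
hits are resolved later.  On a uniform random genome the expected hit
density is roughly one anchor per 7 kb per strand, which the clustering
stage absorbs without issue.

## 3. Windows and clustering

Each anchor yields a window from `U = 30` bp upstream of the anchor to
`W = 1000` bp downstream (minus-strand windows are reverse-complemented so
everything reads element-sense).  The upstream pad exists because the
element's 5′ end lies upstream of the A-box anchor — typically 11 bp — and
boundary calling must be able to see it.

Clustering is single linkage over the graph whose edges are window pairs
with a local alignment of identity ≥ `min_identity` (0.90) over
≥ `min_overlap` (150) columns and an implied anchor shift ≤
`max_anchor_shift` (5) bp.  Single linkage emulates assembly-style contig
formation; note its consequence: a family is recovered when its low-
divergence copies form a connected core, and copies beyond ~10% pairwise
divergence simply fail to join (they are recovered later by the genome-wide
copy scan at 80%).

Engineering choices that do not change results, only cost:

* windows whose anchors coincide within `max_anchor_shift` on the same
  strand are collapsed to one representative first, so member counts mean
  distinct loci;
* candidate pairs must share ≥ `min_shared_kmers` (10) distinct 12-mers, and
  are aligned in order of decreasing sharing so components condense early;
  pairs already connected by transitivity are skipped (single linkage needs
  connectivity only);
* a per-window cap (`max_failed_aligns = 6`) stops sub-threshold
  (degenerate) windows from exhausting the alignment budget;
* only the first `cluster_align_span = 650` bp of each window is aligned —
  anchoring puts the element at the window start and canonical SINEs stay
  under ~600 bp.  Raise this to hunt longer elements.

## 4. Boundaries and consensus

Members are star-aligned to the member with the highest summed edge
identity.  Coarse boundaries follow the conservation rule: the run of
columns whose smoothed modal-base fraction (centered window of
`boundary_window = 20` columns) stays ≥ `boundary_conservation = 0.6`,
anchored at the anchor column.  With only three members the flank
conservation hovers near 0.56, so the coarse call has a ±10-bp character;
two refinements sharpen it:

1. *match-run trimming* — each member's aligned span is trimmed to its
   outermost run of `boundary_match_run = 8` consecutive matches near the
   coarse bounds (a chance 8-match in random flank has probability
   $4^{-8}$);
2. *TSD voting* — each member window is searched for an exact 10–15-bp
   direct repeat whose instances abut a candidate element start/end near
   the trimmed bounds, and members vote in center-column coordinates.
   Pairs are collected at *every* length and ranked by total repeat
   evidence (the summed repeat length over voters): the true pair collects
   each member's full TSD length, a shifted sub-repeat of a long TSD —
   systematic across members — collects strictly less, and chance one-base
   extensions (e.g. an `A` flanking a poly(A) tail) collect from few
   members.  Ties fall to a conservation check (columns just outside a
   true boundary are TSD/flank and unconserved; just inside, element and
   conserved).  Member positions convert to center columns through a local
   diagonal offset measured ~25 bp inside the element, because a
   position-map lookup at the boundary itself is unreliable — the local
   aligner occasionally places a spurious gap inside the mismatch-rich TSD
   region, shifting the map by one base exactly where the vote needs it.
   When members carry intact TSDs — fresh insertions — all this pins both
   element ends exactly, which is what makes the measured `tss_offset`
   exact rather than ±2.  The vote is attempted centered on the trimmed
   bounds and, failing that, on the coarse run bounds.

Degenerate clusters whose members are identical across the whole window are
flagged `"no divergence observed - possible segmental duplication"` and not
boundary-trimmed.

The consensus is the column-wise majority over the boundary span; a column
is emitted iff fewer than half the members are gapped there; ties break in
the fixed order A < C < G < T.  The promoter is re-detected on the
consensus, choosing the hit with the fewest total box mismatches (5′-most
among equals) — choosing the 5′-most outright turned out to be wrong about
8% of the time, because an 11-bp degenerate motif with one tolerated
mismatch matches random sequence too easily.

Two suppression passes remove self-inflicted redundancy.  Secondary
promoter-like hits *inside* an element (either strand) spawn "shadow"
clusters over the same copies; models whose member loci largely overlap are
reduced to one representative.  Models with near-identical consensi (≥90%
identity over ≥80% of the shorter, checked in both orientations) are merged
the same way — this catches families rediscovered through a secondary
anchor in copies whose primary promoter was destroyed by mutation.  The
representative is chosen by TSD refinement first, then membership, then
length: a shadow cluster's windows miss at least one flanking TSD (its
anchor sits inside the element), so it cannot pin its boundaries, whereas
the true cluster can — this discriminates better than length or membership
alone, both of which a sloppy shadow can win.

## 5. Copy scanning and ages

`scan_copies()` seeds candidate loci with shared 12-mers (two seeds per
diagonal group) and verifies each by a semi-global alignment of the
*full-length* consensus at 80% or 90% identity; overlapping candidates are
resolved best-first.  A pigeonhole argument guarantees no misses at ≥90%
identity for ≥150-bp consensi: at 10% divergence, substitutions are on
average 10 bp apart, so runs of ≥12 intact bases are abundant; parity at
80% is enforced against a brute-force sliding oracle in the tests.  The
age profile is `young_fraction = n90/n80` (high = young family);
contig-end-truncated copies are excluded from both counts.

Alignment scoring throughout is match +1, mismatch −1, linear gap −2
(configurable); the published analysis used closed-source tools whose
internal scoring is unrecoverable, so the thresholds are honored and the
scoring is ours.  Identity is matches over alignment columns *including*
internal gaps; `N` never matches and scores as a mismatch.

## 6. TSDs, tails, dimers

`detect_tsd()` searches lengths 15 down to 10 for a direct repeat whose
left instance ends, and right instance starts, within `max_offset` of the
copy boundaries (0 for exact loci; the pipeline uses 12 to tolerate
boundary slack), with `max_mismatch = 0` by default (configurable to 1).
Under the abutting constraint, a spuriously longer repeat requires the TSD
to be internally periodic, so exact plants are recovered exactly.

`classify_tail()` reports perfect tandem repeats (primitive unit 1–6 bp,
≥3 repeats, span ≥8 bp) in the 3′-terminal 60 bp, canonicalized by minimal
rotation.  Because tails are terminal structures, runs are accepted by
chaining from the 3′ end (each accepted run may extend the reach by
`end_slack = 15` bp); this keeps chance micro-repeats in the body from
reporting as tails while still classifying heterogeneous multi-unit tails
as `mixed`.  Note one honest limitation: with a microsatellite tail the
element end is only defined up to the repeat phase, so called lengths can
differ from truth by one unit.

`detect_dimers()` reports a model as a composite when a prefix aligns to
one family and a suffix to another (each ≥80% identity), total coverage
≥90%, junction gap/overlap ≤30 bp.

## 7. The small-RNA arm

Reads are filtered to 26–31 nt (the piRNA range) and collapsed to unique
sequences with multiplicities.  The copy database takes every ≥80% copy,
extracted element-sense, with everything 5′ of the head end removed — tRNA
fragments from TE-independent tRNA genes are abundant PIWI-independent
products and would contaminate the counts.  The head boundary on each copy
is *projected through the consensus-to-copy alignment*, not applied as a
fixed offset.  The consensus head end itself is the B-box end plus
`head_pad = 15` bp, a compromise for the tRNA segment downstream of the B
box (real tRNAs extend ~10–20 bp beyond it).

"Zero mismatches" is implemented as exact substring search (per-width
constant-width dictionaries), reporting every target, offset and
orientation; multireads count at every locus because no multi-mapping
policy is stated for the original analysis.  Per-gene counting weighs each
(read, gene, orientation) once by the read's multiplicity, counts only hits
fully inside introns, and reports exon-overlapping hits separately as a
violation diagnostic.  The cluster caller is a deliberately simple
density-window proxy for a dedicated piRNA-cluster tool (windows of 5 kb,
≥5 unique sequences, ≥0.002 reads/bp, merged below one window gap);
externally produced cluster BED files can be ingested instead.  Both the
unique-sequence and multiplicity-weighted sizes of the SINE-related pool
are reported, since published pool sizes are ambiguous between the two.

## 8. The synthetic world

`sim_config()` defaults describe the world the pipeline assumes: a 2-Mb
genome in two contigs; four families with copy counts 3/10/30/100 whose
young copies diverge up to 2/4/6/8% — small families young, mirroring the
observed age structure in which the rarest family is the most recent — plus
a `degenerate_fraction` (0.25) of copies at 10–18% divergence supplying the
80-but-not-90% identity class; TSD lengths uniform on 10–15 bp; tails with
a tandem span of at least 10 bp (a 5-bp poly(A) would be indistinguishable
from background); one intron-resident copy per family, each in its own
4-exon gene.  Copies are placed at least 1.2 kb apart so neighbouring
copies never share a discovery window.  Reads: SINE-derived reads sampled
from copy bodies (never heads) in both orientations, tRNA-head decoys, and
background reads rejection-sampled so neither they nor their reverse
complements occur in any gene span.

Divergence is substitution-only by default with an *exact* count
(`round(d * L)` positions), so planted identity maps one-to-one onto the
80/90% thresholds.  The generator also records, by direct substring scan of
the intron sequences, which genes every distinct read sequence hits in
which orientation — that is the ground truth `count_by_gene()` must
reproduce read for read.  The one-intron-copy-per-family rule exists
precisely to make that truth well-defined: with two copies of one family in
two genes, a clean read from either copy matches both and per-origin
attribution stops being meaningful.

What the generator does **not** emulate — hence what a green test does not
establish: sequencing error and quality, indel-dominated divergence
(`indel` divergence is configurable but off by default), nested or
fragmented insertions, 5′-truncated copies, CpG-biased substitution, tail
length polymorphism between copies, or genome-scale repeat families beyond
the planted ones.  Recovery statements therefore apply to well-separated,
substitution-diverged, full-length copies.

## 9. Known limitations

* Single linkage + the 90% edge threshold cannot recover a family whose
  low-divergence core has fewer than three promoter-bearing copies; such
  families surface only in the copy scan once some consensus exists.
* With microsatellite tails the 3′ boundary is defined only up to repeat
  phase (±1 unit).
* The proTRAC-style cluster caller is a proxy; for published cluster
  coordinates run the dedicated tool and ingest its BED.
* The E-value filter used by the original genome-wide expansion is
  deliberately replaced by identity/coverage thresholds; no Karlin–Altschul
  statistics are computed.
* Runtime scales with anchor count x window length; the defaults are tuned
  for multi-megabase genomes on one CPU, not for gigabase assemblies in one
  sitting (the copy scan, however, is seed-bounded and scales well).
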