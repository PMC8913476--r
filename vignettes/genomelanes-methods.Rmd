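---
title: "Methods: the genomelanes data model, view geometry, and test worlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the genomelanes data model, view geometry, and test worlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomelanes)
```

`genomelanes` is the computational core of a multi-genome comparative
browser, built as a headless library: given per-genome gene models
(GFF3), assemblies (FASTA), an ortholog table and an annotation table,
it computes what each genome track of a comparative view shows, resolves
cross-genome equivalence, extracts sequence, and renders static SVG.
This vignette records the model, the choices that were genuinely open,
and what the test suite does and does not demonstrate.

## Coordinates and the data model

All genomic coordinates are 1-based closed intervals, the native GFF3
convention, from parsing through view computation; the only conversion
to a different space (pixels) happens inside the renderer. Keeping a
single convention end to end removes the usual half-open/closed
off-by-one drift between modules. Region overlap is likewise
closed-interval: a query touching a gene's last base returns that gene.

A *canonical feature* is a gene identity independent of any particular
assembly; a *genome feature* is its annotation in one genome. The model
enforces at most one instance of a canonical id per genome. Features
whose GFF3 record lacks the canonical-id attribute (key configurable,
default `curie`) become genome-private: they are displayed but never
joined by a swim lane, mirroring real strain annotation sets in which
many predicted genes have no cross-strain identity. The catalog's
interval index is built on `IRanges`; the test suite holds it to exact
agreement with a vectorized linear scan over thousands of randomized
regions, so the index is an optimization, never a semantic.

Ties in query results (equal start) are broken by feature id so that
every consumer — rendering, the backend, the tests — sees one canonical
order.

## Homology resolution

Within one organism, equivalence is simply canonical-id sharing; across
organisms it follows the ortholog pair table. The pair table is
validated on load: ids must exist in the catalog, self-pairs and
same-organism pairs are dropped with warnings, and pairs are unordered
and deduplicated.

Paralogs are *inferred* with a deliberately simple rule: two canonical
ids of the same organism are paralogs when they share at least one
ortholog in another organism. The rule is symmetric and irreflexive, is
checked against brute-force common-neighbor enumeration, and is isolated
behind `infer_paralogs()` precisely because it is a stand-in — curated
paralogy assertions could replace it without touching any caller.

Orientation flags (`same`/`opposite`) compare gene strands against the
anchor's instance in the first displayed genome that carries one (or the
first member, when the anchor's own organism is not displayed). Swim
lanes are colored by this transcriptional concordance, not by on-screen
direction: in an aligned view a minus-strand ortholog is drawn flipped
so its 5′ end lines up, yet its lane stays "opposite", which is the
biologically informative signal.

## View geometry

**Reference mapping.** Any displayed genome can be the reference. Its
region's canonical features are resolved to homologs per genome; per
chromosome with at least one homolog, the bounding interval padded by
10% per side becomes a segment. Genomes with no homolog get an explicit
placeholder segment — absence is part of the view, not an error.

**Aligned views.** "Scaled so the selected feature occupies
approximately the same span" is made exact and testable: a fixed
occupancy fraction *o* (default 0.4, configurable in (0,1)). Each
instance of length *L* gets a segment of length `round(L / o)` placed so
the strand-aware 5′ end sits `round((1−o)/2 · len)` from the segment's
5′ display edge; minus-strand instances set `flipped`. All bp arithmetic
rounds half-up and then clamps into the chromosome, so the invariant the
suite asserts — 5′ offsets equal across tracks within 1 bp, occupancy
within 1/L of *o* — holds wherever the chromosome leaves room for the
segment; near a chromosome end the segment is clamped into bounds and
the anchor shifts off-center by necessity, which the tests acknowledge
by asserting only unclamped tracks.

**Split views.** A genome whose homolog instances lie on different
chromosomes, or farther apart than 10× the rendered view length on one
chromosome (threshold configurable — the upstream behavior is described
only qualitatively), gets one segment per instance group. In
`align_on_feature()` a multi-instance genome simply receives one aligned
segment per instance: each is positioned and scaled by the same rule,
which *is* the split view, so no separate merge step exists to disagree
with it.

**Navigation.** Locked scroll applies the reference-track delta scaled
by `segment length / reference segment length`, preserving each
segment's length ratio to the reference; zoom scales about the fixed
segment midpoint. Flipped segments scroll in display direction (negative
genomic delta) so locked navigation feels uniform on screen; the
upstream description is silent on this, and the choice is confined to
`navigate()`.

**View-state codec.** The state string is a flat `key=value&…` grammar
(documented in `decode_view_state()`), order-insensitive, with unknown
keys rejected by name. Round-trip exactness is asserted for every view
kind; it is what makes bookmarking and the CLI's `view` subcommand
trustworthy.

## Sequence operations

Spliced transcript sequence is the exon concatenation in transcription
order, reverse-complemented for minus-strand genes. CDS extraction
concatenates CDS segments in translation order and trims the first
segment's phase from the 5′ end of the coding-orientation sequence.
Translation uses the standard nuclear code only (the gene models in
scope are nuclear); a codon containing any N yields `X`, internal stops
render `*`, a trailing stop is dropped. Extraction and
reverse-complement delegate to Biostrings; translation is a direct
codon-table lookup because the N-handling contract above is stricter
than fuzzy-codon resolution, and the tests hold it to an independently
hand-written codon table.

The sequence cart stores descriptors, never sequence, so it is
unbounded. A download is rejected when it exceeds 4000 sequences or
100,000,000 residues. "100 MB" is interpreted as residue characters of
the emitted records, headers and newlines excluded — the simplest
testable reading. Both caps are computed from descriptor-predicted
lengths (exact for every descriptor kind) before any sequence is
materialized, so rejecting an oversized download costs nothing. Output
is uppercase regardless of assembly soft-masking, FASTA at 60 columns
with descriptor headers verbatim, which makes downloads byte-stable.
Region drag selection maps the dragged fraction of the source segment
onto every displayed genome's segment when scroll lock is on (mirrored
across flipped segments); dragging right-to-left sets the
reverse-complement flag.

## Rendering

Rendering is a pure function: identical inputs produce byte-identical
SVG (fixed attribute order, `%.2f` coordinates, no timestamps), which is
what makes golden-file and string-search tests meaningful. Within a
track, each segment takes an equal horizontal slice; bp map linearly to
x, mirrored for flipped segments. Feature rows are assigned by
deterministic first-fit bumping over glyph-plus-label extents (sorted by
start, ties by id); expanded features claim one row per transcript
separated by the configured gap. Connectors are quadrilaterals joining a
gene's glyph spans on *vertically adjacent* tracks only — adjacency
matches how the figures of multi-track viewers read, and avoids
crossing ambiguity; consequently an absent middle track breaks the
visible chain, and the absence itself is announced by the placeholder
message. Lane fills default to `lightgray` (same orientation) and
`salmon` (a light red, for opposite); "light red" has no SVG keyword, so
a named near-equivalent was chosen over a hex literal to keep settings
legible. Connectors are drawn for selected/highlighted genes by default
or for every gene in view with `lanes = "all"`. Fonts are referenced by
family name only, never embedded.

## The static-file backend

The backend mirrors a static-file server layout: per genome a JSON
manifest, per chromosome GFF3 chunks tiled in fixed bp windows (default
4 Mb; the upstream tiling granularity is unpublished, so it is a
parameter), and sequence as fixed-width 60-column plain text addressed
by computed byte offsets. Features overlapping a chunk boundary are
written into every chunk they overlap; readers deduplicate by feature
id. This duplication keeps the reader trivial — every query reads only
the chunks it overlaps, which the tests observe through an access log.
Every chunk file for a chromosome exists (empty ones hold only the
version pragma) so a missing file is unambiguously corruption. Builds
are deterministic and therefore idempotent to the byte, which the suite
asserts by hashing the tree twice.

## Synthetic worlds

`fixture_spec()` defines a world: genomes × chromosomes ×
genes-per-chromosome, chromosome length, seed, and scenario set. Gene
lengths are uniform on 1–50 kb by default, each gene carries 1–4
transcripts with up to 4 exons, and protein-coding genes get a CDS whose
total length is a multiple of 3 with GFF3-correct per-segment phases
(recomputed if a scenario flips the strand). The biotype mix is fixed at
70% protein-coding / 20% pseudogene / 10% lncRNA to exercise the
biotype filter. One pseudo-random stream per genome, derived from
(seed, genome index), means adding a genome never perturbs the others —
the property that keeps golden files stable as worlds grow. Same seed,
same bytes: directory-level determinism is itself a test.

Scenarios instantiate the situations the viewer exists for: `drop_gene`
(a gene absent from exactly one strain), `invert_gene` (opposite
orientation in one strain), `polymorphic_pseudogene` (coding in most
strains, pseudogenized — biotype changed, CDS stripped — in one),
`split_ortholog` (one gene of a second organism with orthologs on two
chromosomes of the first), `paralog_family` (a 3×2 complete-bipartite
ortholog family, giving exactly 3 + 1 inferred paralog pairs), and
`boundary_straddle` (a recorded gene/boundary pair for chunk-duplication
tests). When a cross-organism scenario is requested the last genome
becomes a second organism with its own canonical ids.

The generator emulates annotation *structure*, not biology: base
composition is uniform, splice sites are arbitrary, intron lengths are
not realistic, and no assembly gaps or soft-masking exist. Passing tests
therefore demonstrate the correctness of the bookkeeping — coordinates,
homology resolution, view geometry, serialization — on well-formed
inputs, not robustness to the pathologies of real annotation pipelines
(that robustness lives in the explicit error contracts of the parsers).

## Problem sizes and defaults

The suite runs its oracle-equivalence checks at 1000 randomized regions
against a 5000-feature catalog (interval index), and 1000 randomized
probes each for backend region and sequence fetches against smaller
sequence-bearing worlds; sequence algebra uses 1000 random strings and
100 random CDSs. These sizes were chosen to cover chunk boundaries,
strand mixes, and empty results many times over while keeping a full run
in the low minutes on one core. Defaults worth knowing: occupancy 0.4,
reference-mapping margin 10%, split threshold 10× view length, chunk
size 4 Mb, cart caps 4000 sequences / 10^8 residues, FASTA width 60,
track width 800 px.

## Known limitations

- Annotation-term matching is exact (case-insensitive) with no ontology
  expansion; a query for a parent term will not return genes annotated
  to descendants.
- One GFF3 per genome is taken as authoritative; merging multiple
  annotation sources into a unified catalog is out of scope.
- The paralog rule is an inference, not an assertion set.
- Homology is id- and table-driven; there is no sequence-similarity or
  synteny-based inference.
- Rendering draws lanes only between adjacent tracks; track order
  therefore changes which connections are visible (as in the viewers
  this mirrors).
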