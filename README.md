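# genomelanes

A headless R backend for comparative browsing of multiple annotated
genomes — mouse strain panels, assembly versions of one reference, or
reference genomes of different organisms side by side.

Genome browsers traditionally show one genome. Comparative questions —
*is this gene annotated in every strain? is the missing annotation a real
deletion or an assembly gap? where are the orthologs of this human gene
in mouse, and in which orientation?* — need several genomes displayed as
parallel tracks with equivalent features connected across them.
`genomelanes` implements the computational core of such a viewer as a
library plus CLI, with no browser attached: the data model, the
comparative view geometry, sequence extraction, and deterministic SVG
rendering.

## The model

The central abstraction separates a gene's *identity* from its
*annotations*:

- a **canonical feature** is an assembly-independent gene identity with a
  stable accession (e.g. an `MGI:`-style curie) and a symbol;
- a **genome feature** is one gene annotation in one genome: coordinates,
  strand, biotype, and a gene → transcript → exon/CDS hierarchy parsed
  from GFF3.

A canonical gene has at most one instance per genome; genomes lacking an
instance are *absent* for that gene, which drives both the
presence/absence display filter and the rendered "not found" messages.
Cross-genome equivalence ("swim lanes") is resolved three ways:

- **strains of one organism** share canonical ids directly;
- **different organisms** are linked by an ortholog pair table
  (`canonical_a ↔ canonical_b`);
- **paralogs** are inferred: two genes of one organism are paralogs when
  they share at least one ortholog in another organism (a documented,
  replaceable stand-in rule).

Comparative views are computed, not drawn, in genomic coordinates
(1-based, closed intervals throughout):

- `map_reference_region()` — any genome can serve as the reference; its
  displayed region determines, via homology, which region(s) every other
  genome shows;
- `align_on_feature()` — 5′-anchored aligned views: each homolog's track
  is scaled so the gene occupies a fixed fraction *o* of its segment
  (default 0.4) and its strand-aware 5′ end sits at offset (1−*o*)/2
  from the segment's 5′ display edge; minus-strand instances are flipped
  so 5′ ends coincide visually;
- `split_segments()` — when homologs lie on different chromosomes (or
  far apart), the track splits into independently scrollable segments;
- `navigate()` — locked scroll/zoom scales deltas by segment length so
  relative coverage is preserved;
- `encode_view_state()` / `decode_view_state()` — the whole view
  (genomes, segments, mode, filters, selections) round-trips through a
  bookmarkable `key=value&…` string.

Sequence access goes through a **sequence cart** of descriptors (what to
extract, not the sequence): genomic windows, spliced transcripts, and
phase-aware CDS with optional reverse complement and translation. The
cart itself is unbounded; a single download is capped at 4000 sequences
and 100,000,000 residues. `render_view_svg()` draws the whole view —
tracks, glyphs, labels, placeholders, and swim-lane connector polygons
colored light gray / light red for same / opposite transcriptional
orientation — as byte-stable SVG. `build_backend()` materializes the
catalog as a static-file store (JSON manifests, GFF3 chunks tiled in
fixed bp windows, fixed-width plain-text sequence files) that serves
region and sequence requests from flat files.

Everything is exercised against seeded synthetic worlds from
`fixture_spec()` / `generate_fixture()`, whose scenarios reproduce the
phenomena the viewer must handle: a gene dropped from one genome, an
inverted gene, an ortholog split across chromosomes, a
complete-bipartite paralog family, a chunk-boundary straddler, and a
polymorphic pseudogene.

## Worked example

```r
library(genomelanes)

spec <- fixture_spec(n_genomes = 3, seed = 1,
                     scenarios = c("drop_gene", "invert_gene"))
world <- build_fixture_world(spec)
world$catalog
#> <feature_catalog> 3 genomes, 47 features, 16 canonical ids

drop_id <- world$manifest$scenarios$drop_gene$canonical_id
strain_distribution(world$catalog, drop_id)
#>    genome      feature_id chromosome  start    end strand absent
#> 1 strainA strainA_G010002       chr1  92130 122305      -  FALSE
#> 2 strainB            <NA>       <NA>     NA     NA   <NA>   TRUE
#> 3 strainC strainC_G010002       chr1 107102 137277      -  FALSE
```

The distribution table is the per-strain view of one canonical gene:
`strainB` carries no annotation for it. An aligned view centers every
genome on its instance; the carrier tracks are flipped (minus strand) so
5′ ends coincide, and the gene occupies 30176/75440 ≈ 0.4 of each
segment:

```r
state <- align_on_feature(world$catalog, world$hom, drop_id)
state
#> <view_state> 3 genomes, mode: aligned-on:CANA:010002
#>   strainA : chr1:69498..144937 (flipped)
#>   strainB : (placeholder)
#>   strainC : chr1:84470..159909 (flipped)

encode_view_state(state)
#> [1] "genomes=strainA,strainB,strainC&mode=aligned-on:CANA:010002&seg.strainA=chr1:69498..144937r&seg.strainB=.&seg.strainC=chr1:84470..159909r&sel=CANA:010002"

scene <- render_view_svg(state, world$catalog, world$hom)
scene
#> <svg_scene> 2 gene glyphs, 0 transcript glyphs, 0 lanes, 1 placeholders
```

The scene manifest counts what was drawn: one glyph per carrier track, a
"not found" message on the `strainB` track, and no connector polygons —
lanes join vertically *adjacent* tracks, and the absent middle track
breaks the chain. `writeLines(scene$svg, "view.svg")` saves the image.

## Command line

A launcher ships under `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","genomelanes.R",package="genomelanes"))')" \
    fixture demo --seed 1 --genomes 3
# → fixture written under demo (48 features)
Rscript .../genomelanes.R build demo/config.yaml demo-backend
Rscript .../genomelanes.R dist demo/config.yaml CANA:010002
Rscript .../genomelanes.R list demo/annotations.tsv disease parkinsonism-like
```

Subcommands: `build`, `view`, `seq`, `dist`, `list`, `fixture`. Exit
codes: 0 success, 1 operational failure (caps, resolution), 2
usage/config error.

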