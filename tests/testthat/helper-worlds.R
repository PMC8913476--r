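# Shared fixture worlds (memoized: built once per test run) and
# independent oracles used across the suite.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- builder()
  .world_cache[[key]]
}

# small world with sequence, both organisms, every scenario
scenario_world <- function() {
  cached("scenario", function() build_fixture_world(fixture_spec(
    n_genomes = 4, n_chromosomes = 2, genes_per_chromosome = 8,
    chromosome_bp = 600000, seed = 42,
    scenarios = c("drop_gene", "invert_gene", "split_ortholog",
                  "paralog_family", "boundary_straddle",
                  "polymorphic_pseudogene"))))
}

# same-organism world with only the paralog family (clean pair counts)
family_world <- function() {
  cached("family", function() build_fixture_world(fixture_spec(
    n_genomes = 2, n_chromosomes = 2, genes_per_chromosome = 8,
    chromosome_bp = 600000, seed = 11, scenarios = "paralog_family",
    with_sequence = FALSE)))
}

# large annotation-only world for interval-index oracle checks
big_world <- function() {
  cached("big", function() build_fixture_world(fixture_spec(
    n_genomes = 2, n_chromosomes = 2, genes_per_chromosome = 1250,
    chromosome_bp = 40e6, seed = 7, with_sequence = FALSE)))
}

# tiny sequence-bearing world for sequence/backend tests
tiny_world <- function() {
  cached("tiny", function() build_fixture_world(fixture_spec(
    n_genomes = 2, n_chromosomes = 2, genes_per_chromosome = 6,
    chromosome_bp = 80000, seed = 3, gene_bp = c(1000, 8000))))
}

# scenario world written to disk (GFF3/FASTA/TSV/manifest), once
scenario_dir <- function() {
  cached("scenario_dir", function() {
    dir <- file.path(tempdir(), "glw-scenario")
    generate_fixture(fixture_spec(
      n_genomes = 4, n_chromosomes = 2, genes_per_chromosome = 8,
      chromosome_bp = 600000, seed = 42,
      scenarios = c("drop_gene", "invert_gene", "split_ortholog",
                    "paralog_family", "boundary_straddle",
                    "polymorphic_pseudogene")), dir)
    dir
  })
}

# ---- oracles ------------------------------------------------------------

# brute-force linear scan over the catalog's flat table
scan_region <- function(catalog, genome, chromosome, start, end) {
  tab <- catalog$table
  sel <- tab$genome == genome & tab$chromosome == chromosome &
    tab$start <= end & tab$end >= start
  keys <- tab$key[sel]
  feats <- catalog$features[keys]
  ord <- order(vapply(feats, `[[`, 0, "start"),
               vapply(feats, `[[`, "", "feature_id"))
  unname(feats[ord])
}

# hand-written standard nuclear codon table (independent of the
# implementation's lookup)
.oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  aas <- paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIIMTTTTNNKKSSRR",   # ATT..AGG
    "VVVVAAAADDEEGGGG")   # GTT..GGG
  codons <- as.vector(sapply(bases, function(b1)
    sapply(bases, function(b2) paste0(b1, b2, bases))))
  stats::setNames(strsplit(aas, "")[[1]], codons)
})

oracle_translate <- function(s) {
  s <- toupper(s)
  n <- nchar(s) %/% 3
  cods <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(.oracle_code[cods])
  aa[is.na(aa)] <- "X"
  if (n > 0 && aa[n] == "*") aa <- aa[-n]
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# brute-force shared-neighbor paralog enumeration from a raw pair table
oracle_paralogs <- function(pairs, organism_of) {
  ids <- sort(unique(c(pairs$a, pairs$b)))
  nb <- function(x) sort(unique(c(pairs$b[pairs$a == x], pairs$a[pairs$b == x])))
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    a <- ids[i]; b <- ids[j]
    if (!identical(organism_of(a), organism_of(b))) next
    if (length(intersect(nb(a), nb(b))) > 0)
      out[[length(out) + 1L]] <- data.frame(a = a, b = b,
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# fixture canonical ids encode the organism in their prefix
fixture_organism_of <- function(id) substr(id, 1, 4)

# strip list names for structural feature comparison
feature_fields <- function(feats) {
  lapply(unname(feats[order(vapply(feats, `[[`, "", "feature_id"))]), unclass)
}

random_chrom_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small hand-built catalog: two genomes, one chromosome, fully
# controlled coordinates, for arithmetic-exact tests
manual_world <- function(lenA = 10000, lenB = 20000, strandB = "+",
                         chrom_bp = 200000) {
  gA <- genome_info("gA", data.frame(name = "c1", length = chrom_bp),
                    taxon = "orgX")
  gB <- genome_info("gB", data.frame(name = "c1", length = chrom_bp),
                    taxon = "orgX")
  fA <- genome_feature("A1", "gA", "c1", 50001, 50000 + lenA, "+",
                       canonical_id = "CX:1", symbol = "gene1")
  fB <- genome_feature("B1", "gB", "c1", 90001, 90000 + lenB, strandB,
                       canonical_id = "CX:1", symbol = "gene1")
  catalog <- feature_catalog(list(gA, gB), list(fA, fB))
  list(catalog = catalog, hom = homology_map(catalog = catalog))
}
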