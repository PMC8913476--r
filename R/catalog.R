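# Coordinates are 1-based closed intervals everywhere in the model (GFF3
# convention); pixel-space conversion happens only in the renderer.

#' Describe a genome
#'
#' A genome is one assembly of one organism: a short unique label, an
#' assembly version, an organism (taxon) label, and an ordered set of
#' chromosomes with their lengths.
#'
#' @param name Short unique genome label (track label).
#' @param chromosomes Data frame with columns `name` and `length` (bp),
#'   in display order. Chromosome names must be unique, lengths positive.
#' @param assembly Assembly version label.
#' @param taxon Organism label. Genomes sharing a taxon are treated as
#'   strains/assemblies of the same organism for homology resolution.
#' @return A `genome_info` object.
#' @export
genome_info <- function(name, chromosomes, assembly = "unknown", taxon = "unknown") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  if (!all(c("name", "length") %in% names(chromosomes)))
    stop("chromosomes must have columns 'name' and 'length'")
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names in genome '", name, "'")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be > 0 in genome '", name, "'")
  structure(
    list(name = name, assembly = assembly, taxon = taxon,
         chromosomes = chromosomes[, c("name", "length")]),
    class = "genome_info"
  )
}

#' @export
print.genome_info <- function(x, ...) {
  cat("<genome>", x$name, " assembly:", x$assembly, " taxon:", x$taxon,
      " chromosomes:", nrow(x$chromosomes), "\n")
  invisible(x)
}

chrom_length <- function(genome, chromosome) {
  i <- match(chromosome, genome$chromosomes$name)
  if (is.na(i))
    stop("unknown chromosome '", chromosome, "' in genome '", genome$name, "'")
  genome$chromosomes$length[i]
}

#' Construct a transcript
#'
#' @param transcript_id Accession.
#' @param exons Data frame (or 2-column matrix) with columns `start`,
#'   `end`: 1-based closed exon intervals. Stored sorted ascending;
#'   overlapping exons are rejected.
#' @param cds Optional data frame with columns `start`, `end`, `phase`
#'   (phase in 0..2); each CDS segment must lie within an exon.
#' @return A `transcript` object.
#' @export
transcript <- function(transcript_id, exons, cds = NULL) {
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  names(exons)[1:2] <- c("start", "end")
  exons$start <- as.numeric(exons$start); exons$end <- as.numeric(exons$end)
  exons <- exons[order(exons$start, exons$end), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) == 0L) stop("transcript '", transcript_id, "' has no exons")
  if (any(exons$end < exons$start))
    stop("exon with end < start in transcript '", transcript_id, "'")
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript '", transcript_id, "'")
  if (!is.null(cds)) {
    cds <- as.data.frame(cds, stringsAsFactors = FALSE)
    names(cds)[1:3] <- c("start", "end", "phase")
    cds$start <- as.numeric(cds$start); cds$end <- as.numeric(cds$end)
    cds$phase <- as.integer(cds$phase)
    cds <- cds[order(cds$start), c("start", "end", "phase"), drop = FALSE]
    rownames(cds) <- NULL
    if (!all(cds$phase %in% 0:2))
      stop("CDS phase must be 0, 1 or 2 in transcript '", transcript_id, "'")
  }
  structure(list(transcript_id = transcript_id, exons = exons, cds = cds),
            class = "transcript")
}

transcript_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

#' Construct a genome feature (one gene annotation in one genome)
#'
#' @param feature_id Genome-specific accession.
#' @param genome Genome name.
#' @param chromosome Chromosome name.
#' @param start,end 1-based closed coordinates.
#' @param strand "+" or "-".
#' @param biotype Controlled biotype term (e.g. "protein_coding",
#'   "pseudogene", "lncRNA").
#' @param canonical_id Optional canonical (assembly-independent) gene id;
#'   `NA` makes the feature genome-private (no swim lane).
#' @param symbol Gene symbol; defaults to the feature id.
#' @param transcripts List of [transcript()] objects.
#' @return A `genome_feature` object.
#' @export
genome_feature <- function(feature_id, genome, chromosome, start, end, strand,
                           biotype = "protein_coding", canonical_id = NA_character_,
                           symbol = feature_id, transcripts = list()) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for feature '", feature_id, "'")
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid coordinates for feature '", feature_id, "'")
  structure(
    list(feature_id = feature_id, genome = genome, chromosome = chromosome,
         start = start, end = end, strand = strand, biotype = biotype,
         canonical_id = if (is.null(canonical_id)) NA_character_ else canonical_id,
         symbol = symbol, transcripts = transcripts),
    class = "genome_feature"
  )
}

#' @export
print.genome_feature <- function(x, ...) {
  cat(sprintf("<feature> %s %s:%s:%d-%d(%s) %s canon:%s tx:%d\n",
              x$feature_id, x$genome, x$chromosome, x$start, x$end, x$strand,
              x$biotype, ifelse(is.na(x$canonical_id), "-", x$canonical_id),
              length(x$transcripts)))
  invisible(x)
}

feature_key <- function(genome, feature_id) paste0(genome, "::", feature_id)

#' Assemble a feature catalog
#'
#' The catalog holds every displayed genome, every gene annotation, the
#' canonical-gene registry linking instances of the same gene across
#' genomes, and a per-(genome, chromosome) interval index used by
#' [query_region()].
#'
#' @param genomes List of [genome_info()] objects, in display order.
#' @param features List of [genome_feature()] objects.
#' @return A `feature_catalog` object.
#' @export
feature_catalog <- function(genomes, features) {
  if (inherits(genomes, "genome_info")) genomes <- list(genomes)
  names(genomes) <- vapply(genomes, `[[`, "", "name")
  if (anyDuplicated(names(genomes))) stop("duplicate genome names")

  keys <- vapply(features, function(f) feature_key(f$genome, f$feature_id), "")
  if (anyDuplicated(keys)) stop("duplicate feature ids within a genome")
  names(features) <- keys

  # canonical registry: id -> symbol, organism, per-genome instance
  canon <- list()
  for (f in features) {
    cid <- f$canonical_id
    if (is.na(cid)) next
    g <- genomes[[f$genome]]
    if (is.null(g)) stop("feature '", f$feature_id, "' references unknown genome '", f$genome, "'")
    entry <- canon[[cid]]
    if (is.null(entry)) {
      entry <- list(canonical_id = cid, symbol = f$symbol, organism = g$taxon,
                    instances = character())
    }
    if (f$genome %in% names(entry$instances))
      stop("canonical id '", cid, "' has more than one instance in genome '", f$genome, "'")
    entry$instances[[f$genome]] <- f$feature_id
    canon[[cid]] <- entry
  }

  # flat vectors for the linear-scan paths and the interval index
  tab <- data.frame(
    key = keys,
    feature_id = vapply(features, `[[`, "", "feature_id"),
    genome = vapply(features, `[[`, "", "genome"),
    chromosome = vapply(features, `[[`, "", "chromosome"),
    start = vapply(features, `[[`, 0, "start"),
    end = vapply(features, `[[`, 0, "end"),
    stringsAsFactors = FALSE
  )

  index <- list()
  if (nrow(tab) > 0L) {
    grp <- paste0(tab$genome, "::", tab$chromosome)
    for (g in unique(grp)) {
      sel <- which(grp == g)
      index[[g]] <- list(
        ir = IRanges::IRanges(start = tab$start[sel], end = tab$end[sel]),
        keys = tab$key[sel]
      )
    }
  }

  txmap <- character()
  for (f in features)
    for (tx in f$transcripts)
      txmap[[tx$transcript_id]] <- feature_key(f$genome, f$feature_id)

  structure(
    list(genomes = genomes, features = features, canon = canon,
         table = tab, index = index, txmap = txmap),
    class = "feature_catalog"
  )
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("<feature_catalog>", length(x$genomes), "genomes,",
      length(x$features), "features,", length(x$canon), "canonical ids\n")
  invisible(x)
}

get_genome <- function(catalog, genome) {
  g <- catalog$genomes[[genome]]
  if (is.null(g)) stop("unknown genome '", genome, "'")
  g
}

get_feature <- function(catalog, genome, feature_id) {
  f <- catalog$features[[feature_key(genome, feature_id)]]
  if (is.null(f)) stop("unknown feature '", feature_id, "' in genome '", genome, "'")
  f
}

get_canonical <- function(catalog, canonical_id) {
  cf <- catalog$canon[[canonical_id]]
  if (is.null(cf)) stop("unknown canonical id '", canonical_id, "'")
  cf
}

#' Instances of a canonical gene
#'
#' @param catalog A [feature_catalog()].
#' @param canonical_id Canonical gene id.
#' @return List of `genome_feature` objects, in catalog genome order.
#' @export
canonical_instances <- function(catalog, canonical_id) {
  cf <- get_canonical(catalog, canonical_id)
  out <- list()
  for (g in names(catalog$genomes)) {
    fid <- unname(cf$instances[g])
    if (!is.null(fid) && !is.na(fid))
      out[[length(out) + 1L]] <- catalog$features[[feature_key(g, fid)]]
  }
  out
}

get_transcript <- function(catalog, transcript_id) {
  key <- unname(catalog$txmap[transcript_id])
  if (length(key) != 1L || is.na(key))
    stop("unknown transcript '", transcript_id, "'")
  f <- catalog$features[[key]]
  for (tx in f$transcripts)
    if (tx$transcript_id == transcript_id) return(list(feature = f, tx = tx))
  stop("unknown transcript '", transcript_id, "'")
}

#' Query features overlapping a region
#'
#' Closed-interval overlap (touching endpoints count), served by the
#' per-chromosome interval index. Results are sorted by start, ties
#' broken by feature id.
#'
#' @param catalog A [feature_catalog()].
#' @param genome Genome name.
#' @param chromosome Chromosome name.
#' @param start,end Query interval, 1-based closed, within chromosome
#'   bounds.
#' @return List of `genome_feature` objects.
#' @export
query_region <- function(catalog, genome, chromosome, start, end) {
  g <- get_genome(catalog, genome)
  clen <- chrom_length(g, chromosome)
  if (start > end) stop("query start > end")
  if (start < 1 || end > clen)
    stop("query region out of chromosome bounds [1, ", clen, "]")
  idx <- catalog$index[[paste0(genome, "::", chromosome)]]
  if (is.null(idx)) return(list())
  hits <- IRanges::findOverlaps(IRanges::IRanges(start, end), idx$ir)
  keys <- idx$keys[S4Vectors::subjectHits(hits)]
  feats <- catalog$features[keys]
  ord <- order(vapply(feats, `[[`, 0, "start"),
               vapply(feats, `[[`, "", "feature_id"))
  unname(feats[ord])
}

#' Strain distribution of a canonical gene
#'
#' One row per catalog genome, in catalog order, giving the
#' genome-specific identifier and location of the gene, or marking the
#' genome as lacking an annotation.
#'
#' @param catalog A [feature_catalog()].
#' @param canonical_id Canonical gene id.
#' @return Data frame with columns genome, feature_id, chromosome,
#'   start, end, strand, absent (logical).
#' @export
strain_distribution <- function(catalog, canonical_id) {
  cf <- get_canonical(catalog, canonical_id)
  gs <- names(catalog$genomes)
  rows <- lapply(gs, function(g) {
    fid <- unname(cf$instances[g])
    if (is.null(fid) || is.na(fid)) {
      data.frame(genome = g, feature_id = NA_character_,
                 chromosome = NA_character_, start = NA_real_, end = NA_real_,
                 strand = NA_character_, absent = TRUE, stringsAsFactors = FALSE)
    } else {
      f <- catalog$features[[feature_key(g, fid)]]
      data.frame(genome = g, feature_id = f$feature_id,
                 chromosome = f$chromosome, start = f$start, end = f$end,
                 strand = f$strand, absent = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate a catalog against the model invariants
#'
#' Checks every structural invariant of the data model and reports each
#' violation without stopping: coordinates within chromosome bounds,
#' strand values, transcripts within the gene span, exon disjointness,
#' CDS segments contained in exons, CDS length, and canonical-id
#' referential integrity.
#'
#' @param catalog A [feature_catalog()].
#' @return Data frame with columns `entity` and `rule`; zero rows when
#'   the catalog is clean.
#' @export
validate_catalog <- function(catalog) {
  bad <- list()
  report <- function(entity, rule)
    bad[[length(bad) + 1L]] <<- data.frame(entity = entity, rule = rule,
                                           stringsAsFactors = FALSE)
  for (f in catalog$features) {
    g <- catalog$genomes[[f$genome]]
    if (is.null(g)) { report(f$feature_id, "unknown genome"); next }
    ci <- match(f$chromosome, g$chromosomes$name)
    if (is.na(ci)) { report(f$feature_id, "unknown chromosome"); next }
    clen <- g$chromosomes$length[ci]
    if (f$start < 1 || f$start > f$end)
      report(f$feature_id, "start must satisfy 1 <= start <= end")
    if (f$end > clen)
      report(f$feature_id, "end exceeds chromosome length")
    if (!f$strand %in% c("+", "-"))
      report(f$feature_id, "strand not in {+,-}")
    if (!is.na(f$canonical_id) && is.null(catalog$canon[[f$canonical_id]]))
      report(f$feature_id, "canonical id missing from registry")
    for (tx in f$transcripts) {
      sp <- transcript_span(tx)
      if (sp[1] < f$start || sp[2] > f$end)
        report(tx$transcript_id, "transcript outside gene span")
      ex <- tx$exons
      if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
        report(tx$transcript_id, "overlapping exons")
      if (!is.null(tx$cds) && nrow(tx$cds) > 0L) {
        for (k in seq_len(nrow(tx$cds))) {
          inside <- any(ex$start <= tx$cds$start[k] & tx$cds$end[k] <= ex$end)
          if (!inside)
            report(tx$transcript_id, "CDS segment outside all exons")
        }
        if (sum(tx$cds$end - tx$cds$start + 1) < 3)
          report(tx$transcript_id, "total CDS length < 3")
      }
    }
  }
  for (cf in catalog$canon) {
    if (!nzchar(cf$symbol %||% ""))
      report(cf$canonical_id, "empty symbol")
    for (g in names(cf$instances)) {
      fid <- unname(cf$instances[g])
      if (!is.na(fid) && is.null(catalog$features[[feature_key(g, fid)]]))
        report(cf$canonical_id, "instance feature missing")
    }
  }
  if (length(bad) == 0L)
    return(data.frame(entity = character(), rule = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, bad)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up to integer bp; used wherever bp arithmetic produces
# fractions so results are deterministic across platforms
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
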