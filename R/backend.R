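# Static-file data store: per-genome JSON manifest, per-chromosome GFF3
# annotation chunks tiled in fixed bp windows, and fixed-width plain
# text sequence files, so region and sequence requests are served from
# flat files. Features overlapping a chunk boundary are duplicated into
# every chunk they overlap; readers deduplicate by feature id.

SEQ_LINE_WIDTH <- 60L

chunk_range <- function(start, end, chunk_bp) {
  (floor((start - 1) / chunk_bp)):(floor((end - 1) / chunk_bp))
}

#' Build the static-file backend
#'
#' Writes, under `root`, one directory per genome containing
#' `manifest.json`, `annot/<chromosome>/<k>.gff3` annotation chunks
#' (chunk k covers bp `k*chunk_bp + 1 .. (k+1)*chunk_bp`; every chunk
#' file exists, empty ones hold only the version pragma), and, when an
#' assembly store is supplied, `seq/<chromosome>.txt` as 60-character
#' lines. The build is deterministic: rebuilding yields byte-identical
#' files.
#'
#' @param catalog A [feature_catalog()].
#' @param root Output directory.
#' @param store Optional [assembly_store()] for sequence files.
#' @param chunk_bp Chunk window size in bp (default 4,000,000).
#' @return A `backend_layout` object.
#' @export
build_backend <- function(catalog, root, store = NULL, chunk_bp = 4e6) {
  if (chunk_bp <= 0) stop("chunk_bp must be > 0")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create backend root: ", root)
  manifests <- list()
  for (g in names(catalog$genomes)) {
    gi <- catalog$genomes[[g]]
    gdir <- file.path(root, g)
    dir.create(file.path(gdir, "annot"), recursive = TRUE, showWarnings = FALSE)

    feats <- Filter(function(f) f$genome == g, catalog$features)
    by_chrom <- split(feats, vapply(feats, `[[`, "", "chromosome"))

    for (ci in seq_len(nrow(gi$chromosomes))) {
      chrom <- gi$chromosomes$name[ci]
      clen <- gi$chromosomes$length[ci]
      cdir <- file.path(gdir, "annot", chrom)
      dir.create(cdir, showWarnings = FALSE)
      n_chunks <- ceiling(clen / chunk_bp)
      buckets <- vector("list", n_chunks)
      for (f in by_chrom[[chrom]] %||% list()) {
        for (k in chunk_range(f$start, f$end, chunk_bp)) {
          if (k >= n_chunks) next
          buckets[[k + 1L]] <- c(buckets[[k + 1L]], list(f))
        }
      }
      for (k in seq_len(n_chunks))
        write_gff3(buckets[[k]] %||% list(),
                   file.path(cdir, paste0(k - 1L, ".gff3")))
    }

    has_seq <- !is.null(store) && !is.null(store$sequences[[g]])
    if (has_seq) {
      sdir <- file.path(gdir, "seq")
      dir.create(sdir, showWarnings = FALSE)
      for (ci in seq_len(nrow(gi$chromosomes))) {
        chrom <- gi$chromosomes$name[ci]
        s <- toupper(as.character(store$sequences[[g]][[
          match(chrom, names(store$sequences[[g]]))]]))
        con <- file(file.path(sdir, paste0(chrom, ".txt")), open = "wb")
        writeLines(fasta_wrap(s, SEQ_LINE_WIDTH), con, sep = "\n")
        close(con)
      }
    }

    manifest <- list(
      schema_version = 1L,
      genome = g, assembly = gi$assembly, taxon = gi$taxon,
      chunk_bp = chunk_bp,
      chromosomes = data.frame(name = gi$chromosomes$name,
                               length = gi$chromosomes$length,
                               stringsAsFactors = FALSE),
      sequence = list(available = has_seq, line_width = SEQ_LINE_WIDTH))
    jsonlite::write_json(manifest, file.path(gdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifests[[g]] <- manifest
  }
  structure(list(root = root, manifests = manifests), class = "backend_layout")
}

#' Open an existing backend directory
#'
#' @param root Backend root directory (as written by [build_backend()]).
#' @return A `backend_layout` object.
#' @export
read_backend <- function(root) {
  if (!dir.exists(root)) stop("backend root not found: ", root)
  gdirs <- sort(list.dirs(root, recursive = FALSE))
  manifests <- list()
  for (d in gdirs) {
    mf <- file.path(d, "manifest.json")
    if (!file.exists(mf)) next
    m <- jsonlite::read_json(mf, simplifyVector = TRUE)
    manifests[[m$genome]] <- m
  }
  if (length(manifests) == 0L) stop("no genome manifests under ", root)
  structure(list(root = root, manifests = manifests), class = "backend_layout")
}

#' @export
print.backend_layout <- function(x, ...) {
  cat("<backend_layout>", x$root, ":", length(x$manifests), "genomes\n")
  invisible(x)
}

backend_genome_info <- function(m) {
  genome_info(m$genome, as.data.frame(m$chromosomes), assembly = m$assembly,
              taxon = m$taxon)
}

#' Fetch features from the backend
#'
#' Reads only the annotation chunks overlapping the query, deduplicates
#' boundary-straddling features by feature id, and returns exactly what
#' [query_region()] returns on the in-memory catalog.
#'
#' @param layout A `backend_layout`.
#' @param genome Genome name.
#' @param chromosome Chromosome name.
#' @param start,end Query interval.
#' @param log Optional environment; the paths of every chunk file read
#'   are appended to `log$files`.
#' @return List of `genome_feature` objects sorted by start then
#'   feature id.
#' @export
fetch_region_backend <- function(layout, genome, chromosome, start, end,
                                 log = NULL) {
  m <- layout$manifests[[genome]]
  if (is.null(m)) stop("unknown genome '", genome, "' in backend")
  gi <- backend_genome_info(m)
  clen <- chrom_length(gi, chromosome)
  if (start > end || start < 1 || end > clen)
    stop("query region out of chromosome bounds [1, ", clen, "]")
  feats <- list()
  for (k in chunk_range(start, end, m$chunk_bp)) {
    path <- file.path(layout$root, genome, "annot", chromosome,
                      paste0(k, ".gff3"))
    if (!file.exists(path))
      stop("backend corruption: missing chunk file ", path)
    if (!is.null(log)) log$files <- c(log$files, path)
    feats <- c(feats, parse_gff3(path, gi, quiet = TRUE))
  }
  feats <- feats[!duplicated(vapply(feats, `[[`, "", "feature_id"))]
  feats <- Filter(function(f) f$start <= end && f$end >= start, feats)
  ord <- order(vapply(feats, `[[`, 0, "start"),
               vapply(feats, `[[`, "", "feature_id"))
  unname(feats[ord])
}

#' Fetch sequence from the backend
#'
#' Seeks directly into the fixed-width plain-text sequence file; equals
#' [fetch_genomic()] on the source assembly.
#'
#' @param layout A `backend_layout`.
#' @param genome Genome name.
#' @param chromosome Chromosome name.
#' @param start,end 1-based closed coordinates.
#' @return Uppercase nucleotide string.
#' @export
fetch_sequence_backend <- function(layout, genome, chromosome, start, end) {
  m <- layout$manifests[[genome]]
  if (is.null(m)) stop("unknown genome '", genome, "' in backend")
  if (!isTRUE(m$sequence$available))
    stop("backend for '", genome, "' carries no sequence")
  gi <- backend_genome_info(m)
  clen <- chrom_length(gi, chromosome)
  if (start > end || start < 1 || end > clen)
    stop("coordinates out of bounds [1, ", clen, "]")
  w <- m$sequence$line_width
  path <- file.path(layout$root, genome, "seq", paste0(chromosome, ".txt"))
  if (!file.exists(path)) stop("backend corruption: missing sequence file ", path)
  off1 <- (start - 1) + (start - 1) %/% w   # byte offset incl. newlines
  off2 <- (end - 1) + (end - 1) %/% w
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, where = off1, origin = "start")
  raw <- readChar(con, nchars = off2 - off1 + 1, useBytes = TRUE)
  gsub("\n", "", raw, fixed = TRUE)
}

#' Rebuild a catalog from backend chunks
#'
#' Reads every annotation chunk of every genome, deduplicates by
#' feature id, and reconstructs the feature catalog; the round trip of
#' [build_backend()] then `backend_catalog()` reproduces the original
#' catalog.
#'
#' @param layout A `backend_layout`.
#' @return A `feature_catalog`.
#' @export
backend_catalog <- function(layout) {
  genomes <- list(); features <- list()
  for (g in names(layout$manifests)) {
    m <- layout$manifests[[g]]
    gi <- backend_genome_info(m)
    genomes[[g]] <- gi
    feats <- list()
    for (chrom in gi$chromosomes$name) {
      cdir <- file.path(layout$root, g, "annot", chrom)
      files <- list.files(cdir, pattern = "\\.gff3$", full.names = TRUE)
      files <- files[order(as.integer(sub("\\.gff3$", "", basename(files))))]
      for (path in files)
        feats <- c(feats, parse_gff3(path, gi, quiet = TRUE))
    }
    feats <- feats[!duplicated(vapply(feats, `[[`, "", "feature_id"))]
    features <- c(features, feats)
  }
  feature_catalog(genomes, features)
}
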