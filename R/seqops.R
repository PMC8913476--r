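# Sequence extraction: genomic windows, spliced transcripts, phase-aware
# CDS, translation, and the capped sequence cart. Assemblies are held as
# Biostrings DNAStringSet objects, one per genome.

#' Build an assembly store
#'
#' @param sequences Named list (genome name -> `DNAStringSet` whose
#'   names are chromosome names), or a named character vector of FASTA
#'   paths to read with [Biostrings::readDNAStringSet()].
#' @return An `assembly_store` object.
#' @export
assembly_store <- function(sequences) {
  if (is.character(sequences)) {
    paths <- sequences
    sequences <- lapply(paths, Biostrings::readDNAStringSet)
    names(sequences) <- names(paths)
  }
  for (g in names(sequences)) {
    # FASTA headers may carry descriptions; keep the first word
    names(sequences[[g]]) <- sub("\\s.*$", "", names(sequences[[g]]))
  }
  structure(list(sequences = sequences), class = "assembly_store")
}

#' @export
print.assembly_store <- function(x, ...) {
  cat("<assembly_store>", length(x$sequences), "genomes\n")
  invisible(x)
}

store_chrom <- function(store, genome, chromosome) {
  gs <- store$sequences[[genome]]
  if (is.null(gs)) stop("no assembly loaded for genome '", genome, "'")
  i <- match(chromosome, names(gs))
  if (is.na(i)) stop("unknown chromosome '", chromosome, "' in assembly of '", genome, "'")
  gs[[i]]
}

#' Fetch a genomic sequence window
#'
#' @param store An [assembly_store()].
#' @param genome Genome name.
#' @param chromosome Chromosome name.
#' @param start,end 1-based closed coordinates within the chromosome.
#' @param revcomp Return the reverse complement.
#' @return Uppercase nucleotide string of length `end - start + 1`.
#' @export
fetch_genomic <- function(store, genome, chromosome, start, end, revcomp = FALSE) {
  chr <- store_chrom(store, genome, chromosome)
  if (start < 1 || end > length(chr) || start > end)
    stop("coordinates out of bounds [1, ", length(chr), "]")
  s <- toupper(as.character(Biostrings::subseq(chr, start, end)))
  if (revcomp) reverse_complement(s) else s
}

#' Reverse complement
#'
#' Standard complement over {A,C,G,T,N}, reversed; an involution.
#'
#' @param seq Nucleotide string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  if (!grepl("^[ACGTNacgtn]*$", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Spliced transcript sequence
#'
#' Exon sequences concatenated in transcription order; minus-strand
#' transcripts are returned reverse-complemented (coding orientation).
#'
#' @param catalog A [feature_catalog()].
#' @param store An [assembly_store()].
#' @param transcript_id Transcript accession.
#' @return Nucleotide string of length sum(exon lengths).
#' @export
spliced_sequence <- function(catalog, store, transcript_id) {
  rec <- get_transcript(catalog, transcript_id)
  f <- rec$feature; tx <- rec$tx
  parts <- vapply(seq_len(nrow(tx$exons)), function(k)
    fetch_genomic(store, f$genome, f$chromosome,
                  tx$exons$start[k], tx$exons$end[k]), "")
  s <- paste(parts, collapse = "")
  if (f$strand == "-") reverse_complement(s) else s
}

#' CDS sequence of a transcript
#'
#' CDS segments concatenated in translation order in coding orientation,
#' with the first segment's phase honored by trimming that many leading
#' bases.
#'
#' @param catalog A [feature_catalog()].
#' @param store An [assembly_store()].
#' @param transcript_id Transcript accession; must carry CDS segments.
#' @return Nucleotide string.
#' @export
cds_sequence <- function(catalog, store, transcript_id) {
  rec <- get_transcript(catalog, transcript_id)
  f <- rec$feature; tx <- rec$tx
  if (is.null(tx$cds) || nrow(tx$cds) == 0L)
    stop("transcript '", transcript_id, "' has no CDS")
  cds <- tx$cds[order(tx$cds$start), , drop = FALSE]
  parts <- vapply(seq_len(nrow(cds)), function(k)
    fetch_genomic(store, f$genome, f$chromosome, cds$start[k], cds$end[k]), "")
  if (f$strand == "+") {
    s <- paste(parts, collapse = "")
    phase <- cds$phase[1L]
  } else {
    s <- reverse_complement(paste(parts, collapse = ""))
    phase <- cds$phase[nrow(cds)]   # first segment in translation order
  }
  if (phase > 0) s <- substring(s, phase + 1)
  s
}

#' Translate a CDS
#'
#' Standard nuclear genetic code; any codon containing N translates to
#' `X`, internal stops render `*`, a trailing stop is dropped, and a
#' trailing incomplete codon is ignored.
#'
#' @param cds Nucleotide string, length >= 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3) stop("CDS shorter than one codon")
  ncod <- n %/% 3
  codons <- substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (aa[ncod] == "*") aa <- aa[-ncod]
  paste(aa, collapse = "")
}

#' Construct a sequence descriptor
#'
#' A cart entry: what to extract, not the sequence itself. Explicit
#' coordinates imply genomic kind; `translate` requires CDS kind.
#'
#' @param genome Genome name.
#' @param kind "genomic", "transcript" or "cds".
#' @param target Feature/transcript id (transcript, cds) or
#'   `list(chromosome=, start=, end=)` (genomic).
#' @param revcomp Reverse-complement the extracted sequence.
#' @param translate Emit the amino-acid translation (CDS only).
#' @param header FASTA header text; a default is derived from the
#'   target.
#' @return A `sequence_descriptor` object.
#' @export
seq_descriptor <- function(genome, kind = c("genomic", "transcript", "cds"),
                           target, revcomp = FALSE, translate = FALSE,
                           header = NULL) {
  kind <- match.arg(kind)
  if (translate && kind != "cds")
    stop("translate is only valid for CDS descriptors")
  if (is.list(target)) {
    if (kind != "genomic")
      stop("explicit coordinates imply a genomic descriptor")
    stopifnot(all(c("chromosome", "start", "end") %in% names(target)))
  }
  if (is.null(header)) {
    header <- if (is.list(target))
      sprintf("%s:%s:%s..%s%s", genome, target$chromosome,
              fmt_bp(target$start), fmt_bp(target$end),
              if (revcomp) " (reverse complement)" else "")
    else sprintf("%s:%s:%s%s", genome, kind, target,
                 if (translate) " (translated)" else "")
  }
  structure(list(genome = genome, kind = kind, target = target,
                 revcomp = isTRUE(revcomp), translate = isTRUE(translate),
                 header = header),
            class = "sequence_descriptor")
}

#' Create an empty sequence cart
#'
#' The cart holds descriptors only, so it is unbounded; the download
#' caps apply when the cart is resolved.
#'
#' @return A `sequence_cart` object.
#' @export
sequence_cart <- function() {
  structure(list(entries = list()), class = "sequence_cart")
}

#' Add descriptors to a cart
#'
#' @param cart A [sequence_cart()].
#' @param ... `sequence_descriptor` objects (or lists of them).
#' @return The updated cart.
#' @export
cart_add <- function(cart, ...) {
  for (d in list(...)) {
    if (inherits(d, "sequence_descriptor")) cart$entries <- c(cart$entries, list(d))
    else cart$entries <- c(cart$entries, d)
  }
  cart
}

#' @export
print.sequence_cart <- function(x, ...) {
  cat("<sequence_cart>", length(x$entries), "descriptors\n")
  invisible(x)
}

# residues the descriptor will resolve to, computable without fetching
descriptor_length <- function(desc, catalog) {
  n <- switch(desc$kind,
    genomic = desc$target$end - desc$target$start + 1,
    transcript = {
      tx <- get_transcript(catalog, desc$target)$tx
      sum(tx$exons$end - tx$exons$start + 1)
    },
    cds = {
      rec <- get_transcript(catalog, desc$target)
      tx <- rec$tx
      if (is.null(tx$cds) || nrow(tx$cds) == 0L)
        stop("descriptor '", desc$header, "' targets a transcript without CDS")
      total <- sum(tx$cds$end - tx$cds$start + 1)
      phase <- if (rec$feature$strand == "+") tx$cds$phase[1L]
               else tx$cds$phase[nrow(tx$cds)]
      total - phase
    })
  if (desc$translate) n %/% 3 else n
}

resolve_descriptor <- function(desc, store, catalog) {
  s <- switch(desc$kind,
    genomic = fetch_genomic(store, desc$genome, desc$target$chromosome,
                            desc$target$start, desc$target$end),
    transcript = spliced_sequence(catalog, store, desc$target),
    cds = cds_sequence(catalog, store, desc$target))
  if (desc$revcomp) s <- reverse_complement(s)
  if (desc$translate) s <- translate_cds(s)
  s
}

fasta_wrap <- function(seq, width = 60) {
  n <- nchar(seq)
  if (n == 0L) return(character())
  starts <- seq(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

#' Resolve a sequence cart into FASTA text
#'
#' Resolves every descriptor, applies reverse-complement and translate
#' flags, and emits FASTA (60-character lines, descriptor headers
#' verbatim). The whole download is rejected when the cart holds more
#' than `max_sequences` entries or resolves to more than `max_residues`
#' residues; both checks run before any sequence is materialized.
#'
#' @param cart A [sequence_cart()].
#' @param store An [assembly_store()].
#' @param catalog A [feature_catalog()].
#' @param max_sequences Sequence-count cap (default 4000).
#' @param max_residues Residue cap (default 100,000,000; residue
#'   characters, headers excluded).
#' @return FASTA text as a single string.
#' @export
cart_download <- function(cart, store, catalog,
                          max_sequences = 4000, max_residues = 100e6) {
  n <- length(cart$entries)
  if (n > max_sequences)
    stop("download rejected: ", n, " sequences exceeds the sequence-count cap of ",
         max_sequences)
  total <- 0
  for (d in cart$entries) total <- total + descriptor_length(d, catalog)
  if (total > max_residues)
    stop("download rejected: ", fmt_bp(total),
         " residues exceeds the size cap of ", fmt_bp(max_residues))
  out <- character()
  for (d in cart$entries) {
    s <- tryCatch(resolve_descriptor(d, store, catalog), error = function(e)
      stop("unresolvable descriptor '", d$header, "': ", conditionMessage(e),
           call. = FALSE))
    out <- c(out, paste0(">", d$header), fasta_wrap(s))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Build region-selection descriptors (option-drag)
#'
#' One genomic descriptor for the dragged region; with scroll lock on,
#' the corresponding region (same fractional span of the first segment,
#' mirrored on flipped segments) of every displayed genome is selected
#' too. Dragging right to left activates reverse complementation.
#'
#' @param state A `view_state`.
#' @param genome Genome the drag happened in (must be displayed).
#' @param chromosome,start,end Dragged region.
#' @param drag_direction "left_to_right" or "right_to_left".
#' @param scroll_lock Select from all displayed genomes.
#' @return List of `sequence_descriptor` objects.
#' @export
region_select_descriptors <- function(state, genome, chromosome, start, end,
                                      drag_direction = c("left_to_right", "right_to_left"),
                                      scroll_lock = FALSE) {
  drag_direction <- match.arg(drag_direction)
  if (!genome %in% state$genomes)
    stop("genome '", genome, "' is not displayed in this view")
  rc <- drag_direction == "right_to_left"
  mk <- function(g, ch, s, e)
    seq_descriptor(g, "genomic", list(chromosome = ch, start = s, end = e),
                   revcomp = rc)
  if (!scroll_lock)
    return(list(mk(genome, chromosome, start, end)))
  src <- Filter(function(s) !s$placeholder, state$segments[[genome]])
  if (length(src) == 0L) stop("source genome has only placeholder segments")
  src <- src[[1L]]
  slen <- segment_length(src)
  f1 <- clamp((start - src$start) / slen, 0, 1)
  f2 <- clamp((end - src$start + 1) / slen, 0, 1)
  out <- list()
  for (g in state$genomes) {
    if (identical(g, genome)) { out[[length(out) + 1L]] <- mk(g, chromosome, start, end); next }
    segs <- Filter(function(s) !s$placeholder, state$segments[[g]])
    if (length(segs) == 0L) next
    seg <- segs[[1L]]
    len <- segment_length(seg)
    ff <- if (xor(seg$flipped, src$flipped)) c(1 - f2, 1 - f1) else c(f1, f2)
    s <- seg$start + round_half_up(ff[1] * len)
    e <- seg$start + round_half_up(ff[2] * len) - 1
    s <- clamp(s, seg$start, seg$end); e <- clamp(e, s, seg$end)
    out[[length(out) + 1L]] <- mk(g, seg$chromosome, s, e)
  }
  out
}

#' Write or read a cart exchange file
#'
#' One descriptor per line, TSV with columns genome, kind, target,
#' chromosome, start, end, revcomp, translate, header.
#'
#' @param cart A [sequence_cart()].
#' @param path File path.
#' @return `write_cart` returns `path` invisibly; `read_cart` returns a
#'   `sequence_cart`.
#' @export
write_cart <- function(cart, path) {
  rows <- vapply(cart$entries, function(d) {
    if (is.list(d$target))
      paste(d$genome, d$kind, "", d$target$chromosome, fmt_bp(d$target$start),
            fmt_bp(d$target$end), as.integer(d$revcomp),
            as.integer(d$translate), d$header, sep = "\t")
    else
      paste(d$genome, d$kind, d$target, "", "", "", as.integer(d$revcomp),
            as.integer(d$translate), d$header, sep = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste("genome", "kind", "target", "chromosome", "start", "end",
                     "revcomp", "translate", "header", sep = "\t"), rows),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_cart
#' @export
read_cart <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(start = "numeric", end = "numeric"))
  cart <- sequence_cart()
  for (k in seq_len(nrow(tab))) {
    r <- tab[k, ]
    target <- if (nzchar(r$target %||% "") && !is.na(r$target)) r$target
              else list(chromosome = r$chromosome, start = r$start, end = r$end)
    cart <- cart_add(cart, seq_descriptor(r$genome, r$kind, target,
                                          revcomp = r$revcomp == 1,
                                          translate = r$translate == 1,
                                          header = r$header))
  }
  cart
}
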