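# Comparative view computation: which region of each genome a track
# shows. Modes: free (independent tracks), locked (synchronized
# navigation), aligned-on:<id> (5'-anchored, occupancy-scaled).

#' Construct a region segment
#'
#' One displayed window of one genome track. `flipped` marks a segment
#' drawn reverse-complemented (its right display edge is the lowest
#' genomic coordinate).
#'
#' @param genome Genome name.
#' @param chromosome Chromosome name.
#' @param start,end 1-based closed coordinates, start <= end.
#' @param flipped Draw reversed.
#' @return A `region_segment` object.
#' @export
region_segment <- function(genome, chromosome, start, end, flipped = FALSE) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid segment coordinates: start must be <= end")
  if (start < 1) stop("segment start below 1")
  structure(list(genome = genome, chromosome = chromosome, start = start,
                 end = end, flipped = isTRUE(flipped), placeholder = FALSE),
            class = "region_segment")
}

#' Placeholder segment for a genome lacking any homolog
#'
#' @param genome Genome name.
#' @param note Optional id/symbol the placeholder refers to (drives the
#'   rendered "not found" message).
#' @return A `region_segment` with `placeholder = TRUE`.
#' @export
placeholder_segment <- function(genome, note = NA_character_) {
  structure(list(genome = genome, chromosome = NA_character_,
                 start = NA_real_, end = NA_real_, flipped = FALSE,
                 placeholder = TRUE, note = note),
            class = "region_segment")
}

segment_length <- function(seg) seg$end - seg$start + 1

#' Construct a view state
#'
#' The complete, serializable description of one comparative view:
#' displayed genomes in track order, the region segment(s) each track
#' shows, the navigation mode, the optional reference genome, display
#' filters, selected canonical ids and an optional gene-list mode.
#'
#' @param genomes Character vector of genome names, track order.
#' @param segments Named list (genome name -> list of
#'   [region_segment()]); every displayed genome needs at least one
#'   segment.
#' @param mode "free", "locked", or "aligned-on:<canonical id>".
#' @param reference Optional reference genome name.
#' @param filters A [filter_spec()].
#' @param selections Character vector of selected canonical ids.
#' @param list_mode Optional `list(name =, mode =)` with mode one of
#'   "highlight", "restrict", "exclude".
#' @return A `view_state` object.
#' @export
view_state <- function(genomes, segments, mode = "free", reference = NA_character_,
                       filters = filter_spec(), selections = character(),
                       list_mode = NULL) {
  if (length(genomes) == 0L) stop("view state requires at least one genome")
  if (!all(genomes %in% names(segments)))
    stop("every displayed genome needs at least one segment")
  if (!(mode %in% c("free", "locked") || startsWith(mode, "aligned-on:")))
    stop("unknown view mode '", mode, "'")
  for (g in genomes) {
    if (length(segments[[g]]) == 0L)
      stop("genome '", g, "' has no segments")
  }
  if (!is.null(list_mode) &&
      !(is.list(list_mode) && list_mode$mode %in% c("highlight", "restrict", "exclude")))
    stop("list_mode must be list(name=, mode=) with a valid mode")
  structure(list(genomes = as.character(genomes),
                 segments = segments[genomes],
                 mode = mode,
                 reference = reference,
                 filters = filters,
                 selections = sort(unique(as.character(selections))),
                 list_mode = list_mode),
            class = "view_state")
}

#' @export
print.view_state <- function(x, ...) {
  cat("<view_state>", length(x$genomes), "genomes, mode:", x$mode, "\n")
  for (g in x$genomes) {
    segs <- vapply(x$segments[[g]], function(s) {
      if (s$placeholder) "(placeholder)"
      else sprintf("%s:%s..%s%s", s$chromosome, fmt_bp(s$start), fmt_bp(s$end),
                   if (s$flipped) " (flipped)" else "")
    }, "")
    cat(" ", g, ":", paste(segs, collapse = ", "), "\n")
  }
  invisible(x)
}

clamp_segment <- function(seg, clen) {
  # preserve length where possible, truncate to the chromosome otherwise
  len <- segment_length(seg)
  if (len >= clen) { seg$start <- 1; seg$end <- clen; return(seg) }
  if (seg$start < 1) { seg$start <- 1; seg$end <- len }
  if (seg$end > clen) { seg$end <- clen; seg$start <- clen - len + 1 }
  seg
}

#' Map a reference region onto the other displayed genomes
#'
#' Implements reference-genome browsing: collect every canonical feature
#' overlapping the reference region, resolve its homologs in each other
#' displayed genome, and give each genome one segment per chromosome
#' carrying at least one homolog (the bounding interval of its homologs,
#' padded by `margin` of the interval width per side). Genomes with no
#' homolog get a placeholder; the reference keeps its region verbatim.
#'
#' @param catalog A [feature_catalog()].
#' @param hom A `homology_map`.
#' @param reference Reference genome name.
#' @param region A [region_segment()] in the reference genome.
#' @param genomes Displayed genomes (default: all).
#' @param margin Padding fraction per side (default 0.1).
#' @return A `view_state` in "free" mode with `reference` set.
#' @export
map_reference_region <- function(catalog, hom, reference, region,
                                 genomes = names(catalog$genomes),
                                 margin = 0.1) {
  if (!identical(region$genome, reference))
    stop("region does not belong to the reference genome")
  feats <- query_region(catalog, reference, region$chromosome,
                        region$start, region$end)
  cids <- unique(stats::na.omit(vapply(feats, `[[`, "", "canonical_id")))
  segments <- list()
  for (g in genomes) {
    if (identical(g, reference)) {
      segments[[g]] <- list(region)
      next
    }
    rows <- list()
    for (cid in cids) {
      hs <- homologs_of(catalog, hom, cid, genomes = g, mode = "ortholog")
      if (nrow(hs$members)) rows[[length(rows) + 1L]] <- hs$members
    }
    if (length(rows) == 0L) {
      segments[[g]] <- list(placeholder_segment(g))
      next
    }
    mem <- unique(do.call(rbind, rows))
    gi <- get_genome(catalog, g)
    chroms <- intersect(gi$chromosomes$name, unique(mem$chromosome))
    segs <- list()
    for (ch in chroms) {
      sel <- mem[mem$chromosome == ch, , drop = FALSE]
      lo <- min(sel$start); hi <- max(sel$end)
      pad <- round_half_up(margin * (hi - lo + 1))
      seg <- region_segment(g, ch, max(1, lo - pad),
                            min(chrom_length(gi, ch), hi + pad))
      segs[[length(segs) + 1L]] <- seg
    }
    segments[[g]] <- segs
  }
  view_state(genomes, segments, mode = "free", reference = reference)
}

aligned_segment_for <- function(member, gi, occupancy) {
  L <- member$end - member$start + 1
  seglen <- round_half_up(L / occupancy)
  pad5 <- round_half_up((1 - occupancy) / 2 * seglen)
  clen <- chrom_length(gi, member$chromosome)
  if (member$strand == "+") {
    s <- member$start - pad5
    seg <- list(start = s, end = s + seglen - 1, flipped = FALSE)
  } else {
    e <- member$end + pad5
    seg <- list(start = e - seglen + 1, end = e, flipped = TRUE)
  }
  # clamp without changing length when the chromosome allows it
  seg <- clamp_segment(structure(c(list(genome = member$genome,
                                        chromosome = member$chromosome),
                                   seg, list(placeholder = FALSE)),
                                 class = "region_segment"), clen)
  seg
}

#' Compute a 5'-anchored aligned view of a gene across genomes
#'
#' Centers every track on its homolog of the anchor gene: each instance
#' gets a segment of length `feature length / occupancy`, positioned so
#' the feature's strand-aware 5' end sits at the same fractional offset
#' `(1 - occupancy) / 2` from the segment's 5' display edge on every
#' track. Minus-strand instances are flipped so 5' ends coincide
#' visually. Genomes lacking the gene get a placeholder; genomes with
#' several homolog instances get one aligned segment per instance (the
#' split view).
#'
#' @param catalog A [feature_catalog()].
#' @param hom A `homology_map`.
#' @param canonical_id Anchor canonical id.
#' @param genomes Displayed genomes (default: all).
#' @param occupancy Fraction of the segment the feature occupies
#'   (0 < occupancy < 1, default 0.4).
#' @param mode Homology mode, "ortholog" or "paralog".
#' @return A `view_state` in "aligned-on:<id>" mode.
#' @export
align_on_feature <- function(catalog, hom, canonical_id,
                             genomes = names(catalog$genomes),
                             occupancy = 0.4, mode = c("ortholog", "paralog")) {
  mode <- match.arg(mode)
  if (!(occupancy > 0 && occupancy < 1))
    stop("occupancy must be strictly between 0 and 1")
  hs <- homologs_of(catalog, hom, canonical_id, genomes, mode = mode)
  if (nrow(hs$members) == 0L)
    stop("anchor '", canonical_id, "' resolves in none of the displayed genomes")
  segments <- list()
  for (g in genomes) {
    mem <- hs$members[hs$members$genome == g, , drop = FALSE]
    if (nrow(mem) == 0L) {
      segments[[g]] <- list(placeholder_segment(g, note = canonical_id))
      next
    }
    gi <- get_genome(catalog, g)
    ord <- order(match(mem$chromosome, gi$chromosomes$name), mem$start)
    mem <- mem[ord, , drop = FALSE]
    segments[[g]] <- lapply(seq_len(nrow(mem)), function(k)
      aligned_segment_for(mem[k, ], gi, occupancy))
  }
  view_state(genomes, segments, mode = paste0("aligned-on:", canonical_id),
             selections = canonical_id)
}

#' Split segments for a gene's homologs within one genome
#'
#' Emits one segment per group of homolog instances: instances on
#' different chromosomes, or farther apart than
#' `distance_factor * view_bp` on the same chromosome, get independent
#' segments; nearby instances share one bounding segment. Segments are
#' padded by `margin` per side and ordered by chromosome (genome order)
#' then start.
#'
#' @param catalog A [feature_catalog()].
#' @param hom A `homology_map`.
#' @param canonical_id Anchor canonical id.
#' @param genome Genome to split in.
#' @param view_bp Rendered view length used for the distance threshold;
#'   defaults to the largest instance length.
#' @param distance_factor Gap multiple beyond which instances split
#'   (default 10).
#' @param margin Padding fraction per side (default 0.1).
#' @return List of [region_segment()]; empty when the gene has no
#'   instance in the genome.
#' @export
split_segments <- function(catalog, hom, canonical_id, genome,
                           view_bp = NULL, distance_factor = 10, margin = 0.1) {
  hs <- homologs_of(catalog, hom, canonical_id, genomes = genome,
                    mode = "ortholog")
  mem <- hs$members
  if (nrow(mem) == 0L) return(list())
  gi <- get_genome(catalog, genome)
  base <- view_bp %||% max(mem$end - mem$start + 1)
  ord <- order(match(mem$chromosome, gi$chromosomes$name), mem$start)
  mem <- mem[ord, , drop = FALSE]
  segs <- list()
  cur <- NULL
  flush <- function(cur) {
    pad <- round_half_up(margin * (cur$hi - cur$lo + 1))
    region_segment(genome, cur$chrom, max(1, cur$lo - pad),
                   min(chrom_length(gi, cur$chrom), cur$hi + pad))
  }
  for (k in seq_len(nrow(mem))) {
    m <- mem[k, ]
    if (!is.null(cur) && identical(cur$chrom, m$chromosome) &&
        (m$start - cur$hi) <= distance_factor * base) {
      cur$hi <- max(cur$hi, m$end)
    } else {
      if (!is.null(cur)) segs[[length(segs) + 1L]] <- flush(cur)
      cur <- list(chrom = m$chromosome, lo = m$start, hi = m$end)
    }
  }
  segs[[length(segs) + 1L]] <- flush(cur)
  segs
}

#' Scroll or zoom a view
#'
#' In locked (and aligned) mode a scroll of `delta_bp` on the reference
#' track shifts every track by `delta_bp * (segment length / reference
#' segment length)`, preserving relative coverage; zoom multiplies every
#' segment length by the factor about its fixed midpoint. In free mode
#' the action applies only to `target`. Segments are clamped to their
#' chromosomes; flipped segments scroll in display direction (negative
#' genomic shift).
#'
#' @param state A `view_state`.
#' @param catalog A [feature_catalog()] (for chromosome bounds).
#' @param scroll Signed bp delta on the reference segment (exclusive
#'   with `zoom`).
#' @param zoom Positive zoom factor (> 1 widens the view).
#' @param target Genome name for free-mode actions; "all" in locked
#'   mode.
#' @return The updated `view_state`.
#' @export
navigate <- function(state, catalog, scroll = NULL, zoom = NULL, target = "all") {
  if (is.null(scroll) == is.null(zoom))
    stop("supply exactly one of scroll or zoom")
  if (!is.null(zoom) && zoom <= 0) stop("zoom factor must be > 0")
  locked <- state$mode == "locked" || startsWith(state$mode, "aligned-on:")
  apply_to <- if (locked && identical(target, "all")) state$genomes
              else if (identical(target, "all")) stop("free mode requires a target genome")
              else {
                if (!target %in% state$genomes) stop("genome '", target, "' is not displayed")
                target
              }
  ref_genome <- if (!is.na(state$reference %||% NA)) state$reference else state$genomes[1L]
  ref_seg <- Filter(function(s) !s$placeholder, state$segments[[ref_genome]])
  ref_len <- if (length(ref_seg)) segment_length(ref_seg[[1L]]) else NA_real_

  for (g in apply_to) {
    state$segments[[g]] <- lapply(state$segments[[g]], function(seg) {
      if (seg$placeholder) return(seg)
      gi <- get_genome(catalog, g)
      clen <- chrom_length(gi, seg$chromosome)
      if (!is.null(scroll)) {
        d <- if (locked && !is.na(ref_len))
          round_half_up(scroll * segment_length(seg) / ref_len) else scroll
        if (seg$flipped) d <- -d
        seg$start <- seg$start + d; seg$end <- seg$end + d
      } else {
        len <- segment_length(seg)
        newlen <- max(1, round_half_up(len * zoom))
        mid <- (seg$start + seg$end) / 2
        seg$start <- round_half_up(mid - (newlen - 1) / 2)
        seg$end <- seg$start + newlen - 1
      }
      clamp_segment(seg, clen)
    })
  }
  state
}
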