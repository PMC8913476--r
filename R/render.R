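# Deterministic static SVG rendering of a view state: stacked genome
# tracks, gene/transcript glyphs, orientation-colored swim-lane
# connectors, labels, and "not found" placeholders. Rendering is a pure
# function of its inputs: identical inputs give byte-identical SVG.

BIOTYPE_COLORS <- c(protein_coding = "#3b6fb6", pseudogene = "#999999",
                    lncRNA = "#2e8b57")
biotype_color <- function(b) {
  if (b %in% names(BIOTYPE_COLORS)) BIOTYPE_COLORS[[b]] else "#777777"
}

#' Construct render settings
#'
#' The display controls: track width, label font size, feature glyph
#' thickness, the gap between transcript rows, the contrast fade applied
#' to unselected features, transcript expansion, and the swim-lane
#' colors for same/opposite transcriptional orientation.
#'
#' @param track_width_px Track width in pixels.
#' @param font_size_pt Label font size.
#' @param feature_thickness_px Gene/exon glyph height.
#' @param transcript_gap_px Vertical gap between transcript rows.
#' @param contrast_fade Opacity (0..1) of unselected features when a
#'   selection or highlight is active; 1 disables fading.
#' @param expand "none", "selected" or "all": which features show one
#'   row per transcript.
#' @param lane_color_same,lane_color_opposite Swim-lane fill for same /
#'   opposite orientation (defaults light gray / salmon, a light red).
#' @return A `render_settings` object.
#' @export
render_settings <- function(track_width_px = 800, font_size_pt = 10,
                            feature_thickness_px = 10, transcript_gap_px = 4,
                            contrast_fade = 1, expand = c("none", "selected", "all"),
                            lane_color_same = "lightgray",
                            lane_color_opposite = "salmon") {
  expand <- match.arg(expand)
  stopifnot(track_width_px > 0, font_size_pt > 0, feature_thickness_px > 0,
            transcript_gap_px > 0, contrast_fade >= 0, contrast_fade <= 1)
  structure(list(track_width_px = track_width_px, font_size_pt = font_size_pt,
                 feature_thickness_px = feature_thickness_px,
                 transcript_gap_px = transcript_gap_px,
                 contrast_fade = contrast_fade, expand = expand,
                 lane_color_same = lane_color_same,
                 lane_color_opposite = lane_color_opposite),
            class = "render_settings")
}

px <- function(x) sprintf("%.2f", x)

# bp -> x inside one segment slice; pos_right marks the right edge of a
# base so a feature spanning the whole segment maps to the full slice
seg_x <- function(seg, pos, slice_x, slice_w, right = FALSE) {
  len <- segment_length(seg)
  frac <- (pos - seg$start + if (right) 1 else 0) / len
  x <- frac * slice_w
  if (seg$flipped) x <- slice_w - x
  slice_x + x
}

#' Compute pixel geometry for a view
#'
#' Maps genomic coordinates to drawing space: each track's segments get
#' equal horizontal slices of the track width, bp map linearly within a
#' slice (mirrored for flipped segments), features are assigned rows by
#' deterministic first-fit bumping (sorted by start, ties by feature
#' id), and expanded features allocate one row per transcript separated
#' by the transcript gap.
#'
#' @param state A `view_state`.
#' @param features_by_genome Named list (genome -> list of retained
#'   `genome_feature`s) to lay out.
#' @param settings A [render_settings()].
#' @param expand_ids Canonical ids whose transcripts expand when
#'   `settings$expand == "selected"`.
#' @return A `track_layout`: per-track geometry plus total height.
#' @export
compute_layout <- function(state, features_by_genome, settings,
                           expand_ids = character()) {
  W <- settings$track_width_px
  header_h <- settings$font_size_pt + 6
  lane_h <- settings$feature_thickness_px + settings$transcript_gap_px +
    settings$font_size_pt
  tracks <- list()
  y <- 0
  for (g in state$genomes) {
    segs <- state$segments[[g]]
    nseg <- length(segs)
    slice_w <- W / nseg
    geoms <- list()
    lane_end <- numeric()   # per-lane rightmost occupied x
    for (si in seq_len(nseg)) {
      seg <- segs[[si]]
      if (seg$placeholder) next
      if (segment_length(seg) <= 0) stop("zero-length segment in genome '", g, "'")
      slice_x <- (si - 1) * slice_w
      feats <- features_by_genome[[g]] %||% list()
      feats <- Filter(function(f)
        identical(f$chromosome, seg$chromosome) &&
          f$start <= seg$end && f$end >= seg$start, feats)
      ord <- order(vapply(feats, `[[`, 0, "start"),
                   vapply(feats, `[[`, "", "feature_id"))
      for (f in feats[ord]) {
        x1 <- seg_x(seg, max(f$start, seg$start), slice_x, slice_w)
        x2 <- seg_x(seg, min(f$end, seg$end), slice_x, slice_w, right = TRUE)
        if (x2 < x1) { tmp <- x1; x1 <- x2; x2 <- tmp }
        expanded <- settings$expand == "all" ||
          (settings$expand == "selected" && !is.na(f$canonical_id) &&
             f$canonical_id %in% expand_ids)
        nrows <- if (expanded) max(1L, length(f$transcripts)) else 1L
        occ_end <- max(x2, x1 + nchar(f$symbol) * settings$font_size_pt * 0.6)
        # first-fit: lowest lane block of nrows consecutive free lanes
        lane <- 0L
        repeat {
          lanes <- lane + seq_len(nrows)
          while (length(lane_end) < max(lanes)) lane_end <- c(lane_end, -Inf)
          if (all(lane_end[lanes] < x1 - 2)) break
          lane <- lane + 1L
        }
        lane_end[lanes] <- occ_end
        geoms[[length(geoms) + 1L]] <- list(
          feature = f, segment = seg, slice_x = slice_x, x1 = x1, x2 = x2,
          lane = lane, nrows = nrows, expanded = expanded)
      }
    }
    n_lanes <- length(lane_end)
    track_h <- header_h + max(1L, n_lanes) * lane_h + 8
    tracks[[g]] <- list(genome = g, y = y, header_h = header_h,
                        lane_h = lane_h, height = track_h,
                        slice_w = slice_w, segs = segs, geoms = geoms)
    y <- y + track_h
  }
  structure(list(tracks = tracks, width = W, height = y,
                 settings = settings), class = "track_layout")
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  s <- gsub('"', "&quot;", s, fixed = TRUE)
  s
}

#' Render a view to SVG
#'
#' Draws the full scene: one horizontal track per displayed genome,
#' glyphs for the retained features (after display filters and any
#' gene-list mode), swim-lane connector polygons between vertically
#' adjacent tracks for highlighted canonical ids (or all ids with
#' `lanes = "all"`), colored light gray / light red by orientation
#' concordance, and "not found" text placeholders where the gene is
#' absent. Identical inputs yield byte-identical output.
#'
#' @param state A `view_state`.
#' @param catalog A [feature_catalog()].
#' @param hom A `homology_map`.
#' @param settings A [render_settings()].
#' @param lanes "selected" (connectors for selected/highlighted ids) or
#'   "all" (connectors for every canonical id in view).
#' @param lists Named list of [gene_list()] objects, consulted when the
#'   state carries a list mode.
#' @return An `svg_scene`: `list(svg = <document text>, manifest =
#'   <per-track glyph/lane/placeholder counts>)`.
#' @export
render_view_svg <- function(state, catalog, hom, settings = render_settings(),
                            lanes = c("selected", "all"), lists = list()) {
  lanes <- match.arg(lanes)

  highlighted <- state$selections
  features_by_genome <- list()
  for (g in state$genomes) {
    feats <- list()
    for (seg in state$segments[[g]]) {
      if (seg$placeholder) next
      hits <- query_region(catalog, g, seg$chromosome, seg$start, seg$end)
      feats <- c(feats, hits)
    }
    # a feature may fall in two overlapping segments; keep one copy
    feats <- feats[!duplicated(vapply(feats, `[[`, "", "feature_id"))]
    feats <- apply_filters(feats, state$filters, catalog, hom,
                           state$genomes, state$selections)
    if (!is.null(state$list_mode)) {
      gl <- lists[[state$list_mode$name]]
      if (is.null(gl)) stop("unknown gene list '", state$list_mode$name, "'")
      res <- apply_list_mode(feats, gl, state$list_mode$mode)
      feats <- res$retained
      highlighted <- union(highlighted, res$highlighted)
    }
    features_by_genome[[g]] <- feats
  }

  layout <- compute_layout(state, features_by_genome, settings,
                           expand_ids = highlighted)
  th <- settings$feature_thickness_px
  fade_active <- length(highlighted) > 0 && settings$contrast_fade < 1

  body <- character()
  manifest <- list(tracks = list())
  # per-track geometry lookup for connectors: canonical id -> first glyph
  glyph_by_id <- list()

  for (g in state$genomes) {
    tr <- layout$tracks[[g]]
    n_genes <- 0L; n_tx <- 0L; n_ph <- 0L
    body <- c(body, sprintf('<g id="track-%s">', xml_escape(g)))
    body <- c(body, sprintf(
      '<text x="2.00" y="%s" font-family="sans-serif" font-size="%s" font-weight="bold">%s</text>',
      px(tr$y + settings$font_size_pt), px(settings$font_size_pt), xml_escape(g)))
    base_y <- tr$y + tr$height - 4
    body <- c(body, sprintf(
      '<line x1="0.00" y1="%s" x2="%s" y2="%s" stroke="#cccccc" stroke-width="1"/>',
      px(base_y), px(layout$width), px(base_y)))

    # placeholder messages for placeholder segments
    for (si in seq_along(tr$segs)) {
      seg <- tr$segs[[si]]
      if (!seg$placeholder) next
      note <- seg$note %||% NA_character_
      msg <- if (!is.na(note)) {
        sym <- tryCatch(get_canonical(catalog, note)$symbol, error = function(e) note)
        paste0(sym, " not found in this genome")
      } else "no homologous region in this genome"
      body <- c(body, sprintf(
        '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" font-style="italic" fill="#a94442">%s</text>',
        px((si - 1) * tr$slice_w + 4), px(tr$y + tr$header_h + settings$font_size_pt),
        px(settings$font_size_pt), xml_escape(msg)))
      n_ph <- n_ph + 1L
    }

    # "not found" messages for highlighted ids absent from this genome
    # (skip ids a placeholder segment already reports)
    noted <- unlist(lapply(tr$segs, function(s)
      if (s$placeholder) s$note %||% NA_character_ else NA_character_))
    for (cid in sort(highlighted)) {
      if (cid %in% noted) next
      ok <- tryCatch(presence_absence(catalog, hom, cid, g), error = function(e) NA)
      if (isFALSE(unname(ok)[1])) {
        sym <- get_canonical(catalog, cid)$symbol
        body <- c(body, sprintf(
          '<text x="4.00" y="%s" font-family="sans-serif" font-size="%s" font-style="italic" fill="#a94442">%s not found in this genome</text>',
          px(base_y - 2), px(settings$font_size_pt), xml_escape(sym)))
        n_ph <- n_ph + 1L
      }
    }

    for (geom in tr$geoms) {
      f <- geom$feature
      is_hl <- !is.na(f$canonical_id) && f$canonical_id %in% highlighted
      opacity <- if (fade_active && !is_hl) settings$contrast_fade else 1
      y0 <- tr$y + tr$header_h + geom$lane * tr$lane_h
      label_y <- y0 + settings$font_size_pt - 1
      glyph_y <- y0 + settings$font_size_pt + 1
      col <- biotype_color(f$biotype)
      w <- max(geom$x2 - geom$x1, 0.5)
      body <- c(body, sprintf(
        '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" opacity="%s">%s</text>',
        px(geom$x1), px(label_y), px(settings$font_size_pt), px(opacity),
        xml_escape(f$symbol)))
      if (!geom$expanded) {
        body <- c(body, sprintf(
          '<rect class="gene" x="%s" y="%s" width="%s" height="%s" fill="%s" opacity="%s"/>',
          px(geom$x1), px(glyph_y), px(w), px(th), col, px(opacity)))
      } else {
        body <- c(body, sprintf(
          '<rect class="gene" x="%s" y="%s" width="%s" height="1.00" fill="%s" opacity="%s"/>',
          px(geom$x1), px(glyph_y), px(w), col, px(opacity)))
        txs <- f$transcripts
        for (ti in seq_along(txs)) {
          ty <- glyph_y + (ti - 1) * tr$lane_h + 2
          tx <- txs[[ti]]
          sp <- transcript_span(tx)
          body <- c(body, sprintf(
            '<g class="transcript" opacity="%s">', px(opacity)))
          # intron line across the transcript span
          sx1 <- seg_x(geom$segment, max(sp[1], geom$segment$start),
                       geom$slice_x, tr$slice_w)
          sx2 <- seg_x(geom$segment, min(sp[2], geom$segment$end),
                       geom$slice_x, tr$slice_w, right = TRUE)
          if (sx2 < sx1) { tmp <- sx1; sx1 <- sx2; sx2 <- tmp }
          body <- c(body, sprintf(
            '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
            px(sx1), px(ty + th / 2), px(sx2), px(ty + th / 2), col))
          for (k in seq_len(nrow(tx$exons))) {
            es <- max(tx$exons$start[k], geom$segment$start)
            ee <- min(tx$exons$end[k], geom$segment$end)
            if (es > ee) next
            ex1 <- seg_x(geom$segment, es, geom$slice_x, tr$slice_w)
            ex2 <- seg_x(geom$segment, ee, geom$slice_x, tr$slice_w, right = TRUE)
            if (ex2 < ex1) { tmp <- ex1; ex1 <- ex2; ex2 <- tmp }
            body <- c(body, sprintf(
              '<rect class="exon" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
              px(ex1), px(ty), px(max(ex2 - ex1, 0.5)), px(th), col))
          }
          body <- c(body, "</g>")
          n_tx <- n_tx + 1L
        }
      }
      n_genes <- n_genes + 1L
      cid <- f$canonical_id
      if (!is.na(cid) && is.null(glyph_by_id[[g]][[cid]])) {
        if (is.null(glyph_by_id[[g]])) glyph_by_id[[g]] <- list()
        # lanes are colored by transcriptional orientation concordance,
        # so record the genomic strand, not the display orientation
        glyph_by_id[[g]][[cid]] <- list(x1 = geom$x1, x2 = geom$x2,
                                        top = glyph_y, bottom = glyph_y + th,
                                        eff = f$strand)
      }
    }
    body <- c(body, "</g>")
    manifest$tracks[[g]] <- list(genes = n_genes, transcripts = n_tx,
                                 lanes = 0L, placeholders = n_ph)
  }

  # swim-lane connectors between vertically adjacent tracks
  lane_ids <- if (lanes == "all") {
    ids <- unlist(lapply(features_by_genome, function(fs)
      vapply(fs, `[[`, "", "canonical_id")))
    sort(unique(ids[!is.na(ids)]))
  } else sort(unique(highlighted))
  lane_elems <- character()
  n_lanes_total <- 0L
  drawn <- character()
  gs <- state$genomes
  for (cid in lane_ids) {
    # lane membership spans organisms, so member ids differ per genome
    mem <- tryCatch(homologs_of(catalog, hom, cid, gs)$members,
                    error = function(e) NULL)
    if (is.null(mem)) next
    ids_in <- function(g) unique(mem$canonical_id[mem$genome == g])
    first_glyph <- function(g) {
      for (id in sort(ids_in(g)))
        if (!is.null(glyph_by_id[[g]][[id]]))
          return(list(id = id, glyph = glyph_by_id[[g]][[id]]))
      NULL
    }
    for (i in seq_len(length(gs) - 1)) {
      ga <- first_glyph(gs[i]); gb <- first_glyph(gs[i + 1])
      if (is.null(ga) || is.null(gb)) next
      key <- paste(gs[i], ga$id, gs[i + 1], gb$id)
      if (key %in% drawn) next
      drawn <- c(drawn, key)
      a <- ga$glyph; b <- gb$glyph
      col <- if (identical(a$eff, b$eff)) settings$lane_color_same
             else settings$lane_color_opposite
      lane_elems <- c(lane_elems, sprintf(
        '<polygon class="lane" points="%s,%s %s,%s %s,%s %s,%s" fill="%s" opacity="0.5"/>',
        px(a$x1), px(a$bottom), px(a$x2), px(a$bottom),
        px(b$x2), px(b$top), px(b$x1), px(b$top), col))
      manifest$tracks[[gs[i]]]$lanes <- manifest$tracks[[gs[i]]]$lanes + 1L
      n_lanes_total <- n_lanes_total + 1L
    }
  }

  svg <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">\n',
            px(layout$width), px(layout$height), px(layout$width), px(layout$height)),
    paste(c(lane_elems, body), collapse = "\n"),
    "\n</svg>\n")

  manifest$totals <- list(
    genes = sum(vapply(manifest$tracks, function(t) t$genes, 0L)),
    transcripts = sum(vapply(manifest$tracks, function(t) t$transcripts, 0L)),
    lanes = n_lanes_total,
    placeholders = sum(vapply(manifest$tracks, function(t) t$placeholders, 0L)))
  structure(list(svg = svg, manifest = manifest), class = "svg_scene")
}

#' @export
print.svg_scene <- function(x, ...) {
  t <- x$manifest$totals
  cat("<svg_scene>", t$genes, "gene glyphs,", t$transcripts, "transcript glyphs,",
      t$lanes, "lanes,", t$placeholders, "placeholders\n")
  invisible(x)
}
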