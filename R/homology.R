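# Cross-genome equivalence: same-organism strain instances resolve
# through canonical ids; cross-organism equivalence through an ortholog
# pair table; paralogs are inferred by the shared-ortholog-neighbor rule
# (the upstream inference procedure is unpublished, so the rule here is
# a documented, replaceable stand-in).

canon_pair <- function(a, b) {
  flip <- b < a
  data.frame(a = ifelse(flip, b, a), b = ifelse(flip, a, b),
             stringsAsFactors = FALSE)
}

new_homology_map <- function(pairs, catalog) {
  pairs <- unique(canon_pair(pairs$a, pairs$b))
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  adj <- list()
  for (k in seq_len(nrow(pairs))) {
    adj[[pairs$a[k]]] <- c(adj[[pairs$a[k]]], pairs$b[k])
    adj[[pairs$b[k]]] <- c(adj[[pairs$b[k]]], pairs$a[k])
  }
  structure(list(pairs = pairs, adj = adj), class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  cat("<homology_map>", nrow(x$pairs), "ortholog pairs\n")
  invisible(x)
}

#' Load an ortholog pair table
#'
#' Tab-separated file with header `canonical_a<TAB>canonical_b`; each
#' row asserts orthology between two canonical ids of different
#' organisms. Pairs are unordered and deduplicated. Rows naming an id
#' absent from the catalog, self-pairs, and same-organism rows are
#' skipped with a warning giving the count.
#'
#' @param path Path to the TSV file.
#' @param catalog A [feature_catalog()] used to validate ids and
#'   organisms.
#' @return A `homology_map` object.
#' @export
load_homology_table <- function(path, catalog) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("canonical_a", "canonical_b") %in% names(tab)))
    stop("homology table must have columns canonical_a and canonical_b")
  keep <- rep(TRUE, nrow(tab))
  n_unknown <- 0L; n_self <- 0L; n_sameorg <- 0L
  for (k in seq_len(nrow(tab))) {
    a <- tab$canonical_a[k]; b <- tab$canonical_b[k]
    ca <- catalog$canon[[a]]; cb <- catalog$canon[[b]]
    if (is.null(ca) || is.null(cb)) { keep[k] <- FALSE; n_unknown <- n_unknown + 1L; next }
    if (a == b) { keep[k] <- FALSE; n_self <- n_self + 1L; next }
    if (identical(ca$organism, cb$organism)) { keep[k] <- FALSE; n_sameorg <- n_sameorg + 1L }
  }
  if (n_unknown > 0L)
    warning("skipped ", n_unknown, " row(s) with ids absent from the catalog")
  if (n_self > 0L)
    warning("skipped ", n_self, " self-pair row(s)")
  if (n_sameorg > 0L)
    warning("skipped ", n_sameorg, " same-organism row(s)")
  new_homology_map(data.frame(a = tab$canonical_a[keep], b = tab$canonical_b[keep],
                              stringsAsFactors = FALSE), catalog)
}

#' Build a homology map from an in-memory pair table
#'
#' @param pairs Data frame with columns `a`, `b` (canonical ids).
#' @param catalog A [feature_catalog()].
#' @return A `homology_map` object.
#' @export
homology_map <- function(pairs = data.frame(a = character(), b = character()),
                         catalog = NULL) {
  new_homology_map(pairs, catalog)
}

#' Write an ortholog (or inferred-paralog) pair table
#'
#' @param pairs Data frame with columns `a`, `b`.
#' @param path Output path.
#' @export
write_homology_table <- function(pairs, path) {
  pairs <- unique(canon_pair(pairs$a, pairs$b))
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("canonical_a\tcanonical_b",
               paste(pairs$a, pairs$b, sep = "\t")), con, sep = "\n")
  invisible(path)
}

ortholog_neighbors <- function(hom, canonical_id) {
  unique(hom$adj[[canonical_id]] %||% character())
}

#' Infer paralogs by shared ortholog neighbors
#'
#' Two canonical ids of the same organism are called inferred paralogs
#' when they share at least one ortholog in another organism. The
#' relation is symmetric and irreflexive.
#'
#' @param catalog A [feature_catalog()].
#' @param hom A `homology_map` of ortholog pairs.
#' @return Data frame with columns `a`, `b` (a < b), sorted, one row per
#'   inferred pair.
#' @export
infer_paralogs <- function(catalog, hom) {
  out <- list()
  for (x in names(hom$adj)) {
    nb <- ortholog_neighbors(hom, x)
    if (length(nb) < 2L) next
    org <- vapply(nb, function(id) catalog$canon[[id]]$organism, "")
    for (o in unique(org)) {
      ids <- sort(nb[org == o])
      if (length(ids) < 2L) next
      cmb <- utils::combn(ids, 2L)
      for (k in seq_len(ncol(cmb)))
        out[[length(out) + 1L]] <- data.frame(a = cmb[1, k], b = cmb[2, k],
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  pairs <- unique(do.call(rbind, out))
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

paralog_partners <- function(catalog, hom, canonical_id) {
  # paralogs of one id under the shared-neighbor rule
  org <- catalog$canon[[canonical_id]]$organism
  out <- character()
  for (x in ortholog_neighbors(hom, canonical_id)) {
    for (y in ortholog_neighbors(hom, x)) {
      if (y != canonical_id && identical(catalog$canon[[y]]$organism, org))
        out <- c(out, y)
    }
  }
  sort(unique(out))
}

#' Resolve the swim-lane homology set of a canonical gene
#'
#' For genomes of the anchor's organism, the member is the canonical
#' gene's own instance; for genomes of other organisms, members are
#' instances of canonical ids linked to the anchor by an ortholog pair.
#' In paralog mode, inferred paralogs (shared-neighbor rule) of the ids
#' already included are added per organism. Each member carries an
#' orientation flag (same/opposite) relative to the anchor instance in
#' the first displayed genome carrying it, or to the first member if the
#' anchor is not displayed.
#'
#' @param catalog A [feature_catalog()].
#' @param hom A `homology_map`.
#' @param canonical_id Anchor canonical id.
#' @param genomes Genome names to resolve in (default: all catalog
#'   genomes, catalog order).
#' @param mode "ortholog" or "paralog".
#' @return A `homology_set`: list with `mode`, `anchor`,
#'   `reference_strand`, and `members` (data frame: genome, feature_id,
#'   canonical_id, chromosome, start, end, strand, orientation).
#' @export
homologs_of <- function(catalog, hom, canonical_id,
                        genomes = names(catalog$genomes),
                        mode = c("ortholog", "paralog")) {
  mode <- match.arg(mode)
  anchor <- get_canonical(catalog, canonical_id)
  rows <- list()
  for (g in genomes) {
    gi <- get_genome(catalog, g)
    ids <- if (identical(gi$taxon, anchor$organism)) {
      canonical_id
    } else {
      nb <- ortholog_neighbors(hom, canonical_id)
      nb[vapply(nb, function(id) identical(catalog$canon[[id]]$organism, gi$taxon), TRUE)]
    }
    if (mode == "paralog" && length(ids))
      ids <- unique(c(ids, unlist(lapply(ids, paralog_partners,
                                         catalog = catalog, hom = hom))))
    for (id in sort(unique(ids))) {
      fid <- unname(catalog$canon[[id]]$instances[g])
      if (is.null(fid) || is.na(fid)) next
      f <- catalog$features[[feature_key(g, fid)]]
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, feature_id = f$feature_id, canonical_id = id,
        chromosome = f$chromosome, start = f$start, end = f$end,
        strand = f$strand, stringsAsFactors = FALSE)
    }
  }
  members <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome = character(), feature_id = character(),
               canonical_id = character(), chromosome = character(),
               start = numeric(), end = numeric(), strand = character(),
               stringsAsFactors = FALSE)
  rownames(members) <- NULL

  # orientation reference: the anchor's own instance in the first
  # displayed genome that has one; else the first member
  ref_strand <- NA_character_
  anchor_rows <- which(members$canonical_id == canonical_id)
  if (length(anchor_rows)) ref_strand <- members$strand[anchor_rows[1L]]
  else if (nrow(members)) ref_strand <- members$strand[1L]
  members$orientation <- ifelse(members$strand == ref_strand, "same", "opposite")

  structure(list(mode = mode, anchor = canonical_id,
                 reference_strand = ref_strand, members = members),
            class = "homology_set")
}

#' @export
print.homology_set <- function(x, ...) {
  cat("<homology_set>", x$anchor, "mode:", x$mode, "members:",
      nrow(x$members), "\n")
  invisible(x)
}

#' Per-genome presence/absence of a canonical gene
#'
#' A genome is present when ortholog-mode resolution yields at least one
#' instance there; absent entries drive the "not found" placeholders in
#' rendering.
#'
#' @param catalog A [feature_catalog()].
#' @param hom A `homology_map`.
#' @param canonical_id Canonical gene id.
#' @param genomes Genome names (default: all, catalog order).
#' @return Named logical vector (TRUE = present), one entry per genome.
#' @export
presence_absence <- function(catalog, hom, canonical_id,
                             genomes = names(catalog$genomes)) {
  hs <- homologs_of(catalog, hom, canonical_id, genomes, mode = "ortholog")
  out <- genomes %in% hs$members$genome
  names(out) <- genomes
  out
}
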