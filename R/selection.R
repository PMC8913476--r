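# Display filters and gene lists. Filters compose conjunctively and are
# order-independent; gene lists apply highlight / restrict / exclude
# semantics over the features in view.

ANNOTATION_CATEGORIES <- c("function", "phenotype", "disease", "pathway")

#' Construct a display filter specification
#'
#' All criteria are optional and combine conjunctively: a feature is
#' retained iff it passes every active criterion.
#'
#' @param biotypes Optional character set of biotypes to keep.
#' @param min_length,max_length Optional gene-span length bounds in bp
#'   (length = end - start + 1, measured on the gene span).
#' @param differential Keep only features whose canonical gene is
#'   present in at least one and absent from at least one displayed
#'   genome.
#' @param selected_only Keep only features whose canonical id is
#'   selected.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(biotypes = NULL, min_length = NULL, max_length = NULL,
                        differential = FALSE, selected_only = FALSE) {
  if (!is.null(min_length) && !is.null(max_length) && min_length > max_length)
    stop("min_length must be <= max_length")
  structure(list(biotypes = biotypes, min_length = min_length,
                 max_length = max_length, differential = isTRUE(differential),
                 selected_only = isTRUE(selected_only)),
            class = "filter_spec")
}

# per-genome presence of a feature's canonical gene among the displayed
# genomes; genome-private features are present only in their own genome
feature_presence <- function(f, catalog, hom, genomes) {
  if (is.na(f$canonical_id)) {
    out <- genomes == f$genome
    names(out) <- genomes
    return(out)
  }
  presence_absence(catalog, hom, f$canonical_id, genomes)
}

#' Apply display filters to a set of features
#'
#' @param features List of `genome_feature` objects (the features in
#'   view).
#' @param spec A [filter_spec()].
#' @param catalog,hom Needed only for the differential criterion.
#' @param genomes Displayed genome names (differential criterion).
#' @param selections Selected canonical ids (selected-only criterion).
#' @return The retained features (same order).
#' @export
apply_filters <- function(features, spec, catalog = NULL, hom = NULL,
                          genomes = NULL, selections = character()) {
  keep <- vapply(features, function(f) {
    if (!is.null(spec$biotypes) && !(f$biotype %in% spec$biotypes)) return(FALSE)
    len <- f$end - f$start + 1
    if (!is.null(spec$min_length) && len < spec$min_length) return(FALSE)
    if (!is.null(spec$max_length) && len > spec$max_length) return(FALSE)
    if (spec$selected_only &&
        !(!is.na(f$canonical_id) && f$canonical_id %in% selections)) return(FALSE)
    if (spec$differential) {
      if (is.null(catalog) || is.null(hom) || is.null(genomes))
        stop("differential filter needs catalog, hom and displayed genomes")
      p <- feature_presence(f, catalog, hom, genomes)
      if (!(any(p) && any(!p))) return(FALSE)
    }
    TRUE
  }, TRUE)
  features[keep]
}

#' Construct a gene list
#'
#' @param name List name.
#' @param ids Canonical gene ids (non-empty for a saved list).
#' @return A `gene_list` object.
#' @export
gene_list <- function(name, ids) {
  ids <- unique(as.character(ids))
  structure(list(name = name, ids = ids), class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("<gene_list>", x$name, ":", length(x$ids), "ids\n")
  invisible(x)
}

#' Read an annotation table
#'
#' TSV with columns `canonical_id`, `category`, `term`; category must be
#' one of function, phenotype, disease, pathway.
#'
#' @param path Path to the TSV file.
#' @return Data frame of annotation rows.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("canonical_id", "category", "term") %in% names(tab)))
    stop("annotation table must have columns canonical_id, category, term")
  bad <- setdiff(unique(tab$category), ANNOTATION_CATEGORIES)
  if (length(bad))
    stop("unknown annotation categories: ", paste(bad, collapse = ", "))
  tab
}

#' Build a gene list from an annotation query
#'
#' Exact, case-insensitive term match within one category (no ontology
#' expansion). An unmatched term yields an empty list with a warning,
#' not an error.
#'
#' @param annotations Annotation table (see [read_annotation_table()]).
#' @param category One of function, phenotype, disease, pathway.
#' @param term Term text.
#' @param name List name (defaults to "category:term").
#' @return A `gene_list`.
#' @export
list_from_query <- function(annotations, category, term, name = NULL) {
  if (!category %in% ANNOTATION_CATEGORIES)
    stop("unknown annotation category '", category, "'")
  hit <- annotations$category == category &
    tolower(annotations$term) == tolower(term)
  ids <- sort(unique(annotations$canonical_id[hit]))
  if (length(ids) == 0L)
    warning("no genes annotated to ", category, ":'", term, "'")
  gene_list(name %||% paste0(category, ":", term), ids)
}

#' Apply a gene list to the features in view
#'
#' highlight keeps everything and flags list members; restrict keeps
#' only list members; exclude keeps the complement. restrict and
#' exclude on the same list partition the input.
#'
#' @param features List of `genome_feature` objects.
#' @param list A [gene_list()].
#' @param mode "highlight", "restrict" or "exclude".
#' @return `list(retained = <features>, highlighted = <canonical ids>)`.
#' @export
apply_list_mode <- function(features, list, mode = c("highlight", "restrict", "exclude")) {
  mode <- match.arg(mode)
  if (!inherits(list, "gene_list")) stop("not a gene_list")
  member <- vapply(features, function(f)
    !is.na(f$canonical_id) && f$canonical_id %in% list$ids, TRUE)
  switch(mode,
    highlight = list(retained = features,
                     highlighted = intersect(list$ids,
                       vapply(features, `[[`, "", "canonical_id"))),
    restrict = list(retained = features[member], highlighted = character()),
    exclude = list(retained = features[!member], highlighted = character()))
}

#' Write or read a gene list file
#'
#' Newline-delimited canonical ids with a `# name:` header line.
#'
#' @param list A [gene_list()].
#' @param path File path.
#' @return `write_gene_list` returns `path` invisibly; `read_gene_list`
#'   returns a `gene_list`.
#' @export
write_gene_list <- function(list, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("# name: ", list$name), list$ids), con, sep = "\n")
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  name <- "unnamed"
  hdr <- grep("^# name:", lines)
  if (length(hdr)) name <- trimws(sub("^# name:", "", lines[hdr[1L]]))
  ids <- lines[!startsWith(lines, "#") & nzchar(lines)]
  gene_list(name, ids)
}
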