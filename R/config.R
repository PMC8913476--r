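# Configuration: catalog config files (YAML listing genomes and data
# paths) and the tool-level defaults (cart caps, occupancy, chunk size,
# render settings, preset genome groups).

#' Default tool configuration
#'
#' Carries the operational defaults: the download caps (4000 sequences,
#' 100,000,000 residues), the aligned-view occupancy fraction, the
#' backend chunk size, render settings, and preset genome groups,
#' including the eight founder strains of the Collaborative Cross.
#'
#' @return A `gl_config` list.
#' @export
default_config <- function() {
  structure(list(
    cart_max_sequences = 4000,
    cart_max_residues = 100e6,
    occupancy = 0.4,
    chunk_bp = 4e6,
    margin = 0.1,
    render = render_settings(),
    preset_groups = list(
      collaborative_cross_founders = c(
        "A/J", "C57BL/6J", "129S1/SvImJ", "NOD/ShiLtJ",
        "NZO/HlLtJ", "CAST/EiJ", "PWK/PhJ", "WSB/EiJ")
    )
  ), class = "gl_config")
}

#' Load a tool configuration file
#'
#' YAML file whose keys override [default_config()]; unknown keys are
#' an error. `preset_groups` entries replace the defaults wholesale.
#'
#' @param path Path to a YAML config file; `NULL` gives the defaults.
#' @return A `gl_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  known <- c("cart_max_sequences", "cart_max_residues", "occupancy",
             "chunk_bp", "margin", "render", "preset_groups")
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in setdiff(names(user), "render")) cfg[[k]] <- user[[k]]
  if (!is.null(user$render))
    cfg$render <- do.call(render_settings, user$render)
  if (cfg$cart_max_sequences <= 0 || cfg$cart_max_residues <= 0)
    stop("cart limits must be > 0")
  cfg
}

#' Look up a preset genome group
#'
#' @param config A `gl_config`.
#' @param name Group name, e.g. "collaborative_cross_founders".
#' @return Character vector of genome names.
#' @export
preset_group <- function(config, name) {
  g <- config$preset_groups[[name]]
  if (is.null(g)) stop("unknown preset group '", name, "'")
  g
}

#' Load a catalog from a config file
#'
#' Reads the structured catalog config written by [generate_fixture()]
#' (or by hand): a YAML file listing genomes with their GFF3/FASTA
#' paths and chromosomes, plus optional homology and annotation tables.
#' Relative paths resolve against the config file's directory.
#'
#' @param path Path to the catalog config YAML.
#' @param with_sequence Load assemblies (FASTA) too.
#' @return List with `catalog`, `hom`, `store` (NULL if no FASTA),
#'   `annotations` (NULL if none).
#' @export
load_catalog_config <- function(path, with_sequence = TRUE) {
  if (!file.exists(path)) stop("catalog config not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.null(p)) NULL else
    if (startsWith(p, "/")) p else file.path(base, p)
  genomes <- list(); features <- list(); seqs <- list()
  for (gc in cfg$genomes) {
    chroms <- do.call(rbind, lapply(gc$chromosomes, function(ch)
      data.frame(name = ch$name, length = ch$length, stringsAsFactors = FALSE)))
    gi <- genome_info(gc$name, chroms, assembly = gc$assembly %||% "unknown",
                      taxon = gc$taxon %||% "unknown")
    genomes[[gc$name]] <- gi
    gpath <- rel(gc$gff3)
    if (is.null(gpath) || !file.exists(gpath))
      stop("GFF3 file not found for genome '", gc$name, "': ",
           gpath %||% "<missing>")
    features <- c(features, parse_gff3(gpath, gi, quiet = TRUE))
    if (with_sequence && !is.null(gc$fasta)) {
      fpath <- rel(gc$fasta)
      if (!file.exists(fpath))
        stop("FASTA file not found for genome '", gc$name, "': ", fpath)
      seqs[[gc$name]] <- Biostrings::readDNAStringSet(fpath)
    }
  }
  catalog <- feature_catalog(genomes, features)
  hom <- if (!is.null(cfg$homology))
    load_homology_table(rel(cfg$homology), catalog)
  else homology_map(catalog = catalog)
  annotations <- if (!is.null(cfg$annotations))
    read_annotation_table(rel(cfg$annotations)) else NULL
  list(catalog = catalog, hom = hom,
       store = if (length(seqs)) assembly_store(seqs) else NULL,
       annotations = annotations)
}
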