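# Deterministic generator of synthetic multi-genome worlds: FASTA +
# GFF3 + ortholog table + annotation table + a JSON manifest of the
# ground truth. One pseudo-random stream per genome, derived from
# (seed, genome index), so adding a genome never perturbs the others.
# Scenarios reproduce the phenomena a comparative browser must handle:
# a gene dropped from one genome, an inverted gene, an ortholog split
# across chromosomes, a complete-bipartite paralog family, a gene
# straddling a storage chunk boundary, and a polymorphic pseudogene.

FIXTURE_SCENARIOS <- c("drop_gene", "invert_gene", "split_ortholog",
                       "paralog_family", "boundary_straddle",
                       "polymorphic_pseudogene")

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

seed_stream <- function(seed, stream) {
  set.seed(derive_seed(seed, stream), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Specify a synthetic fixture world
#'
#' @param n_genomes Number of genomes. When a cross-organism scenario
#'   (`split_ortholog`, `paralog_family`) is requested the last genome
#'   belongs to a second organism and carries its own canonical ids,
#'   linked to the first organism's through the ortholog table.
#' @param n_chromosomes Chromosomes per genome.
#' @param genes_per_chromosome Genes per chromosome.
#' @param chromosome_bp Chromosome length in bp.
#' @param seed Integer seed fixing all randomness.
#' @param scenarios Character subset of `drop_gene`, `invert_gene`,
#'   `split_ortholog`, `paralog_family`, `boundary_straddle`,
#'   `polymorphic_pseudogene`.
#' @param gene_bp Length-2 range of gene lengths in bp (default 1-50 kb).
#' @param with_sequence Generate assembly sequence (random uniform
#'   A/C/G/T).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_genomes = 4, n_chromosomes = 2,
                         genes_per_chromosome = 8, chromosome_bp = 600000,
                         seed = 1, scenarios = character(),
                         gene_bp = c(1000, 50000), with_sequence = TRUE) {
  stopifnot(n_genomes > 0, n_chromosomes > 0, genes_per_chromosome > 0,
            chromosome_bp > 0, gene_bp[1] >= 100, gene_bp[1] <= gene_bp[2])
  bad <- setdiff(scenarios, FIXTURE_SCENARIOS)
  if (length(bad)) stop("unknown scenarios: ", paste(bad, collapse = ", "))
  cross <- any(c("split_ortholog", "paralog_family") %in% scenarios)
  if (cross && n_genomes < 2)
    stop("cross-organism scenarios need at least 2 genomes")
  if ("split_ortholog" %in% scenarios && n_chromosomes < 2)
    stop("split_ortholog needs at least 2 chromosomes")
  if (length(scenarios) && genes_per_chromosome < 6)
    stop("scenarios need at least 6 genes per chromosome")
  if (any(c("drop_gene", "invert_gene", "polymorphic_pseudogene") %in% scenarios) &&
      n_genomes < 2)
    stop("per-genome scenarios need at least 2 genomes")
  structure(list(n_genomes = n_genomes, n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 chromosome_bp = chromosome_bp, seed = seed,
                 scenarios = scenarios, gene_bp = gene_bp,
                 with_sequence = isTRUE(with_sequence),
                 cross_organism = cross),
            class = "fixture_spec")
}

# phases in GFF3 convention for CDS segments (ascending genomic order),
# honoring translation order for the given strand
compute_phases <- function(segs, strand) {
  ord <- if (strand == "+") order(segs$start) else order(-segs$start)
  lens <- segs$end[ord] - segs$start[ord] + 1
  phases <- integer(length(lens))
  cum <- 0
  for (i in seq_along(lens)) {
    phases[i] <- (3 - cum %% 3) %% 3
    cum <- cum + lens[i]
  }
  segs$phase[ord] <- phases
  segs
}

# relative (1..L) transcript structures for one gene template
build_tx_templates <- function(L, n_tx, coding) {
  lapply(seq_len(n_tx), function(t) {
    n_ex <- sample(1:4, 1)
    if (2 * n_ex - 1 > max(1, L %/% 60)) n_ex <- max(1L, min(n_ex, L %/% 120))
    if (n_ex < 1L) n_ex <- 1L
    nb <- 2L * n_ex - 1L
    w <- stats::runif(nb, 0.5, 1.5)
    lens <- pmax(30, floor(w / sum(w) * L))
    lens[nb] <- L - sum(lens[-nb])      # exact fit; last block is an exon
    if (lens[nb] < 30) {                # fold a short tail into one exon
      n_ex <- 1L; nb <- 1L; lens <- L
    }
    stops <- cumsum(lens)
    starts <- c(1, stops[-nb] + 1)
    exi <- seq(1, nb, by = 2)
    exons <- data.frame(start = starts[exi], end = stops[exi])
    cds <- NULL
    if (coding) {
      E <- sum(exons$end - exons$start + 1)
      utr5 <- min(30, E %/% 10)
      utr3 <- min(30, E %/% 10)
      cds_len <- E - utr5 - utr3
      cds_len <- cds_len - cds_len %% 3
      if (cds_len < 3) { utr5 <- 0; cds_len <- 3 }
      # map transcription-order exonic interval [utr5+1, utr5+cds_len]
      # to genomic segments; strand is applied by the caller via
      # mirroring, so build here in ascending ("+") orientation
      lo <- utr5 + 1; hi <- utr5 + cds_len
      segs <- list(); off <- 0
      for (k in seq_len(nrow(exons))) {
        el <- exons$end[k] - exons$start[k] + 1
        s <- max(lo, off + 1); e <- min(hi, off + el)
        if (s <= e)
          segs[[length(segs) + 1L]] <- data.frame(
            start = exons$start[k] + (s - off - 1),
            end = exons$start[k] + (e - off - 1), phase = 0L)
        off <- off + el
      }
      cds <- do.call(rbind, segs)
    }
    list(exons = exons, cds = cds)
  })
}

mirror_rel <- function(df, L) {
  # reflect relative coordinates so the 5' UTR sits at the high end
  out <- df
  out$start <- L - df$end + 1
  out$end <- L - df$start + 1
  out[order(out$start), , drop = FALSE]
}

biotype_for <- function(u) {
  if (u < 0.7) "protein_coding" else if (u < 0.9) "pseudogene" else "lncRNA"
}

#' Build a synthetic multi-genome world in memory
#'
#' The in-memory form of [generate_fixture()]: catalog, homology map,
#' assembly store, annotation table and ground-truth manifest, without
#' touching disk.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `catalog`, `hom`, `store` (NULL without
#'   sequence), `annotations`, `pairs`, `manifest`.
#' @export
build_fixture_world <- function(spec) {
  G <- spec$genes_per_chromosome
  NC <- spec$n_chromosomes
  NG <- spec$n_genomes
  chroms <- paste0("chr", seq_len(NC))

  # --- canonical gene templates (stream 0, shared by all genomes) ---
  seed_stream(spec$seed, 0)
  templates <- list()
  for (c in seq_len(NC)) {
    for (j in seq_len(G)) {
      L <- round(stats::runif(1, spec$gene_bp[1], spec$gene_bp[2]))
      strand <- sample(c("+", "-"), 1)
      bt <- biotype_for(stats::runif(1))
      # the polymorphic-pseudogene target is coding in its base form
      if (c == 1L && j == 4L && "polymorphic_pseudogene" %in% spec$scenarios)
        bt <- "protein_coding"
      n_tx <- sample(1:4, 1)
      templates[[paste(c, j)]] <- list(
        c = c, j = j, L = L, strand = strand, biotype = bt,
        tx = build_tx_templates(L, n_tx, bt == "protein_coding"))
    }
  }
  feas <- vapply(seq_len(NC), function(c)
    sum(vapply(seq_len(G), function(j) templates[[paste(c, j)]]$L, 0)), 0)
  if (any(feas + (G + 1) * 50 > spec$chromosome_bp))
    stop("infeasible packing: genes do not fit in chromosome_bp = ",
         fmt_bp(spec$chromosome_bp))

  # --- genome roster ---
  genome_names <- paste0("strain", LETTERS[seq_len(NG)])
  taxa <- rep("organismA", NG)
  if (spec$cross_organism) {
    genome_names[NG] <- "speciesB"
    taxa[NG] <- "organismB"
  }

  cana <- function(c, j) sprintf("CANA:%02d%04d", c, j)
  canb <- function(c, j) sprintf("CANB:%02d%04d", c, j)
  scen <- list()
  sc <- spec$scenarios
  same_org_alt <- if (NG >= 2) 2L else 1L   # genome carrying variant alleles

  if ("drop_gene" %in% sc)
    scen$drop_gene <- list(canonical_id = cana(1, 2),
                           absent_genome = genome_names[same_org_alt])
  if ("invert_gene" %in% sc)
    scen$invert_gene <- list(canonical_id = cana(1, 3),
                             inverted_genome = genome_names[same_org_alt])
  if ("polymorphic_pseudogene" %in% sc)
    scen$polymorphic_pseudogene <- list(canonical_id = cana(1, 4),
                                        pseudo_genome = genome_names[same_org_alt])
  if ("split_ortholog" %in% sc)
    scen$split_ortholog <- list(anchor = canb(1, 5),
                                partners = c(cana(1, 5), cana(2, 5)),
                                chromosomes = chroms[1:2])
  if ("paralog_family" %in% sc)
    scen$paralog_family <- list(family_a = cana(2, 1:3), family_b = canb(2, 1:2),
                                orphan_b = canb(2, 3))

  # --- per-genome instantiation (stream gi per genome) ---
  genomes <- list(); features <- list(); sequences <- list()
  manifest_feats <- list()
  for (gi in seq_len(NG)) {
    gname <- genome_names[gi]
    is_b <- spec$cross_organism && gi == NG
    seed_stream(spec$seed, gi)
    gi_info <- genome_info(gname,
                           data.frame(name = chroms, length = spec$chromosome_bp),
                           assembly = paste0(gname, ".1"), taxon = taxa[gi])
    genomes[[gname]] <- gi_info
    for (c in seq_len(NC)) {
      lens <- vapply(seq_len(G), function(j) templates[[paste(c, j)]]$L, 0)
      slack <- spec$chromosome_bp - sum(lens)
      w <- stats::runif(G + 1, 0.5, 1.5)
      gaps <- pmax(1, floor(w / sum(w) * slack))
      pos <- 1
      for (j in seq_len(G)) {
        tpl <- templates[[paste(c, j)]]
        pos <- pos + gaps[j]
        start <- pos
        pos <- pos + tpl$L
        cid <- if (is_b) canb(c, j) else cana(c, j)
        dropped <- !is.null(scen$drop_gene) &&
          identical(scen$drop_gene$canonical_id, cid) &&
          identical(scen$drop_gene$absent_genome, gname)
        if (dropped) next
        strand <- tpl$strand
        if (!is.null(scen$invert_gene) &&
            identical(scen$invert_gene$canonical_id, cid) &&
            identical(scen$invert_gene$inverted_genome, gname))
          strand <- if (strand == "+") "-" else "+"
        pseudo <- !is.null(scen$polymorphic_pseudogene) &&
          identical(scen$polymorphic_pseudogene$canonical_id, cid) &&
          identical(scen$polymorphic_pseudogene$pseudo_genome, gname)
        biotype <- if (pseudo) "pseudogene" else tpl$biotype
        fid <- sprintf("%s_G%02d%04d", gname, c, j)
        txs <- lapply(seq_along(tpl$tx), function(t) {
          tt <- tpl$tx[[t]]
          exons <- tt$exons; cds <- tt$cds
          if (strand == "-") {
            exons <- mirror_rel(exons, tpl$L)
            if (!is.null(cds)) cds <- mirror_rel(cds, tpl$L)
          }
          exons$start <- exons$start + start - 1
          exons$end <- exons$end + start - 1
          if (!is.null(cds) && !pseudo) {
            cds$start <- cds$start + start - 1
            cds$end <- cds$end + start - 1
            cds <- compute_phases(cds, strand)
          } else cds <- NULL
          transcript(sprintf("%s.t%d", fid, t), exons, cds)
        })
        f <- genome_feature(fid, gname, chroms[c], start, start + tpl$L - 1,
                            strand, biotype = biotype, canonical_id = cid,
                            symbol = sprintf("Gene%d-%d", c, j),
                            transcripts = txs)
        features[[length(features) + 1L]] <- f
        manifest_feats[[length(manifest_feats) + 1L]] <- data.frame(
          genome = gname, feature_id = fid, canonical_id = cid,
          chromosome = chroms[c], start = f$start, end = f$end,
          strand = strand, biotype = biotype, symbol = f$symbol,
          n_transcripts = length(txs), stringsAsFactors = FALSE)
        if ("boundary_straddle" %in% sc && is.null(scen$boundary_straddle) &&
            gi == 1L && c == 1L && j == 1L) {
          scen$boundary_straddle <- list(
            feature_id = fid, genome = gname, chromosome = chroms[1],
            boundary_bp = floor((f$start + f$end) / 2))
        }
      }
    }
    if (spec$with_sequence) {
      seqs <- vapply(seq_len(NC), function(c)
        paste(sample(c("A", "C", "G", "T"), spec$chromosome_bp, replace = TRUE),
              collapse = ""), "")
      ss <- Biostrings::DNAStringSet(seqs)
      names(ss) <- chroms
      sequences[[gname]] <- ss
    }
  }

  # --- ortholog pairs ---
  pairs <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  if (spec$cross_organism) {
    rows <- list()
    fam_cols <- if (!is.null(scen$paralog_family)) 1:3 else integer()
    for (c in seq_len(NC)) {
      for (j in seq_len(G)) {
        if (c == 2 && j %in% fam_cols) next   # family handled below
        rows[[length(rows) + 1L]] <- data.frame(a = cana(c, j), b = canb(c, j),
                                                stringsAsFactors = FALSE)
      }
    }
    if (!is.null(scen$split_ortholog))
      rows[[length(rows) + 1L]] <- data.frame(a = cana(2, 5), b = canb(1, 5),
                                              stringsAsFactors = FALSE)
    if (!is.null(scen$paralog_family)) {
      for (ja in 1:3) for (jb in 1:2)
        rows[[length(rows) + 1L]] <- data.frame(a = cana(2, ja), b = canb(2, jb),
                                                stringsAsFactors = FALSE)
    }
    pairs <- unique(do.call(rbind, rows))
  }

  catalog <- feature_catalog(genomes, features)
  hom <- homology_map(pairs, catalog)

  # --- annotation table (organism A canonicals) ---
  ann <- list()
  park <- cana(1, 2:min(6, G))
  for (id in park)
    ann[[length(ann) + 1L]] <- data.frame(canonical_id = id, category = "disease",
                                          term = "parkinsonism-like",
                                          stringsAsFactors = FALSE)
  for (c in seq_len(NC)) for (j in seq_len(G)) {
    id <- cana(c, j)
    if (j %% 2 == 1)
      ann[[length(ann) + 1L]] <- data.frame(canonical_id = id,
                                            category = "function",
                                            term = "nucleotide-binding",
                                            stringsAsFactors = FALSE)
    if (j %% 3 == 0)
      ann[[length(ann) + 1L]] <- data.frame(canonical_id = id,
                                            category = "pathway",
                                            term = "xenobiotic-metabolism",
                                            stringsAsFactors = FALSE)
    if (j %% 5 == 0)
      ann[[length(ann) + 1L]] <- data.frame(canonical_id = id,
                                            category = "phenotype",
                                            term = "reduced-body-weight",
                                            stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann)

  manifest <- list(
    spec = list(n_genomes = NG, n_chromosomes = NC,
                genes_per_chromosome = G, chromosome_bp = spec$chromosome_bp,
                seed = spec$seed, scenarios = sc, gene_bp = spec$gene_bp,
                with_sequence = spec$with_sequence),
    genomes = lapply(genomes, function(g)
      list(name = g$name, assembly = g$assembly, taxon = g$taxon)),
    features = do.call(rbind, manifest_feats),
    ortholog_pairs = pairs,
    scenarios = scen,
    disease_list = park,
    counts = as.list(table(vapply(features, `[[`, "", "genome"))))

  list(catalog = catalog, hom = hom,
       store = if (spec$with_sequence) assembly_store(sequences) else NULL,
       annotations = annotations, pairs = pairs, manifest = manifest)
}

#' Generate a fixture world on disk
#'
#' Writes, under `dir`: `<genome>.gff3` and `<genome>.fa` per genome,
#' `homology.tsv`, `annotations.tsv`, `config.yaml` (a catalog config
#' consumable by [load_catalog_config()]), and `manifest.json` (the
#' ground truth). The same seed produces byte-identical output.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return The world list of [build_fixture_world()], invisibly, with a
#'   `dir` element added.
#' @export
generate_fixture <- function(spec, dir) {
  world <- build_fixture_world(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_genomes <- list()
  for (g in names(world$catalog$genomes)) {
    gi <- world$catalog$genomes[[g]]
    feats <- Filter(function(f) f$genome == g, world$catalog$features)
    write_gff3(feats, file.path(dir, paste0(g, ".gff3")))
    if (!is.null(world$store))
      Biostrings::writeXStringSet(world$store$sequences[[g]],
                                  file.path(dir, paste0(g, ".fa")), width = 60)
    cfg_genomes[[length(cfg_genomes) + 1L]] <- list(
      name = g, assembly = gi$assembly, taxon = gi$taxon,
      gff3 = paste0(g, ".gff3"),
      fasta = if (!is.null(world$store)) paste0(g, ".fa") else NULL,
      chromosomes = lapply(seq_len(nrow(gi$chromosomes)), function(k)
        list(name = gi$chromosomes$name[k], length = gi$chromosomes$length[k])))
  }
  write_homology_table(world$pairs, file.path(dir, "homology.tsv"))
  con <- file(file.path(dir, "annotations.tsv"), open = "wb")
  writeLines(c("canonical_id\tcategory\tterm",
               paste(world$annotations$canonical_id, world$annotations$category,
                     world$annotations$term, sep = "\t")), con, sep = "\n")
  close(con)
  cfg <- list(genomes = cfg_genomes, homology = "homology.tsv",
              annotations = "annotations.tsv")
  writeLines(yaml::as.yaml(cfg), file.path(dir, "config.yaml"))
  jsonlite::write_json(world$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  world$dir <- dir
  invisible(world)
}
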