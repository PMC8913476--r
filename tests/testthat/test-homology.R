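test_that("ortholog table loading deduplicates and rejects bad rows", {
  w <- scenario_world()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("canonical_a\tcanonical_b",
               "CANA:010001\tCANB:010001",
               "CANB:010001\tCANA:010001",    # duplicate, reversed
               "CANA:010006\tCANB:010006"), path)
  hom <- load_homology_table(path, w$catalog)
  expect_equal(nrow(hom$pairs), 2L)
  # self pair and unknown-id rows are skipped with warnings
  writeLines(c("canonical_a\tcanonical_b",
               "CANA:010001\tCANA:010001",
               "CANA:010001\tNOPE:1",
               "CANA:010001\tCANB:010001"), path)
  expect_warning(expect_warning(hom2 <- load_homology_table(path, w$catalog),
                                "absent from the catalog"), "self-pair")
  expect_equal(nrow(hom2$pairs), 1L)
})

test_that("the fixture ortholog table round-trips through disk", {
  w <- scenario_world()
  dir <- scenario_dir()
  hom <- load_homology_table(file.path(dir, "homology.tsv"), w$catalog)
  expect_equal(hom$pairs, w$hom$pairs)
  expect_equal(hom$pairs[order(hom$pairs$a, hom$pairs$b), ],
               unique(canonicalize <- w$manifest$ortholog_pairs[
                 order(w$manifest$ortholog_pairs$a,
                       w$manifest$ortholog_pairs$b), ]),
               ignore_attr = TRUE)
})

test_that("a split ortholog resolves to multiple instances across organisms", {
  w <- scenario_world()
  split <- w$manifest$scenarios$split_ortholog
  hs <- homologs_of(w$catalog, w$hom, split$anchor,
                    genomes = c("strainA", "speciesB"))
  # one anchor instance plus two partner instances on different chromosomes
  expect_equal(nrow(hs$members), 3L)
  expect_setequal(unique(hs$members$genome), c("strainA", "speciesB"))
  inA <- hs$members[hs$members$genome == "strainA", ]
  expect_setequal(inA$chromosome, c("chr1", "chr2"))
})

test_that("without ortholog rows only same-organism instances resolve", {
  w <- scenario_world()
  empty <- homology_map(catalog = w$catalog)
  hs <- homologs_of(w$catalog, empty, "CANA:010006")
  expect_setequal(unique(hs$members$genome), c("strainA", "strainB", "strainC"))
})

test_that("orientation flags mark members on the opposite strand from the anchor", {
  w <- scenario_world()
  inv <- w$manifest$scenarios$invert_gene
  hs <- homologs_of(w$catalog, w$hom, inv$canonical_id)
  flags <- stats::setNames(hs$members$orientation, hs$members$genome)
  expect_equal(unname(flags[inv$inverted_genome]), "opposite")
  expect_true(all(flags[setdiff(names(flags), inv$inverted_genome)] == "same"))
})

test_that("flipping one member's strand flips exactly that member's flag", {
  base <- manual_world(strandB = "+")
  flip <- manual_world(strandB = "-")
  h1 <- homologs_of(base$catalog, base$hom, "CX:1")
  h2 <- homologs_of(flip$catalog, flip$hom, "CX:1")
  expect_equal(h1$members$orientation, c("same", "same"))
  expect_equal(h2$members$orientation, c("same", "opposite"))
})

test_that("inferred paralogs equal brute-force shared-neighbor enumeration", {
  for (w in list(family_world(), scenario_world())) {
    got <- infer_paralogs(w$catalog, w$hom)
    want <- oracle_paralogs(w$hom$pairs, fixture_organism_of)
    expect_equal(got, want)
    # symmetric and irreflexive by construction of the a < b form
    expect_true(all(got$a < got$b))
  }
})

test_that("a complete bipartite family yields all within-organism pairs", {
  w <- family_world()
  fam <- w$manifest$scenarios$paralog_family
  got <- infer_paralogs(w$catalog, w$hom)
  # 3 organism-A genes sharing 2 organism-B orthologs: choose(3,2) A
  # pairs and choose(2,2) B pair
  a_pairs <- got[startsWith(got$a, "CANA"), ]
  b_pairs <- got[startsWith(got$a, "CANB"), ]
  expect_equal(nrow(a_pairs), 3L)
  expect_equal(nrow(b_pairs), 1L)
  expect_setequal(unique(c(a_pairs$a, a_pairs$b)), fam$family_a)
  expect_setequal(unique(c(b_pairs$a, b_pairs$b)), fam$family_b)
})

test_that("genes with no shared neighbor are not called paralogs", {
  w <- tiny_world()   # 1:1 orthology absent entirely (single organism)
  expect_equal(nrow(infer_paralogs(w$catalog, w$hom)), 0L)
})

test_that("presence/absence matches the drop scenario and the distribution table", {
  w <- scenario_world()
  drop <- w$manifest$scenarios$drop_gene
  pa <- presence_absence(w$catalog, w$hom, drop$canonical_id)
  expect_false(pa[[drop$absent_genome]])
  sameorg <- setdiff(names(pa), c(drop$absent_genome, "speciesB"))
  expect_true(all(pa[sameorg]))
  # full-presence gene
  expect_true(all(presence_absence(w$catalog, w$hom, "CANA:010006",
                                   c("strainA", "strainB", "strainC"))))
  # agreement with strain_distribution absences within the organism
  for (cid in c(drop$canonical_id, "CANA:010006", "CANA:020002")) {
    tab <- strain_distribution(w$catalog, cid)
    tab <- tab[tab$genome != "speciesB", ]
    pa2 <- presence_absence(w$catalog, w$hom, cid, tab$genome)
    expect_equal(unname(pa2), !tab$absent)
  }
})
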