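test_that("genomic fetches match the generator's stored sequence", {
  w <- tiny_world()
  raw <- as.character(w$store$sequences$strainA[["chr1"]])
  expect_identical(fetch_genomic(w$store, "strainA", "chr1", 1, 10),
                   substr(raw, 1, 10))
  expect_identical(fetch_genomic(w$store, "strainA", "chr1", 500, 500),
                   substr(raw, 500, 500))
  expect_identical(fetch_genomic(w$store, "strainA", "chr1", 101, 160,
                                 revcomp = TRUE),
                   oracle_revcomp(substr(raw, 101, 160)))
  expect_error(fetch_genomic(w$store, "strainA", "chr1", 0, 10), "bounds")
  expect_error(fetch_genomic(w$store, "strainA", "chrZ", 1, 10),
               "unknown chromosome")
})

test_that("reverse complement is the standard involution over ACGTN", {
  expect_identical(reverse_complement("AAGT"), "ACTT")
  expect_identical(reverse_complement("N"), "N")
  expect_identical(reverse_complement("ACGT"), "ACGT")   # palindrome
  expect_error(reverse_complement("ACGU"), "outside")
  set.seed(5)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1),
                      replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("spliced sequences concatenate exons in transcription order", {
  w <- tiny_world()
  raw <- lapply(w$store$sequences, function(ss)
    stats::setNames(lapply(seq_along(ss), function(i) as.character(ss[[i]])),
                    names(ss)))
  checked_plus <- FALSE; checked_minus <- FALSE
  for (f in w$catalog$features) {
    for (tx in f$transcripts) {
      got <- spliced_sequence(w$catalog, w$store, tx$transcript_id)
      chr <- raw[[f$genome]][[f$chromosome]]
      parts <- vapply(seq_len(nrow(tx$exons)), function(k)
        substr(chr, tx$exons$start[k], tx$exons$end[k]), "")
      fwd <- paste(parts, collapse = "")
      want <- if (f$strand == "+") fwd else oracle_revcomp(fwd)
      expect_identical(got, want)
      expect_equal(nchar(got), sum(tx$exons$end - tx$exons$start + 1))
      if (f$strand == "+") checked_plus <- TRUE else checked_minus <- TRUE
      # degenerate splice: single exon equals the raw genomic fetch
      if (nrow(tx$exons) == 1L && f$strand == "+")
        expect_identical(got, fetch_genomic(w$store, f$genome, f$chromosome,
                                            tx$exons$start, tx$exons$end))
    }
  }
  expect_true(checked_plus && checked_minus)
  expect_error(spliced_sequence(w$catalog, w$store, "no.such.tx"),
               "unknown transcript")
})

test_that("CDS extraction honors segment order, strand and phase", {
  w <- tiny_world()
  n_checked <- 0L
  for (f in w$catalog$features) {
    for (tx in f$transcripts) {
      if (is.null(tx$cds)) next
      got <- cds_sequence(w$catalog, w$store, tx$transcript_id)
      chr <- as.character(w$store$sequences[[f$genome]][[
        match(f$chromosome, names(w$store$sequences[[f$genome]]))]])
      parts <- vapply(seq_len(nrow(tx$cds)), function(k)
        substr(chr, tx$cds$start[k], tx$cds$end[k]), "")
      if (f$strand == "+") {
        want <- paste(parts, collapse = "")
        phase <- tx$cds$phase[1]
      } else {
        want <- oracle_revcomp(paste(parts, collapse = ""))
        phase <- tx$cds$phase[nrow(tx$cds)]
      }
      if (phase > 0) want <- substring(want, phase + 1)
      expect_identical(got, want)
      expect_equal(nchar(got) %% 3, 0)   # fixture CDSs are complete
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 5L)
  # explicit phase trimming on a hand-built minus and plus pair
  gi <- genome_info("g1", data.frame(name = "c1", length = 100))
  seqs <- Biostrings::DNAStringSet(c(c1 = "ATGAAACCCGGGTTTTAAACGTACGTACGTA"))
  store <- assembly_store(list(g1 = seqs))
  txp <- transcript("tp", data.frame(start = 1, end = 18),
                    cds = data.frame(start = 1, end = 18, phase = 1))
  cat1 <- feature_catalog(list(gi), list(
    genome_feature("fp", "g1", "c1", 1, 18, "+", transcripts = list(txp))))
  expect_identical(cds_sequence(cat1, store, "tp"), "TGAAACCCGGGTTTTAA")
  # phase-0 CDS equal to one exon is just that exon's sequence
  tx0 <- transcript("t0", data.frame(start = 4, end = 12),
                    cds = data.frame(start = 4, end = 12, phase = 0))
  cat0 <- feature_catalog(list(gi), list(
    genome_feature("f0", "g1", "c1", 1, 20, "+", transcripts = list(tx0))))
  expect_identical(cds_sequence(cat0, store, "t0"), "AAACCCGGG")
  expect_error(cds_sequence(cat0, store, "missing"), "unknown transcript")
})

test_that("translation follows the standard code with N and stop handling", {
  expect_identical(translate_cds("ATG"), "M")
  expect_identical(translate_cds("ATGTAA"), "M")      # trailing stop dropped
  expect_identical(translate_cds("ATGTAACCC"), "M*P") # internal stop kept
  expect_identical(translate_cds("ATGNNNTGA"), "MX")
  expect_identical(translate_cds("ATGAA"), "M")       # incomplete tail ignored
  expect_error(translate_cds("AT"), "shorter")
  set.seed(6)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    expect_identical(translate_cds(s), oracle_translate(s))
  }
})

test_that("region drag selection honors scroll lock and drag direction", {
  w <- tiny_world()
  st <- map_reference_region(w$catalog, w$hom, "strainA",
                             region_segment("strainA", "chr1", 1000, 20000))
  ds <- region_select_descriptors(st, "strainA", "chr1", 2000, 3000,
                                  "left_to_right", scroll_lock = TRUE)
  expect_length(ds, length(st$genomes))
  expect_true(all(!vapply(ds, `[[`, TRUE, "revcomp")))
  ds2 <- region_select_descriptors(st, "strainA", "chr1", 2000, 3000,
                                   "right_to_left", scroll_lock = FALSE)
  expect_length(ds2, 1L)
  expect_true(ds2[[1]]$revcomp)
  expect_error(region_select_descriptors(st, "ghost", "chr1", 1, 2,
                                         "left_to_right"), "not displayed")
})

test_that("cart downloads enforce both caps before resolving, then emit FASTA", {
  w <- tiny_world()
  one_bp <- seq_descriptor("strainA", "genomic",
                           list(chromosome = "chr1", start = 1, end = 1))
  cart <- sequence_cart()
  cart$entries <- rep(list(one_bp), 4001)
  expect_error(cart_download(cart, w$store, w$catalog), "sequence-count cap")
  cart$entries <- rep(list(one_bp), 4000)
  fa <- cart_download(cart, w$store, w$catalog)
  expect_equal(length(gregexpr(">", fa, fixed = TRUE)[[1]]), 4000L)
  # residue cap: predicted lengths reject without materializing
  wide <- seq_descriptor("strainA", "genomic",
                         list(chromosome = "chr1", start = 1, end = 40001))
  cart$entries <- rep(list(wide), 2500)   # 100,002,500 residues
  expect_error(cart_download(cart, w$store, w$catalog), "size cap")
  cart$entries <- rep(list(wide), 2)
  expect_silent(cart_download(cart, w$store, w$catalog))
})

test_that("cart FASTA re-parses to exactly the resolved sequences", {
  w <- tiny_world()
  coding_tx <- NULL
  for (f in w$catalog$features)
    for (tx in f$transcripts)
      if (!is.null(tx$cds) && is.null(coding_tx)) coding_tx <- tx$transcript_id
  cart <- cart_add(sequence_cart(),
    seq_descriptor("strainA", "genomic",
                   list(chromosome = "chr1", start = 101, end = 290)),
    seq_descriptor("strainA", "genomic",
                   list(chromosome = "chr2", start = 1, end = 75),
                   revcomp = TRUE),
    seq_descriptor(sub("_.*", "", coding_tx), "transcript", coding_tx,
                   header = "tx-entry"),
    seq_descriptor(sub("_.*", "", coding_tx), "cds", coding_tx,
                   translate = TRUE, header = "aa-entry"))
  # genome of the transcript descriptors must match its feature's genome
  gname <- w$catalog$txmap[[coding_tx]]
  cart$entries[[3]]$genome <- sub("::.*", "", gname)
  cart$entries[[4]]$genome <- sub("::.*", "", gname)
  fa <- cart_download(cart, w$store, w$catalog)
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(fa, path, sep = "")
  back <- Biostrings::readBStringSet(path)
  expect_length(back, 4L)
  expect_identical(as.character(back[[1]]),
                   fetch_genomic(w$store, "strainA", "chr1", 101, 290))
  expect_identical(as.character(back[[2]]),
                   reverse_complement(fetch_genomic(w$store, "strainA", "chr2", 1, 75)))
  expect_identical(as.character(back[[3]]),
                   spliced_sequence(w$catalog, w$store, coding_tx))
  expect_identical(as.character(back[[4]]),
                   translate_cds(cds_sequence(w$catalog, w$store, coding_tx)))
  expect_identical(names(back)[4], "aa-entry")
  # 60-column body lines
  lines <- strsplit(fa, "\n")[[1]]
  body <- lines[!startsWith(lines, ">")]
  expect_true(all(nchar(body) <= 60))
})

test_that("descriptor invariants and cart exchange files hold", {
  expect_error(seq_descriptor("g", "transcript", "t1", translate = TRUE),
               "only valid for CDS")
  expect_error(seq_descriptor("g", "cds",
                              list(chromosome = "c", start = 1, end = 2)),
               "genomic")
  w <- tiny_world()
  cart <- cart_add(sequence_cart(),
    seq_descriptor("strainA", "genomic",
                   list(chromosome = "chr1", start = 5, end = 50),
                   revcomp = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cart(cart, path)
  back <- read_cart(path)
  expect_equal(back$entries, cart$entries)
})
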