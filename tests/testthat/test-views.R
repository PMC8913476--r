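test_that("reference mapping carries flanking genes into every genome", {
  w <- scenario_world()
  # two genes present in all same-organism genomes bracket the region
  left <- w$catalog$canon[["CANA:010006"]]
  right <- w$catalog$canon[["CANA:010007"]]
  fa <- w$catalog$features[[paste0("strainA::", left$instances[["strainA"]])]]
  fb <- w$catalog$features[[paste0("strainA::", right$instances[["strainA"]])]]
  region <- region_segment("strainA", "chr1", fa$start, fb$end)
  st <- map_reference_region(w$catalog, w$hom, "strainA", region,
                             genomes = c("strainA", "strainB", "strainC"))
  expect_identical(st$segments$strainA[[1]]$start, region$start)
  expect_identical(st$segments$strainA[[1]]$end, region$end)
  for (g in c("strainB", "strainC")) {
    seg <- st$segments[[g]][[1]]
    expect_false(seg$placeholder)
    for (cid in c("CANA:010006", "CANA:010007")) {
      inst <- w$catalog$canon[[cid]]$instances[[g]]
      f <- w$catalog$features[[paste0(g, "::", inst)]]
      expect_lte(seg$start, f$start)
      expect_gte(seg$end, f$end)
    }
  }
})

test_that("a reference region with no canonical features yields placeholders", {
  w <- scenario_world()
  # find an intergenic gap on strainA chr1
  tab <- w$catalog$table
  a <- tab[tab$genome == "strainA" & tab$chromosome == "chr1", ]
  a <- a[order(a$start), ]
  gap_start <- a$end[1] + 1; gap_end <- a$start[2] - 1
  expect_true(gap_end > gap_start)
  st <- map_reference_region(w$catalog, w$hom, "strainA",
                             region_segment("strainA", "chr1", gap_start + 1,
                                            gap_end - 1),
                             genomes = c("strainA", "strainB"))
  expect_true(st$segments$strainB[[1]]$placeholder)
})

test_that("homologs split across chromosomes give that genome two segments", {
  w <- scenario_world()
  split <- w$manifest$scenarios$split_ortholog
  segs <- split_segments(w$catalog, w$hom, split$anchor, "strainA")
  expect_length(segs, 2L)
  expect_equal(vapply(segs, `[[`, "", "chromosome"), c("chr1", "chr2"))
  # single instance: one segment; no instance: none
  expect_length(split_segments(w$catalog, w$hom, "CANA:010006", "strainA"), 1L)
  drop <- w$manifest$scenarios$drop_gene
  expect_length(split_segments(w$catalog, w$hom, drop$canonical_id,
                               drop$absent_genome), 0L)
})

test_that("aligned-view arithmetic is exact for the forced two-genome case", {
  mw <- manual_world(lenA = 10000, lenB = 20000)
  st <- align_on_feature(mw$catalog, mw$hom, "CX:1", occupancy = 0.4)
  segA <- st$segments$gA[[1]]; segB <- st$segments$gB[[1]]
  expect_equal(segA$end - segA$start + 1, 25000)
  expect_equal(segB$end - segB$start + 1, 50000)
  # the feature occupies exactly the configured fraction of its segment
  expect_equal(10000 / 25000, 0.4)
  # 5' fractional offset is (1 - occupancy) / 2 in both tracks
  offA <- (50001 - segA$start) / 25000
  offB <- (90001 - segB$start) / 50000
  expect_equal(offA, 0.3, tolerance = 1e-4)
  expect_equal(offB, 0.3, tolerance = 1e-4)
})

test_that("minus-strand instances flip and keep the same 5' fractional offset", {
  plus <- manual_world(strandB = "+")
  minus <- manual_world(strandB = "-")
  sp <- align_on_feature(plus$catalog, plus$hom, "CX:1")$segments$gB[[1]]
  sm <- align_on_feature(minus$catalog, minus$hom, "CX:1")$segments$gB[[1]]
  expect_false(sp$flipped)
  expect_true(sm$flipped)
  len <- sp$end - sp$start + 1
  off_plus <- (90001 - sp$start) / len           # 5' end = feature start
  off_minus <- (sm$end - (90000 + 20000)) / len  # 5' end = feature end
  expect_equal(off_plus, off_minus, tolerance = 1.5 / len)
})

test_that("a genome missing the aligned gene gets a placeholder track", {
  w <- scenario_world()
  drop <- w$manifest$scenarios$drop_gene
  st <- align_on_feature(w$catalog, w$hom, drop$canonical_id,
                         genomes = c("strainA", drop$absent_genome, "strainC"))
  expect_true(st$segments[[drop$absent_genome]][[1]]$placeholder)
  expect_false(st$segments$strainA[[1]]$placeholder)
})

test_that("5' offsets agree within 1 bp across mixed-strand homologs", {
  w <- scenario_world()
  occ <- 0.4
  for (cid in paste0("CANA:01000", 6:8)) {
    st <- align_on_feature(w$catalog, w$hom, cid,
                           genomes = c("strainA", "strainB", "strainC"),
                           occupancy = occ)
    hs <- homologs_of(w$catalog, w$hom, cid,
                      c("strainA", "strainB", "strainC"))
    for (k in seq_len(nrow(hs$members))) {
      m <- hs$members[k, ]
      seg <- st$segments[[m$genome]][[1]]
      len <- seg$end - seg$start + 1
      off_bp <- if (seg$flipped) seg$end - m$end else m$start - seg$start
      expect_lte(abs(off_bp - (1 - occ) / 2 * len), 1)
      occ_got <- (m$end - m$start + 1) / len
      expect_lte(abs(occ_got - occ), 1 / (m$end - m$start + 1) + 1e-9)
    }
  }
})

test_that("locked navigation scales scroll by segment length and zoom keeps midpoints", {
  mw <- manual_world()
  st <- view_state(c("gA", "gB"),
                   list(gA = list(region_segment("gA", "c1", 50001, 60000)),
                        gB = list(region_segment("gB", "c1", 80001, 100000))),
                   mode = "locked", reference = "gA")
  n1 <- navigate(st, mw$catalog, scroll = 1000)
  expect_equal(n1$segments$gA[[1]]$start, 51001)
  expect_equal(n1$segments$gB[[1]]$start, 82001)   # twice as long, +2000
  n2 <- navigate(st, mw$catalog, zoom = 2)
  sA <- n2$segments$gA[[1]]
  expect_equal(sA$end - sA$start + 1, 20000)
  expect_equal((sA$start + sA$end) / 2, (50001 + 60000) / 2, tolerance = 1)
  # ratio to the reference is preserved under locked scrolls
  r0 <- 20000 / 10000
  r1 <- (n1$segments$gB[[1]]$end - n1$segments$gB[[1]]$start + 1) /
    (n1$segments$gA[[1]]$end - n1$segments$gA[[1]]$start + 1)
  expect_equal(r1, r0)
  # clamping at chromosome start
  st2 <- view_state("gA", list(gA = list(region_segment("gA", "c1", 100, 1099))),
                    mode = "locked")
  n3 <- navigate(st2, mw$catalog, scroll = -5000)
  expect_equal(n3$segments$gA[[1]]$start, 1)
  expect_equal(n3$segments$gA[[1]]$end, 1000)
  expect_error(navigate(st, mw$catalog, zoom = 0), "zoom factor")
  # free mode touches only the target
  st$mode <- "free"
  n4 <- navigate(st, mw$catalog, scroll = 1000, target = "gB")
  expect_equal(n4$segments$gA[[1]]$start, 50001)
  expect_equal(n4$segments$gB[[1]]$start, 81001)
})

test_that("view-state encoding round-trips exactly", {
  st <- view_state(
    c("gA", "gB", "gC"),
    list(gA = list(region_segment("gA", "c1", 1000, 5000)),
         gB = list(region_segment("gB", "c1", 2000, 9000, flipped = TRUE),
                   region_segment("gB", "c2", 100, 400)),
         gC = list(placeholder_segment("gC"))),
    mode = "locked", reference = "gA",
    filters = filter_spec(biotypes = c("protein_coding", "lncRNA"),
                          min_length = 500, max_length = 40000,
                          differential = TRUE),
    selections = c("CX:2", "CX:1"),
    list_mode = list(name = "mylist", mode = "restrict"))
  enc <- encode_view_state(st)
  expect_match(enc, "genomes=gA,gB,gC")
  expect_match(enc, "seg.gB=c1:2000..9000r,c2:100..400", fixed = TRUE)
  dec <- decode_view_state(enc)
  expect_equal(dec, st)
  # aligned mode round-trips the anchor id
  w <- scenario_world()
  st2 <- align_on_feature(w$catalog, w$hom, "CANA:010006")
  expect_equal(decode_view_state(encode_view_state(st2)), st2)
})

test_that("view-state decoding rejects malformed input by name", {
  expect_error(decode_view_state(""), "genomes")
  expect_error(decode_view_state("mode=free"), "genomes")
  expect_error(decode_view_state("genomes=a&seg.a=c1:1..9&bogus=1&junk=2"),
               "unknown key.*bogus.*junk")
  expect_error(decode_view_state("genomes=a&seg.a=c1:9..x"), "malformed segment")
  expect_error(decode_view_state("genomes=a"), "no segments")
})
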