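settings <- render_settings()

test_that("a feature spanning its whole segment fills the track width", {
  gi <- genome_info("g1", data.frame(name = "c1", length = 10000))
  f <- genome_feature("f1", "g1", "c1", 1001, 2000, "+", symbol = "s1")
  st <- view_state("g1", list(g1 = list(region_segment("g1", "c1", 1001, 2000))))
  lay <- compute_layout(st, list(g1 = list(f)), settings)
  geom <- lay$tracks$g1$geoms[[1]]
  expect_equal(geom$x1, 0)
  expect_equal(geom$x2, settings$track_width_px)
})

test_that("flipping a segment mirrors the x order of features", {
  gi <- genome_info("g1", data.frame(name = "c1", length = 10000))
  f1 <- genome_feature("f1", "g1", "c1", 1100, 1200, "+", symbol = "a")
  f2 <- genome_feature("f2", "g1", "c1", 1800, 1900, "+", symbol = "b")
  mk <- function(flip) {
    st <- view_state("g1", list(g1 = list(
      region_segment("g1", "c1", 1001, 2000, flipped = flip))))
    lay <- compute_layout(st, list(g1 = list(f1, f2)), settings)
    vapply(lay$tracks$g1$geoms, function(g) g$x1, 0)
  }
  xs <- mk(FALSE); xf <- mk(TRUE)
  expect_true(xs[1] < xs[2])
  expect_true(xf[1] > xf[2])
})

test_that("expanding a 3-transcript gene allocates one row per transcript", {
  gi <- genome_info("g1", data.frame(name = "c1", length = 10000))
  txs <- lapply(1:3, function(i)
    transcript(paste0("t", i), data.frame(start = 1000 + 10 * i,
                                          end = 3000 - 10 * i)))
  f <- genome_feature("f1", "g1", "c1", 1000, 3000, "+", symbol = "s",
                      transcripts = txs)
  cat1 <- feature_catalog(list(gi), list(f))
  hom <- homology_map(catalog = cat1)
  st <- view_state("g1", list(g1 = list(region_segment("g1", "c1", 500, 3500))))
  scene <- render_view_svg(st, cat1, hom,
                           render_settings(expand = "all"))
  expect_equal(scene$manifest$tracks$g1$transcripts, 3L)
  expect_equal(lengths(regmatches(scene$svg,
    gregexpr('<g class="transcript"', scene$svg, fixed = TRUE))), 3L)
})

test_that("manifest counts equal the drawn glyphs and connectors", {
  w <- scenario_world()
  st <- align_on_feature(w$catalog, w$hom, "CANA:010006",
                         genomes = c("strainA", "strainB", "strainC"))
  scene <- render_view_svg(st, w$catalog, w$hom, settings)
  m <- scene$manifest
  n_rect <- lengths(regmatches(scene$svg,
    gregexpr('<rect class="gene"', scene$svg, fixed = TRUE)))
  expect_equal(n_rect, m$totals$genes)
  n_poly <- lengths(regmatches(scene$svg,
    gregexpr('<polygon class="lane"', scene$svg, fixed = TRUE)))
  expect_equal(n_poly, m$totals$lanes)
  # anchor present in all three adjacent tracks: 2 connectors
  expect_equal(m$totals$lanes, 2L)
})

test_that("absent genes yield placeholders and opposite strands color the lane", {
  w <- scenario_world()
  drop <- w$manifest$scenarios$drop_gene
  st <- align_on_feature(w$catalog, w$hom, drop$canonical_id,
                         genomes = c("strainA", drop$absent_genome, "strainC"))
  scene <- render_view_svg(st, w$catalog, w$hom, settings)
  expect_match(scene$svg, "not found in this genome")
  expect_equal(scene$manifest$totals$placeholders, 1L)
  # the drop genome shows the message; the others draw the gene
  expect_equal(scene$manifest$tracks[[drop$absent_genome]]$genes +
                 scene$manifest$tracks[[drop$absent_genome]]$transcripts, 0L)

  inv <- w$manifest$scenarios$invert_gene
  st2 <- map_reference_region(w$catalog, w$hom, "strainA",
    region_segment("strainA", "chr1",
      strain_distribution(w$catalog, inv$canonical_id)$start[1],
      strain_distribution(w$catalog, inv$canonical_id)$end[1]),
    genomes = c("strainA", inv$inverted_genome))
  st2$selections <- inv$canonical_id
  scene2 <- render_view_svg(st2, w$catalog, w$hom, settings)
  expect_match(scene2$svg, settings$lane_color_opposite, fixed = TRUE)
})

test_that("an empty view renders a valid document with zero glyphs", {
  gi <- genome_info("g1", data.frame(name = "c1", length = 10000))
  cat0 <- feature_catalog(list(gi), list())
  hom <- homology_map(catalog = cat0)
  st <- view_state("g1", list(g1 = list(region_segment("g1", "c1", 1, 5000))))
  scene <- render_view_svg(st, cat0, hom, settings)
  expect_equal(scene$manifest$totals$genes, 0L)
  expect_silent(xml2::read_xml(scene$svg))
})

test_that("rendering is pure: identical inputs give byte-identical SVG", {
  w <- scenario_world()
  st <- align_on_feature(w$catalog, w$hom, "CANA:010007")
  s1 <- render_view_svg(st, w$catalog, w$hom, settings)
  s2 <- render_view_svg(st, w$catalog, w$hom, settings)
  expect_identical(s1$svg, s2$svg)
  expect_silent(xml2::read_xml(s1$svg))
})

test_that("all drawn x coordinates stay inside the track width", {
  w <- scenario_world()
  st <- align_on_feature(w$catalog, w$hom, "CANA:020006")
  scene <- render_view_svg(st, w$catalog, w$hom,
                           render_settings(expand = "all"))
  xml <- xml2::read_xml(scene$svg)
  xs <- as.numeric(unlist(lapply(c("x", "x1", "x2"), function(a)
    xml2::xml_attr(xml2::xml_find_all(xml, sprintf("//*[@%s]", a)), a))))
  xs <- xs[!is.na(xs)]
  expect_true(all(xs >= 0 - 1e-9))
  expect_true(all(xs <= settings$track_width_px + 1e-9))
})

test_that("contrast fade dims only unselected features", {
  w <- scenario_world()
  # region view over several genes, one of them selected
  st <- map_reference_region(w$catalog, w$hom, "strainA",
                             region_segment("strainA", "chr1", 1, 600000),
                             genomes = "strainA")
  st$selections <- "CANA:010006"
  scene <- render_view_svg(st, w$catalog, w$hom,
                           render_settings(contrast_fade = 0.25))
  expect_match(scene$svg, 'opacity="0.25"')
  expect_match(scene$svg, 'opacity="1.00"')
})
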