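test_that("pI axis interpolates, includes boundaries, refuses extrapolation", {
  ax <- linearAxis18()
  expect_equal(positionToPH(ax, 9), 7)
  expect_equal(positionToPH(ax, 18), 11)    # boundary included
  expect_equal(positionToPH(ax, 0), 3)
  expect_error(positionToPH(ax, 18.1), "outside calibrated range")
  expect_error(piAxis(data.frame(position = c(0, 18), pH = c(11, 3))),
               "strictly increase")
  ## inverse map round-trips
  nl <- piAxis(nl311Anchors())
  pos <- seq(0, 18, by = 0.5)
  expect_equal(phToPosition(nl, positionToPH(nl, pos)), pos,
               tolerance = 1e-9)
})

test_that("Mw axis fits log-linear migration", {
  ax <- mwAxis(toyMarkers())
  expect_equal(migrationToMw(ax, 0.5), 31622.7766, tolerance = 1e-3)
  expect_equal(migrationToMw(ax, 0.2), 1e5, tolerance = 1e-6)
  expect_equal(mwToMigration(ax, 1e4), 0.8, tolerance = 1e-9)
  expect_error(mwAxis(data.frame(migration = 0.5, mw = 5e4)), "2 markers")
  expect_error(mwAxis(data.frame(migration = c(0.5, 0.5),
                                 mw = c(5e4, 4e4))), "duplicate migration")
  ## increasing ladders (slope >= 0) are physically impossible
  expect_error(mwAxis(data.frame(migration = c(0.2, 0.8),
                                 mw = c(1e4, 1e5))), "slope")
})

test_that("section location uses half-open intervals, last closed", {
  sc <- sectionScheme("strip36")
  expect_equal(locateSection(sc, 0.75)$col, 1L)     # floor(0.75 / 0.5)
  expect_equal(locateSection(sc, 0.5)$col, 1L)      # boundary -> higher index
  expect_equal(locateSection(sc, 18)$col, 35L)      # upper edge -> last
  expect_true(locateSection(sc, 18.5)$off_gel)
  expect_true(locateSection(sc, -0.1)$off_gel)
  ## every in-range coordinate maps to exactly one section (partition audit)
  xs <- seq(0, 18, by = 0.01)
  loc <- locateSection(sc, xs)
  expect_false(any(loc$off_gel))
  expect_true(all(loc$col >= 0 & loc$col <= 35))
  ## boundaries land in the upper section except the final edge
  expect_equal(locateSection(sc, seq(0, 17.5, by = 0.5))$col, 0:35)
})

test_that("grid96 partitions the plane into 96 sections", {
  sc <- sectionScheme("grid96")
  expect_equal(sc@nRows * sc@nCols, 96L)
  pts <- expand.grid(pos = seq(0, 7, by = 0.1),
                     mig = seq(0, 1, by = 0.05))
  loc <- locateSection(sc, pts$pos, pts$mig)
  expect_false(any(loc$off_gel))
  ids <- sectionId(sc, loc$row, loc$col)
  expect_equal(length(unique(ids)), 96L)
  rc <- parseSectionId(sc, ids)
  expect_equal(rc$row, loc$row)
  expect_equal(rc$col, loc$col)
})

test_that("buildPattern places spots with section pI windows", {
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  quant <- data.frame(accession = c("A", "A", "B"),
                      section_id = c("s00", "s11", "s05"),
                      empai = c(1, 2, 4))
  pat <- buildPattern(quant, sc, ax,
                      theoreticalMw = c(A = 27265, B = 15946))
  sp <- spots(pat)
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$mw[sp$accession == "A"], c(27265, 27265))
  ## conservation of total emPAI
  expect_equal(sum(sp$empai), sum(quant$empai))
  ## strip sections 0-11 of a linear 3-11/18cm axis span pH [3, 8)
  ext <- spotExtent(pat, "A")
  expect_equal(unname(ext["pi_min"]), 3)
  expect_equal(unname(ext["pi_max"]),
               positionToPH(ax, 12 * 0.5))          # 5.666...
  expect_error(spotExtent(pat, "Z"), "not in pattern")
  ## single spot -> zero-width box at the spot
  extB <- spotExtent(pat, "B")
  expect_equal(unname(extB["mw_min"]), unname(extB["mw_max"]))
  ## extent is order independent
  pat2 <- buildPattern(quant[c(3, 1, 2), ], sc, ax,
                       theoreticalMw = c(A = 27265, B = 15946))
  expect_equal(spotExtent(pat2, "A"), ext)
  ## missing theoretical mass is an explicit error
  expect_error(buildPattern(quant, sc, ax, theoreticalMw = c(A = 27265)),
               "no theoretical Mw .*B")
  ## empty quant -> empty pattern
  expect_equal(nrow(spots(buildPattern(quant[0, ], sc, ax,
                                       theoreticalMw = c(A = 1)))), 0L)
})

test_that("grid96 patterns take the section mid-Mw from the axis", {
  sc <- sectionScheme("grid96")
  axP <- piAxis(data.frame(position = c(0, 7), pH = c(3, 11)))
  axM <- mwAxis(toyMarkers())
  quant <- data.frame(accession = "A", section_id = "r2c05", empai = 1)
  pat <- buildPattern(quant, sc, axP, mwAxis = axM)
  mid <- (sc@rowBounds[3] + sc@rowBounds[4]) / 2
  expect_equal(spots(pat)$mw, migrationToMw(axM, mid))
  expect_error(buildPattern(quant, sc, axP), "mwAxis")
})

test_that("pattern comparison matches identical patterns exactly", {
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  quant <- data.frame(accession = rep("A", 4),
                      section_id = sprintf("s%02d", 4:7),
                      empai = c(0.5, 2, 3, 1))
  pat <- buildPattern(quant, sc, ax, theoreticalMw = c(A = 27265))
  cmp <- comparePatterns(pat, pat, piTol = 0.1, mwTolFraction = 0.01)
  expect_equal(nrow(cmp$matches), 4L)
  expect_equal(cmp$matches$log2_ratio, rep(0, 4))
  expect_equal(nrow(cmp$only_a), 0L)
  ## doubled abundance: all ratios 1 (up to the pseudocount)
  q2 <- quant; q2$empai <- q2$empai * 2
  pat2 <- buildPattern(q2, sc, ax, theoreticalMw = c(A = 27265))
  cmp2 <- comparePatterns(pat2, pat, piTol = 0.1, mwTolFraction = 0.01,
                          pseudocount = 0)
  expect_equal(cmp2$matches$log2_ratio, rep(1, 4))
  ## disjoint accessions never match
  q3 <- quant; q3$accession <- "B"
  pat3 <- buildPattern(q3, sc, ax, theoreticalMw = c(B = 1000))
  cmp3 <- comparePatterns(pat, pat3, piTol = 5, mwTolFraction = 1)
  expect_equal(nrow(cmp3$matches), 0L)
  expect_equal(nrow(cmp3$only_a), 4L)
  expect_equal(nrow(cmp3$only_b), 4L)
})

test_that("patterns refuse duplicate spots per section", {
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  quant <- data.frame(accession = c("A", "A"),
                      section_id = c("s00", "s00"), empai = c(1, 2))
  expect_error(buildPattern(quant, sc, ax, theoreticalMw = c(A = 1000)),
               "one spot per")
})

test_that("SVG rendering is deterministic with area-proportional circles", {
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  quant <- data.frame(accession = "A", section_id = c("s04", "s09"),
                      empai = c(1, 4))
  pat <- buildPattern(quant, sc, ax, theoreticalMw = c(A = 27265))
  svg1 <- renderPattern(pat)
  svg2 <- renderPattern(pat)
  expect_identical(svg1, svg2)           # byte-identical
  circ <- grep("<circle", svg1, value = TRUE)
  expect_equal(length(circ), 2L)         # n spots -> n circles
  r <- as.numeric(sub('.*r="([0-9.]+)".*', "\\1", circ))
  expect_equal(max(r) / min(r), 2, tolerance = 1e-6)  # area ratio 4 -> radius 2
  ## radius mode: radius ratio equals the emPAI ratio
  r2 <- as.numeric(sub('.*r="([0-9.]+)".*', "\\1",
                       grep("<circle", renderPattern(pat, sizeMode = "radius"),
                            value = TRUE)))
  expect_equal(max(r2) / min(r2), 4, tolerance = 1e-6)
  expect_error(renderPattern(buildPattern(quant[0, ], sc, ax,
                                          theoreticalMw = c(A = 1))),
               "empty pattern")
})
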