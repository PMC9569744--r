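test_that("average and monoisotopic masses follow residue arithmetic", {
  expect_equal(proteinMass("G"), 75.07, tolerance = 1e-4)
  expect_equal(proteinMass("GG"), 132.12, tolerance = 1e-4)
  ## peptide-bond additivity: mass(s1 + s2) = mass(s1) + mass(s2) - water
  set.seed(11)
  for (i in 1:20) {
    s1 <- randomPeptide(sample(1:30, 1))
    s2 <- randomPeptide(sample(1:30, 1))
    expect_equal(proteinMass(paste0(s1, s2)),
                 proteinMass(s1) + proteinMass(s2) - 18.01524,
                 tolerance = 1e-9)
    expect_equal(proteinMass(paste0(s1, s2), kind = "monoisotopic"),
                 proteinMass(s1, kind = "monoisotopic") +
                   proteinMass(s2, kind = "monoisotopic") - 18.0105646863,
                 tolerance = 1e-9)
  }
})

test_that("non-canonical and empty sequences are rejected with position", {
  expect_error(proteinMass(""), "non-empty")
  expect_error(proteinMass("ACDX"), "position 4")
  expect_error(proteinMass("ACBDE"), "'B' at position 3")
  expect_error(proteinMass("ACUDE"), "position 3")   # no approximation of U
})

test_that("net charge has the right limits and monotonicity", {
  expect_equal(netCharge("G", pH = 0), 1.0, tolerance = 1e-3)
  ## carboxyl half-ionized at its pKa; N-term residual deviation is ~1e-4
  expect_equal(netCharge("G", pH = 3.55), 0.5, tolerance = 5e-4)
  set.seed(21)
  for (i in 1:20) {
    s <- randomPeptide(sample(3:40, 1))
    grid <- seq(0, 14, length.out = 60)
    q <- netCharge(s, pH = grid)
    expect_true(all(diff(q) < 0))        # strictly decreasing in pH
    ## adding acid groups can only lower the charge
    qp <- netCharge(s, mods = list(modPhospho(1)), pH = grid)
    expect_true(all(qp < q))
  }
  expect_error(netCharge("G", pH = -1), "pH")
})

test_that("pI bisection agrees with the 1e-4 grid-scan oracle", {
  set.seed(31)
  for (i in 1:100) {
    s <- randomPeptide(sample(5:30, 1))
    mods <- if (i %% 3 == 0) list(modPhospho(sample(0:2, 1))) else list()
    got <- tryCatch(isoelectricPoint(s, mods), error = function(e) e)
    if (inherits(got, "error")) {
      ## no acidic or no basic group: oracle cannot bracket a root either
      q0 <- netCharge(s, mods, 0); q14 <- netCharge(s, mods, 14)
      expect_true(q0 <= 0 || q14 >= 0)
      next
    }
    expect_equal(got, oracleGridPI(s, mods), tolerance = 2e-4)
  }
})

test_that("two-group molecules have pI at the mean of the two pKas", {
  pk <- pkaSet()
  expect_equal(isoelectricPoint("G"),
               (pk$cterm[["default"]] + pk$nterm[["G"]]) / 2,
               tolerance = 1e-4)
  expect_equal(isoelectricPoint("AIA", pka = pkaSet("emboss")),
               (3.60 + 8.60) / 2, tolerance = 1e-4)
})

test_that("phosphorylation monotonically lowers the pI", {
  set.seed(41)
  for (i in 1:10) {
    s <- paste0("K", randomPeptide(sample(5:20, 1)), "R")  # ensure basic
    pis <- vapply(0:3, function(k)
      isoelectricPoint(s, if (k) list(modPhospho(k)) else list()),
      numeric(1))
    expect_true(all(diff(pis) < 0))
  }
})

test_that("over-removal of basic groups is rejected", {
  ## acetylation strips lysine amines; asking for more than the lysines
  ## present must fail loudly rather than yield a phantom charge state
  expect_error(isoelectricPoint("KDD", list(modAcetyl(2))),
               "remove more ionizable groups")
})

test_that("proteoforms carry consistent mass and shifted coordinates", {
  rec <- proteinRecord("X1", "MADSEKHHALKRGGWSSTKYQ",
                       chains = data.frame(name = "m", start = 2, end = 21),
                       siteCounts = c(phospho = 3))
  base <- makeProteoform(rec, "m")
  expect_s4_class(base, "Proteoform")
  p1 <- makeProteoform(rec, "m", list(modPhospho(1)))
  expect_equal(mwValue(p1) - mwValue(base), 79.9799, tolerance = 1e-6)
  expect_lt(piValue(p1), piValue(base))
  ## glyco: mass from composition; sialic acids acidify
  g <- makeProteoform(rec, "m", list(modGlycan(Hex = 3, NeuAc = 2)))
  expect_equal(mwValue(g) - mwValue(base), 3 * 162.14 + 2 * 291.26,
               tolerance = 1e-6)
  expect_lt(piValue(g), piValue(base))
  ## errors: unknown chain, site over-allocation
  expect_error(makeProteoform(rec, "nope"), "unknown chain")
  expect_error(makeProteoform(rec, "m", list(modPhospho(4))),
               "only 3 annotated site")
})

test_that("proteoform Mw invariant holds for random modification lists", {
  set.seed(51)
  rec <- proteinRecord("X2", randomPeptide(60))
  for (i in 1:20) {
    mods <- list(modPhospho(sample(0:3, 1)), modOxidation(sample(0:2, 1)),
                 modGlycan(Hex = sample(0:4, 1), HexNAc = sample(0:3, 1),
                           NeuAc = sample(0:2, 1), Fuc = sample(0:1, 1)))
    pf <- tryCatch(makeProteoform(rec, "full", mods),
                   error = function(e) NULL)
    if (is.null(pf)) next                # ensemble without basic group etc.
    delta <- sum(vapply(mods, function(m) m@massDeltaAvg, numeric(1)))
    expect_equal(mwValue(pf), proteinMass(pf@sequence) + delta,
                 tolerance = 1e-6)
  }
})

test_that("the three pKa sets give different but ordered estimates", {
  s <- "MADSEKHHALKRGGW"
  pis <- vapply(c("bjellqvist", "emboss", "lehninger"), function(n)
    isoelectricPoint(s, pka = pkaSet(n)), numeric(1))
  expect_true(all(pis > 0 & pis < 14))
  expect_gt(max(pis) - min(pis), 0.01)   # the sets are genuinely distinct
})
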