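toyRecord <- function()
  proteinRecord("T1", paste0("MV", "ADSEKHHALKR", "GGWSSTKYQACDEFGHILK",
                             "PQRSTVWYAEK"),
                chains = data.frame(name = "m", start = 2, end = 43))

test_that("simulateTrain enumerates the binomial x glycoform ensemble", {
  rec <- toyRecord()
  ## no sites, one glycoform: exactly one species, weight 1
  tr <- simulateTrain(rec, "m")
  expect_length(tr, 1L)
  expect_equal(abundanceWeight(tr[[1]]), 1)
  ## full occupancy: only the fully phosphorylated species survives
  tr1 <- simulateTrain(rec, "m", nPhosphoSites = 3, occupancy = 1)
  tab1 <- ensembleTable(tr1)
  expect_equal(tab1$n_phospho, 3L)
  expect_equal(tab1$weight, 1)
  ## occupancy 0.5, 2 sites: binomial weights 1/4, 1/2, 1/4
  tr2 <- simulateTrain(rec, "m", nPhosphoSites = 2, occupancy = 0.5)
  tab2 <- ensembleTable(tr2)
  expect_equal(tab2$weight[order(tab2$n_phospho)], c(0.25, 0.5, 0.25))
  ## weights always sum to 1, also with glycoforms
  gf <- list(list(glycan = modGlycan(Hex = 2), weight = 0.3),
             list(glycan = modGlycan(Hex = 2, NeuAc = 2), weight = 0.7))
  tr3 <- simulateTrain(rec, "m", nPhosphoSites = 3, occupancy = 0.4,
                       glycoforms = gf)
  expect_equal(sum(ensembleTable(tr3)$weight), 1, tolerance = 1e-12)
  ## successive phosphates shift the train acidic
  pis <- tab2$pI[order(tab2$n_phospho)]
  expect_true(all(diff(pis) < 0))
  expect_error(simulateTrain(rec, "m", glycoforms = list(
    list(glycan = NULL, weight = 0.5))), "sum to 1")
})

test_that("fixed seeds reproduce tables byte-for-byte; seeds differ", {
  rec <- toyRecord()
  tr <- simulateTrain(rec, "m", nPhosphoSites = 2, occupancy = 0.5)
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  win <- observabilityWindow(200, 4500, 3, 50)
  s1 <- simulateSectionTable(tr, sc, ax, depth = 5, jitterSD = 0.02,
                             seed = 7, window = win)
  s2 <- simulateSectionTable(tr, sc, ax, depth = 5, jitterSD = 0.02,
                             seed = 7, window = win)
  expect_identical(s1, s2)
  s3 <- simulateSectionTable(tr, sc, ax, depth = 5, jitterSD = 0.02,
                             seed = 8, window = win)
  expect_false(identical(s1$psm, s3$psm))
  ## the simulator leaves the global RNG stream untouched
  set.seed(99); before <- runif(3)
  set.seed(99)
  invisible(simulateSectionTable(tr, sc, ax, depth = 5, seed = 7,
                                 window = win))
  expect_identical(runif(3), before)
})

test_that("zero-weight species never generate rows", {
  rec <- toyRecord()
  tr <- simulateTrain(rec, "m", nPhosphoSites = 1, occupancy = 1)
  ## occupancy 1 removes the k=0 species entirely
  expect_equal(length(tr), 1L)
  tab <- ensembleTable(tr)
  expect_true(all(tab$weight > 0))
})

test_that("saturation: at extreme depth reconstructed emPAI approaches 9", {
  rec <- toyRecord()
  tr <- simulateTrain(rec, "m")          # one species
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  win <- observabilityWindow(200, 4500, 3, 50)
  sim <- simulateSectionTable(tr, sc, ax, depth = 1e6, jitterSD = 0,
                              seed = 3, window = win)
  q <- proteinQuantTable(sim$psm, sim$n_obsbl)
  expect_equal(q$n_obs, unname(sim$n_obsbl["T1"]))
  expect_equal(q$empai, 9)               # 10^1 - 1 at saturation
})

test_that("expected and realized counts agree over replicates", {
  rec <- toyRecord()
  tr <- simulateTrain(rec, "m", nPhosphoSites = 1, occupancy = 0.5)
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  win <- observabilityWindow(200, 4500, 3, 50)
  exp1 <- simulateSectionTable(tr, sc, ax, depth = 0.4, jitterSD = 0,
                               seed = 1, window = win)$expected
  set.seed(71)
  tot <- replicate(100, {
    s <- simulateSectionTable(tr, sc, ax, depth = 0.4, jitterSD = 0,
                              seed = sample.int(1e6, 1), window = win)
    sum(s$psm$score >= 0)                # total rows = total observed peptides
  })
  ## mean total observed peptides approx sum of expected (Poisson, far from
  ## saturation); 100 reps give a few-percent Monte-Carlo error
  expect_equal(mean(tot), sum(exp1$expected_n), tolerance = 0.15)
})

test_that("deeper sampling never recovers fewer sections (paired seeds)", {
  rec <- toyRecord()
  tr <- simulateTrain(rec, "m", nPhosphoSites = 2, occupancy = 0.5)
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  win <- observabilityWindow(200, 4500, 3, 50)
  nSections <- function(depth, seed) {
    s <- simulateSectionTable(tr, sc, ax, depth = depth, jitterSD = 0,
                              seed = seed, window = win)
    length(unique(s$psm$section_id))
  }
  for (seed in 1:10)
    expect_lte(nSections(0.5, seed), nSections(50, seed))
})

test_that("noise-free reconstruction recovers every species' section", {
  rec <- toyRecord()
  tr <- simulateTrain(rec, "m", nPhosphoSites = 3, occupancy = 0.5)
  sc <- sectionScheme("strip36")
  ax <- linearAxis18()
  win <- observabilityWindow(200, 4500, 3, 50)
  sim <- simulateSectionTable(tr, sc, ax, depth = 8, jitterSD = 0,
                              seed = 11, window = win)
  q <- proteinQuantTable(sim$psm, sim$n_obsbl, minUnique = 1)
  pat <- buildPattern(q, sc, ax,
                      theoreticalMw = c(T1 = mwValue(tr[[1]])))
  rep <- recoveryReport(pat, tr, sc, ax)
  expect_equal(rep$recovered_fraction, 1)
  ## the reconstructed centroid lies within the true train's pH span
  truthPis <- ensembleTable(tr)$pI
  loc <- locateSection(sc, phToPosition(ax, truthPis))
  wins <- sectionPiWindow(sc, ax, loc$col)
  expect_gte(rep$centroid_pi, min(wins$pi_low))
  expect_lte(rep$centroid_pi, max(wins$pi_high))
  ## single proteoform -> train width 1
  tr1 <- simulateTrain(rec, "m")
  sim1 <- simulateSectionTable(tr1, sc, ax, depth = 8, jitterSD = 0,
                               seed = 12, window = win)
  q1 <- proteinQuantTable(sim1$psm, sim1$n_obsbl, minUnique = 1)
  pat1 <- buildPattern(q1, sc, ax,
                       theoreticalMw = c(T1 = mwValue(tr1[[1]])))
  expect_equal(recoveryReport(pat1, tr1, sc, ax)$width_true, 1L)
})
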