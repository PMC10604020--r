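test_that("the same seed reproduces an identical bundle", {
  b1 <- simulateCohort(simulationConfig(seed = 5, nCompounds = 400))
  b2 <- simulateCohort(simulationConfig(seed = 5, nCompounds = 400))
  for (nm in c("properties", "reference", "pkas", "reactivity", "docking"))
    expect_identical(b1[[nm]], b2[[nm]])
  b3 <- simulateCohort(simulationConfig(seed = 6, nCompounds = 400))
  expect_false(identical(b1$properties, b3$properties))
})

test_that("missing-toxicity rate drives the first-screen drop count", {
  # zero rate: nothing dropped
  b0 <- simulateCohort(simulationConfig(seed = 2, nCompounds = 500,
                                        missingToxRate = 0))
  expect_equal(firstScreen(b0$properties)$counts[["dropped"]], 0L)
  # rate 0.24 at the full cohort size: inside the 99% binomial interval
  b <- simulateCohort(simulationConfig(seed = 3, missingToxRate = 0.24))
  dropped <- firstScreen(b$properties)$counts[["dropped"]]
  bounds <- qbinom(c(0.005, 0.995), 8358, 0.24)  # parent never flagged
  expect_gte(dropped, bounds[1])
  expect_lte(dropped, bounds[2])
})

test_that("generated tables satisfy every downstream schema invariant", {
  cfg <- simulationConfig(seed = 9, nCompounds = 600)
  b <- simulateCohort(cfg)
  p <- b$properties
  expect_equal(nrow(p), 600L)
  expect_false(anyDuplicated(p$id) > 0)
  counts <- c("hbd", "hba", "rotb", "heavy_atoms", "carbons",
              "heteroatoms", "rings")
  for (cl in counts) expect_true(all(p[[cl]] >= 0))
  expect_true(all(p$sa >= 0 & p$sa <= 100))
  expect_true(all(is.na(p$ld50) | p$ld50 > 0))
  for (cl in c("mutagenicity", "dev_tox"))
    expect_true(all(is.na(p[[cl]]) | (p[[cl]] >= 0 & p[[cl]] <= 1)))
  # reference table is complete and non-degenerate
  rs <- referenceStats(b$reference)
  expect_true(all(rs$sd > 0))
  # pKa ladders strictly ascending within each compound
  pk <- as.matrix(b$pkas[c("pka1", "pka2", "pka3")])
  for (i in seq_len(nrow(pk))) {
    v <- pk[i, !is.na(pk[i, ])]
    if (length(v) > 1) expect_true(all(diff(v) > 0))
  }
  expect_true(all(pk[!is.na(pk)] >= cfg$pkaRange[1] &
                  pk[!is.na(pk)] <= cfg$pkaRange[2]))
  # reactivity covers only relevant species; BDE/IP in configured ranges
  spec <- speciateTable(b$pkas, cfg$ph, cfg$relevanceThreshold)
  relKey <- paste(spec$id, spec$species)[spec$relevant == 1]
  expect_true(all(paste(b$reactivity$id, b$reactivity$species) %in% relKey))
  expect_true(all(b$reactivity$ip >= cfg$ipRange[1] &
                  b$reactivity$ip <= cfg$ipRange[2]))
  expect_true(all(b$reactivity$bde >= cfg$bdeRange[1] &
                  b$reactivity$bde <= cfg$bdeRange[2]))
  # docking scores negative, three enzymes per species
  expect_true(all(b$docking$dg < 0))
  expect_setequal(unique(b$docking$enzyme), c("COMT", "MAOB", "AChE"))
  # whole bundle survives a CSV round trip
  dir <- tempfile()
  writeBundle(b, dir)
  b2 <- readBundle(dir)
  expect_equal(b2$properties$mw, b$properties$mw, tolerance = 1e-9)
  expect_equal(nrow(b2$docking), nrow(b$docking))
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(simulationConfig(missingToxRate = 1.4), "missingToxRate")
  expect_error(simulationConfig(nCompounds = 1), "nCompounds")
  expect_error(simulationConfig(dockingRange = c(-2, 3)), "dockingRange")
  expect_error(simulationConfig(pkaCountProbs = c(1, 1, 1, 1)),
               "pkaCountProbs")
  expect_error(simulationConfig(plantedMargin = -1), "plantedMargin")
})

test_that("planted winners beat thresholds, dominate Trolox and bind", {
  cfg <- simulationConfig(seed = 21, nCompounds = 800)
  pw <- plantKnownWinners(cfg, k = 4)
  b <- pw$bundle
  expect_length(pw$answerKey, 4L)
  expect_true(all(pw$answerKey %in% b$properties$id))
  # (a) selection scores above parent and reference average
  scr <- firstScreen(b$properties)
  expect_true(all(pw$answerKey %in% scr$kept$id))
  rs <- referenceStats(b$reference)
  sc <- scoreCohort(scr$kept, rs)
  parent <- sc$s_sel[sc$id == "dQ1"]
  refAvg <- mean(selectionScore(b$reference, rs)$s_sel)
  win <- sc[sc$id %in% pw$answerKey, ]
  expect_true(all(win$s_sel > parent & win$s_sel > refAvg))
  # (b) reactivity dominating Trolox on both axes
  trol <- b$panel[b$panel$name == "Trolox", ]
  rea <- b$reactivity[b$reactivity$id %in% pw$answerKey, ]
  expect_true(all(rea$ip < trol$ip & rea$bde < trol$bde))
  # (c) positive polygenic score
  spec <- speciateTable(b$pkas[b$pkas$id %in% pw$answerKey, ])
  aff <- affinityTable(b$docking[b$docking$id %in% pw$answerKey, ],
                       spec, b$baselines)
  expect_true(all(aff$s_poly > 0))
  # k = 0: empty answer key, untouched bundle size
  pw0 <- plantKnownWinners(cfg, k = 0)
  expect_length(pw0$answerKey, 0L)
  expect_error(plantKnownWinners(cfg, k = 800), "k")
})
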