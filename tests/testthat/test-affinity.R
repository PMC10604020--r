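test_that("weighted score reduces, averages and respects bounds", {
  expect_equal(weightedScore(c(A = -7), c(A = 1)), -7)
  expect_equal(weightedScore(c(A = -6, B = -8), c(A = 0.5, B = 0.5)), -7)
  expect_equal(weightedScore(c(A = -5, B = -10), c(A = 0.9, B = 0.1)), -5.5)
  # invariant to the normalization scale of the fractions
  expect_equal(weightedScore(c(A = -5, B = -10), c(A = 9, B = 1)), -5.5)
  set.seed(31)
  for (i in 1:50) {
    k <- sample(1:4, 1)
    sc <- setNames(-runif(k, 4, 10), paste0("s", 1:k))
    fr <- setNames(runif(k, 0.01, 1), paste0("s", 1:k))
    w <- weightedScore(sc, fr)
    expect_gte(w, min(sc)); expect_lte(w, max(sc))
    expect_equal(w, sum(sc * fr) / sum(fr), tolerance = 1e-12)
  }
  expect_error(weightedScore(setNames(numeric(0), character(0)), c(A = 1)),
               "empty")
  expect_error(weightedScore(c(A = -7), c(B = 1)), "no fraction")
  expect_error(weightedScore(c(A = -7), c(A = 0)), "zero")
})

test_that("enzyme term is the log10 ratio with substrate-equivalence zero", {
  set.seed(32)
  for (x in -runif(20, 0.5, 12)) expect_equal(enzymeTerm(x, x), 0)
  expect_equal(enzymeTerm(-10, -5), log10(2))
  expect_equal(enzymeTerm(-5, -10), -log10(2))
  expect_equal(enzymeTerm(-10, -5, base = exp(1)), log(2))
  # strictly increasing in binding strength at fixed baseline
  dg <- seq(-9, -1, by = 0.5)
  expect_true(all(diff(enzymeTerm(dg, -5)) < 0))
  expect_error(enzymeTerm(0, -5), "negative")
  expect_error(enzymeTerm(-5, 1), "negative")
})

test_that("polygenic score sums the three enzyme terms", {
  expect_equal(polygenicScore(c(COMT = 0, MAOB = 0, AChE = 0)), 0)
  expect_equal(polygenicScore(c(COMT = 0.3, MAOB = 0.1, AChE = -0.1)), 0.3)
  expect_error(polygenicScore(c(COMT = 0.3, MAOB = 0.1)), "AChE")
})

test_that("chained aggregation equals a brute-force recomputation", {
  set.seed(33)
  enzymes <- c("COMT", "MAOB", "AChE")
  bl <- substrateBaselines()
  for (rep in 1:100) {
    nsp <- sample(1:3, 1)
    species <- paste0("sp", seq_len(nsp))
    fr <- runif(nsp, 0.02, 1)
    speciation <- data.frame(id = "c1", species = species, fraction = fr)
    docking <- expand.grid(id = "c1", species = species, enzyme = enzymes,
                           stringsAsFactors = FALSE)
    docking$dg <- -runif(nrow(docking), 4, 10)
    aff <- affinityTable(docking, speciation, bl, threshold = 0.01)
    # independent single-pass oracle
    sPoly <- 0
    for (enz in enzymes) {
      num <- 0; den <- 0
      for (j in seq_len(nsp)) {
        dgj <- docking$dg[docking$enzyme == enz & docking$species ==
                            species[j]]
        num <- num + fr[j] * dgj; den <- den + fr[j]
      }
      dgw <- num / den
      expect_equal(aff$dgw[aff$enzyme == enz], dgw, tolerance = 1e-9)
      sPoly <- sPoly + log10(dgw / bl[[enz]])
    }
    expect_equal(unique(aff$s_poly), sPoly, tolerance = 1e-9)
  }
})

test_that("affinity aggregation drops non-relevant species and renormalizes", {
  speciation <- data.frame(id = "c1", species = c("A", "B", "C"),
                           fraction = c(0.70, 0.295, 0.005))
  docking <- expand.grid(id = "c1", species = c("A", "B", "C"),
                         enzyme = c("COMT", "MAOB", "AChE"),
                         stringsAsFactors = FALSE)
  docking$dg <- rep(c(-6, -8, -100), times = 3)
  aff <- affinityTable(docking, speciation, substrateBaselines())
  # the 0.5% species (dg = -100) must not contribute
  exp_dgw <- (0.70 * -6 + 0.295 * -8) / (0.70 + 0.295)
  expect_equal(aff$dgw, rep(exp_dgw, 3), tolerance = 1e-12)
})

test_that("psp segments carry signs and sum to the polygenic score", {
  speciation <- data.frame(id = c("c1", "c2"), species = "A", fraction = 1)
  docking <- expand.grid(id = c("c1", "c2"), species = "A",
                         enzyme = c("COMT", "MAOB", "AChE"),
                         stringsAsFactors = FALSE)
  bl <- substrateBaselines()
  # c1 binds 2x stronger everywhere; c2 2x weaker on COMT only
  docking$dg <- ifelse(docking$id == "c1", bl[docking$enzyme] * 2,
                       ifelse(docking$enzyme == "COMT",
                              bl[docking$enzyme] / 2, bl[docking$enzyme]))
  psp <- pspTable(affinityTable(docking, speciation, bl))
  agg <- tapply(psp$segment, psp$id, sum)
  expect_equal(unname(agg["c1"]), 3 * log10(2), tolerance = 1e-12)
  expect_equal(unname(agg["c2"]), -log10(2), tolerance = 1e-12)
  expect_equal(unique(psp$s_poly[psp$id == "c1"]), 3 * log10(2),
               tolerance = 1e-12)
  expect_lt(psp$segment[psp$id == "c2" & psp$enzyme == "COMT"], 0)
  # empty input -> empty export
  empty <- affinityTable(docking[0, ], speciation, bl)
  expect_equal(nrow(pspTable(empty)), 0L)
})

test_that("docking logs round-trip through the text importer", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# engine-agnostic best-pose table",
               "c1 A COMT -6.25", "c1 A MAOB -5.5", "c1 A AChE -7.125"), f)
  d <- readDockingLog(f)
  expect_equal(nrow(d), 3L)
  expect_equal(d$dg, c(-6.25, -5.5, -7.125))
  expect_equal(names(d), c("id", "species", "enzyme", "dg"))
})
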