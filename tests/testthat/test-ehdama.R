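refsPanel <- referencePanel()

test_that("the donation map carries minimum BDE and the full panel", {
  rea <- data.frame(id = c("x", "x", "y"),
                    species = c("A", "A", "A"),
                    ip = c(100, 100, 95),
                    site = c("phenol_OH", "ester_CH3", "amine_NH"),
                    bde = c(80, 95, 82))
  m <- buildEhdamaMap(rea, refsPanel)
  expect_equal(m$bde_min[m$id == "x"], 80)      # min over sites
  expect_equal(m$n_sites[m$id == "x"], 2L)
  expect_equal(m$bde_min[m$id == "y"], 82)      # singleton min
  expect_setequal(m$id[m$kind != "candidate"],
                  c("Trolox", "alpha-tocopherol", "ascorbate", "OOH"))
  # empty record list: only the four reference rows
  m0 <- buildEhdamaMap(rea[0, ], refsPanel)
  expect_equal(nrow(m0), 4L)
  badPanel <- refsPanel[refsPanel$name != "Trolox", ]
  expect_error(buildEhdamaMap(rea, badPanel), "Trolox")
})

test_that("classification against references follows strict dominance", {
  trol <- refsPanel[refsPanel$name == "Trolox", ]
  rea <- data.frame(id = c("dom", "simset", "mixed"),
                    species = "A",
                    ip = c(trol$ip - 5, trol$ip + 0.05, 99),
                    site = "phenol_OH",
                    bde = c(trol$bde - 5, trol$bde - 3, 73))
  cl <- classifySpecies(buildEhdamaMap(rea, refsPanel), refsPanel)
  # strictly below Trolox in both: better via SET and HAT
  expect_equal(cl$set_trolox[cl$id == "dom"], "better")
  expect_equal(cl$hat_trolox[cl$id == "dom"], "better")
  # ip within 0.1 of Trolox: similar electron donor
  expect_equal(cl$set_trolox[cl$id == "simset"], "similar")
  expect_equal(cl$hat_trolox[cl$id == "simset"], "better")
  # below ascorbate BDE but above its IP: better HAT, worse SET
  asc <- refsPanel[refsPanel$name == "ascorbate", ]
  expect_lt(73, asc$bde); expect_gt(99, asc$ip)
  expect_equal(cl$hat_ascorbate[cl$id == "mixed"], "better")
  expect_equal(cl$set_ascorbate[cl$id == "mixed"], "worse")
  # hydroperoxyl comparisons reported separately
  expect_equal(cl$hat_ooh[cl$id == "dom"], "favored")
  expect_true(all(c("set_ooh", "hat_ooh") %in% names(cl)))
})

test_that("a species identical to a reference is similar on both axes", {
  trol <- refsPanel[refsPanel$name == "Trolox", ]
  rea <- data.frame(id = "twin", species = "A", ip = trol$ip,
                    site = "phenol_OH", bde = trol$bde)
  cl <- classifySpecies(buildEhdamaMap(rea, refsPanel), refsPanel)
  expect_equal(cl$set_trolox, "similar")
  expect_equal(cl$hat_trolox, "similar")
  expect_equal(cl$n_dominated, 0L)
})

test_that("classification is invariant under a shared unit conversion", {
  set.seed(77)
  rea <- data.frame(id = paste0("s", 1:12), species = "A",
                    ip = runif(12, 90, 130), site = "phenol_OH",
                    bde = runif(12, 70, 95))
  clK <- classifySpecies(buildEhdamaMap(rea, refsPanel), refsPanel,
                         tol = 0.1)
  kj <- 4.184
  reaJ <- rea; reaJ$ip <- rea$ip * kj; reaJ$bde <- rea$bde * kj
  panelJ <- referencePanel(
    trolox = c(ip = 108.0 * kj, bde = 78.4 * kj),
    tocopherol = c(ip = 105.0 * kj, bde = 77.2 * kj),
    ascorbate = c(ip = 96.0 * kj, bde = 74.3 * kj),
    oohTarget = c(ip = 150.0 * kj, bde = 87.8 * kj), unit = "kJ/mol")
  clJ <- classifySpecies(buildEhdamaMap(reaJ, panelJ), panelJ,
                         tol = 0.1 * kj)
  cols <- grep("^(set|hat)_", names(clK), value = TRUE)
  expect_identical(clK[cols], clJ[cols])
})

test_that("lowering a site BDE never worsens the HAT class", {
  rank3 <- c(worse = 1, similar = 2, better = 3)
  set.seed(88)
  for (i in 1:25) {
    bde <- runif(2, 72, 94)
    rea <- data.frame(id = "m", species = "A", ip = 100,
                      site = c("phenol_OH", "ester_CH3"), bde = bde)
    lower <- rea; lower$bde[1] <- lower$bde[1] - runif(1, 0, 10)
    c1 <- classifySpecies(buildEhdamaMap(rea, refsPanel), refsPanel)
    c2 <- classifySpecies(buildEhdamaMap(lower, refsPanel), refsPanel)
    for (cl in grep("^hat_", names(c1), value = TRUE)) {
      r1 <- if (cl == "hat_ooh") c(unfavored = 1, similar = 2, favored = 3)
            else rank3
      expect_gte(r1[[c2[[cl]]]], r1[[c1[[cl]]]])
    }
  }
})

test_that("ranking agrees with a brute-force sort on the declared key", {
  set.seed(99)
  rea <- data.frame(id = paste0("s", sprintf("%02d", 1:30)), species = "A",
                    ip = runif(30, 90, 130), site = "phenol_OH",
                    bde = runif(30, 70, 95))
  ranked <- rankAntioxidants(buildEhdamaMap(rea, refsPanel), refsPanel)
  cl <- classifySpecies(buildEhdamaMap(rea, refsPanel), refsPanel)
  ord <- order(-cl$n_dominated, cl$bde_min, cl$ip, cl$id, cl$species)
  expect_equal(ranked$id, cl$id[ord])
  # Pareto dominance puts the dominant species first
  two <- data.frame(id = c("weak", "strong"), species = "A",
                    ip = c(107, 95), site = "phenol_OH", bde = c(78, 72))
  r2 <- rankAntioxidants(buildEhdamaMap(two, refsPanel), refsPanel)
  expect_equal(r2$id[1], "strong")
  one <- rankAntioxidants(buildEhdamaMap(two[1, ], refsPanel), refsPanel)
  expect_equal(nrow(one), 1L)
})
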