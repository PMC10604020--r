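test_that("a compound at the reference centroid has zero elimination score", {
  rs <- referenceStats(tinyRefs())
  p <- centroidRow(rs)
  e <- eliminationScore(p, rs)
  expect_equal(e$s_elim, 0)
  comp <- unlist(e[c("S_ADME2", "S_ADME8", "S_ADMET", "S_ADMETSA")])
  expect_equal(unname(comp), rep(0, 4))
  expect_equal(unname(unlist(e[grep("^e_", names(e))])),
               rep(0, length(scoredProperties())))
})

test_that("one unit of standardized deviation gives s_elim = 1", {
  rs <- referenceStats(tinyRefs())
  p <- centroidRow(rs)
  k <- match("tpsa", rs$property)
  p$tpsa <- rs$mean[k] + rs$sd[k]
  e <- eliminationScore(p, rs)
  expect_equal(e$s_elim, 1)
  expect_equal(e$e_tpsa, 1)
})

test_that("elimination equals the brute-force sum of |z| and components nest", {
  refs <- tinyRefs(12)
  rs <- referenceStats(refs)
  props <- tinyProps(6)
  e <- eliminationScore(props, rs)
  # independent z-score oracle, property by property
  for (i in seq_len(nrow(props))) {
    z <- 0
    for (pp in scoredProperties()) {
      mu <- mean(refs[[pp]]); sdev <- sd(refs[[pp]])
      z <- z + abs(props[[pp]][i] - mu) / sdev
    }
    expect_equal(e$s_elim[i], z, tolerance = 1e-12)
  }
  # exact component identities
  toxSum <- e$e_ld50 + e$e_mutagenicity + e$e_dev_tox + e$e_bf
  expect_equal(e$S_ADMETSA, e$S_ADMET + e$e_sa)
  expect_equal(e$S_ADMET, e$S_ADME8 + toxSum)
  expect_equal(e$S_ADME2, e$e_mw + e$e_logp)
  expect_equal(e$s_elim, e$S_ADMETSA, tolerance = 1e-9)
})

test_that("elimination score scales linearly with the deviations", {
  rs <- referenceStats(tinyRefs())
  p1 <- centroidRow(rs)
  p2 <- p1
  for (pp in scoredProperties()) {
    k <- match(pp, rs$property)
    p1[[pp]] <- rs$mean[k] + 0.5 * rs$sd[k]
    p2[[pp]] <- rs$mean[k] + 1.5 * rs$sd[k]
  }
  e1 <- eliminationScore(p1, rs); e2 <- eliminationScore(p2, rs)
  expect_equal(e2$s_elim, 3 * e1$s_elim, tolerance = 1e-9)
})

test_that("selection score is monotone in each safety/ease direction", {
  rs <- referenceStats(tinyRefs())
  base <- tinyProps(1)
  s0 <- selectionScore(base, rs)$s_sel
  # safer: higher LD50
  up <- base; up$ld50 <- base$ld50 + 200
  expect_gt(selectionScore(up, rs)$s_sel, s0)
  # more mutagenic: worse
  worse <- base; worse$mutagenicity <- base$mutagenicity + 0.2
  expect_lt(selectionScore(worse, rs)$s_sel, s0)
  # easier to synthesize: better
  easy <- base; easy$sa <- base$sa + 20
  expect_gt(selectionScore(easy, rs)$s_sel, s0)
  # less developmental toxicity and bioaccumulation: better
  safer <- base; safer$dev_tox <- base$dev_tox - 0.15
  expect_gt(selectionScore(safer, rs)$s_sel, s0)
  lowbf <- base; lowbf$bf <- base$bf - 1
  expect_gt(selectionScore(lowbf, rs)$s_sel, s0)
})

test_that("selection blocks match a spreadsheet-style hand computation", {
  rs <- referenceStats(tinyRefs())
  p <- tinyProps(5)
  s <- selectionScore(p, rs)
  r <- applyRules(p)
  for (i in seq_len(nrow(p))) {
    expect_equal(s$block_adme[i], r$rules_passed[i] * 4 / 5)
    zb <- c(
      (p$ld50[i] - rs$mean[rs$property == "ld50"]) /
        rs$sd[rs$property == "ld50"],
      -(p$mutagenicity[i] - rs$mean[rs$property == "mutagenicity"]) /
        rs$sd[rs$property == "mutagenicity"],
      -(p$dev_tox[i] - rs$mean[rs$property == "dev_tox"]) /
        rs$sd[rs$property == "dev_tox"],
      -(p$bf[i] - rs$mean[rs$property == "bf"]) / rs$sd[rs$property == "bf"])
    expect_equal(s$block_tox[i], mean(4 * pnorm(zb)), tolerance = 1e-12)
    expect_equal(s$block_sa[i], p$sa[i] * 4 / 100)
    expect_equal(s$s_sel[i],
                 mean(c(s$block_adme[i], s$block_tox[i], s$block_sa[i])))
  }
  # a compound at the centroid scores exactly 2 on the toxicity block
  expect_equal(selectionScore(centroidRow(rs), rs)$block_tox, 2)
})

test_that("scoring refuses missing inputs and degenerate references", {
  rs <- referenceStats(tinyRefs())
  p <- tinyProps(3)
  p$ld50[2] <- NA
  expect_error(selectionScore(p, rs), "firstScreen")
  expect_error(eliminationScore(p, rs), "firstScreen")
  refs <- tinyRefs()
  refs$rotb <- 4L  # zero variance
  expect_warning(rs2 <- referenceStats(refs), "degenerate")
  expect_false("rotb" %in% rs2$property)
  expect_error(eliminationScore(tinyProps(2), rs2), "rotb")
  expect_error(referenceStats(tinyRefs(1)), "at least 2")
})

test_that("rank-and-select filters on both thresholds and orders stably", {
  sc <- data.frame(id = sprintf("c%02d", 1:8),
                   s_sel = c(3.2, 2.9, 3.5, 2.1, 3.2, 3.0, 3.2, 3.4),
                   s_elim = c(5, 4, 6, 2, 5, 7, 4, 5))
  out <- rankAndSelect(sc, topN = 10, parentScore = 2.95, refAvgScore = 3.0)
  # survivors: s_sel > 3.0 -> c01, c03, c05, c07, c08
  expect_equal(attr(out, "n_passing"), 5L)
  # ascending s_elim, ties by descending s_sel then id:
  # c07 (4), then s_elim 5: c08 (3.4) before c01/c05 (3.2, id order), c03 (6)
  expect_equal(out$id, c("c07", "c08", "c01", "c05", "c03"))
  out2 <- rankAndSelect(sc, topN = 2, parentScore = 2.95, refAvgScore = 3.0)
  expect_equal(out2$id, c("c07", "c08"))
  # all below the thresholds: empty selection
  out3 <- rankAndSelect(sc, topN = 5, parentScore = 4, refAvgScore = 4)
  expect_equal(nrow(out3), 0L)
  expect_error(rankAndSelect(sc, topN = 0, 1, 1), "positive")
})

test_that("cohort self-thresholds retain a strict subset", {
  refs <- tinyRefs(10)
  rs <- referenceStats(refs)
  props <- tinyProps(12)
  sc <- scoreCohort(props, rs)
  thr <- median(sc$s_sel)
  out <- rankAndSelect(sc, topN = 99, parentScore = thr, refAvgScore = thr)
  expect_lt(nrow(out), nrow(sc))
})
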