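## synthetic-data stage: generate the external input tables (toxicity, SA,
## pKa, reactivity, docking) with the statistical structure the analysis
## assumes, so every downstream stage is testable without external software.

#' Simulation configuration
#'
#' Validated parameter bundle for [simulateCohort()]. The defaults encode
#' the study conditions of the quinoline campaign: a cohort of 8,359
#' structures (parent included), a 2033/8358 missing-toxicity rate, a
#' 30-compound reference set, pH 7.4, a 1\% species-relevance threshold
#' and 25 selected candidates. Endpoint distributions are loosely
#' calibrated to the campaign's qualitative structure: derivatives are
#' smaller than the reference neuroprotectors, slightly safer on LD50 and
#' mutagenicity, clearly safer on developmental toxicity, lower but widely
#' dispersed on bioaccumulation, and easier to synthesize.
#'
#' @param seed integer RNG seed.
#' @param nCompounds cohort size including the parent (default 8359).
#' @param missingToxRate probability that a compound has at least one
#'   missing toxicity endpoint (default 2033/8358).
#' @param nRefs reference-set size (default 30).
#' @param topN candidates retained by selection (default 25).
#' @param ph working pH (default 7.4).
#' @param relevanceThreshold species-relevance cutoff (default 0.01).
#' @param refMeans,refSds named numeric over [scoredProperties()] plus
#'   `carbons`, `heteroatoms`, `rings`: reference-set property
#'   distributions.
#' @param pkaCountProbs probabilities of 0-3 pKa values per compound.
#' @param pkaRange support of pKa values (default 2-12).
#' @param ipRange ionization-potential range, bracketing the reference
#'   panel (default 90-130 kcal/mol).
#' @param bdeRange bond-dissociation-energy range, bracketing the panel
#'   (default 70-95 kcal/mol).
#' @param dockingRange binding-score range per enzyme (default -9 to -4
#'   kcal/mol; strictly negative).
#' @param baselines a [substrateBaselines()] vector.
#' @param panel a [referencePanel()].
#' @param plantedMargin standardized margin used by [plantKnownWinners()]
#'   (default 1.5 reference standard deviations).
#' @return a validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nCompounds = 8359L,
                             missingToxRate = 2033 / 8358,
                             nRefs = 30L,
                             topN = 25L,
                             ph = 7.4,
                             relevanceThreshold = 0.01,
                             refMeans = NULL, refSds = NULL,
                             pkaCountProbs = c(0.2, 0.4, 0.3, 0.1),
                             pkaRange = c(2, 12),
                             ipRange = c(90, 130),
                             bdeRange = c(70, 95),
                             dockingRange = c(-9, -4),
                             baselines = substrateBaselines(),
                             panel = referencePanel(),
                             plantedMargin = 1.5) {
    if (is.null(refMeans))
        refMeans <- c(mw = 330, logp = 2.8, hbd = 2, hba = 5, tpsa = 75,
                      rotb = 5, mr = 95, heavy_atoms = 24, carbons = 18,
                      heteroatoms = 6, rings = 3, sa = 45, ld50 = 600,
                      mutagenicity = 0.38, dev_tox = 0.50, bf = 1.5)
    if (is.null(refSds))
        refSds <- c(mw = 80, logp = 1.2, hbd = 1, hba = 1.5, tpsa = 20,
                    rotb = 2, mr = 20, heavy_atoms = 5, carbons = 4,
                    heteroatoms = 2, rings = 1, sa = 12, ld50 = 250,
                    mutagenicity = 0.15, dev_tox = 0.15, bf = 1.2)
    cfg <- list(seed = as.integer(seed), nCompounds = as.integer(nCompounds),
                missingToxRate = missingToxRate, nRefs = as.integer(nRefs),
                topN = as.integer(topN), ph = ph,
                relevanceThreshold = relevanceThreshold,
                refMeans = refMeans, refSds = refSds,
                pkaCountProbs = pkaCountProbs, pkaRange = pkaRange,
                ipRange = ipRange, bdeRange = bdeRange,
                dockingRange = dockingRange, baselines = baselines,
                panel = panel, plantedMargin = plantedMargin)
    bad <- character(0)
    if (is.na(cfg$seed)) bad <- c(bad, "seed")
    if (is.na(cfg$nCompounds) || cfg$nCompounds < 2L) bad <- c(bad, "nCompounds")
    if (!is.finite(cfg$missingToxRate) || cfg$missingToxRate < 0 ||
        cfg$missingToxRate > 1) bad <- c(bad, "missingToxRate")
    if (is.na(cfg$nRefs) || cfg$nRefs < 2L) bad <- c(bad, "nRefs")
    if (is.na(cfg$topN) || cfg$topN < 1L) bad <- c(bad, "topN")
    need <- c(scoredProperties(), "carbons", "heteroatoms", "rings")
    if (!all(need %in% names(cfg$refMeans))) bad <- c(bad, "refMeans")
    if (!all(need %in% names(cfg$refSds)) || any(cfg$refSds[need] <= 0))
        bad <- c(bad, "refSds")
    if (length(cfg$pkaCountProbs) != 4L || any(cfg$pkaCountProbs < 0) ||
        abs(sum(cfg$pkaCountProbs) - 1) > 1e-9) bad <- c(bad, "pkaCountProbs")
    for (rg in c("pkaRange", "ipRange", "bdeRange", "dockingRange"))
        if (length(cfg[[rg]]) != 2L || diff(cfg[[rg]]) <= 0) bad <- c(bad, rg)
    if (any(cfg$dockingRange >= 0)) bad <- c(bad, "dockingRange")
    if (!is.finite(cfg$plantedMargin) || cfg$plantedMargin <= 0)
        bad <- c(bad, "plantedMargin")
    if (length(bad))
        stop("invalid simulation config field(s): ",
             paste(unique(bad), collapse = ", "))
    class(cfg) <- "simulationConfig"
    cfg
}

## descriptor values of the quinoline parent (fixed; OpenBabel-derived)
parentProperties <- function() {
    data.frame(id = "dQ1", mw = 129.159, logp = 2.235, hbd = 0L, hba = 1L,
               tpsa = 12.89, rotb = 0L, mr = 41.74, heavy_atoms = 10L,
               carbons = 9L, heteroatoms = 1L, rings = 2L,
               stringsAsFactors = FALSE)
}

.rnormClamp <- function(n, mean, sd, lo = -Inf, hi = Inf, integer = FALSE) {
    x <- stats::rnorm(n, mean, sd)
    x <- pmin(pmax(x, lo), hi)
    if (integer) as.integer(round(x)) else x
}

#' Simulate a full input bundle
#'
#' Generates every table the pipeline consumes: the compound property
#' table (descriptors + SA + toxicity, with compound-level missing
#' toxicity at the configured rate), the reference-set property table, the
#' pKa table (0-3 ascending values per compound in the configured range),
#' the per-species reactivity table (IP and per-site BDE bracketing the
#' reference panel) and the per-species, per-enzyme docking table
#' (strictly negative scores). Reproducible: the same configuration (same
#' seed) yields an identical bundle. The parent compound `dQ1` carries the
#' fixed quinoline descriptor block and always has complete toxicity data.
#'
#' @param cfg a [simulationConfig()].
#' @return list of class `cohortBundle`: `properties`, `reference`,
#'   `pkas`, `reactivity`, `docking`, `baselines`, `panel`, `config`.
#' @export
simulateCohort <- function(cfg = simulationConfig()) {
    if (!inherits(cfg, "simulationConfig")) cfg <- do.call(simulationConfig, cfg)
    set.seed(cfg$seed)
    n <- cfg$nCompounds
    ids <- paste0("dQ", seq_len(n))

    ## --- derivative property table -----------------------------------
    props <- data.frame(id = ids, stringsAsFactors = FALSE)
    props$mw <- .rnormClamp(n, 240, 45, lo = 129)
    props$logp <- stats::rnorm(n, 2.0, 1.0)
    props$hbd <- .rnormClamp(n, 1.2, 1.0, lo = 0, integer = TRUE)
    props$hba <- .rnormClamp(n, 3, 1.2, lo = 1, integer = TRUE)
    props$tpsa <- .rnormClamp(n, 60, 22, lo = 3)
    props$rotb <- .rnormClamp(n, 2, 1.3, lo = 0, integer = TRUE)
    props$mr <- .rnormClamp(n, 65, 12, lo = 20)
    props$heavy_atoms <- .rnormClamp(n, 17, 3, lo = 10, integer = TRUE)
    props$carbons <- .rnormClamp(n, 12, 2, lo = 5, integer = TRUE)
    props$heteroatoms <- pmax(props$heavy_atoms - props$carbons, 1L)
    props$rings <- 2L + stats::rbinom(n, 1, 0.15)
    props$sa <- .rnormClamp(n, 65, 10, lo = 0, hi = 100)
    props$ld50 <- stats::rlnorm(n, log(700), 0.6)
    props$mutagenicity <- stats::rbeta(n, 2, 6)
    props$dev_tox <- stats::rbeta(n, 2, 5)
    props$bf <- stats::rnorm(n, 0.8, 0.7)
    props[1, names(parentProperties())] <- parentProperties()
    props$sa[1] <- 80; # unsubstituted core: easy to make

    ## compound-level missing toxicity: a flagged compound loses a
    ## non-empty random subset of the four endpoints (parent never flagged)
    flag <- stats::runif(n) < cfg$missingToxRate
    flag[1] <- FALSE
    maskIdx <- sample.int(15L, n, replace = TRUE)   # non-empty 4-bit masks
    tox <- toxicityColumns()
    for (b in 1:4) {
        hit <- flag & bitwAnd(maskIdx, bitwShiftL(1L, b - 1L)) > 0L
        props[[tox[b]]][hit] <- NA_real_
    }

    ## --- reference set ------------------------------------------------
    m <- cfg$refMeans; s <- cfg$refSds
    ref <- data.frame(id = paste0("ref", seq_len(cfg$nRefs)),
                      stringsAsFactors = FALSE)
    for (p in c("mw", "logp", "tpsa", "mr", "bf"))
        ref[[p]] <- stats::rnorm(cfg$nRefs, m[[p]], s[[p]])
    for (p in c("hbd", "hba", "rotb", "heavy_atoms", "carbons",
                "heteroatoms", "rings"))
        ref[[p]] <- .rnormClamp(cfg$nRefs, m[[p]], s[[p]], lo = 0,
                                integer = TRUE)
    ref$sa <- .rnormClamp(cfg$nRefs, m[["sa"]], s[["sa"]], 0, 100)
    ref$ld50 <- .rnormClamp(cfg$nRefs, m[["ld50"]], s[["ld50"]], lo = 10)
    ref$mutagenicity <- .rnormClamp(cfg$nRefs, m[["mutagenicity"]],
                                    s[["mutagenicity"]], 0.01, 0.99)
    ref$dev_tox <- .rnormClamp(cfg$nRefs, m[["dev_tox"]], s[["dev_tox"]],
                               0.01, 0.99)
    ref <- ref[c("id", descriptorColumns(), "sa", toxicityColumns())]

    ## --- pKa table (0-3 ascending values in range) --------------------
    kcount <- sample(0:3, n, replace = TRUE, prob = cfg$pkaCountProbs)
    kcount[1] <- 1L                     # parent: ring-N pKa only
    pkmat <- matrix(NA_real_, n, 3)
    for (cc in 1:3) {
        rows <- which(kcount == cc)
        if (!length(rows)) next
        v <- matrix(stats::runif(length(rows) * cc, cfg$pkaRange[1],
                                 cfg$pkaRange[2]), ncol = cc)
        if (cc > 1) v <- t(apply(v, 1, sort))
        pkmat[rows, seq_len(cc)] <- v
    }
    pkmat[1, ] <- c(4.85, NA, NA)       # quinolinium-like parent
    pkas <- data.frame(id = ids, pka1 = pkmat[, 1], pka2 = pkmat[, 2],
                       pka3 = pkmat[, 3], stringsAsFactors = FALSE)

    ## --- reactivity (per relevant species) ----------------------------
    spec <- speciateTable(pkas, ph = cfg$ph,
                          threshold = cfg$relevanceThreshold)
    rel <- spec[spec$relevant == 1L, , drop = FALSE]
    nr <- nrow(rel)
    siteInventory <- c("phenol_OH", "amine_NH", "thiol_SH", "ester_CH3")
    nSites <- 1L + stats::rbinom(nr, 2, 0.4)
    ipBySpecies <- stats::runif(nr, cfg$ipRange[1], cfg$ipRange[2])
    row2sp <- rep(seq_len(nr), nSites)
    siteIdx <- unlist(lapply(nSites, function(k)
        sample.int(length(siteInventory), k)), use.names = FALSE)
    reactivity <- data.frame(id = rel$id[row2sp],
                             species = rel$species[row2sp],
                             ip = ipBySpecies[row2sp],
                             site = siteInventory[siteIdx],
                             bde = stats::runif(length(row2sp),
                                                cfg$bdeRange[1],
                                                cfg$bdeRange[2]),
                             stringsAsFactors = FALSE)

    ## --- docking (per relevant species x enzyme) -----------------------
    docking <- expand.grid(key = seq_len(nr), enzyme = .enzymes,
                           stringsAsFactors = FALSE)
    docking <- data.frame(id = rel$id[docking$key],
                          species = rel$species[docking$key],
                          enzyme = docking$enzyme, stringsAsFactors = FALSE)
    docking$dg <- stats::runif(nrow(docking), cfg$dockingRange[1],
                               cfg$dockingRange[2])

    structure(list(properties = props, reference = ref, pkas = pkas,
                   reactivity = reactivity, docking = docking,
                   baselines = cfg$baselines, panel = cfg$panel,
                   config = cfg),
              class = "cohortBundle")
}

#' Plant recoverable winners in a simulated bundle
#'
#' Overwrites `k` randomly chosen non-parent compounds so that, by
#' construction, they (a) beat both selection-score thresholds and carry
#' the lowest elimination scores -- every scored property sits exactly on
#' the empirical reference centroid (deviation ~ 0) except synthetic
#' accessibility, which is set to its 100 cap for selection-score
#' headroom; (b) dominate Trolox on both donation axes by
#' `plantedMargin`-scaled energy gaps; and (c) bind every enzyme more
#' strongly than its natural substrate by a margin-scaled factor. Because
#' the selection-side construction is saturated (centroid + SA cap), the
#' margin knob only widens the (b)/(c) gaps: recovery does not hinge on
#' razor-thin energy differences. Used for end-to-end recovery tests: the
#' final proposal list must contain the answer key.
#'
#' @param cfg a [simulationConfig()].
#' @param k number of winners to plant (`0 <= k < nCompounds`).
#' @param marginScale multiplier on `cfg$plantedMargin` (robustness knob).
#' @return list `bundle` (a `cohortBundle`) and `answerKey` (character
#'   ids, sorted).
#' @export
plantKnownWinners <- function(cfg = simulationConfig(), k = 4L,
                              marginScale = 1) {
    if (!inherits(cfg, "simulationConfig")) cfg <- do.call(simulationConfig, cfg)
    k <- as.integer(k)
    if (is.na(k) || k < 0L || k >= cfg$nCompounds)
        stop("'k' must satisfy 0 <= k < nCompounds")
    bundle <- simulateCohort(cfg)
    if (k == 0L) return(list(bundle = bundle, answerKey = character(0)))
    margin <- cfg$plantedMargin * marginScale
    ids <- bundle$properties$id
    winners <- sort(sample(ids[-1], k))

    w <- match(winners, ids)
    pr <- bundle$properties
    intCols <- c("hbd", "hba", "rotb", "heavy_atoms", "carbons",
                 "heteroatoms", "rings")
    emp <- function(p) mean(bundle$reference[[p]])
    for (p in c("mw", "logp", "tpsa", "mr", "ld50", "mutagenicity",
                "dev_tox", "bf"))
        pr[[p]][w] <- emp(p)
    for (p in intCols) pr[[p]][w] <- as.integer(round(emp(p)))
    pr$sa[w] <- 100
    bundle$properties <- pr

    ## single high pKa: neutral species dominates at pH 7.4
    bundle$pkas[w, c("pka1", "pka2", "pka3")] <- NA_real_
    bundle$pkas$pka1[w] <- 9.8

    trol <- bundle$panel[bundle$panel$name == "Trolox", , drop = FALSE]
    drop <- !(bundle$reactivity$id %in% winners)
    bundle$reactivity <- bundle$reactivity[drop, , drop = FALSE]
    planted <- data.frame(id = winners, species = "A",
                          ip = trol$ip - 2 * margin, site = "phenol_OH",
                          bde = trol$bde - 2 * margin,
                          stringsAsFactors = FALSE)
    bundle$reactivity <- rbind(bundle$reactivity, planted)

    keep <- !(bundle$docking$id %in% winners)
    bundle$docking <- bundle$docking[keep, , drop = FALSE]
    extra <- expand.grid(id = winners, enzyme = .enzymes,
                         stringsAsFactors = FALSE)
    extra <- data.frame(id = extra$id, species = "A", enzyme = extra$enzyme,
                        dg = unname(bundle$baselines[extra$enzyme]) *
                            (1 + 0.1 * margin),
                        stringsAsFactors = FALSE)
    bundle$docking <- rbind(bundle$docking, extra)
    rownames(bundle$docking) <- rownames(bundle$reactivity) <- NULL
    list(bundle = bundle, answerKey = winners)
}

#' @export
print.simulationConfig <- function(x, ...) {
    cat("simulationConfig: n =", x$nCompounds, "(seed", x$seed, ")\n")
    cat("  missing-toxicity rate", signif(x$missingToxRate, 4),
        "| refs", x$nRefs, "| topN", x$topN, "| pH", x$ph, "\n")
    invisible(x)
}

#' @export
print.cohortBundle <- function(x, ...) {
    cat("cohortBundle:", nrow(x$properties), "compounds,",
        nrow(x$reference), "references,", nrow(x$reactivity),
        "reactivity rows,", nrow(x$docking), "docking rows\n")
    invisible(x)
}
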