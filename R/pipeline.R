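## pipeline stage: screen -> score -> select -> speciate -> donation map ->
## affinity -> proposals, with a manifest of counts and parameters.

#' Run the full screening pipeline on an input bundle
#'
#' Orchestrates the staged analysis on a `cohortBundle` (simulated via
#' [simulateCohort()] / [plantKnownWinners()], or assembled from real
#' tables with the same schemas):
#' \enumerate{
#'   \item first screening: drop compounds with missing toxicity;
#'   \item selection / elimination scoring against the reference set;
#'   \item candidate selection: selection score above both the parent's
#'     and the reference average, ordered by ascending elimination score,
#'     truncated to `topN`;
#'   \item acid-base speciation of the candidates at the working pH;
#'   \item donation map and classification of their relevant species
#'     against the reference antioxidants;
#'   \item fraction-weighted docking aggregation and polygenic scores;
#'   \item final proposals: candidates with at least one relevant species
#'     dominating Trolox via both SET and HAT and a positive polygenic
#'     score, ordered by descending polygenic score.
#' }
#' If the first screening leaves no compound the run halts with status
#' `"empty cohort"`.
#'
#' @param bundle a `cohortBundle` (see [simulateCohort()]).
#' @param topN,ph,threshold stage parameters; default from the bundle's
#'   config (or 25 / 7.4 / 0.01 for hand-built bundles).
#' @param weights selection-score block weights (see [selectionScore()]).
#' @param parentId identifier of the parent molecule (default `"dQ1"`).
#' @param outDir optional directory: stage tables are written as CSV and
#'   their MD5 hashes recorded in the manifest.
#' @return list of class `pipelineRun`: `status` (`"ok"` or
#'   `"empty cohort"`), `proposals` (data.frame `id`, `s_poly`,
#'   `n_dominated`), `candidates`, `scores`, `speciation`, `ehdama`,
#'   `affinity`, and `manifest` (parameters, stage counts, file hashes).
#' @export
runPipeline <- function(bundle, topN = NULL, ph = NULL, threshold = NULL,
                        weights = c(adme = 1, tox = 1, sa = 1),
                        parentId = "dQ1", outDir = NULL) {
    cfg <- bundle$config
    if (is.null(topN)) topN <- if (!is.null(cfg)) cfg$topN else 25L
    if (is.null(ph)) ph <- if (!is.null(cfg)) cfg$ph else 7.4
    if (is.null(threshold))
        threshold <- if (!is.null(cfg)) cfg$relevanceThreshold else 0.01

    manifest <- list(parameters = list(topN = topN, ph = ph,
                                       threshold = threshold,
                                       weights = as.list(weights),
                                       parentId = parentId))

    ## 1. first screening -------------------------------------------------
    scr <- firstScreen(bundle$properties)
    counts <- list(built = nrow(bundle$properties),
                   screened_out = unname(scr$counts[["dropped"]]),
                   kept = unname(scr$counts[["kept"]]))
    if (counts$kept == 0L) {
        manifest$counts <- counts
        return(structure(list(status = "empty cohort", proposals = NULL,
                              manifest = manifest),
                         class = "pipelineRun"))
    }

    ## 2. scoring ---------------------------------------------------------
    rs <- referenceStats(bundle$reference)
    scores <- scoreCohort(scr$kept, rs, weights)
    if (!parentId %in% scores$id)
        stop("parent compound '", parentId,
             "' absent from the screened cohort")
    parentScore <- scores$s_sel[scores$id == parentId]
    refAvg <- mean(selectionScore(bundle$reference, rs, weights)$s_sel)

    ## 3. selection -------------------------------------------------------
    cand <- rankAndSelect(scores, topN, parentScore, refAvg)
    counts$passing_thresholds <- attr(cand, "n_passing")
    counts$selected <- nrow(cand)

    ## 4. speciation ------------------------------------------------------
    pk <- bundle$pkas[bundle$pkas$id %in% cand$id, , drop = FALSE]
    spec <- speciateTable(pk, ph = ph, threshold = threshold)
    counts$relevant_species <- sum(spec$relevant)

    ## 5. donation map ----------------------------------------------------
    relKey <- paste(spec$id, spec$species)[spec$relevant == 1L]
    rea <- bundle$reactivity
    rea <- rea[rea$id %in% cand$id &
               paste(rea$id, rea$species) %in% relKey, , drop = FALSE]
    map <- buildEhdamaMap(rea, bundle$panel)
    classed <- classifySpecies(map, bundle$panel)
    counts$classified_species <- nrow(classed)

    ## 6. affinity --------------------------------------------------------
    dock <- bundle$docking[bundle$docking$id %in% cand$id, , drop = FALSE]
    aff <- affinityTable(dock, spec, bundle$baselines,
                         threshold = threshold)
    counts$scored_complexes <- nrow(aff)

    ## 7. proposals -------------------------------------------------------
    domIds <- unique(classed$id[classed$n_dominated >= 1L &
        (classed$set_trolox == "better" & classed$hat_trolox == "better")])
    sPoly <- aff[!duplicated(aff$id), c("id", "s_poly"), drop = FALSE]
    prop <- sPoly[!is.na(sPoly$s_poly) & sPoly$s_poly > 0 &
                  sPoly$id %in% domIds, , drop = FALSE]
    nd <- vapply(prop$id, function(i)
        max(classed$n_dominated[classed$id == i]), integer(1))
    prop$n_dominated <- nd
    prop <- prop[order(-prop$s_poly, prop$id), , drop = FALSE]
    rownames(prop) <- NULL
    counts$proposed <- nrow(prop)
    manifest$counts <- counts

    out <- structure(list(status = "ok", proposals = prop,
                          candidates = cand, scores = scores,
                          speciation = spec, ehdama = classed,
                          affinity = aff, manifest = manifest),
                     class = "pipelineRun")
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        files <- c(scores = "scores.csv", candidates = "candidates.csv",
                   speciation = "speciation.csv", ehdama = "ehdama.csv",
                   affinity = "affinity.csv", proposals = "proposals.csv")
        for (nm in names(files)) {
            path <- file.path(outDir, files[[nm]])
            utils::write.csv(out[[nm]], path, row.names = FALSE)
        }
        paths <- file.path(outDir, files)
        out$manifest$hashes <- stats::setNames(unname(tools::md5sum(paths)),
                                               files)
    }
    out
}

#' @export
print.pipelineRun <- function(x, ...) {
    cat("pipelineRun:", x$status, "\n")
    cn <- x$manifest$counts
    if (!is.null(cn))
        cat(" ", paste(names(cn), unlist(cn), sep = "=", collapse = " | "),
            "\n")
    if (!is.null(x$proposals) && nrow(x$proposals)) {
        cat("  proposals:\n")
        print(x$proposals)
    }
    invisible(x)
}

#' Write / read an input bundle as CSV files
#'
#' `writeBundle()` serializes the five input tables of a `cohortBundle`
#' (`properties.csv`, `reference.csv`, `pkas.csv`, `reactivity.csv`,
#' `docking.csv`) plus `baselines.csv` and `panel.csv`; `readBundle()`
#' reassembles them, so each pipeline stage can be re-run from disk.
#'
#' @param bundle a `cohortBundle`.
#' @param dir directory to write to / read from.
#' @return `writeBundle()`: the directory, invisibly. `readBundle()`: a
#'   `cohortBundle` (without a simulation config).
#' @export
writeBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("properties", "reference", "pkas", "reactivity", "docking"))
        utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    utils::write.csv(data.frame(enzyme = names(bundle$baselines),
                                dg_sub = as.numeric(bundle$baselines)),
                     file.path(dir, "baselines.csv"), row.names = FALSE)
    utils::write.csv(bundle$panel, file.path(dir, "panel.csv"),
                     row.names = FALSE)
    invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
    rd <- function(f) utils::read.csv(file.path(dir, f),
                                      stringsAsFactors = FALSE)
    bl <- rd("baselines.csv")
    structure(list(properties = rd("properties.csv"),
                   reference = rd("reference.csv"),
                   pkas = rd("pkas.csv"),
                   reactivity = rd("reactivity.csv"),
                   docking = rd("docking.csv"),
                   baselines = do.call(substrateBaselines,
                                       as.list(stats::setNames(bl$dg_sub,
                                                               bl$enzyme))),
                   panel = {
                       p <- rd("panel.csv")
                       attr(p, "unit") <- "kcal/mol"
                       p
                   },
                   config = NULL),
              class = "cohortBundle")
}
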