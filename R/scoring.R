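## scoring stage: selection score S^S, elimination score S^E, ranking.

#' Properties entering the elimination score
#'
#' Thirteen scored properties: the eight ADME descriptors (mw, logp, hbd,
#' hba, tpsa, rotb, mr, heavy_atoms), the four toxicity endpoints (ld50,
#' mutagenicity, dev_tox, bf) and synthetic accessibility (sa).
#' @return character vector of column names.
#' @export
scoredProperties <- function()
    c("mw", "logp", "hbd", "hba", "tpsa", "rotb", "mr", "heavy_atoms",
      "ld50", "mutagenicity", "dev_tox", "bf", "sa")

## benefit direction of each toxicity endpoint: +1 higher is safer
.toxDirection <- c(ld50 = 1, mutagenicity = -1, dev_tox = -1, bf = -1)

#' Reference-set statistics
#'
#' Per-property mean and standard deviation over the reference compound set
#' (neuroprotectors in the default application). Properties whose reference
#' standard deviation is zero cannot be standardized and are excluded with
#' a warning.
#'
#' @param ref reference property data.frame (same schema as the compound
#'   property table; no missing values in scored columns).
#' @param properties columns to summarize; default [scoredProperties()].
#' @return data.frame with columns `property`, `mean`, `sd`; attribute
#'   `n_refs`.
#' @export
referenceStats <- function(ref, properties = scoredProperties()) {
    miss <- setdiff(properties, names(ref))
    if (length(miss))
        stop("reference table lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(ref) < 2L) stop("need at least 2 reference compounds")
    if (any(vapply(properties, function(p) anyNA(ref[[p]]), logical(1))))
        stop("reference table contains missing values in scored columns")
    mu <- vapply(properties, function(p) mean(ref[[p]]), numeric(1))
    sd_ <- vapply(properties, function(p) stats::sd(ref[[p]]), numeric(1))
    degen <- sd_ == 0
    if (any(degen)) {
        warning("excluding degenerate (zero-variance) reference propert",
                if (sum(degen) > 1) "ies: " else "y: ",
                paste(properties[degen], collapse = ", "))
        mu <- mu[!degen]; sd_ <- sd_[!degen]
        properties <- properties[!degen]
    }
    out <- data.frame(property = properties, mean = unname(mu),
                      sd = unname(sd_), stringsAsFactors = FALSE)
    attr(out, "n_refs") <- nrow(ref)
    out
}

.refLookup <- function(refStats, property) {
    i <- match(property, refStats$property)
    if (anyNA(i))
        stop("reference statistics lack propert",
             if (sum(is.na(i)) > 1) "ies: " else "y: ",
             paste(property[is.na(i)], collapse = ", "))
    list(mean = refStats$mean[i], sd = refStats$sd[i])
}

.checkComplete <- function(props, cols) {
    for (cl in cols) {
        if (is.null(props[[cl]]))
            stop("property table lacks column '", cl, "'")
        if (anyNA(props[[cl]]))
            stop("missing values in '", cl, "' for id ",
                 paste(utils::head(props$id[is.na(props[[cl]])], 3),
                       collapse = ", "),
                 " - run firstScreen() upstream")
    }
    invisible(TRUE)
}

#' Selection score
#'
#' Composite desirability on a 0-4 scale, the mean of three blocks:
#' \itemize{
#'   \item ADME block: number of satisfied drug-likeness rule sets (0-5,
#'     from [applyRules()]) rescaled to 0-4;
#'   \item toxicity block: per endpoint, `4 * pnorm(z)` where `z` is the
#'     standardized deviation from the reference mean signed so that
#'     safer-than-reference is positive (higher LD50, lower mutagenicity,
#'     developmental toxicity and bioaccumulation); averaged over the four
#'     endpoints;
#'   \item synthetic-accessibility block: the 0-100 SA value rescaled to
#'     0-4.
#' }
#' Higher is better. Missing inputs are an error: the first screening must
#' run upstream.
#'
#' @param props property data.frame (descriptors + sa + toxicity, complete).
#' @param refStats output of [referenceStats()].
#' @param weights positive block weights, named `adme`, `tox`, `sa`;
#'   default equal. The score is the weighted mean of the three blocks.
#' @param rules optional precomputed [applyRules()] output for `props`.
#' @return data.frame `id`, `s_sel`, `block_adme`, `block_tox`, `block_sa`.
#' @export
selectionScore <- function(props, refStats,
                           weights = c(adme = 1, tox = 1, sa = 1),
                           rules = NULL) {
    .checkComplete(props, c(descriptorColumns(), "sa", toxicityColumns()))
    if (!all(c("adme", "tox", "sa") %in% names(weights)) ||
        any(weights[c("adme", "tox", "sa")] <= 0))
        stop("'weights' must be positive and named adme, tox, sa")
    if (any(props$sa < 0 | props$sa > 100))
        stop("'sa' outside [0, 100]")
    if (is.null(rules)) rules <- applyRules(props)
    blockAdme <- rules$rules_passed * 4 / 5

    tox <- toxicityColumns()
    st <- .refLookup(refStats, tox)
    zb <- mapply(function(k, cl) .toxDirection[[cl]] *
                     (props[[cl]] - st$mean[k]) / st$sd[k],
                 seq_along(tox), tox)
    zb <- matrix(zb, nrow = nrow(props))
    blockTox <- rowMeans(4 * stats::pnorm(zb))

    blockSa <- props$sa * 4 / 100
    w <- weights[c("adme", "tox", "sa")]
    sSel <- (blockAdme * w[["adme"]] + blockTox * w[["tox"]] +
             blockSa * w[["sa"]]) / sum(w)
    data.frame(id = props$id, s_sel = sSel, block_adme = blockAdme,
               block_tox = blockTox, block_sa = blockSa,
               stringsAsFactors = FALSE)
}

#' Elimination score
#'
#' Direction-agnostic deviation from the reference set: per scored property
#' the elimination coefficient is `|x - mean_ref| / sd_ref`, and the
#' elimination score is their sum (so a compound at the reference centroid
#' scores 0 and the most atypical compounds score highest). Nested
#' component sums mirror growing property panels: `S_ADME2` (mw, logp),
#' `S_ADME8` (+ hbd, hba, tpsa, rotb, mr, heavy_atoms), `S_ADMET`
#' (+ the four toxicity endpoints), `S_ADMETSA` (+ sa, the full sum).
#'
#' @inheritParams selectionScore
#' @return data.frame `id`, `s_elim`, `S_ADME2`, `S_ADME8`, `S_ADMET`,
#'   `S_ADMETSA`, and one `e_<property>` coefficient column per property.
#' @export
eliminationScore <- function(props, refStats) {
    properties <- scoredProperties()
    .checkComplete(props, properties)
    st <- .refLookup(refStats, properties)
    if (any(st$sd <= 0))
        stop("non-positive reference sd for: ",
             paste(properties[st$sd <= 0], collapse = ", "))
    e <- vapply(seq_along(properties), function(k)
        abs(props[[properties[k]]] - st$mean[k]) / st$sd[k],
        numeric(nrow(props)))
    e <- matrix(e, nrow = nrow(props),
                dimnames = list(NULL, properties))
    adme2 <- c("mw", "logp")
    adme8 <- c(adme2, "hbd", "hba", "tpsa", "rotb", "mr", "heavy_atoms")
    out <- data.frame(id = props$id,
                      s_elim = rowSums(e),
                      S_ADME2 = rowSums(e[, adme2, drop = FALSE]),
                      S_ADME8 = rowSums(e[, adme8, drop = FALSE]),
                      stringsAsFactors = FALSE)
    out$S_ADMET <- out$S_ADME8 + rowSums(e[, toxicityColumns(), drop = FALSE])
    out$S_ADMETSA <- out$S_ADMET + e[, "sa"]
    for (p in properties) out[[paste0("e_", p)]] <- e[, p]
    out
}

#' Score a cohort against a reference set
#'
#' Convenience wrapper joining [selectionScore()] and [eliminationScore()]
#' into one record per compound.
#'
#' @inheritParams selectionScore
#' @return data.frame with the columns of both score tables.
#' @export
scoreCohort <- function(props, refStats,
                        weights = c(adme = 1, tox = 1, sa = 1)) {
    sel <- selectionScore(props, refStats, weights)
    eli <- eliminationScore(props, refStats)
    stopifnot(identical(sel$id, eli$id))
    cbind(sel, eli[setdiff(names(eli), "id")])
}

#' Select candidates by score thresholds and elimination rank
#'
#' Keeps compounds whose selection score beats both the parent molecule's
#' score and the reference-set average, orders the survivors by ascending
#' elimination score (most reference-like first; ties broken by descending
#' selection score, then id), and returns the first `topN`.
#'
#' @param scores data.frame with `id`, `s_sel`, `s_elim` (e.g. from
#'   [scoreCohort()]).
#' @param topN maximum number of candidates to return (default 25).
#' @param parentScore the parent molecule's selection score.
#' @param refAvgScore the reference-set average selection score.
#' @return the selected rows, ordered; attributes `thresholds` and
#'   `n_passing` (survivor count before truncation).
#' @export
rankAndSelect <- function(scores, topN = 25L, parentScore, refAvgScore) {
    topN <- as.integer(topN)
    if (is.na(topN) || topN <= 0L) stop("'topN' must be a positive integer")
    if (nrow(scores) == 0L) stop("empty score table")
    stopifnot(all(c("id", "s_sel", "s_elim") %in% names(scores)))
    pass <- scores$s_sel > parentScore & scores$s_sel > refAvgScore
    surv <- scores[pass, , drop = FALSE]
    ord <- order(surv$s_elim, -surv$s_sel, surv$id)
    surv <- surv[ord, , drop = FALSE]
    out <- utils::head(surv, topN)
    rownames(out) <- NULL
    attr(out, "thresholds") <- c(parent = parentScore, ref_avg = refAvgScore)
    attr(out, "n_passing") <- nrow(surv)
    out
}
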