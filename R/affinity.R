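## affinity stage: fraction-weighted docking scores, per-enzyme log-ratio
## affinities versus natural substrates, polygenic score.

.enzymes <- c("COMT", "MAOB", "AChE")

#' Natural-substrate docking baselines
#'
#' Binding scores of the three enzymes' natural substrates: dopamine
#' (COMT), phenylethylamine (MAOB) and acetylcholine (AChE). The default
#' values are synthetic placeholders at plausible docking-score magnitudes
#' (kcal/mol, negative = favorable); supply measured baselines for real
#' use.
#'
#' @param COMT,MAOB,AChE substrate binding scores, strictly negative.
#' @return named numeric vector with attribute `substrates`.
#' @export
substrateBaselines <- function(COMT = -6.6, MAOB = -5.9, AChE = -5.3) {
    out <- c(COMT = COMT, MAOB = MAOB, AChE = AChE)
    if (any(!is.finite(out)) || any(out >= 0))
        stop("substrate baselines must be finite and strictly negative")
    attr(out, "substrates") <- c(COMT = "dopamine", MAOB = "phenylethylamine",
                                 AChE = "acetylcholine")
    out
}

#' Fraction-weighted binding score
#'
#' Linear average of per-species docking scores weighted by the molar
#' fractions of the species at the working pH, the fractions being
#' renormalized over the scored (relevant) species.
#'
#' @param speciesScores named numeric, species -> binding score (kcal/mol).
#' @param fractions named numeric, species -> molar fraction; every scored
#'   species must have a fraction, and the fractions must not sum to zero.
#' @return the weighted score (lies between the species extremes).
#' @examples
#' weightedScore(c(A = -6, `H-1A-` = -8), c(A = 0.5, `H-1A-` = 0.5))
#' @export
weightedScore <- function(speciesScores, fractions) {
    if (length(speciesScores) == 0L) stop("empty species set")
    if (is.null(names(speciesScores)) || is.null(names(fractions)))
        stop("'speciesScores' and 'fractions' must be named by species")
    miss <- setdiff(names(speciesScores), names(fractions))
    if (length(miss))
        stop("no fraction for species: ", paste(miss, collapse = ", "))
    f <- fractions[names(speciesScores)]
    if (anyNA(f) || anyNA(speciesScores)) stop("NA score or fraction")
    tot <- sum(f)
    if (tot <= 0) stop("fractions sum to zero over the scored species")
    sum(speciesScores * f / tot)
}

#' Per-enzyme log-ratio affinity term
#'
#' `log(dgw / baseline)` (base 10 by default) of the compound's weighted
#' binding score over the natural substrate's score, both strictly
#' negative. Zero means substrate-equivalent affinity; positive means the
#' compound binds more strongly than the natural substrate.
#'
#' @param dgw weighted binding score, strictly negative.
#' @param baseline substrate binding score, strictly negative.
#' @param base logarithm base (default 10).
#' @return the log-ratio term (vectorized over `dgw`).
#' @examples
#' enzymeTerm(-10, -5)   # log10(2)
#' enzymeTerm(-5, -5)    # 0
#' @export
enzymeTerm <- function(dgw, baseline, base = 10) {
    if (any(!is.finite(dgw)) || any(!is.finite(baseline)))
        stop("binding scores must be finite")
    if (any(dgw >= 0) || any(baseline >= 0))
        stop("binding scores must be strictly negative")
    log(dgw / baseline, base = base)
}

#' Polygenic neuroprotection score
#'
#' Sum of the three per-enzyme log-ratio terms. A compound matching every
#' natural substrate scores 0; a positive score means broadly stronger
#' binding than the substrates.
#'
#' @param terms named numeric with entries `COMT`, `MAOB`, `AChE`.
#' @return the polygenic score.
#' @examples
#' polygenicScore(c(COMT = 0.3, MAOB = 0.1, AChE = -0.1))
#' @export
polygenicScore <- function(terms) {
    miss <- setdiff(.enzymes, names(terms))
    if (length(miss))
        stop("missing enzyme term(s): ", paste(miss, collapse = ", "))
    if (anyNA(terms[.enzymes])) stop("NA enzyme term")
    sum(terms[.enzymes])
}

#' Aggregate a docking table into affinity records
#'
#' Joins per-species docking scores with speciation fractions, keeps the
#' relevant species (fraction at or above `threshold`), renormalizes the
#' fractions, and computes per compound and enzyme the weighted binding
#' score and the log-ratio term versus the substrate baseline, plus the
#' per-compound polygenic score over the three enzymes.
#'
#' @param docking long data.frame `id`, `species`, `enzyme`, `dg`
#'   (kcal/mol, strictly negative).
#' @param speciation long data.frame `id`, `species`, `fraction` (e.g. from
#'   [speciateTable()]).
#' @param baselines a [substrateBaselines()] vector.
#' @param threshold relevance cutoff on fractions (default 0.01,
#'   inclusive).
#' @param base logarithm base for the affinity terms.
#' @return data.frame `id`, `enzyme`, `dgw`, `baseline`, `term`, `s_poly`
#'   (repeated over the compound's enzyme rows; `NA` if an enzyme is
#'   missing for that compound).
#' @export
affinityTable <- function(docking, speciation,
                          baselines = substrateBaselines(),
                          threshold = 0.01, base = 10) {
    stopifnot(all(c("id", "species", "enzyme", "dg") %in% names(docking)),
              all(c("id", "species", "fraction") %in% names(speciation)))
    if (!all(.enzymes %in% names(baselines)))
        stop("baselines must cover ", paste(.enzymes, collapse = ", "))
    if (nrow(docking) == 0L)
        return(data.frame(id = character(0), enzyme = character(0),
                          dgw = numeric(0), baseline = numeric(0),
                          term = numeric(0), s_poly = numeric(0)))
    rel <- speciation[speciation$fraction >= threshold, , drop = FALSE]
    fkey <- paste(rel$id, rel$species, sep = "\r")
    rows <- list()
    for (cid in unique(docking$id)) {
        dsub <- docking[docking$id == cid, , drop = FALSE]
        terms <- stats::setNames(rep(NA_real_, length(.enzymes)), .enzymes)
        dgws <- terms
        for (enz in .enzymes) {
            de <- dsub[dsub$enzyme == enz, , drop = FALSE]
            if (nrow(de) == 0L) next
            fr <- rel$fraction[match(paste(cid, de$species, sep = "\r"),
                                     fkey)]
            keep <- !is.na(fr)
            if (!any(keep)) next
            dgw <- weightedScore(stats::setNames(de$dg[keep],
                                                 de$species[keep]),
                                 stats::setNames(fr[keep], de$species[keep]))
            dgws[enz] <- dgw
            terms[enz] <- enzymeTerm(dgw, baselines[[enz]], base = base)
        }
        sPoly <- if (anyNA(terms)) NA_real_ else polygenicScore(terms)
        rows[[cid]] <- data.frame(id = cid, enzyme = .enzymes,
                                  dgw = unname(dgws),
                                  baseline = unname(baselines[.enzymes]),
                                  term = unname(terms), s_poly = sPoly,
                                  stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Polygenic-score plot table
#'
#' Per-compound, per-enzyme signed segments for a stacked-bar rendering of
#' the polygenic score: positive segments stack upward (stronger binding
#' than the substrate), negative segments downward. Segment sums equal the
#' polygenic score.
#'
#' @param affinity output of [affinityTable()].
#' @return data.frame `id`, `enzyme`, `segment`, `s_poly`.
#' @export
pspTable <- function(affinity) {
    if (nrow(affinity) == 0L)
        return(data.frame(id = character(0), enzyme = character(0),
                          segment = numeric(0), s_poly = numeric(0)))
    data.frame(id = affinity$id, enzyme = affinity$enzyme,
               segment = affinity$term, s_poly = affinity$s_poly,
               stringsAsFactors = FALSE)
}

#' Plot the polygenic-score bars
#'
#' @param psp output of [pspTable()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the segment matrix.
#' @export
plotPsp <- function(psp, ...) {
    ids <- unique(psp$id)
    m <- sapply(ids, function(i)
        stats::setNames(psp$segment[psp$id == i][match(.enzymes,
            psp$enzyme[psp$id == i])], .enzymes))
    m <- matrix(m, nrow = length(.enzymes),
                dimnames = list(.enzymes, ids))
    pos <- pmax(m, 0); neg <- pmin(m, 0)
    ylim <- c(min(colSums(neg, na.rm = TRUE), 0),
              max(colSums(pos, na.rm = TRUE), 0))
    cols <- c(COMT = "steelblue", MAOB = "seagreen", AChE = "firebrick")
    graphics::barplot(pos, col = cols, ylim = ylim, las = 2,
                      ylab = "log-ratio affinity", ...)
    graphics::barplot(neg, col = cols, add = TRUE, las = 2, ...)
    graphics::legend("topright", legend = .enzymes, fill = cols, bty = "n")
    invisible(m)
}

#' Parse an engine-agnostic docking log table
#'
#' Reads whitespace-separated lines `id species enzyme score` (comment
#' lines starting with `#` ignored) into the docking data.frame consumed
#' by [affinityTable()].
#'
#' @param file path to the text log.
#' @return data.frame `id`, `species`, `enzyme`, `dg`.
#' @export
readDockingLog <- function(file) {
    d <- utils::read.table(file, header = FALSE, comment.char = "#",
                           col.names = c("id", "species", "enzyme", "dg"),
                           stringsAsFactors = FALSE)
    d$dg <- as.numeric(d$dg)
    d
}
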