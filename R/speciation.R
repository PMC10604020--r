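## speciation stage: multiprotic microspecies fractions at a given pH.

#' Microspecies molar fractions at a given pH
#'
#' Closed-form fractions for a single (macroscopic) deprotonation ladder:
#' with n strictly ascending pKa values there are n + 1 species, and the
#' species with j protons removed has relative weight
#' `10^(j * pH - sum(pKa[1:j]))`; fractions are the normalized weights.
#' The computation runs in log10 space with max-subtraction, so extreme pH
#' or pKa values cannot overflow.
#'
#' Species labels carry a formal charge. pKa values alone do not fix the
#' charge origin, so by default every deprotonation step with pKa below 7
#' is taken to remove a proton from a cationic site (ring-N-H+ in
#' quinolines) and steps at or above 7 from a neutral site (phenol, thiol);
#' override with `maxCharge`, the charge of the fully protonated species.
#' The charge assignment only affects labels, never fractions.
#'
#' @param pkas numeric vector (possibly empty, at most 4 values), strictly
#'   ascending.
#' @param ph the pH (default 7.4, physiological).
#' @param id optional compound identifier.
#' @param maxCharge charge of the fully protonated species; default
#'   `sum(pkas < 7)`.
#' @return an [AcidBaseProfile-class].
#' @examples
#' speciesFractions(c(4.7), ph = 7.4)          # quinolinium / quinoline
#' speciesFractions(c(4, 10), ph = 7)          # diprotic ladder
#' @export
speciesFractions <- function(pkas = numeric(0), ph = 7.4,
                             id = NA_character_, maxCharge = NULL) {
    pkas <- as.numeric(pkas)
    if (length(pkas) > 4L)
        stop("at most 4 pKa values are supported")
    if (anyNA(pkas) || any(!is.finite(pkas)))
        stop("pKa values must be finite")
    if (length(pkas) > 1L && any(diff(pkas) <= 0))
        stop("pKa values must be strictly ascending")
    if (length(ph) != 1L || !is.finite(ph)) stop("'ph' must be finite")
    lf <- .ladderFractions(pkas, ph, maxCharge)
    methods::new("AcidBaseProfile", id = as.character(id), pkas = pkas,
                 ph = as.numeric(ph), fractions = lf$fractions,
                 charges = lf$charges, species = lf$species)
}

## closed-form ladder fractions in log10 space (no S4 overhead)
.ladderFractions <- function(pkas, ph, maxCharge = NULL) {
    n <- length(pkas)
    j <- 0:n
    logw <- j * ph - cumsum(c(0, pkas))
    w <- 10^(logw - max(logw))
    f <- w / sum(w)
    if (is.null(maxCharge)) maxCharge <- sum(pkas < 7)
    charges <- as.integer(maxCharge - j)
    list(fractions = f, charges = charges, species = speciesLabel(charges))
}

## display labels by charge: H2A2+, HA+, A, H-1A-, H-2A2- ...
speciesLabel <- function(charges) {
    vapply(charges, function(ch) {
        if (ch > 0) paste0(if (ch > 1) paste0("H", ch) else "H", "A",
                           if (ch > 1) ch else "", "+")
        else if (ch == 0) "A"
        else paste0("H", ch, "A", if (ch < -1) -ch else "", "-")
    }, "")
}

#' Species with non-negligible fractions
#'
#' Filters an [AcidBaseProfile-class] to the species whose molar fraction
#' is at or above the threshold (inclusive boundary: a species at exactly
#' 1\% counts as present), preserving protonation order.
#'
#' @param profile an [AcidBaseProfile-class].
#' @param threshold fraction cutoff in (0, 1); default 0.01.
#' @return data.frame `species`, `charge`, `fraction` of retained species.
#' @export
relevantSpecies <- function(profile, threshold = 0.01) {
    stopifnot(methods::is(profile, "AcidBaseProfile"))
    if (length(threshold) != 1L || !is.finite(threshold) ||
        threshold <= 0 || threshold >= 1)
        stop("'threshold' must lie strictly between 0 and 1")
    keep <- profile@fractions >= threshold
    data.frame(species = profile@species[keep],
               charge = profile@charges[keep],
               fraction = profile@fractions[keep],
               stringsAsFactors = FALSE)
}

#' Speciate a table of compounds
#'
#' @param pkaTable data.frame with `id` and pKa columns `pka1`, `pka2`, ...
#'   (`NA` = absent; values must be ascending within a row). Compounds with
#'   no pKa value yield a single neutral species with fraction 1.
#' @param ph pH (default 7.4).
#' @param threshold relevance cutoff passed to [relevantSpecies()].
#' @return long data.frame `id`, `species`, `charge`, `fraction`,
#'   `relevant` (0/1), one row per species.
#' @export
speciateTable <- function(pkaTable, ph = 7.4, threshold = 0.01) {
    stopifnot("id" %in% names(pkaTable))
    pkaCols <- grep("^pka[0-9]+$", names(pkaTable), value = TRUE)
    pk <- as.matrix(pkaTable[pkaCols])
    res <- lapply(seq_len(nrow(pkaTable)), function(i) {
        v <- pk[i, ]
        v <- sort(v[!is.na(v)])
        if (length(v) > 1L && any(diff(v) <= 0))
            stop("non-ascending pKa values for id ", pkaTable$id[i])
        .ladderFractions(v, ph)
    })
    nsp <- vapply(res, function(r) length(r$fractions), integer(1))
    fr <- unlist(lapply(res, `[[`, "fractions"), use.names = FALSE)
    out <- data.frame(id = rep(pkaTable$id, nsp),
                      species = unlist(lapply(res, `[[`, "species"),
                                       use.names = FALSE),
                      charge = unlist(lapply(res, `[[`, "charges"),
                                      use.names = FALSE),
                      fraction = fr,
                      relevant = as.integer(fr >= threshold),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
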