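#' Construct a Scaffold
#'
#' @param core SMILES template with one `{label}` placeholder per
#'   substitutable position.
#' @param sites character vector of site labels, in the order used for
#'   deterministic enumeration.
#' @param validate if `TRUE` (default), check that the parent structure
#'   (all placeholders removed) parses as a molecule.
#' @return a [Scaffold-class] object.
#' @examples
#' sc <- Scaffold("c1cc({R1})cc({R2})c1", c("R1", "R2"))
#' @export
Scaffold <- function(core, sites, validate = TRUE) {
    obj <- methods::new("Scaffold", core = as.character(core),
                        sites = as.character(sites))
    if (validate) {
        parent <- substituteSites(obj, stats::setNames(character(0), character(0)))
        tryCatch(canonicalizeSmiles(parent),
                 error = function(e) stop("scaffold core does not parse ",
                                          "with all sites on hydrogen: ",
                                          conditionMessage(e), call. = FALSE))
    }
    obj
}

#' Construct a SubstituentLibrary
#'
#' @param fragments named character vector mapping group names to monovalent
#'   fragment SMILES (attachment through the first atom).
#' @param validate if `TRUE`, check that each fragment parses when attached
#'   to a methyl probe.
#' @return a [SubstituentLibrary-class] object.
#' @examples
#' SubstituentLibrary(c(OH = "O", NH2 = "N"))
#' @export
SubstituentLibrary <- function(fragments, validate = TRUE) {
    obj <- methods::new("SubstituentLibrary",
                        fragments = vapply(fragments, as.character, ""))
    if (validate) {
        for (i in seq_along(obj@fragments)) {
            probe <- paste0("C", obj@fragments[i])
            tryCatch(canonicalizeSmiles(probe),
                     error = function(e) stop("fragment '",
                                              names(obj@fragments)[i],
                                              "' does not parse: ",
                                              conditionMessage(e),
                                              call. = FALSE))
        }
    }
    obj
}

#' The quinoline scaffold with seven substitution sites
#'
#' Quinoline (benzo-fused pyridine, C9H7N) with its seven CH positions
#' (ring positions 2-8) labeled R1-R7. R1-R3 sit on the pyridine ring
#' (positions 2-4), R4-R7 on the benzo ring (positions 5-8). All seven
#' positions are symmetry-distinct, so distinct substitution patterns give
#' distinct molecules.
#'
#' @return a [Scaffold-class].
#' @examples
#' quinolineScaffold()
#' @export
quinolineScaffold <- function() {
    Scaffold("c1{R1}c{R2}c{R3}c2c{R4}c{R5}c{R6}c{R7}c2n1",
             paste0("R", 1:7), validate = FALSE)
}

#' The six-group functional library
#'
#' Hydroxyl, amino, thiol, formyl (carbaldehyde), acetyl and methyl-ester
#' groups, the fragment set used to decorate the quinoline core.
#'
#' @return a [SubstituentLibrary-class].
#' @examples
#' defaultSubstituentLibrary()
#' @export
defaultSubstituentLibrary <- function() {
    SubstituentLibrary(c(OH     = "O",
                         NH2    = "N",
                         SH     = "S",
                         COH    = "C=O",
                         COCH3  = "C(C)=O",
                         COOCH3 = "C(=O)OC"),
                       validate = FALSE)
}

## Replace placeholders: named character pattern site -> fragment SMILES.
## Sites absent from `pattern` collapse to hydrogen.
substituteSites <- function(scaffold, pattern) {
    smi <- scaffold@core
    for (s in scaffold@sites) {
        token <- sprintf("{%s}", s)
        repl <- if (s %in% names(pattern)) paste0("(", pattern[[s]], ")") else ""
        smi <- sub(token, repl, smi, fixed = TRUE)
    }
    smi
}

#' Canonicalize SMILES strings
#'
#' Maps each input SMILES to OpenBabel's canonical SMILES, so that two
#' spellings of the same molecule compare equal. Idempotent.
#'
#' @param smiles character vector of SMILES.
#' @param names optional identifiers used in error messages; defaults to the
#'   input position.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalizeSmiles(c("c1ccc2ncccc2c1", "C"))
#' @export
canonicalizeSmiles <- function(smiles, names = NULL) {
    if (length(smiles) == 0L) return(character(0))
    if (any(is.na(smiles) | !nzchar(smiles)))
        stop("empty or NA SMILES at position ",
             paste(which(is.na(smiles) | !nzchar(smiles)), collapse = ", "))
    if (is.null(names)) names <- as.character(seq_along(smiles))
    out <- character(length(smiles))
    ## chunked batch conversion; OpenBabel tags each output with our index
    chunk <- 2000L
    starts <- seq(1L, length(smiles), by = chunk)
    for (s0 in starts) {
        idx <- s0:min(s0 + chunk - 1L, length(smiles))
        txt <- paste(paste(smiles[idx], idx), collapse = "\n")
        res <- suppressWarnings(
            ChemmineOB::convertFormat("SMI", "CAN", paste0(txt, "\n")))
        lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
        lines <- lines[nzchar(lines)]
        parts <- strsplit(lines, "[\t ]+")
        got <- vapply(parts, function(p) p[length(p)], "")
        can <- vapply(parts, function(p)
            paste(p[-length(p)], collapse = " "), "")
        hit <- match(as.character(idx), got)
        if (anyNA(hit) || any(!nzchar(can[hit[!is.na(hit)]]))) {
            bad <- idx[is.na(hit)]
            if (!length(bad)) bad <- idx[!nzchar(can[hit])]
            stop("SMILES parse failure for entry '", names[bad[1]],
                 "': ", smiles[bad[1]])
        }
        out[idx] <- can[hit]
    }
    out
}

#' Enumerate substituted derivatives of a scaffold
#'
#' Generates every derivative carrying k = 1..`maxK` substituents: each
#' k-subset of sites combined with every assignment of library groups to
#' those sites, i.e. choose(s, k) * g^k records per order k. The parent
#' (k = 0) is emitted first when `includeParent = TRUE`. Enumeration order
#' is deterministic: subsets in lexicographic site order, assignments in
#' odometer order with the first site's group varying slowest, groups in
#' library order. Identifiers are `"dQ"` followed by the 1-based position
#' in this order (the parent is always dQ1, whether or not it is emitted).
#'
#' @param scaffold a [Scaffold-class].
#' @param library a [SubstituentLibrary-class].
#' @param maxK maximum substitution order, `1 <= maxK <=` number of sites.
#' @param includeParent emit the unsubstituted parent as the first record.
#' @param canonical canonicalize the generated SMILES (recommended; needed
#'   for deduplication guarantees).
#' @return data.frame with columns `id`, `pattern` (e.g. `"R1=OH;R4=SH"`,
#'   empty for the parent), `order_k`, `smiles`.
#' @examples
#' sc <- Scaffold("c1cc({R1})ccc1{R2}", c("R1", "R2"))
#' lib <- SubstituentLibrary(c(OH = "O", SH = "S"))
#' enumerateDerivatives(sc, lib, maxK = 2)
#' @export
enumerateDerivatives <- function(scaffold, library, maxK = 3L,
                                 includeParent = TRUE, canonical = TRUE) {
    methods::validObject(scaffold)
    methods::validObject(library)
    s <- length(scaffold@sites)
    g <- length(library@fragments)
    maxK <- as.integer(maxK)
    if (maxK < 1L) stop("'maxK' must be at least 1")
    if (maxK > s) stop("'maxK' (", maxK, ") exceeds the number of sites (",
                       s, ")")
    groups <- names(library@fragments)

    pats <- list()
    ks <- integer(0)
    for (k in seq_len(maxK)) {
        subsets <- utils::combn(s, k)
        ## odometer over group assignments, first site most significant
        assign <- as.matrix(rev(expand.grid(rev(replicate(k, seq_len(g),
                                                          simplify = FALSE)))))
        for (j in seq_len(ncol(subsets))) {
            sites_j <- scaffold@sites[subsets[, j]]
            for (r in seq_len(nrow(assign))) {
                pats[[length(pats) + 1L]] <-
                    stats::setNames(groups[assign[r, ]], sites_j)
            }
            ks <- c(ks, rep.int(k, nrow(assign)))
        }
    }

    patternString <- vapply(pats, function(p)
        paste(paste0(names(p), "=", p), collapse = ";"), "")
    smiles <- vapply(pats, function(p)
        substituteSites(scaffold,
                        stats::setNames(library@fragments[p], names(p))), "")
    ids <- paste0("dQ", seq_along(pats) + 1L)

    if (includeParent) {
        patternString <- c("", patternString)
        smiles <- c(substituteSites(scaffold, character(0)), smiles)
        ids <- c("dQ1", ids)
        ks <- c(0L, ks)
    }
    if (canonical) smiles <- canonicalizeSmiles(smiles, names = ids)
    data.frame(id = ids, pattern = patternString, order_k = ks,
               smiles = smiles, stringsAsFactors = FALSE)
}

#' Write derivatives as a SMILES file
#'
#' One `smiles<TAB>id` line per record, the interchange format read by
#' standard chemistry toolkits.
#'
#' @param derivatives data.frame from [enumerateDerivatives()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
exportSmiles <- function(derivatives, file) {
    stopifnot(all(c("id", "smiles") %in% names(derivatives)))
    writeLines(paste(derivatives$smiles, derivatives$id, sep = "\t"), file)
    invisible(file)
}
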