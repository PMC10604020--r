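## eH-DAMA stage: electron / hydrogen-atom donation map and classification.

#' Reference panel for the donation map
#'
#' The three reference antioxidants (Trolox, alpha-tocopherol, ascorbate)
#' and the oxidant target (H2O2 / hydroperoxyl radical), each with an
#' ionization potential (SET axis) and an X-H bond dissociation energy
#' (HAT axis) in a shared energy unit.
#'
#' The default panel values are synthetic placeholders, placed at
#' literature-plausible aqueous-phase magnitudes (phenolic O-H BDEs near
#' 74-88 kcal/mol, IPs near 96-108 kcal/mol) purely so the comparison
#' machinery is exercised realistically; they are not computed reference
#' energies and any real application should supply its own panel.
#'
#' @param trolox,tocopherol,ascorbate,oohTarget numeric vectors
#'   `c(ip = ..., bde = ...)`.
#' @param unit energy unit tag, `"kcal/mol"` (default) or `"kJ/mol"`;
#'   informational, all comparisons assume panel and records share it.
#' @return data.frame `name`, `role` (`"antioxidant"`/`"oxidant"`), `ip`,
#'   `bde`, with attribute `unit`.
#' @export
referencePanel <- function(trolox = c(ip = 108.0, bde = 78.4),
                           tocopherol = c(ip = 105.0, bde = 77.2),
                           ascorbate = c(ip = 96.0, bde = 74.3),
                           oohTarget = c(ip = 150.0, bde = 87.8),
                           unit = c("kcal/mol", "kJ/mol")) {
    unit <- match.arg(unit)
    entries <- list(Trolox = trolox, `alpha-tocopherol` = tocopherol,
                    ascorbate = ascorbate, OOH = oohTarget)
    for (nm in names(entries))
        if (!all(c("ip", "bde") %in% names(entries[[nm]])) ||
            any(!is.finite(entries[[nm]][c("ip", "bde")])))
            stop("panel entry '", nm, "' needs finite ip and bde")
    out <- data.frame(name = names(entries),
                      role = c("antioxidant", "antioxidant", "antioxidant",
                               "oxidant"),
                      ip = vapply(entries, `[[`, numeric(1), "ip"),
                      bde = vapply(entries, `[[`, numeric(1), "bde"),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "unit") <- unit
    out
}

.checkPanel <- function(refs) {
    need <- c("Trolox", "alpha-tocopherol", "ascorbate", "OOH")
    if (!is.data.frame(refs) ||
        !all(c("name", "ip", "bde") %in% names(refs)) ||
        !all(need %in% refs$name))
        stop("reference panel must contain entries: ",
             paste(need, collapse = ", "), " (see referencePanel())")
    invisible(refs)
}

#' Build the electron / hydrogen-atom donation map
#'
#' One row per acid-base species with its ionization potential (electron
#' donation, SET axis) and minimum bond dissociation energy over the
#' declared H-donor sites (hydrogen-atom donation, HAT axis), together
#' with the reference-panel coordinates, ready for plotting or export.
#' Restrict `reactivity` to relevant species (see [relevantSpecies()])
#' upstream.
#'
#' @param reactivity long data.frame `id`, `species`, `ip`, `site`, `bde`:
#'   one row per H-donor site; species with no donor site may carry
#'   `NA` site/bde.
#' @param refs a [referencePanel()].
#' @return data.frame `id`, `species`, `kind` (`"candidate"` or the panel
#'   role), `ip`, `bde_min`, `n_sites`.
#' @export
buildEhdamaMap <- function(reactivity, refs = referencePanel()) {
    .checkPanel(refs)
    stopifnot(all(c("id", "species", "ip") %in% names(reactivity)))
    refRows <- data.frame(id = refs$name, species = refs$name,
                          kind = refs$role, ip = refs$ip, bde_min = refs$bde,
                          n_sites = NA_integer_, stringsAsFactors = FALSE)
    if (nrow(reactivity) == 0L) return(refRows)
    if (anyNA(reactivity$ip)) stop("missing ip in reactivity records")
    if (!"bde" %in% names(reactivity)) reactivity$bde <- NA_real_
    key <- paste(reactivity$id, reactivity$species, sep = "\r")
    sp <- split(reactivity, factor(key, levels = unique(key)))
    rows <- lapply(sp, function(d) {
        bde <- d$bde[!is.na(d$bde)]
        data.frame(id = d$id[1], species = d$species[1], kind = "candidate",
                   ip = d$ip[1],
                   bde_min = if (length(bde)) min(bde) else NA_real_,
                   n_sites = length(bde), stringsAsFactors = FALSE)
    })
    out <- rbind(do.call(rbind, rows), refRows)
    rownames(out) <- NULL
    out
}

.cmpClass <- function(x, refVal, tol) {
    ifelse(is.na(x), NA_character_,
           ifelse(abs(x - refVal) <= tol, "similar",
                  ifelse(x < refVal, "better", "worse")))
}

#' Classify species against the reference antioxidants
#'
#' For each candidate species and each reference antioxidant: a lower
#' ionization potential means a better single-electron-transfer (SET)
#' donor, a lower minimum BDE a better hydrogen-atom-transfer (HAT) donor;
#' values equal within `tol` are "similar". Against the oxidant target the
#' two comparisons are reported separately: H donation to the hydroperoxyl
#' radical is taken as favored when the species' minimum BDE is below the
#' H-OOH entry, and electron donation when its IP is below the panel's
#' electron-acceptance entry.
#'
#' @param mapTable output of [buildEhdamaMap()] (candidate rows are
#'   classified; reference rows are ignored).
#' @param refs the same [referencePanel()].
#' @param tol similarity tolerance in the panel's energy unit
#'   (default 0.1 kcal/mol).
#' @return data.frame `id`, `species`, `ip`, `bde_min`, then per
#'   antioxidant `set_<name>` / `hat_<name>` with values
#'   better/similar/worse, `set_ooh` / `hat_ooh` with values
#'   favored/similar/unfavored, and `n_dominated` (number of reference
#'   antioxidants beaten via both mechanisms).
#' @export
classifySpecies <- function(mapTable, refs = referencePanel(), tol = 0.1) {
    .checkPanel(refs)
    cand <- mapTable[mapTable$kind == "candidate", , drop = FALSE]
    out <- cand[c("id", "species", "ip", "bde_min")]
    anti <- refs[refs$role == "antioxidant", , drop = FALSE]
    domin <- matrix(FALSE, nrow(cand), nrow(anti))
    for (k in seq_len(nrow(anti))) {
        tag <- tolower(gsub("[^A-Za-z0-9]+", "_", anti$name[k]))
        setCl <- .cmpClass(cand$ip, anti$ip[k], tol)
        hatCl <- .cmpClass(cand$bde_min, anti$bde[k], tol)
        out[[paste0("set_", tag)]] <- setCl
        out[[paste0("hat_", tag)]] <- hatCl
        domin[, k] <- !is.na(setCl) & !is.na(hatCl) &
            setCl == "better" & hatCl == "better"
    }
    ooh <- refs[refs$name == "OOH", , drop = FALSE]
    out$set_ooh <- c(better = "favored", similar = "similar",
                     worse = "unfavored")[.cmpClass(cand$ip, ooh$ip, tol)]
    out$hat_ooh <- c(better = "favored", similar = "similar",
                     worse = "unfavored")[.cmpClass(cand$bde_min, ooh$bde,
                                                    tol)]
    out$n_dominated <- as.integer(rowSums(domin))
    rownames(out) <- NULL
    out
}

#' Rank species by antioxidant promise
#'
#' Orders classified species by decreasing number of reference antioxidants
#' dominated via both SET and HAT, breaking ties by ascending minimum BDE,
#' then ascending IP, then id and species label. Deterministic.
#'
#' @inheritParams classifySpecies
#' @return the classification table, ordered best-first.
#' @export
rankAntioxidants <- function(mapTable, refs = referencePanel(), tol = 0.1) {
    cl <- classifySpecies(mapTable, refs, tol)
    ord <- order(-cl$n_dominated, cl$bde_min, cl$ip, cl$id, cl$species)
    out <- cl[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Plot the donation map
#'
#' Scatter of IP versus minimum BDE: candidates as points, reference
#' antioxidants and the oxidant target as labeled symbols. Both axes are
#' "lower = better donor", so the best antioxidants sit bottom-left.
#'
#' @param mapTable output of [buildEhdamaMap()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `mapTable`.
#' @export
plotEhdama <- function(mapTable, ...) {
    cand <- mapTable[mapTable$kind == "candidate", , drop = FALSE]
    refs <- mapTable[mapTable$kind != "candidate", , drop = FALSE]
    rng <- function(v) range(v, na.rm = TRUE)
    graphics::plot(rng(mapTable$bde_min), rng(mapTable$ip), type = "n",
                   xlab = "minimum BDE", ylab = "IP", ...)
    graphics::points(cand$bde_min, cand$ip, pch = 16,
                     col = grDevices::adjustcolor("steelblue", 0.6))
    graphics::points(refs$bde_min, refs$ip, pch = 17, col = "firebrick")
    graphics::text(refs$bde_min, refs$ip, refs$name, pos = 3, cex = 0.8)
    invisible(mapTable)
}
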