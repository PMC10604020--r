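## admet stage: descriptors, drug-likeness rules, first screening.

descriptorColumns <- function()
    c("mw", "logp", "hbd", "hba", "tpsa", "rotb", "mr",
      "heavy_atoms", "carbons", "heteroatoms", "rings")

#' @noRd
toxicityColumns <- function() c("ld50", "mutagenicity", "dev_tox", "bf")

## parse a Hill-order molecular formula into a named count vector
parseFormula <- function(formula) {
    toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    el <- sub("[0-9]*$", "", toks)
    n <- as.integer(sub("^[A-Za-z]+", "", toks))
    n[is.na(n)] <- 1L
    tapply(n, el, sum)
}

## number of SSSR rings = ring-closure bond count in a SMILES string
## (spanning-tree argument: closures = edges - vertices + 1 per component)
ringCountFromSmiles <- function(smiles) {
    vapply(smiles, function(s) {
        s <- gsub("\\[[^]]*\\]", "A", s)      # drop bracket-atom innards
        two <- gregexpr("%[0-9]{2}", s)[[1]]
        n2 <- if (two[1] == -1L) 0L else length(two)
        s <- gsub("%[0-9]{2}", "", s)
        one <- gregexpr("[0-9]", s)[[1]]
        n1 <- if (one[1] == -1L) 0L else length(one)
        as.integer((n1 + 2L * n2) / 2L)
    }, integer(1), USE.NAMES = FALSE)
}

## SMARTS used for hand-reproducible Lipinski-style counts
.smarts <- list(
    nh1 = "[#7;H1]", nh2 = "[#7;H2]", nh3 = "[#7;H3]",
    oh1 = "[#8;H1]", oh2 = "[#8;H2]",
    no  = "[#7,#8]",
    rotb = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")

#' Compute physicochemical descriptors from structures
#'
#' Populates the descriptor block of the property vector for each SMILES:
#' molecular weight, Crippen-type logP, TPSA, molar refractivity (all from
#' OpenBabel), hydrogen-bond donors and acceptors by the classic Lipinski
#' hand-count definitions (HBD = number of O-H plus N-H hydrogens, HBA =
#' number of N plus O atoms), rotatable bonds (single acyclic non-terminal
#' bonds between non-triple-bonded atoms), atom counts from the molecular
#' formula and the smallest-set-of-smallest-rings count. Synthetic
#' accessibility and the four toxicity endpoints are external inputs and
#' are returned as `NA` (missing) columns.
#'
#' @param smiles character vector of SMILES.
#' @param id identifiers; defaults to `cmp1, cmp2, ...`.
#' @return data.frame with columns `id`, the descriptor block
#'   (`mw, logp, hbd, hba, tpsa, rotb, mr, heavy_atoms, carbons,
#'   heteroatoms, rings`), and `sa, ld50, mutagenicity, dev_tox, bf`
#'   initialized to `NA`.
#' @examples
#' computeDescriptors(c("c1ccc2ncccc2c1", "Oc1ccccc1"), c("quinoline", "phenol"))
#' @export
computeDescriptors <- function(smiles, id = NULL) {
    if (is.null(id)) id <- paste0("cmp", seq_along(smiles))
    if (length(id) != length(smiles))
        stop("'id' and 'smiles' lengths differ")
    if (any(is.na(smiles) | !nzchar(smiles)))
        stop("empty SMILES for id ",
             id[which(is.na(smiles) | !nzchar(smiles))[1]])
    can <- canonicalizeSmiles(smiles, names = id)

    input <- paste(paste(smiles, seq_along(smiles)), collapse = "\n")
    rows <- ChemmineOB::forEachMol("SMILES", input, function(m) {
        p <- ChemmineOB::prop_OB(m)
        cnt <- vapply(.smarts, function(sm)
            ChemmineOB::smartsSearch_OB(list(m), sm), numeric(1))
        data.frame(title = p$title, formula = p$formula, mw = p$MW,
                   logp = p$logP, tpsa = p$TPSA, mr = p$MR,
                   hbd = cnt[["nh1"]] + 2 * cnt[["nh2"]] + 3 * cnt[["nh3"]] +
                         cnt[["oh1"]] + 2 * cnt[["oh2"]],
                   hba = cnt[["no"]], rotb = cnt[["rotb"]],
                   stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    if (nrow(d) != length(smiles))
        stop("structure parse failure (got ", nrow(d), " of ",
             length(smiles), " molecules)")
    d <- d[order(as.integer(d$title)), , drop = FALSE]

    atoms <- lapply(d$formula, parseFormula)
    heavy <- vapply(atoms, function(a) sum(a[names(a) != "H"]), numeric(1))
    carbons <- vapply(atoms, function(a)
        if ("C" %in% names(a)) a[["C"]] else 0, numeric(1))

    out <- data.frame(id = id,
                      mw = d$mw, logp = d$logp, hbd = as.integer(d$hbd),
                      hba = as.integer(d$hba), tpsa = d$tpsa,
                      rotb = as.integer(d$rotb), mr = d$mr,
                      heavy_atoms = as.integer(heavy),
                      carbons = as.integer(carbons),
                      heteroatoms = as.integer(heavy - carbons),
                      rings = ringCountFromSmiles(can),
                      stringsAsFactors = FALSE)
    out$sa <- NA_real_
    out[toxicityColumns()] <- NA_real_
    out
}

#' Drug-likeness rule thresholds
#'
#' The five rule sets with their standard literature thresholds (boundaries
#' inclusive): Lipinski (mw <= 500, logp <= 5, hbd <= 5, hba <= 10; the set
#' passes with at most one violation), Ghose (160 <= mw <= 480,
#' -0.4 <= logp <= 5.6, 40 <= mr <= 130, 20 <= heavy atoms <= 70), Veber
#' (rotb <= 10, tpsa <= 140), Egan (logp <= 5.88, tpsa <= 131.6) and Muegge
#' (200 <= mw <= 600, -2 <= logp <= 5, tpsa <= 150, rings <= 7, carbons > 4,
#' heteroatoms > 1, rotb <= 15, hbd <= 5, hba <= 10).
#'
#' @return named list of per-rule checker functions (internal use); see
#'   [applyRules()].
#' @keywords internal
ruleChecks <- function() {
    list(
        lipinski = function(p) c(p$mw > 500, p$logp > 5, p$hbd > 5,
                                 p$hba > 10),
        ghose    = function(p) c(p$mw < 160, p$mw > 480, p$logp < -0.4,
                                 p$logp > 5.6, p$mr < 40, p$mr > 130,
                                 p$heavy_atoms < 20, p$heavy_atoms > 70),
        veber    = function(p) c(p$rotb > 10, p$tpsa > 140),
        egan     = function(p) c(p$logp > 5.88, p$tpsa > 131.6),
        muegge   = function(p) c(p$mw < 200, p$mw > 600, p$logp < -2,
                                 p$logp > 5, p$tpsa > 150, p$rings > 7,
                                 p$carbons <= 4, p$heteroatoms <= 1,
                                 p$rotb > 15, p$hbd > 5, p$hba > 10))
}

## violation tolerance per rule set: a set "passes" with at most this many
.ruleTolerance <- c(lipinski = 1L, ghose = 0L, veber = 0L, egan = 0L,
                    muegge = 0L)

#' Evaluate the five drug-likeness rule sets
#'
#' @param props data.frame with the descriptor columns of
#'   [computeDescriptors()] (at least `mw, logp, hbd, hba, tpsa, rotb, mr,
#'   heavy_atoms, carbons, heteroatoms, rings`) and an `id` column.
#' @return data.frame with, per rule set, `<rule>_violations` and
#'   `<rule>_pass`, plus `rules_passed` (0-5), `total_rules_violated`
#'   (count of failed rule sets) and `bioavailability_concern`
#'   (two or more failed rule sets).
#' @examples
#' p <- computeDescriptors("c1ccc2ncccc2c1", "quinoline")
#' applyRules(p)
#' @export
applyRules <- function(props) {
    need <- c("id", descriptorColumns())
    miss <- setdiff(need, names(props))
    if (length(miss))
        stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
    bad <- vapply(descriptorColumns(), function(cl) anyNA(props[[cl]]),
                  logical(1))
    if (any(bad))
        stop("NA descriptor value(s) in: ",
             paste(names(bad)[bad], collapse = ", "))
    checks <- ruleChecks()
    out <- data.frame(id = props$id, stringsAsFactors = FALSE)
    n <- nrow(props)
    for (rule in names(checks)) {
        ## each comparison is a length-n vector; row sums count violations
        v <- rowSums(matrix(checks[[rule]](props), nrow = n))
        out[[paste0(rule, "_violations")]] <- as.integer(v)
        out[[paste0(rule, "_pass")]] <- v <= .ruleTolerance[[rule]]
    }
    passCols <- paste0(names(checks), "_pass")
    out$rules_passed <- as.integer(rowSums(out[passCols]))
    out$total_rules_violated <- as.integer(length(checks) - out$rules_passed)
    out$bioavailability_concern <- out$total_rules_violated >= 2L
    out
}

#' First screening: drop compounds with missing toxicity endpoints
#'
#' Partitions a property table into compounds with complete toxicity data
#' and compounds missing at least one of the four endpoints (LD50, Ames
#' mutagenicity, developmental toxicity, bioaccumulation factor), which are
#' eliminated before scoring.
#'
#' @param props property data.frame with `id` and the four toxicity columns.
#' @return list with data.frames `kept` and `dropped` (a partition of the
#'   input rows, input order preserved) and integer `counts`.
#' @examples
#' p <- data.frame(id = c("a", "b"), ld50 = c(500, NA), mutagenicity = 0.2,
#'                 dev_tox = 0.3, bf = 1)
#' firstScreen(p)$counts
#' @export
firstScreen <- function(props) {
    tox <- toxicityColumns()
    miss <- setdiff(c("id", tox), names(props))
    if (length(miss))
        stop("missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(props) == 0L)
        return(list(kept = props, dropped = props,
                    counts = c(input = 0L, kept = 0L, dropped = 0L)))
    hasMissing <- rowSums(is.na(props[tox])) > 0
    list(kept = props[!hasMissing, , drop = FALSE],
         dropped = props[hasMissing, , drop = FALSE],
         counts = c(input = nrow(props),
                    kept = sum(!hasMissing),
                    dropped = sum(hasMissing)))
}
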