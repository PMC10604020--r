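#' Scaffold: a substitutable molecular core
#'
#' A `Scaffold` holds a SMILES template of a molecular core in which each
#' substitutable position is marked by a placeholder of the form
#' \code{\{R1\}}, \code{\{R2\}}, ... The placeholder labels are the site
#' labels; removing all placeholders must leave a valid SMILES (the parent
#' molecule, every site carrying hydrogen).
#'
#' @slot core character(1). SMILES template with `{label}` placeholders.
#' @slot sites character. Ordered site labels; each occurs exactly once in
#'   `core`.
#' @seealso [quinolineScaffold()], [enumerateDerivatives()]
#' @exportClass Scaffold
setClass("Scaffold",
         representation(core = "character", sites = "character"))

setValidity("Scaffold", function(object) {
    msg <- character()
    if (length(object@core) != 1L || is.na(object@core) || !nzchar(object@core))
        msg <- c(msg, "'core' must be a single non-empty SMILES template")
    if (length(object@sites) < 1L)
        msg <- c(msg, "at least one site label is required")
    if (anyDuplicated(object@sites))
        msg <- c(msg, "duplicate site labels: ",
                 paste(unique(object@sites[duplicated(object@sites)]),
                       collapse = ", "))
    for (s in unique(object@sites)) {
        n <- lengths(regmatches(object@core,
                                gregexpr(sprintf("\\{%s\\}", s), object@core)))
        if (n != 1L)
            msg <- c(msg, sprintf("site '%s' occurs %d times in core (need 1)",
                                  s, n))
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SubstituentLibrary: named monovalent fragments
#'
#' Maps functional-group names to monovalent SMILES fragments. Each fragment
#' is written as it will appear inside a branch, attached through its first
#' atom (e.g. `"O"` for hydroxyl, `"C(=O)OC"` for a methyl ester).
#'
#' @slot fragments named character. group name -> fragment SMILES.
#' @seealso [defaultSubstituentLibrary()]
#' @exportClass SubstituentLibrary
setClass("SubstituentLibrary",
         representation(fragments = "character"))

setValidity("SubstituentLibrary", function(object) {
    msg <- character()
    nm <- names(object@fragments)
    if (length(object@fragments) < 1L)
        msg <- c(msg, "library must contain at least one fragment")
    if (is.null(nm) || any(!nzchar(nm)))
        msg <- c(msg, "every fragment must be named")
    if (anyDuplicated(nm))
        msg <- c(msg, "duplicate fragment names: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
    if (any(!nzchar(object@fragments)))
        msg <- c(msg, "empty fragment SMILES")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' AcidBaseProfile: microspecies fractions of a multiprotic compound
#'
#' Result of [speciesFractions()]: the molar fraction of each acid-base
#' microspecies of one compound at a given pH, under a single (macroscopic)
#' deprotonation ladder. Species are ordered from the most protonated to the
#' most deprotonated; with n pKa values there are n + 1 species.
#'
#' @slot id character(1) compound identifier (may be NA).
#' @slot pkas numeric, strictly ascending macroscopic pKa values.
#' @slot ph numeric(1).
#' @slot fractions numeric, one per species, summing to 1.
#' @slot charges integer, formal charge of each species.
#' @slot species character, display label of each species.
#' @seealso [speciesFractions()], [relevantSpecies()]
#' @exportClass AcidBaseProfile
setClass("AcidBaseProfile",
         representation(id = "character", pkas = "numeric", ph = "numeric",
                        fractions = "numeric", charges = "integer",
                        species = "character"))

setValidity("AcidBaseProfile", function(object) {
    msg <- character()
    n <- length(object@pkas)
    if (length(object@ph) != 1L || !is.finite(object@ph))
        msg <- c(msg, "'ph' must be a single finite value")
    if (n > 0 && any(diff(object@pkas) <= 0))
        msg <- c(msg, "pKa values must be strictly ascending")
    if (length(object@fractions) != n + 1L)
        msg <- c(msg, "need |pkas| + 1 fractions")
    if (length(object@species) != n + 1L || length(object@charges) != n + 1L)
        msg <- c(msg, "species/charges must have |pkas| + 1 entries")
    if (any(object@fractions < 0) || any(object@fractions > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (abs(sum(object@fractions) - 1) > 1e-12)
        msg <- c(msg, "fractions must sum to 1 (within 1e-12)")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
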