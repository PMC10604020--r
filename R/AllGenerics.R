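#' @rdname Scaffold-class
#' @param x a `Scaffold`
#' @export
setGeneric("scaffoldCore", function(x) standardGeneric("scaffoldCore"))

#' @rdname Scaffold-class
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname SubstituentLibrary-class
#' @param x a `SubstituentLibrary`
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname SubstituentLibrary-class
#' @export
setGeneric("groupFragments", function(x) standardGeneric("groupFragments"))

#' @rdname AcidBaseProfile-class
#' @param x an `AcidBaseProfile`
#' @export
setGeneric("pkaValues", function(x) standardGeneric("pkaValues"))

#' @rdname AcidBaseProfile-class
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname AcidBaseProfile-class
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname AcidBaseProfile-class
#' @export
setGeneric("speciesCharges", function(x) standardGeneric("speciesCharges"))

setMethod("scaffoldCore", "Scaffold", function(x) x@core)
setMethod("siteLabels", "Scaffold", function(x) x@sites)
setMethod("groupNames", "SubstituentLibrary", function(x) names(x@fragments))
setMethod("groupFragments", "SubstituentLibrary", function(x) x@fragments)
setMethod("pkaValues", "AcidBaseProfile", function(x) x@pkas)
setMethod("fractions", "AcidBaseProfile",
          function(x) stats::setNames(x@fractions, x@species))
setMethod("speciesLabels", "AcidBaseProfile", function(x) x@species)
setMethod("speciesCharges", "AcidBaseProfile",
          function(x) stats::setNames(x@charges, x@species))

setMethod("show", "Scaffold", function(object) {
    cat("Scaffold with", length(object@sites), "substitution sites\n")
    cat("  core:  ", object@core, "\n")
    cat("  sites: ", paste(object@sites, collapse = ", "), "\n")
})

setMethod("show", "SubstituentLibrary", function(object) {
    cat("SubstituentLibrary with", length(object@fragments), "groups\n")
    for (i in seq_along(object@fragments))
        cat(sprintf("  %-10s %s\n", names(object@fragments)[i],
                    object@fragments[i]))
})

setMethod("show", "AcidBaseProfile", function(object) {
    cat("AcidBaseProfile", if (!is.na(object@id)) object@id else "",
        sprintf("(pH %.2f)\n", object@ph))
    if (length(object@pkas))
        cat("  pKa:", paste(format(object@pkas), collapse = ", "), "\n")
    else cat("  no ionizable sites\n")
    df <- data.frame(species = object@species, charge = object@charges,
                     fraction = signif(object@fractions, 4))
    print(df, row.names = FALSE)
})
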