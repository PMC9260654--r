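#' Accessors for package classes
#'
#' `counts()` returns the raw count matrix (samples x taxa); `sampleIDs()`
#' and `taxonIDs()` the identifier vectors; `nSamples()`/`nTaxa()` the
#' dimensions; `pseudoP()` the empirical pseudo p-value of a neutrality
#' test; `bnti()` the z-score matrix of a [BNTIMatrix-class].
#'
#' @param object a package object.
#' @return The slot content described above.
#' @name accessors
#' @examples
#' ct <- CountTable(matrix(1:4, 2, 2))
#' counts(ct); sampleIDs(ct); nTaxa(ct)
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("taxonIDs", function(object) standardGeneric("taxonIDs"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nTaxa", function(object) standardGeneric("nTaxa"))
#' @rdname accessors
#' @export
setGeneric("pseudoP", function(object) standardGeneric("pseudoP"))
#' @rdname accessors
#' @export
setGeneric("bnti", function(object) standardGeneric("bnti"))

#' @rdname accessors
setMethod("counts", "CountTable", function(object) object@counts)
#' @rdname accessors
setMethod("sampleIDs", "CountTable", function(object) rownames(object@counts))
#' @rdname accessors
setMethod("taxonIDs", "CountTable", function(object) colnames(object@counts))
#' @rdname accessors
setMethod("nSamples", "CountTable", function(object) nrow(object@counts))
#' @rdname accessors
setMethod("nTaxa", "CountTable", function(object) ncol(object@counts))
#' @rdname accessors
setMethod("pseudoP", "NeutralityResult", function(object) object@pseudoP)
#' @rdname accessors
setMethod("bnti", "BNTIMatrix", function(object) object@bnti)

setMethod("show", "CountTable", function(object) {
    cat("CountTable:", nSamples(object), "samples x", nTaxa(object),
        "taxa\n", "  totals:", paste(range(rowSums(counts(object))),
        collapse = " - "), "reads per sample\n")
})

setMethod("show", "DMMFit", function(object) {
    cat("DMMFit: K =", object@K, "components,",
        nrow(object@responsibilities), "samples\n",
        " neg log evidence (Laplace):",
        format(object@negLogEvidence, digits = 6), "\n",
        " converged:", object@converged,
        "after", object@iterations, "iterations\n")
})

setMethod("show", "HDPPosterior", function(object) {
    s <- object@settings
    cat("HDPPosterior:", length(object@theta), "retained draws",
        sprintf("(sweeps %d, burn-in %d, thinning %d)\n",
                s$sweeps, s$burn_in, s$thinning),
        " theta posterior median:",
        format(median(object@theta), digits = 4), "\n",
        " Geweke z (logLik trace):", format(object@gewekeZ, digits = 3), "\n")
})

setMethod("show", "NeutralityResult", function(object) {
    p <- if (object@pseudoP == 0)
        paste0("< ", format(1 / object@nDraws, digits = 3))
    else format(object@pseudoP, digits = 4)
    cat("NeutralityResult (", object@variant, " model): pseudo-p ", p,
        " over ", object@nDraws, " draws -> ",
        if (object@reject) "REJECT neutrality" else "compatible with neutrality",
        " at p < ", object@threshold, "\n", sep = "")
})

setMethod("show", "BNTIMatrix", function(object) {
    off <- object@bnti[upper.tri(object@bnti)]
    cat("BNTIMatrix:", nrow(object@bnti), "samples,",
        object@nNull, "null realizations\n",
        " significant pairs (|betaNTI| > 2):",
        sum(abs(off) > 2, na.rm = TRUE), "/", sum(!is.na(off)), "\n")
})

setMethod("show", "ZINBFit", function(object) {
    cat("ZINBFit:",
        if (object@zeroInflated) "zero-inflated negative binomial"
        else "negative binomial (zero part dropped)",
        "\n  dispersion:", format(object@dispersion, digits = 4),
        " logLik:", format(object@logLik, digits = 6),
        " converged:", object@converged, "\n")
    print(round(object@countCoefs, 4))
})

setMethod("show", "GeneProfileTable", function(object) {
    cat("GeneProfileTable:", nrow(object@proportions), "features x",
        ncol(object@proportions), "samples;",
        length(unique(object@groups)), "groups\n")
})
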