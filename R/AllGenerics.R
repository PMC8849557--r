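#' @include AllClasses.R
NULL

#' Accessors for lineageFidelity classes
#'
#' Small accessor family: \code{maskArea} returns the pixel area of a
#' \linkS4class{BinaryMask}; \code{maskAreas} the four areas of a
#' \linkS4class{MaskSet}; \code{ratios} the three coexpression ratios of a
#' \linkS4class{FidelityRecord}; \code{stateCounts}/\code{stateProps} the
#' counts and proportions of a \linkS4class{StateDistribution};
#' \code{oddsRatio}/\code{log2OR} the overlap odds ratio of an
#' \linkS4class{OverlapResult}; \code{pValue} the p-value of an
#' \linkS4class{OverlapResult} or \linkS4class{TestResult};
#' \code{truthTable} the ground-truth table of a
#' \linkS4class{LabeledImage}; \code{imageChannels} its H x W x 3
#' intensity array and \code{cellLabels} its label raster.
#'
#' @param x an object of the matching class.
#' @return The accessed component (numeric, matrix or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname accessors
#' @export
setGeneric("maskAreas", function(x) standardGeneric("maskAreas"))
#' @rdname accessors
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))
#' @rdname accessors
#' @export
setGeneric("stateCounts", function(x) standardGeneric("stateCounts"))
#' @rdname accessors
#' @export
setGeneric("stateProps", function(x) standardGeneric("stateProps"))
#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
#' @rdname accessors
#' @export
setGeneric("log2OR", function(x) standardGeneric("log2OR"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("imageChannels", function(x) standardGeneric("imageChannels"))
#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
setMethod("maskArea", "BinaryMask", function(x) sum(x@pixels))
#' @rdname accessors
setMethod("maskAreas", "MaskSet", function(x)
    c(a14 = x@a14, a19 = x@a19, a_and = x@aAnd, a_or = x@aOr))
#' @rdname accessors
setMethod("ratios", "FidelityRecord", function(x)
    c(r_lep = x@rLep, r_all = x@rAll, r_mep = x@rMep))
#' @rdname accessors
setMethod("stateCounts", "StateDistribution", function(x) x@counts)
#' @rdname accessors
setMethod("stateProps", "StateDistribution", function(x) {
    if (x@nCells == 0L) stop("empty distribution has no proportions")
    x@counts / x@nCells
})
#' @rdname accessors
setMethod("oddsRatio", "OverlapResult", function(x) x@oddsRatio)
#' @rdname accessors
setMethod("log2OR", "OverlapResult", function(x) x@log2OR)
#' @rdname accessors
setMethod("pValue", "OverlapResult", function(x) x@pValue)
#' @rdname accessors
setMethod("pValue", "TestResult", function(x) x@pValue)
#' @rdname accessors
setMethod("truthTable", "LabeledImage", function(x) x@truth)
#' @rdname accessors
setMethod("imageChannels", "LabeledImage", function(x) x@channels)
#' @rdname accessors
setMethod("cellLabels", "LabeledImage", function(x) x@cellLabels)
#' @rdname accessors
setMethod("geneIds", "GeneSet", function(x) x@genes)

setMethod("show", "MaskSet", function(object) {
    a <- maskAreas(object)
    cat("MaskSet: a14 =", a[1], " a19 =", a[2],
        " AND =", a[3], " OR =", a[4], "\n")
})

setMethod("show", "FidelityRecord", function(object) {
    r <- round(ratios(object), 4)
    cat(sprintf("FidelityRecord [%s/%s]: r_lep = %s, r_all = %s, r_mep = %s\n",
                object@sampleId, object@imageId, r[1], r[2], r[3]))
})

setMethod("show", "LabeledImage", function(object) {
    d <- dim(object@channels)
    cat("LabeledImage:",
        if (length(object@channels)) sprintf("%d x %d x %d", d[1], d[2], d[3])
        else "(truth only)",
        "|", nrow(object@truth), "cells\n")
})

setMethod("show", "StateDistribution", function(object) {
    cat("StateDistribution over", object@nCells, "cells\n")
    print(rbind(count = object@counts,
                proportion = if (object@nCells) round(stateProps(object), 4)
                             else rep(NA, 4)))
})

setMethod("show", "OverlapResult", function(object) {
    cat(sprintf(
        "OverlapResult: a=%d b=%d c=%d d=%d | OR = %.4g (log2 %.3f), p = %.4g%s\n",
        object@table[1, 1], object@table[1, 2], object@table[2, 1],
        object@table[2, 2], object@oddsRatio, object@log2OR, object@pValue,
        if (length(object@flags)) paste0(" [", paste(object@flags,
                                                     collapse = ","), "]")
        else ""))
})

setMethod("show", "TestResult", function(object) {
    cat(sprintf("%s: %s%s, p = %s (%s)%s\n", object@test,
                paste(names(object@statistic), "=",
                      signif(object@statistic, 5), collapse = ", "),
                if (!is.na(object@df)) paste0(", df = ", object@df) else "",
                format(signif(object@pValue, 4)), object@method,
                if (length(object@warnings))
                    paste0(" [", paste(object@warnings, collapse = ","), "]")
                else ""))
})

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s': %d genes%s\n", object@name,
                length(object@genes),
                if (nzchar(object@provenance))
                    paste0(" (", object@provenance, ")") else ""))
})

setMethod("show", "GroupComparison", function(object) {
    cat("GroupComparison of", object@metric, "across",
        length(object@groups), "groups\n")
    show(object@omnibus)
    if (nrow(object@pairwise)) {
        cat("Pairwise (Dunn, Bonferroni):\n")
        print(object@pairwise, digits = 4)
    }
})

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf("CohortSpec '%s' (%s): %d samples x %d images, %d archetypes\n",
                object@presetName, object@riskLabel, object@nSamples,
                object@imagesPerSample, length(object@archetypes)))
})
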