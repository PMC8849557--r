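#' @import methods
NULL

STATE_LEVELS <- c("undifferentiated", "K14_only", "K19_only", "double_positive")

## ---- generator parameter classes -------------------------------------------

#' Parameters of a synthetic bilayered-duct image
#'
#' Describes one tissue "archetype": ducts rendered as a ring of
#' myoepithelial (MEp, KRT14) cells enclosing luminal (LEp, KRT19) cells,
#' with per-cell probabilities of coexpressing the opposite-lineage keratin.
#' Ground-truth archetype parameters map directly onto the expected mask
#' ratios: with luminal area fraction x, luminal coexpression probability
#' alpha and myoepithelial coexpression probability beta,
#' E(r_lep) = (alpha*x + beta*(1-x)) / (x + beta*(1-x)),
#' E(r_mep) = (alpha*x + beta*(1-x)) / ((1-x) + alpha*x) and
#' E(r_all) = alpha*x + beta*(1-x).
#'
#' @slot imageSize integer(2), image height and width in pixels.
#' @slot nDucts number of ducts per image.
#' @slot ductRadius,cellRadius duct and cell radii in pixels.
#' @slot pCoexpressLuminal probability that a luminal cell also expresses KRT14.
#' @slot pCoexpressMyoepithelial probability that a myoepithelial cell also
#'   expresses KRT19.
#' @slot luminalAreaFraction target fraction of epithelial area that is luminal.
#' @slot intensityFg,intensityBg foreground/background fluorescence (arbitrary
#'   units); \code{intensityFg > intensityBg >= 0}.
#' @slot noiseSd standard deviation of additive Gaussian noise.
#' @exportClass TissueImageSpec
setClass("TissueImageSpec",
    slots = c(
        imageSize = "integer", nDucts = "integer",
        ductRadius = "numeric", cellRadius = "numeric",
        pCoexpressLuminal = "numeric", pCoexpressMyoepithelial = "numeric",
        luminalAreaFraction = "numeric",
        intensityFg = "numeric", intensityBg = "numeric", noiseSd = "numeric"
    ),
    prototype = list(
        imageSize = c(288L, 288L), nDucts = 3L,
        ductRadius = 40, cellRadius = 4,
        pCoexpressLuminal = 0, pCoexpressMyoepithelial = 0,
        luminalAreaFraction = 0.5,
        intensityFg = 3000, intensityBg = 100, noiseSd = 50
    )
)

setValidity("TissueImageSpec", function(object) {
    msg <- character()
    probs <- c(object@pCoexpressLuminal, object@pCoexpressMyoepithelial,
               object@luminalAreaFraction)
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
        msg <- c(msg, "probabilities and luminalAreaFraction must lie in [0, 1]")
    if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
        msg <- c(msg, "imageSize must be two positive integers")
    if (object@ductRadius <= 0 || object@cellRadius <= 0)
        msg <- c(msg, "radii must be > 0")
    if (object@cellRadius >= object@ductRadius)
        msg <- c(msg, "cellRadius must be smaller than ductRadius")
    if (!(object@intensityFg > object@intensityBg) || object@intensityBg < 0)
        msg <- c(msg, "need intensityFg > intensityBg >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@nDucts < 1L) msg <- c(msg, "nDucts must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{TissueImageSpec}
#' @param ... slot values overriding the defaults (see the class page).
#' @return A validated \code{TissueImageSpec}.
#' @examples
#' TissueImageSpec(pCoexpressLuminal = 0.5, luminalAreaFraction = 0.2)
#' @export
TissueImageSpec <- function(...) {
    args <- list(...)
    for (s in c("imageSize", "nDucts"))
        if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
    do.call(new, c("TissueImageSpec", args))
}

#' Parameters of a synthetic tissue cohort
#'
#' A cohort draws each sample from a small set of archetypes
#' (\linkS4class{TissueImageSpec}) with given weights, then renders
#' \code{imagesPerSample} images per sample. Archetype counts are
#' apportioned to samples deterministically (largest remainder), so the
#' cohort composition matches the weights exactly; see the vignette.
#'
#' @slot nSamples number of samples (donors).
#' @slot imagesPerSample images rendered per sample.
#' @slot archetypes list of \code{TissueImageSpec}.
#' @slot weights nonnegative archetype weights summing to 1.
#' @slot riskLabel \code{"AR"} or \code{"HR"}.
#' @slot presetName free-text preset identifier.
#' @exportClass CohortSpec
setClass("CohortSpec",
    slots = c(nSamples = "integer", imagesPerSample = "integer",
              archetypes = "list", weights = "numeric",
              riskLabel = "character", presetName = "character"),
    prototype = list(nSamples = 1L, imagesPerSample = 3L,
                     archetypes = list(), weights = numeric(),
                     riskLabel = "AR", presetName = "custom")
)

setValidity("CohortSpec", function(object) {
    msg <- character()
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (object@imagesPerSample < 1L) msg <- c(msg, "imagesPerSample must be >= 1")
    if (length(object@archetypes) == 0L)
        msg <- c(msg, "archetypes must be a nonempty list")
    if (!all(vapply(object@archetypes, is, logical(1), "TissueImageSpec")))
        msg <- c(msg, "all archetypes must be TissueImageSpec objects")
    if (length(object@weights) != length(object@archetypes))
        msg <- c(msg, "weights and archetypes must have equal length")
    if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must be >= 0 and sum to 1")
    if (!object@riskLabel %in% c("AR", "HR"))
        msg <- c(msg, "riskLabel must be 'AR' or 'HR'")
    if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{CohortSpec}
#' @param archetypes list of \linkS4class{TissueImageSpec}.
#' @param weights archetype weights (normalised to sum to 1 is NOT done;
#'   supply weights summing to 1).
#' @param nSamples,imagesPerSample cohort dimensions.
#' @param riskLabel "AR" or "HR".
#' @param presetName preset identifier.
#' @return A validated \code{CohortSpec}.
#' @export
CohortSpec <- function(archetypes, weights, nSamples = 1L,
                       imagesPerSample = 3L, riskLabel = "AR",
                       presetName = "custom") {
    new("CohortSpec", archetypes = archetypes, weights = as.numeric(weights),
        nSamples = as.integer(nSamples),
        imagesPerSample = as.integer(imagesPerSample),
        riskLabel = riskLabel, presetName = presetName)
}

#' Parameters of a synthetic progenitor-colony experiment
#'
#' Cells occupy one of four differentiation states (undifferentiated,
#' KRT14-only, KRT19-only, double-positive); per-state keratin intensities
#' follow log-normal distributions with well-separated "low" and "high"
#' modes.
#'
#' @slot nCells number of cells.
#' @slot stateProportions named numeric(4) summing to 1, order
#'   undifferentiated, K14_only, K19_only, double_positive.
#' @slot intensityModel 4 x 4 numeric matrix, rows = states, columns
#'   \code{meanlog14, sdlog14, meanlog19, sdlog19} (natural-log scale).
#' @slot minCellSpacing minimum center-to-center distance in pixels when
#'   rendering an image.
#' @slot imageSize,cellRadius,nucleusRadius rendering geometry (pixels).
#' @slot intensityBg,noiseSd background level and additive Gaussian noise.
#' @exportClass ColonySpec
setClass("ColonySpec",
    slots = c(nCells = "integer", stateProportions = "numeric",
              intensityModel = "matrix", minCellSpacing = "numeric",
              imageSize = "integer", cellRadius = "numeric",
              nucleusRadius = "numeric", intensityBg = "numeric",
              noiseSd = "numeric"),
    prototype = list(nCells = 100L,
                     stateProportions = structure(rep(0.25, 4),
                                                  names = STATE_LEVELS),
                     minCellSpacing = 18, imageSize = c(512L, 512L),
                     cellRadius = 7, nucleusRadius = 3,
                     intensityBg = 20, noiseSd = 4)
)

setValidity("ColonySpec", function(object) {
    msg <- character()
    sp <- object@stateProportions
    if (length(sp) != 4L || any(sp < 0) || any(sp > 1))
        msg <- c(msg, "stateProportions must be 4 values in [0, 1]")
    if (abs(sum(sp) - 1) > 1e-9)
        msg <- c(msg, "stateProportions must sum to 1 (tolerance 1e-9)")
    if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
    im <- object@intensityModel
    if (!is.numeric(im) || !all(dim(im) == c(4L, 4L)))
        msg <- c(msg, "intensityModel must be a 4 x 4 numeric matrix")
    if (object@minCellSpacing <= 0 || object@cellRadius <= 0)
        msg <- c(msg, "spacing and radii must be > 0")
    if (length(msg)) msg else TRUE
})

## default per-state intensity model: low mode 50, high mode 1000 (20x apart)
.defaultIntensityModel <- function(low = log(50), high = log(1000),
                                   sdlog = 0.35) {
    m <- rbind(
        undifferentiated = c(low,  sdlog, low,  sdlog),
        K14_only         = c(high, sdlog, low,  sdlog),
        K19_only         = c(low,  sdlog, high, sdlog),
        double_positive  = c(high, sdlog, high, sdlog))
    colnames(m) <- c("meanlog14", "sdlog14", "meanlog19", "sdlog19")
    m
}

#' Constructor for \linkS4class{ColonySpec}
#' @param nCells number of cells.
#' @param stateProportions numeric(4) state mixture (order: undifferentiated,
#'   K14_only, K19_only, double_positive); must sum to 1.
#' @param intensityModel optional 4 x 4 log-normal parameter matrix; the
#'   default separates low and high modes 20-fold.
#' @param ... further slots (see the class page).
#' @return A validated \code{ColonySpec}.
#' @examples
#' ColonySpec(nCells = 500, stateProportions = c(0.29, 0.19, 0.33, 0.19))
#' @export
ColonySpec <- function(nCells = 100L, stateProportions = rep(0.25, 4),
                       intensityModel = .defaultIntensityModel(), ...) {
    sp <- as.numeric(stateProportions)
    names(sp) <- STATE_LEVELS
    args <- list(...)
    for (s in "imageSize")
        if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
    do.call(new, c("ColonySpec",
                   list(nCells = as.integer(nCells), stateProportions = sp,
                        intensityModel = intensityModel), args))
}

#' Parameters of a synthetic differential-expression table
#'
#' @slot nGenes number of genes.
#' @slot fracUp,fracDown fractions of genes planted up/down;
#'   \code{fracUp + fracDown <= 1}.
#' @slot effectLog2fc planted absolute log2 fold change.
#' @slot nullLog2fcSd standard deviation of null-gene log2 fold changes.
#' @slot plantedPMax planted genes draw p ~ Uniform(0, plantedPMax);
#'   null genes draw p ~ Uniform(0, 1).
#' @exportClass DETableSpec
setClass("DETableSpec",
    slots = c(nGenes = "integer", fracUp = "numeric", fracDown = "numeric",
              effectLog2fc = "numeric", nullLog2fcSd = "numeric",
              plantedPMax = "numeric"),
    prototype = list(nGenes = 1000L, fracUp = 0.05, fracDown = 0.05,
                     effectLog2fc = 3, nullLog2fcSd = 0.25,
                     plantedPMax = 1e-8)
)

setValidity("DETableSpec", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@fracUp < 0 || object@fracDown < 0 ||
        object@fracUp + object@fracDown > 1 + 1e-12)
        msg <- c(msg, "need fracUp, fracDown >= 0 and fracUp + fracDown <= 1")
    if (object@nullLog2fcSd < 0) msg <- c(msg, "nullLog2fcSd must be >= 0")
    if (object@plantedPMax < 0 || object@plantedPMax > 1)
        msg <- c(msg, "plantedPMax must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{DETableSpec}
#' @param nGenes,fracUp,fracDown,effectLog2fc,nullLog2fcSd,plantedPMax see
#'   the class page.
#' @return A validated \code{DETableSpec}.
#' @export
DETableSpec <- function(nGenes = 1000L, fracUp = 0.05, fracDown = 0.05,
                        effectLog2fc = 3, nullLog2fcSd = 0.25,
                        plantedPMax = 1e-8) {
    new("DETableSpec", nGenes = as.integer(nGenes), fracUp = fracUp,
        fracDown = fracDown, effectLog2fc = effectLog2fc,
        nullLog2fcSd = nullLog2fcSd, plantedPMax = plantedPMax)
}

## ---- data containers -------------------------------------------------------

#' Synthetic multichannel image with per-cell ground truth
#'
#' @slot channels numeric array H x W x 3 with dimnames
#'   \code{c("nuclei", "KRT14", "KRT19")} on the third margin. May have
#'   zero extent when generated truth-only (\code{render = FALSE}).
#' @slot cellLabels integer matrix, 0 = background, k > 0 = cell k.
#' @slot truth data.frame with one row per positive label (columns
#'   \code{cell_id} plus generator-specific ground truth).
#' @exportClass LabeledImage
setClass("LabeledImage",
    slots = c(channels = "array", cellLabels = "matrix", truth = "data.frame"),
    prototype = list(channels = array(numeric(), c(0, 0, 3)),
                     cellLabels = matrix(integer(), 0, 0),
                     truth = data.frame(cell_id = integer()))
)

setValidity("LabeledImage", function(object) {
    msg <- character()
    rendered <- length(object@channels) > 0L
    if (rendered) {
        d <- dim(object@channels)
        if (length(d) != 3L || d[3] != 3L)
            msg <- c(msg, "channels must be an H x W x 3 array")
        else if (!identical(d[1:2], dim(object@cellLabels)))
            msg <- c(msg, "channels and cellLabels must share height/width")
        labs <- sort(unique(object@cellLabels[object@cellLabels > 0L]))
        if (!all(labs %in% object@truth$cell_id))
            msg <- c(msg, "every positive label needs exactly one truth row")
    }
    if (anyDuplicated(object@truth$cell_id))
        msg <- c(msg, "truth cell_id values must be unique")
    if (length(msg)) msg else TRUE
})

#' Binary mask from automated thresholding
#'
#' @slot pixels logical matrix.
#' @slot threshold intensity threshold used (\code{NA} when degenerate).
#' @slot degenerate TRUE when the source channel was constant and no
#'   threshold exists; the mask is then empty.
#' @exportClass BinaryMask
setClass("BinaryMask",
    slots = c(pixels = "matrix", threshold = "numeric", degenerate = "logical"),
    prototype = list(pixels = matrix(logical(), 0, 0),
                     threshold = NA_real_, degenerate = FALSE)
)

setValidity("BinaryMask", function(object) {
    if (!is.logical(object@pixels)) return("pixels must be logical")
    TRUE
})

#' Areas of the KRT14/KRT19 mask algebra for one image
#'
#' @slot a14,a19 areas (pixel counts) of the KRT14 and KRT19 masks.
#' @slot aAnd area of their intersection ("AND mask").
#' @slot aOr area of their union ("OR mask");
#'   always \code{a14 + a19 - aAnd}.
#' @exportClass MaskSet
setClass("MaskSet",
    slots = c(a14 = "numeric", a19 = "numeric",
              aAnd = "numeric", aOr = "numeric"),
    prototype = list(a14 = 0, a19 = 0, aAnd = 0, aOr = 0)
)

setValidity("MaskSet", function(object) {
    msg <- character()
    v <- c(object@a14, object@a19, object@aAnd, object@aOr)
    if (any(v < 0)) msg <- c(msg, "areas must be >= 0")
    if (object@aAnd > min(object@a14, object@a19) + 1e-9)
        msg <- c(msg, "aAnd cannot exceed min(a14, a19)")
    if (abs(object@aOr - (object@a14 + object@a19 - object@aAnd)) > 1e-9)
        msg <- c(msg, "aOr must equal a14 + a19 - aAnd")
    if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{MaskSet}
#' @param a14,a19,aAnd areas of the KRT14 mask, KRT19 mask and their
#'   intersection; the union area is implied.
#' @return A validated \code{MaskSet}.
#' @examples
#' MaskSet(4, 3, 1)  # aOr = 6
#' @export
MaskSet <- function(a14, a19, aAnd) {
    new("MaskSet", a14 = as.numeric(a14), a19 = as.numeric(a19),
        aAnd = as.numeric(aAnd),
        aOr = as.numeric(a14) + as.numeric(a19) - as.numeric(aAnd))
}

#' Coexpression (lineage-fidelity) ratios of one image
#'
#' \code{r_lep = aAnd/a19} (fraction of KRT19+ area also KRT14+),
#' \code{r_all = aAnd/aOr} (double-positive fraction of all epithelium),
#' \code{r_mep = aAnd/a14}. A ratio whose denominator is 0 is \code{NA}
#' (flagged missing, never NaN).
#'
#' @slot rLep,rAll,rMep the three ratios (\code{NA} = missing).
#' @slot maskSet the underlying \linkS4class{MaskSet}.
#' @slot sampleId,imageId identifiers (may be \code{NA}).
#' @exportClass FidelityRecord
setClass("FidelityRecord",
    slots = c(rLep = "numeric", rAll = "numeric", rMep = "numeric",
              maskSet = "MaskSet", sampleId = "character",
              imageId = "character"),
    prototype = list(rLep = NA_real_, rAll = NA_real_, rMep = NA_real_,
                     maskSet = new("MaskSet"), sampleId = NA_character_,
                     imageId = NA_character_)
)

setValidity("FidelityRecord", function(object) {
    v <- c(object@rLep, object@rAll, object@rMep)
    v <- v[!is.na(v)]
    if (length(v) && (any(v < -1e-12) || any(v > 1 + 1e-12)))
        return("defined ratios must lie in [0, 1]")
    TRUE
})

#' Per-channel intensity gates for four-state classification
#'
#' @slot t14,t19 intensity thresholds on the raw (not log) scale.
#' @slot method gate-fitting method tag.
#' @slot fallback named logical(2): TRUE where the bimodal split failed and
#'   the 75th-percentile fallback was used.
#' @exportClass GateThresholds
setClass("GateThresholds",
    slots = c(t14 = "numeric", t19 = "numeric", method = "character",
              fallback = "logical"),
    prototype = list(t14 = NA_real_, t19 = NA_real_, method = "otsu-log",
                     fallback = c(KRT14 = FALSE, KRT19 = FALSE))
)

setValidity("GateThresholds", function(object) {
    if (!is.finite(object@t14) || !is.finite(object@t19) ||
        object@t14 <= 0 || object@t19 <= 0)
        return("thresholds must be finite and > 0")
    TRUE
})

#' Distribution of cells over the four differentiation states
#'
#' @slot counts named integer(4) in state order undifferentiated, K14_only,
#'   K19_only, double_positive.
#' @slot nCells total cell count.
#' @exportClass StateDistribution
setClass("StateDistribution",
    slots = c(counts = "integer", nCells = "integer"),
    prototype = list(counts = structure(integer(4), names = STATE_LEVELS),
                     nCells = 0L)
)

setValidity("StateDistribution", function(object) {
    msg <- character()
    if (length(object@counts) != 4L ||
        !identical(names(object@counts), STATE_LEVELS))
        msg <- c(msg, "counts must be named with the four state levels")
    if (any(object@counts < 0L)) msg <- c(msg, "counts must be >= 0")
    if (sum(object@counts) != object@nCells)
        msg <- c(msg, "counts must sum to nCells")
    if (length(msg)) msg else TRUE
})

#' A named gene set
#'
#' @slot name set name.
#' @slot genes unique gene identifiers.
#' @slot provenance free-text note recording how the set was built.
#' @exportClass GeneSet
setClass("GeneSet",
    slots = c(name = "character", genes = "character",
              provenance = "character"),
    prototype = list(name = "geneset", genes = character(), provenance = "")
)

setValidity("GeneSet", function(object) {
    if (anyDuplicated(object@genes)) return("genes must be unique")
    TRUE
})

#' Constructor for \linkS4class{GeneSet}
#' @param name set name.
#' @param genes character vector of gene identifiers (duplicates dropped).
#' @param provenance free-text provenance note.
#' @return A \code{GeneSet}.
#' @export
GeneSet <- function(name, genes, provenance = "") {
    new("GeneSet", name = name, genes = unique(as.character(genes)),
        provenance = provenance)
}

#' Result of a one-sided gene-set overlap test
#'
#' The 2x2 membership table of two gene sets within a universe:
#' a = |A and B|, b = |A only|, c = |B only|, d = |neither|. The sample
#' odds ratio is (a d)/(b c); the p-value is the hypergeometric upper
#' tail P(X >= a) (Fisher's exact test, alternative = greater).
#'
#' @slot table 2x2 integer matrix (rows: in A / not in A; columns:
#'   in B / not in B).
#' @slot oddsRatio sample odds ratio (possibly \code{Inf} or \code{NaN},
#'   then flagged).
#' @slot log2OR \code{log2(oddsRatio)}.
#' @slot pValue one-sided Fisher p-value.
#' @slot flags zero or more of \code{"infinite_or"}, \code{"undefined_or"},
#'   \code{"haldane_corrected"}.
#' @exportClass OverlapResult
setClass("OverlapResult",
    slots = c(table = "matrix", oddsRatio = "numeric", log2OR = "numeric",
              pValue = "numeric", flags = "character"),
    prototype = list(table = matrix(0L, 2, 2), oddsRatio = NA_real_,
                     log2OR = NA_real_, pValue = NA_real_,
                     flags = character())
)

setValidity("OverlapResult", function(object) {
    msg <- character()
    if (any(object@table < 0)) msg <- c(msg, "table cells must be >= 0")
    if (!is.na(object@pValue) &&
        (object@pValue < -1e-12 || object@pValue > 1 + 1e-12))
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (is.finite(object@oddsRatio) && object@oddsRatio < 0)
        msg <- c(msg, "oddsRatio must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Matrix of pairwise gene-set overlap results
#'
#' @slot pValues,log2OR numeric matrices (rows = row sets, columns =
#'   column sets).
#' @slot results list of \linkS4class{OverlapResult}, filled column-major.
#' @exportClass OverlapMatrix
setClass("OverlapMatrix",
    slots = c(pValues = "matrix", log2OR = "matrix", results = "list"))

setValidity("OverlapMatrix", function(object) {
    if (length(object@results) != length(object@pValues))
        return("results must hold one OverlapResult per matrix cell")
    TRUE
})

#' Result of a statistical test
#'
#' Common container for the package's nonparametric tests.
#'
#' @slot test test name.
#' @slot statistic named numeric vector of statistics.
#' @slot df degrees of freedom (\code{NA} when not applicable).
#' @slot pValue p-value (\code{NA} when the test is not applicable, see
#'   \code{warnings}).
#' @slot method note stating the computation branch (exact vs approximate).
#' @slot warnings character vector of condition flags (possibly empty).
#' @slot extra list of auxiliary results (e.g. contingency or pairwise
#'   tables).
#' @exportClass TestResult
setClass("TestResult",
    slots = c(test = "character", statistic = "numeric", df = "numeric",
              pValue = "numeric", method = "character",
              warnings = "character", extra = "list"),
    prototype = list(test = "", statistic = numeric(), df = NA_real_,
                     pValue = NA_real_, method = "", warnings = character(),
                     extra = list())
)

setValidity("TestResult", function(object) {
    if (!is.na(object@pValue) &&
        (object@pValue < -1e-12 || object@pValue > 1 + 1e-12))
        return("pValue must lie in [0, 1]")
    if (!nzchar(object@method)) return("method note must be populated")
    TRUE
})

#' Group comparison of a per-sample metric
#'
#' @slot metric name of the compared metric.
#' @slot groups named list of per-group numeric values.
#' @slot omnibus \linkS4class{TestResult}: Mann-Whitney U for two groups,
#'   Kruskal-Wallis for three or more.
#' @slot pairwise data.frame of Dunn pairwise z-tests with
#'   Bonferroni-adjusted p (only when there are >= 3 groups, else 0 rows).
#' @exportClass GroupComparison
setClass("GroupComparison",
    slots = c(metric = "character", groups = "list", omnibus = "TestResult",
              pairwise = "data.frame"))

setValidity("GroupComparison", function(object) {
    k <- length(object@groups)
    if (k >= 3L && nrow(object@pairwise) != choose(k, 2))
        return("pairwise table must hold one row per group pair when k >= 3")
    if (k == 2L && nrow(object@pairwise) != 0L)
        return("pairwise table must be empty for two groups")
    TRUE
})
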