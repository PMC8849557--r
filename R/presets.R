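## Calibrated cohort and colony presets.
##
## Tissue archetypes are parameterised as (x, alpha, beta) = (luminal area
## fraction, luminal coexpression probability, myoepithelial coexpression
## probability). Expected mask ratios follow in closed form:
##   E(r_lep) = (alpha x + beta (1-x)) / (x + beta (1-x))
##   E(r_mep) = (alpha x + beta (1-x)) / ((1-x) + alpha x)
##   E(r_all) = alpha x + beta (1-x)
## and 1/r_all = 1/r_lep + 1/r_mep - 1. The HR cohort means
## (r_lep, r_mep, r_all) = (0.31, 0.18, 0.11) violate that identity for any
## single archetype, so the HR preset is a three-archetype mixture solved to
## hit the cohort means; the AR pair (0.07, 0.03) is self-consistent and the
## AR preset is homogeneous. Derivations are in the vignette.

.tissueArchetype <- function(x, alpha, beta, ...) {
    TissueImageSpec(luminalAreaFraction = x, pCoexpressLuminal = alpha,
                    pCoexpressMyoepithelial = beta, ...)
}

#' Calibrated tissue-cohort presets
#'
#' \code{"HR"}: a 23-sample high-risk cohort built from three duct
#' archetypes mixed so that the expected cohort means of the coexpression
#' ratios are (r_lep, r_mep, r_all) = (0.31, 0.18, 0.11). \code{"AR"}: a
#' homogeneous 26-sample average-risk cohort with expected
#' (r_lep, r_all) = (0.069, 0.029).
#'
#' @param name \code{"HR"} or \code{"AR"}.
#' @param nSamples,imagesPerSample cohort dimensions (defaults: the
#'   calibrated cohort sizes 23/26 samples, 3 images each).
#' @return A \linkS4class{CohortSpec}.
#' @examples
#' tissuePreset("HR")
#' @export
tissuePreset <- function(name = c("HR", "AR"), nSamples = NULL,
                         imagesPerSample = 3L) {
    name <- match.arg(name)
    if (name == "HR") {
        arch <- list(.tissueArchetype(0.182, 0.50, 0.0),
                     .tissueArchetype(0.656, 0.0, 0.26),
                     .tissueArchetype(0.381, 0.25, 0.054))
        w <- c(0.2415, 0.2415, 0.517)
        n <- if (is.null(nSamples)) 23L else nSamples
    } else {
        arch <- list(.tissueArchetype(0.416, 0.056, 0.010))
        w <- 1
        n <- if (is.null(nSamples)) 26L else nSamples
    }
    CohortSpec(archetypes = arch, weights = w, nSamples = n,
               imagesPerSample = imagesPerSample, riskLabel = name,
               presetName = paste0(name, "-tissue"))
}

## Colony state mixtures (undifferentiated, K14_only, K19_only,
## double_positive). The undifferentiated weights of the day-2 presets and
## the KRT14-positive totals (K14_only + double_positive) of the day-7
## presets are the calibrated quantities; the remaining splits are the
## package's own choices (documented in the vignette).
.colonyMixtures <- list(
    "AR-day2" = c(0.29, 0.19, 0.33, 0.19),
    "HR-day2" = c(0.50, 0.20, 0.10, 0.20),
    "AR-day7" = c(0.26, 0.17, 0.40, 0.17),  # K14+ total 0.34
    "HR-day7" = c(0.14, 0.31, 0.35, 0.20)   # K14+ total 0.51
)

#' Calibrated colony presets
#'
#' Four-state mixtures of cKit-progeny differentiation outcomes at day 2
#' and day 7 for average-risk (AR) and high-risk (HR) progenitors.
#'
#' @param name one of \code{"AR-day2"}, \code{"HR-day2"}, \code{"AR-day7"},
#'   \code{"HR-day7"}.
#' @param nCells number of cells (default 2000).
#' @param ... further arguments to \code{\link{ColonySpec}}.
#' @return A \linkS4class{ColonySpec}.
#' @examples
#' colonyPreset("AR-day2")
#' @export
colonyPreset <- function(name = names(.colonyMixtures), nCells = 2000L, ...) {
    name <- match.arg(name)
    ColonySpec(nCells = nCells, stateProportions = .colonyMixtures[[name]],
               ...)
}

## Expected per-archetype ratios from (x, alpha, beta); used by tests and
## the vignette, exported for transparency.

#' Closed-form expected coexpression ratios of a tissue archetype
#'
#' @param spec a \linkS4class{TissueImageSpec}.
#' @return Named numeric: expected \code{r_lep}, \code{r_all}, \code{r_mep}
#'   in the continuum (area-fraction) limit of the archetype parameters.
#' @examples
#' expectedRatios(tissuePreset("AR")@archetypes[[1]])
#' @export
expectedRatios <- function(spec) {
    x <- spec@luminalAreaFraction
    a <- spec@pCoexpressLuminal
    b <- spec@pCoexpressMyoepithelial
    and <- a * x + b * (1 - x)
    c(r_lep = if (x + b * (1 - x) > 0) and / (x + b * (1 - x)) else NA_real_,
      r_all = and,
      r_mep = if ((1 - x) + a * x > 0) and / ((1 - x) + a * x) else NA_real_)
}
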