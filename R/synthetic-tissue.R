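## Synthetic bilayered-duct images with per-cell ground truth.

## Candidate cell positions of one duct centered at the origin.
## The outermost ring is myoepithelial; inner rings are luminal.
.ductLayout <- function(spec) {
    R <- spec@ductRadius; r <- spec@cellRadius
    gap <- 2 * r + 2
    radii <- seq(R - r, r, by = -gap)
    if (length(radii) < 2L)
        stop("ductRadius too small to hold a luminal ring inside the ",
             "myoepithelial ring")
    pos <- lapply(seq_along(radii), function(i) {
        rr <- radii[i]
        # chord-based count so neighbouring disks never overlap
        n <- if (2 * rr <= gap) 1L else floor(pi / asin(gap / (2 * rr)))
        if (n < 2L) return(data.frame(dy = 0, dx = 0, ring = i))
        th <- runif(1, 0, 2 * pi) + 2 * pi * (seq_len(n) - 1) / n
        data.frame(dy = rr * sin(th), dx = rr * cos(th), ring = i)
    })
    pos <- do.call(rbind, pos)
    pos$compartment <- ifelse(pos$ring == 1L, "MEp", "LEp")
    pos
}

## Luminal/myoepithelial cell counts realising luminalAreaFraction x given
## ring capacities (equal-sized cells, so area fraction = count fraction).
.ductCounts <- function(x, nLumCap, nMyoCap) {
    if (x <= 0) return(c(nl = 0L, nm = nMyoCap))
    if (x >= 1) return(c(nl = nLumCap, nm = 0L))
    desired <- round(x / (1 - x) * nMyoCap)
    if (desired <= nLumCap)
        c(nl = as.integer(desired), nm = nMyoCap)
    else
        c(nl = nLumCap, nm = as.integer(round((1 - x) / x * nLumCap)))
}

## Draw one duct image from the current RNG state.
.ductImage <- function(spec, render = TRUE, sampleId = NA_character_,
                       imageId = NA_character_) {
    H <- spec@imageSize[1]; W <- spec@imageSize[2]
    k <- ceiling(sqrt(spec@nDucts))
    cellH <- H / k; cellW <- W / k
    margin <- min(cellH, cellW) / 2 - spec@ductRadius - spec@cellRadius - 1
    if (margin < 0)
        stop("ducts do not fit the image: increase imageSize or reduce ",
             "ductRadius/nDucts")
    cells <- list()
    nextId <- 1L
    for (d in seq_len(spec@nDucts)) {
        gi <- (d - 1L) %/% k; gj <- (d - 1L) %% k
        cy <- (gi + 0.5) * cellH + runif(1, -margin, margin)
        cx <- (gj + 0.5) * cellW + runif(1, -margin, margin)
        lay <- .ductLayout(spec)
        lum <- lay[lay$compartment == "LEp", ]
        myo <- lay[lay$compartment == "MEp", ]
        cnt <- .ductCounts(spec@luminalAreaFraction, nrow(lum), nrow(myo))
        keepL <- if (cnt["nl"] < nrow(lum))
            lum[sort(sample.int(nrow(lum), cnt["nl"])), ] else lum
        keepM <- if (cnt["nm"] < nrow(myo))
            myo[sort(sample.int(nrow(myo), cnt["nm"])), ] else myo
        duct <- rbind(keepL, keepM)
        if (nrow(duct) == 0L) next
        co <- ifelse(duct$compartment == "LEp",
                     stats::rbinom(nrow(duct), 1, spec@pCoexpressLuminal),
                     stats::rbinom(nrow(duct), 1,
                                   spec@pCoexpressMyoepithelial))
        cells[[d]] <- data.frame(
            cell_id = seq.int(nextId, length.out = nrow(duct)),
            duct = d, lineage = duct$compartment,
            coexpressing = as.logical(co),
            y = cy + duct$dy, x = cx + duct$dx)
        nextId <- nextId + nrow(duct)
    }
    truth <- if (length(cells)) do.call(rbind, cells)
             else data.frame(cell_id = integer(), duct = integer(),
                             lineage = character(), coexpressing = logical(),
                             y = numeric(), x = numeric())
    rownames(truth) <- NULL
    if (!render)
        return(new("LabeledImage", truth = truth))
    bg <- spec@intensityBg; fg <- spec@intensityFg; r <- spec@cellRadius
    nuc <- matrix(bg, H, W); k14 <- matrix(bg, H, W); k19 <- matrix(bg, H, W)
    labels <- matrix(0L, H, W)
    for (i in seq_len(nrow(truth))) {
        cy <- truth$y[i]; cx <- truth$x[i]
        isLum <- truth$lineage[i] == "LEp"
        co <- truth$coexpressing[i]
        if (isLum || co) k19 <- paintDisk(k19, cy, cx, r, fg)
        if (!isLum || co) k14 <- paintDisk(k14, cy, cx, r, fg)
        nuc <- paintDisk(nuc, cy, cx, r / 2, fg)
        labels <- paintDisk(labels, cy, cx, r, truth$cell_id[i])
    }
    if (spec@noiseSd > 0) {
        nuc <- nuc + matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
        k14 <- k14 + matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
        k19 <- k19 + matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
        nuc[nuc < 0] <- 0; k14[k14 < 0] <- 0; k19[k19 < 0] <- 0
    }
    img <- newLabeledImage(nuc, k14, k19, labels, truth)
    img
}

#' Generate a synthetic bilayered-duct image
#'
#' Renders ducts as a ring of myoepithelial (KRT14) cells enclosing rings of
#' luminal (KRT19) cells. Each cell coexpresses the opposite-lineage keratin
#' with the probability given in \code{spec}; the truth table records each
#' cell's lineage and coexpression flag. Identical \code{(spec, seed)} pairs
#' produce identical output.
#'
#' @param spec a \linkS4class{TissueImageSpec}.
#' @param seed integer seed.
#' @param render if \code{FALSE}, skip rasterisation and return a
#'   truth-only \linkS4class{LabeledImage} (fast path for calibration
#'   studies).
#' @return A \linkS4class{LabeledImage}.
#' @examples
#' img <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 0.5), seed = 1)
#' head(truthTable(img))
#' @export
generateDuctImage <- function(spec, seed, render = TRUE) {
    stopifnot(is(spec, "TissueImageSpec"))
    validObject(spec)
    withSeed(seed, .ductImage(spec, render = render))
}

.ageGroup <- function(age, youngMax = 35, oldMin = 55) {
    ifelse(age <= youngMax, "young", ifelse(age >= oldMin, "old", "middle"))
}

#' Generate a synthetic tissue cohort
#'
#' Apportions the cohort's samples to its archetypes by largest-remainder
#' allocation of the archetype weights (so the cohort composition matches
#' the weights exactly; the assignment order is randomised), then draws
#' \code{imagesPerSample} duct images per sample and fills in sample
#' metadata. Reruns with the same seed are identical.
#'
#' @param cohort a \linkS4class{CohortSpec}.
#' @param seed integer seed.
#' @param render passed to the image generator; \code{FALSE} generates
#'   truth tables only.
#' @return A list with one element per sample, each holding
#'   \code{$metadata} (one-row data.frame: sample_id, risk_group, mutation,
#'   age, age_group, tissue_type, archetype) and \code{$images} (list of
#'   \linkS4class{LabeledImage}).
#' @examples
#' coh <- generateTissueCohort(tissuePreset("AR", nSamples = 2), seed = 1,
#'                             render = FALSE)
#' coh[[1]]$metadata
#' @export
generateTissueCohort <- function(cohort, seed, render = TRUE) {
    stopifnot(is(cohort, "CohortSpec"))
    validObject(cohort)
    withSeed(seed, {
        n <- cohort@nSamples
        counts <- apportion(n, cohort@weights)
        assign <- sample(rep.int(seq_along(counts), counts))
        hr <- cohort@riskLabel == "HR"
        muts <- if (hr) sample(c("BRCA1", "BRCA2", "PALB2"), n,
                               replace = TRUE, prob = c(0.4, 0.35, 0.25))
                else rep("none", n)
        ages <- round(pmin(75, pmax(
            if (hr) 24 else 18,
            stats::rnorm(n, if (hr) 45.5 else 38.5, if (hr) 10 else 12))))
        lapply(seq_len(n), function(i) {
            spec <- cohort@archetypes[[assign[i]]]
            imgs <- lapply(seq_len(cohort@imagesPerSample), function(j)
                .ductImage(spec, render = render))
            md <- data.frame(
                sample_id = sprintf("%s_S%02d", cohort@riskLabel, i),
                risk_group = cohort@riskLabel, mutation = muts[i],
                age = ages[i], age_group = .ageGroup(ages[i]),
                tissue_type = "normal", archetype = assign[i])
            list(metadata = md, images = imgs)
        })
    })
}

#' Coexpression ratios implied by a ground-truth table
#'
#' Computes the three lineage-fidelity ratios directly from the generator's
#' per-cell truth (equal-area cells, so area ratios equal count ratios).
#' Used to study generator calibration without rasterising images.
#'
#' @param truth a truth data.frame from \code{\link{generateDuctImage}}, or
#'   a \linkS4class{LabeledImage}.
#' @return A \linkS4class{FidelityRecord}.
#' @examples
#' img <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 1), seed = 1,
#'                          render = FALSE)
#' ratios(truthFidelity(img))
#' @export
truthFidelity <- function(truth) {
    if (is(truth, "LabeledImage")) truth <- truth@truth
    lum <- truth$lineage == "LEp"
    cL <- sum(lum & truth$coexpressing)
    cM <- sum(!lum & truth$coexpressing)
    ms <- MaskSet(a14 = sum(!lum) + cL, a19 = sum(lum) + cM, aAnd = cL + cM)
    fidelityRatios(ms)
}
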