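## Mask-based quantification of keratin coexpression in duct images.

## Otsu threshold over a 256-bin histogram: exhaustive search of the split
## maximising between-class variance. Returns the threshold on the intensity
## scale, plus the fraction of total variance explained by the split.
.otsu <- function(v, nbins = 256L) {
    rng <- range(v)
    if (!all(is.finite(rng))) stop("intensities must be finite")
    if (diff(rng) == 0) return(list(threshold = NA_real_, explained = 0))
    edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
    h <- as.numeric(tabulate(pmin(findInterval(v, edges,
                                               rightmost.closed = TRUE),
                                  nbins), nbins))
    n <- length(v)
    mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
    w0 <- cumsum(h)[-nbins]
    w1 <- n - w0
    s0 <- cumsum(h * mids)[-nbins]
    mu <- sum(h * mids) / n
    valid <- w0 > 0 & w1 > 0
    bcv <- rep(-Inf, nbins - 1L)
    bcv[valid] <- (mu * w0[valid] - s0[valid])^2 / (w0[valid] * w1[valid]) * n
    i <- which.max(bcv)
    totalVar <- sum(h * (mids - mu)^2)
    list(threshold = edges[i + 1L],
         explained = if (totalVar > 0) (bcv[i] / n) / (totalVar / n) else 0)
}

#' Automated (Otsu) thresholding of a fluorescence channel
#'
#' Chooses the threshold that maximises the between-class variance of the
#' channel's 256-bin intensity histogram; the mask is true where intensity
#' is strictly greater than the threshold. Constant channels have no
#' threshold: the mask is empty and flagged degenerate.
#'
#' @param channel numeric matrix of nonnegative intensities.
#' @return A \linkS4class{BinaryMask}.
#' @examples
#' m <- matrix(10, 8, 8); m[1, 1:4] <- 200
#' maskArea(autoThreshold(m))  # 4
#' @export
autoThreshold <- function(channel) {
    if (!is.matrix(channel) || length(channel) == 0L)
        stop("channel must be a nonempty numeric matrix")
    if (any(!is.finite(channel))) stop("channel intensities must be finite")
    o <- .otsu(as.numeric(channel))
    if (is.na(o$threshold))
        return(new("BinaryMask",
                   pixels = matrix(FALSE, nrow(channel), ncol(channel)),
                   threshold = NA_real_, degenerate = TRUE))
    new("BinaryMask", pixels = channel > o$threshold,
        threshold = o$threshold, degenerate = FALSE)
}

#' Mask algebra: areas of the AND and OR masks
#'
#' @param m14,m19 \linkS4class{BinaryMask} objects (or logical matrices) of
#'   identical shape for the KRT14 and KRT19 channels.
#' @return A \linkS4class{MaskSet} with the four areas; the identity
#'   \code{a_or = a14 + a19 - a_and} holds exactly.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE), 3, 3)
#' b <- matrix(c(TRUE, FALSE, FALSE), 3, 3)
#' maskAreas(computeMaskSet(a, b))
#' @export
computeMaskSet <- function(m14, m19) {
    p14 <- if (is(m14, "BinaryMask")) m14@pixels else m14
    p19 <- if (is(m19, "BinaryMask")) m19@pixels else m19
    if (!identical(dim(p14), dim(p19)))
        stop("masks must have identical shape")
    MaskSet(a14 = sum(p14), a19 = sum(p19), aAnd = sum(p14 & p19))
}

#' Coexpression ratios from mask areas
#'
#' Computes \code{r_lep = a_and/a19}, \code{r_all = a_and/a_or} and
#' \code{r_mep = a_and/a14}. A zero denominator flags the corresponding
#' ratio missing (\code{NA}); no NaN is ever propagated.
#'
#' @param ms a \linkS4class{MaskSet}.
#' @param sampleId,imageId optional identifiers carried on the record.
#' @return A \linkS4class{FidelityRecord}.
#' @examples
#' ratios(fidelityRatios(MaskSet(4, 3, 1)))  # 1/3, 1/6, 1/4
#' @export
fidelityRatios <- function(ms, sampleId = NA_character_,
                           imageId = NA_character_) {
    stopifnot(is(ms, "MaskSet"))
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    new("FidelityRecord",
        rLep = safe(ms@aAnd, ms@a19),
        rAll = safe(ms@aAnd, ms@aOr),
        rMep = safe(ms@aAnd, ms@a14),
        maskSet = ms, sampleId = sampleId, imageId = imageId)
}

#' Quantify keratin coexpression in one image
#'
#' Composition of the three pipeline stages: Otsu thresholding of the KRT14
#' and KRT19 channels (within the region of interest if one is given), mask
#' AND/OR algebra, and the three coexpression ratios.
#'
#' @param image a \linkS4class{LabeledImage}, an H x W x 3 array with named
#'   channels, or a named list with elements \code{KRT14} and \code{KRT19}.
#' @param roi optional logical matrix (or \linkS4class{BinaryMask});
#'   thresholds are fitted on ROI pixels only and the masks are clipped to
#'   the ROI. Default: the full frame.
#' @param sampleId,imageId optional identifiers.
#' @return A \linkS4class{FidelityRecord}.
#' @examples
#' img <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 1), seed = 1)
#' ratios(quantifyImage(img))
#' @export
quantifyImage <- function(image, roi = NULL, sampleId = NA_character_,
                          imageId = NA_character_) {
    k14 <- getChannel(image, "KRT14")
    k19 <- getChannel(image, "KRT19")
    if (!identical(dim(k14), dim(k19)))
        stop("KRT14 and KRT19 channels must have identical shape")
    if (is(roi, "BinaryMask")) roi <- roi@pixels
    if (is.null(roi)) {
        ms <- computeMaskSet(autoThreshold(k14), autoThreshold(k19))
    } else {
        if (!identical(dim(roi), dim(k14)))
            stop("roi must match the channel shape")
        thrMask <- function(ch) {
            v <- ch[roi]
            if (length(v) == 0L || diff(range(v)) == 0)
                return(matrix(FALSE, nrow(ch), ncol(ch)))
            t <- .otsu(v)$threshold
            ch > t & roi
        }
        ms <- computeMaskSet(thrMask(k14), thrMask(k19))
    }
    fidelityRatios(ms, sampleId = sampleId, imageId = imageId)
}

#' Aggregate per-image records into a per-sample summary
#'
#' Arithmetic mean of each ratio over the images where it is defined;
#' images with a missing (zero-denominator) ratio are excluded from that
#' ratio's mean only.
#'
#' @param records list of \linkS4class{FidelityRecord}.
#' @param sampleId sample identifier for the summary row.
#' @return A one-row data.frame: \code{sample_id}, \code{n_images}, mean
#'   \code{r_lep}, \code{r_all}, \code{r_mep}, and per-ratio image counts
#'   \code{n_lep}, \code{n_all}, \code{n_mep}. A ratio undefined in every
#'   image is \code{NA}.
#' @examples
#' r1 <- fidelityRatios(MaskSet(10, 10, 2))
#' r2 <- fidelityRatios(MaskSet(10, 10, 4))
#' aggregateSample(list(r1, r2), "S1")
#' @export
aggregateSample <- function(records, sampleId) {
    if (length(records) == 0L) stop("need at least one record")
    m <- do.call(rbind, lapply(records, ratios))
    meanDef <- function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE)
                           else NA_real_
    data.frame(sample_id = sampleId, n_images = length(records),
               r_lep = meanDef(m[, "r_lep"]), r_all = meanDef(m[, "r_all"]),
               r_mep = meanDef(m[, "r_mep"]),
               n_lep = sum(!is.na(m[, "r_lep"])),
               n_all = sum(!is.na(m[, "r_all"])),
               n_mep = sum(!is.na(m[, "r_mep"])))
}

#' Quantify a whole synthetic cohort
#'
#' Convenience wrapper: runs \code{\link{quantifyImage}} on every image of
#' every sample of a generated cohort and aggregates per sample.
#'
#' @param cohort the list returned by \code{\link{generateTissueCohort}}
#'   (rendered).
#' @return A list with \code{$images} (per-image data.frame of areas,
#'   ratios and ids) and \code{$samples} (per-sample summary data.frame
#'   joined with the sample metadata).
#' @export
quantifyCohort <- function(cohort) {
    perImage <- list(); perSample <- list()
    for (s in cohort) {
        sid <- s$metadata$sample_id
        recs <- lapply(seq_along(s$images), function(j) {
            quantifyImage(s$images[[j]], sampleId = sid,
                          imageId = sprintf("%s_I%02d", sid, j))
        })
        perImage[[sid]] <- do.call(rbind, lapply(recs, function(r) {
            a <- maskAreas(r@maskSet)
            data.frame(sample_id = r@sampleId, image_id = r@imageId,
                       a14 = a["a14"], a19 = a["a19"], a_and = a["a_and"],
                       a_or = a["a_or"], r_lep = r@rLep, r_all = r@rAll,
                       r_mep = r@rMep, row.names = NULL)
        }))
        perSample[[sid]] <- cbind(aggregateSample(recs, sid)[, -1],
                                  s$metadata)
    }
    imgs <- do.call(rbind, perImage); rownames(imgs) <- NULL
    smp <- do.call(rbind, perSample); rownames(smp) <- NULL
    list(images = imgs, samples = smp)
}

#' Nonparametric comparison of a per-sample metric between groups
#'
#' Two groups are compared by the two-sided Mann-Whitney U-test; three or
#' more by the Kruskal-Wallis test followed by Dunn pairwise z-tests with
#' Bonferroni adjustment. The comparison runs on per-sample means, one
#' value per sample.
#'
#' @param summaries data.frame of per-sample summaries (as from
#'   \code{\link{quantifyCohort}}), or a numeric vector of metric values.
#' @param grouping group labels, one per row/value.
#' @param metric column name of the compared metric (ignored when
#'   \code{summaries} is a vector).
#' @return A \linkS4class{GroupComparison}.
#' @examples
#' compareGroups(c(0.30, 0.31, 0.29, 0.05, 0.07, 0.06),
#'               rep(c("HR", "AR"), each = 3))
#' @export
compareGroups <- function(summaries, grouping, metric = "r_lep") {
    values <- if (is.data.frame(summaries)) summaries[[metric]]
              else as.numeric(summaries)
    if (length(values) != length(grouping))
        stop("grouping must have one label per sample")
    groups <- split(values, grouping)
    if (length(groups) < 2L) stop("need at least two groups")
    allMissing <- names(groups)[vapply(groups, function(g) all(is.na(g)),
                                       logical(1))]
    if (length(allMissing))
        stop("metric '", metric, "' is missing for every sample in group(s): ",
             paste(allMissing, collapse = ", "))
    groups <- lapply(groups, function(g) g[!is.na(g)])
    if (length(groups) == 2L) {
        omnibus <- mannWhitney(groups[[1]], groups[[2]])
        pw <- data.frame()
    } else {
        g <- factor(rep(names(groups), lengths(groups)),
                    levels = names(groups))
        v <- unlist(groups, use.names = FALSE)
        kw <- stats::kruskal.test(v, g)
        omnibus <- new("TestResult", test = "Kruskal-Wallis",
                       statistic = c(H = unname(kw$statistic)),
                       df = unname(kw$parameter), pValue = kw$p.value,
                       method = "chi-square approximation")
        pw <- dunnPosthoc(v, g)
    }
    new("GroupComparison", metric = metric, groups = groups,
        omnibus = omnibus, pairwise = pw)
}

#' Spearman correlation of a per-sample metric with age
#'
#' @param values per-sample metric values.
#' @param ages paired ages (years).
#' @return A \linkS4class{TestResult} with Spearman's rho and a two-sided
#'   p-value; constant input is flagged undefined and carries no p-value.
#' @examples
#' ageCorrelation(c(1, 2, 3, 5), c(30, 40, 50, 62))
#' @export
ageCorrelation <- function(values, ages) {
    keep <- !is.na(values) & !is.na(ages)
    spearmanTest(values[keep], ages[keep])
}
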