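## Single-cell differentiation readout: marker-based watershed segmentation,
## per-cell intensity measurement, four-state gating and chi-square
## comparison of state distributions.

#' Marker-based watershed segmentation of colony images
#'
#' Thresholds the nuclei channel (Otsu), turns distance-transform maxima of
#' the nuclear mask into seeds, and expands the seeds over the combined
#' keratin signal (seeded propagation restricted to the cell mask). Labels
#' are positive integers; background is 0.
#'
#' @param image a \linkS4class{LabeledImage}, H x W x 3 array, or named
#'   list with \code{nuclei}, \code{KRT14}, \code{KRT19} matrices.
#' @return Integer label matrix; a blank nuclei channel yields an all-zero
#'   labeling with a warning.
#' @examples
#' img <- generateColonyImage(colonyPreset("AR-day2", nCells = 5,
#'                            imageSize = c(192, 192), minCellSpacing = 40),
#'                            seed = 1)
#' max(segmentCells(img))  # 5
#' @export
segmentCells <- function(image) {
    nuc <- getChannel(image, "nuclei")
    k14 <- getChannel(image, "KRT14")
    k19 <- getChannel(image, "KRT19")
    nmask <- autoThreshold(nuc)
    if (nmask@degenerate || maskArea(nmask) == 0L) {
        warning("blank nuclei channel: no cells segmented")
        return(matrix(0L, nrow(nuc), ncol(nuc)))
    }
    dm <- EBImage::distmap(nmask@pixels * 1)
    seeds <- EBImage::watershed(dm)
    combined <- k14 + k19
    cmask <- autoThreshold(combined)
    cellMask <- cmask@pixels | nmask@pixels
    labels <- EBImage::propagate(combined, seeds = seeds, mask = cellMask)
    storage.mode(labels) <- "integer"
    matrix(labels, nrow(nuc), ncol(nuc))
}

#' Per-cell mean keratin intensities
#'
#' @param labels integer label matrix (0 = background).
#' @param image the image the labels came from (any form accepted by
#'   \code{\link{segmentCells}}).
#' @return A data.frame with one row per positive label: \code{cell_id},
#'   \code{mean_krt14}, \code{mean_krt19}, \code{area} (pixels).
#'   Background pixels contribute to no row.
#' @export
measureCells <- function(labels, image) {
    k14 <- getChannel(image, "KRT14")
    k19 <- getChannel(image, "KRT19")
    if (!identical(dim(labels), dim(k14)))
        stop("labels and channels must have identical shape")
    keep <- labels > 0L
    if (!any(keep))
        return(data.frame(cell_id = integer(), mean_krt14 = numeric(),
                          mean_krt19 = numeric(), area = integer()))
    f <- factor(labels[keep], levels = sort(unique(labels[keep])))
    data.frame(cell_id = as.integer(levels(f)),
               mean_krt14 = as.numeric(tapply(k14[keep], f, mean)),
               mean_krt19 = as.numeric(tapply(k19[keep], f, mean)),
               area = as.integer(table(f)), row.names = NULL)
}

## Otsu split of a continuous vector on the log scale; returns the
## threshold (raw scale) and the explained-variance fraction.
.logOtsu <- function(v) {
    lv <- log(v + 1)
    o <- .otsu(lv)
    list(threshold = if (is.na(o$threshold)) NA_real_
                     else exp(o$threshold) - 1,
         explained = o$explained)
}

#' Fit per-channel intensity gates
#'
#' Per keratin channel, an Otsu threshold on log-transformed per-cell mean
#' intensities separates the "low" and "high" expression modes. If the
#' optimal split explains less than half of the channel's variance (the
#' distribution is effectively unimodal), the gate falls back to the 75th
#' percentile and the fallback flag is set for that channel.
#'
#' @param table a CellIntensityTable data.frame (columns \code{mean_krt14},
#'   \code{mean_krt19}); at least 20 cells.
#' @return A \linkS4class{GateThresholds}.
#' @examples
#' gc <- generateColonyCells(colonyPreset("AR-day2", nCells = 200), seed = 1)
#' fitGates(gc$cells)
#' @export
fitGates <- function(table) {
    if (!all(c("mean_krt14", "mean_krt19") %in% names(table)))
        stop("table must have mean_krt14 and mean_krt19 columns")
    if (nrow(table) < 20L)
        stop("need at least 20 cells to fit gates (got ", nrow(table), ")")
    fit1 <- function(v) {
        o <- .logOtsu(v)
        if (is.na(o$threshold) || o$explained < 0.5)
            list(t = as.numeric(stats::quantile(v, 0.75)), fallback = TRUE)
        else list(t = o$threshold, fallback = FALSE)
    }
    f14 <- fit1(table$mean_krt14)
    f19 <- fit1(table$mean_krt19)
    new("GateThresholds", t14 = f14$t, t19 = f19$t,
        method = "otsu-log, 75th-percentile fallback",
        fallback = c(KRT14 = f14$fallback, KRT19 = f19$fallback))
}

#' Classify cells into the four differentiation states
#'
#' A cell at or above a gate is positive for that keratin (values equal to
#' the gate count as positive). Below both gates: undifferentiated; KRT14
#' only: K14_only; KRT19 only: K19_only; both: double_positive.
#'
#' @param table a CellIntensityTable data.frame.
#' @param gates a \linkS4class{GateThresholds}.
#' @return The input data.frame with an added \code{state} factor column.
#' @examples
#' g <- new("GateThresholds", t14 = 100, t19 = 100)
#' classifyStates(data.frame(cell_id = 1:2, mean_krt14 = c(50, 150),
#'                           mean_krt19 = c(50, 150)), g)$state
#' @export
classifyStates <- function(table, gates) {
    stopifnot(is(gates, "GateThresholds"))
    validObject(gates)
    pos14 <- table$mean_krt14 >= gates@t14
    pos19 <- table$mean_krt19 >= gates@t19
    state <- ifelse(pos14 & pos19, "double_positive",
             ifelse(pos14, "K14_only",
             ifelse(pos19, "K19_only", "undifferentiated")))
    table$state <- factor(state, levels = STATE_LEVELS)
    table
}

#' State distribution of a classified cell table
#'
#' @param states a CellStateTable data.frame (with a \code{state} column)
#'   or a factor of states.
#' @return A \linkS4class{StateDistribution}.
#' @examples
#' sd <- stateDistribution(factor(c("K14_only", "K14_only",
#'                                  "undifferentiated"),
#'                         levels = c("undifferentiated", "K14_only",
#'                                    "K19_only", "double_positive")))
#' stateProps(sd)
#' @export
stateDistribution <- function(states) {
    s <- if (is.data.frame(states)) states$state else states
    if (length(s) == 0L) stop("empty table has no state distribution")
    s <- factor(s, levels = STATE_LEVELS)
    if (anyNA(s)) stop("unknown state labels present")
    counts <- table(s)
    new("StateDistribution",
        counts = structure(as.integer(counts), names = STATE_LEVELS),
        nCells = length(s))
}

#' Chi-square comparison of state distributions
#'
#' Stacks the count vectors into a contingency table, drops all-zero
#' columns and applies the Pearson chi-square test without continuity
#' correction. Expected counts below 5 set a warning flag; tables
#' degenerate after dropping (e.g. both groups in one identical state) are
#' flagged not testable with df 0.
#'
#' @param a,b \linkS4class{StateDistribution} objects (or further
#'   distributions via \code{...} for a k-group comparison).
#' @param ... additional \code{StateDistribution} objects.
#' @return A \linkS4class{TestResult}; \code{extra$observed} holds the
#'   contingency used.
#' @examples
#' x <- stateDistribution(factor(rep(c("K14_only", "K19_only"), c(20, 10)),
#'                        levels = c("undifferentiated", "K14_only",
#'                                   "K19_only", "double_positive")))
#' y <- stateDistribution(factor(rep(c("K14_only", "K19_only"), c(10, 20)),
#'                        levels = names(stateCounts(x))))
#' compareDistributions(x, y)
#' @export
compareDistributions <- function(a, b, ...) {
    dists <- c(list(a, b), list(...))
    stopifnot(all(vapply(dists, is, logical(1), "StateDistribution")))
    counts <- do.call(rbind, lapply(dists, stateCounts))
    rownames(counts) <- paste0("group", seq_len(nrow(counts)))
    chiSquareIndependence(counts)
}

#' Run the full differentiation readout on a colony image
#'
#' Convenience composition: segment, measure, gate, classify, and tabulate.
#'
#' @param image a rendered colony \linkS4class{LabeledImage}.
#' @param gates optional precomputed \linkS4class{GateThresholds}; fitted
#'   from the measured cells when missing.
#' @return A list with \code{$cells} (CellStateTable data.frame),
#'   \code{$gates} and \code{$distribution}
#'   (\linkS4class{StateDistribution}).
#' @export
differentiationReadout <- function(image, gates = NULL) {
    labels <- segmentCells(image)
    cells <- measureCells(labels, image)
    if (is.null(gates)) gates <- fitGates(cells)
    cells <- classifyStates(cells, gates)
    list(cells = cells, gates = gates,
         distribution = stateDistribution(cells))
}
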