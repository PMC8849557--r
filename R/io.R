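## File interchange: multipage 16-bit TIFF for images (page order nuclei,
## KRT14, KRT19), single-page TIFF for label rasters, CSV for tables.

TIFF_MAX <- 65535

#' Write and read synthetic images as TIFF
#'
#' Images are written as multipage 16-bit TIFF with one page per channel in
#' the order nuclei, KRT14, KRT19; intensities are scaled by
#' \code{maxIntensity} into the 16-bit range. Label rasters go to a
#' separate single-page TIFF and the truth table to CSV alongside.
#'
#' @param image a rendered \linkS4class{LabeledImage}.
#' @param path output TIFF path; \code{<path>_labels.tif} and
#'   \code{<path>_truth.csv} are written next to it.
#' @param maxIntensity intensity mapped to the top of the 16-bit range.
#' @return \code{writeLabeledImage}: the main path, invisibly;
#'   \code{readMultichannelTIFF}: an H x W x 3 named channel array.
#' @export
writeLabeledImage <- function(image, path, maxIntensity = 4096) {
    stopifnot(is(image, "LabeledImage"))
    if (length(image@channels) == 0L)
        stop("cannot write a truth-only LabeledImage")
    pages <- lapply(c("nuclei", "KRT14", "KRT19"), function(ch)
        pmin(image@channels[, , ch] / maxIntensity, 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    base <- sub("\\.tiff?$", "", path)
    tiff::writeTIFF(image@cellLabels / TIFF_MAX,
                    paste0(base, "_labels.tif"), bits.per.sample = 16L)
    utils::write.csv(image@truth, paste0(base, "_truth.csv"),
                     row.names = FALSE)
    invisible(path)
}

#' @rdname writeLabeledImage
#' @param scale multiply intensities read back (inverse of the write
#'   scaling).
#' @export
readMultichannelTIFF <- function(path, scale = 4096) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 3L)
        stop("expected a 3-page TIFF (nuclei, KRT14, KRT19); got ",
             length(pages), " page(s)")
    ch <- array(0, c(dim(pages[[1]]), 3L),
                dimnames = list(NULL, NULL, c("nuclei", "KRT14", "KRT19")))
    for (i in 1:3) ch[, , i] <- pages[[i]] * scale
    ch
}

#' Serialize a TestResult or OverlapResult to a JSON-ready list
#'
#' @param x a \linkS4class{TestResult} or \linkS4class{OverlapResult}.
#' @return A plain list suitable for \code{jsonlite::write_json}.
#' @export
resultAsList <- function(x) {
    if (is(x, "TestResult"))
        return(list(test = x@test, statistic = as.list(x@statistic),
                    df = x@df, p = x@pValue, method = x@method,
                    warnings = x@warnings))
    if (is(x, "OverlapResult"))
        return(list(table = as.vector(t(x@table)),
                    odds_ratio = x@oddsRatio, log2_or = x@log2OR,
                    p_one_sided = x@pValue, flags = x@flags))
    stop("unsupported class: ", class(x)[1])
}
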