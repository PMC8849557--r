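## Gene-signature construction from DE tables and Fisher one-sided
## overlap odds-ratio statistics.

.checkDETable <- function(de) {
    need <- c("gene", "log2fc", "p")
    miss <- setdiff(need, names(de))
    if (length(miss))
        stop("DE table is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(de$gene)) stop("DE table genes must be unique")
    if (!"padj" %in% names(de)) de$padj <- bhAdjust(de$p)
    de
}

#' Lineage-specific gene signature from a DE table
#'
#' Selects genes at least \code{min_fold}-fold upregulated
#' (\code{log2fc >= log2(min_fold)}, inclusive) with BH-adjusted
#' \code{padj < alpha} (strict).
#'
#' @param de data.frame with columns \code{gene}, \code{log2fc}, \code{p}
#'   and optionally \code{padj} (computed by \code{\link{bhAdjust}} when
#'   absent).
#' @param min_fold minimum fold change (default 2).
#' @param alpha BH-adjusted p cutoff (default 0.001).
#' @param name name for the resulting set.
#' @return A \linkS4class{GeneSet} whose provenance records the filter.
#' @examples
#' de <- data.frame(gene = paste0("g", 1:3), log2fc = c(3, 1, 0.5),
#'                  p = 1e-6, padj = 1e-5)
#' geneIds(lineageSpecificGenes(de))
#' @export
lineageSpecificGenes <- function(de, min_fold = 2, alpha = 0.001,
                                 name = "lineage_specific") {
    de <- .checkDETable(de)
    sel <- de$log2fc >= log2(min_fold) & de$padj < alpha
    GeneSet(name, de$gene[sel],
            provenance = sprintf(
                "log2fc >= log2(%g) and BH padj < %g (%d of %d genes)",
                min_fold, alpha, sum(sel), nrow(de)))
}

#' Aging gene signature from a DE table
#'
#' Selects upregulated genes (\code{log2fc > 0}) with BH-adjusted
#' \code{padj < alpha} (strict).
#'
#' @inheritParams lineageSpecificGenes
#' @param alpha BH-adjusted p cutoff (default 0.05).
#' @return A \linkS4class{GeneSet}.
#' @export
agingSignature <- function(de, alpha = 0.05, name = "aging_signature") {
    de <- .checkDETable(de)
    sel <- de$log2fc > 0 & de$padj < alpha
    GeneSet(name, de$gene[sel],
            provenance = sprintf(
                "upregulated with BH padj < %g (%d of %d genes)",
                alpha, sum(sel), nrow(de)))
}

.asGenes <- function(x) if (is(x, "GeneSet")) x@genes else unique(as.character(x))

#' One-sided gene-set overlap test
#'
#' Builds the 2x2 membership contingency of sets A and B within the
#' universe, reports the sample odds ratio \code{(a d)/(b c)}, its log2,
#' and the one-sided Fisher p-value (hypergeometric upper tail
#' \code{P(X >= a)} with \code{X ~ Hypergeom(N = |U|, K = |A|, n = |B|)}).
#' A zero \code{b c} with positive \code{a d} is flagged infinite unless
#' the Haldane correction (+0.5 to every cell) is enabled.
#'
#' @param A,B \linkS4class{GeneSet} objects or character vectors; both
#'   must be subsets of \code{universe}.
#' @param universe the gene universe (\code{GeneSet} or character).
#' @param haldane apply the Haldane +0.5 correction when \code{b} or
#'   \code{c} is zero (default off).
#' @return An \linkS4class{OverlapResult}.
#' @examples
#' u <- paste0("g", 1:1277)
#' r <- overlapTest(u[1:177], u[c(1:77, 178:277)], u)
#' oddsRatio(r)  # 7.7
#' @export
overlapTest <- function(A, B, universe, haldane = FALSE) {
    gA <- .asGenes(A); gB <- .asGenes(B); gU <- .asGenes(universe)
    badA <- setdiff(gA, gU); badB <- setdiff(gB, gU)
    if (length(badA) || length(badB))
        stop("sets must be subsets of the universe; offenders: ",
             paste(utils::head(c(badA, badB), 10), collapse = ", "))
    a <- length(intersect(gA, gB))
    b <- length(gA) - a
    c <- length(gB) - a
    d <- length(gU) - a - b - c
    tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                  dimnames = list(c("inA", "notA"), c("inB", "notB")))
    flags <- character()
    if (b * c > 0) {
        or <- (a * d) / (b * c)
    } else if (a * d > 0) {
        if (haldane) {
            or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
            flags <- "haldane_corrected"
        } else {
            or <- Inf
            flags <- "infinite_or"
        }
    } else {
        if (haldane) {
            or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
            flags <- "haldane_corrected"
        } else {
            or <- NaN
            flags <- "undefined_or"
        }
    }
    p <- pValue(fisherGreater(a, b, c, d))
    new("OverlapResult", table = tab, oddsRatio = or,
        log2OR = log2(or), pValue = p, flags = flags)
}

#' Matrix of pairwise overlap tests
#'
#' Runs \code{\link{overlapTest}} for every (row set, column set) pair.
#'
#' @param rowSets,colSets lists of \linkS4class{GeneSet} (or character
#'   vectors); names become the matrix dimnames.
#' @param universe the shared gene universe.
#' @param haldane passed to \code{\link{overlapTest}}.
#' @return An \linkS4class{OverlapMatrix} with p-value and log2(OR)
#'   matrices.
#' @export
overlapMatrix <- function(rowSets, colSets, universe, haldane = FALSE) {
    rn <- names(rowSets)
    if (is.null(rn)) rn <- paste0("row", seq_along(rowSets))
    cn <- names(colSets)
    if (is.null(cn)) cn <- paste0("col", seq_along(colSets))
    res <- list()
    p <- matrix(NA_real_, length(rowSets), length(colSets),
                dimnames = list(rn, cn))
    l2 <- p
    for (j in seq_along(colSets)) for (i in seq_along(rowSets)) {
        r <- overlapTest(rowSets[[i]], colSets[[j]], universe,
                         haldane = haldane)
        res[[length(res) + 1L]] <- r
        p[i, j] <- pValue(r)
        l2[i, j] <- log2OR(r)
    }
    new("OverlapMatrix", pValues = p, log2OR = l2, results = res)
}

#' Read and write GMT gene-set files
#'
#' \code{readGMT} parses a tab-separated GMT file (name, description,
#' genes...) into a named list of \linkS4class{GeneSet}; \code{writeGMT}
#' writes a list of sets (the provenance note becomes the description
#' field).
#'
#' @param path file path.
#' @param sets list of \linkS4class{GeneSet}.
#' @return \code{readGMT}: a named list of \code{GeneSet};
#'   \code{writeGMT}: the path, invisibly.
#' @export
readGMT <- function(path) {
    sets <- fgsea::gmtPathways(path)
    lapply(stats::setNames(names(sets), names(sets)),
           function(n) GeneSet(n, sets[[n]]))
}

#' @rdname readGMT
#' @export
writeGMT <- function(sets, path) {
    lines <- vapply(sets, function(s) {
        desc <- if (nzchar(s@provenance)) s@provenance else "na"
        paste(c(s@name, desc, s@genes), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
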