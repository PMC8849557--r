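## Synthetic DE tables with planted effects, and the deterministic inverse
## of the overlap test (gene-list pairs realising a chosen 2x2 table).

#' Generate a synthetic differential-expression table
#'
#' Plants \code{fracUp}/\code{fracDown} of genes at \code{+/- effectLog2fc}
#' with small p-values (Uniform(0, plantedPMax)); null genes draw
#' \code{log2fc ~ Normal(0, nullLog2fcSd)} and \code{p ~ Uniform(0, 1)}.
#' BH-adjusted p-values are included. Same \code{(spec, seed)}: identical
#' table.
#'
#' @param spec a \linkS4class{DETableSpec}.
#' @param seed integer seed.
#' @return A data.frame with columns \code{gene}, \code{log2fc}, \code{p},
#'   \code{padj}, \code{planted} (\code{"up"}, \code{"down"} or
#'   \code{"null"}).
#' @examples
#' de <- generateDETable(DETableSpec(nGenes = 500), seed = 1)
#' table(de$planted)
#' @export
generateDETable <- function(spec, seed) {
    stopifnot(is(spec, "DETableSpec"))
    validObject(spec)
    withSeed(seed, {
        n <- spec@nGenes
        nUp <- round(spec@fracUp * n)
        nDown <- round(spec@fracDown * n)
        status <- rep("null", n)
        planted <- sample.int(n, nUp + nDown)
        status[planted[seq_len(nUp)]] <- "up"
        if (nDown > 0) status[planted[nUp + seq_len(nDown)]] <- "down"
        lfc <- stats::rnorm(n, 0, spec@nullLog2fcSd)
        lfc[status == "up"] <- spec@effectLog2fc
        lfc[status == "down"] <- -spec@effectLog2fc
        p <- stats::runif(n)
        isPlanted <- status != "null"
        p[isPlanted] <- stats::runif(sum(isPlanted), 0, spec@plantedPMax)
        data.frame(gene = sprintf("gene%05d", seq_len(n)), log2fc = lfc,
                   p = p, padj = bhAdjust(p), planted = status)
    })
}

#' Construct gene lists realising a 2x2 contingency table
#'
#' Deterministic inverse of \code{\link{overlapTest}}: builds synthetic
#' gene sets A (size a+b), B (size a+c) with |A and B| = a inside a
#' universe of size a+b+c+d.
#'
#' @param a,b,c,d nonnegative cell counts (overlap, A-only, B-only,
#'   neither); \code{a} may be a length-4 vector.
#' @return A list with \code{GeneSet} elements \code{A}, \code{B},
#'   \code{universe}.
#' @examples
#' l <- constructOverlapLists(50, 50, 100, 2500)
#' oddsRatio(overlapTest(l$A, l$B, l$universe))  # 25
#' @export
constructOverlapLists <- function(a, b = NULL, c = NULL, d = NULL) {
    if (length(a) == 4L && is.null(b)) {
        d <- a[4]; c <- a[3]; b <- a[2]; a <- a[1]
    }
    cells <- c(a, b, c, d)
    if (any(!is.finite(cells)) || any(cells < 0) ||
        any(cells != round(cells)))
        stop("all four cells must be nonnegative integers")
    N <- sum(cells)
    genes <- sprintf("gene%06d", seq_len(N))
    A <- genes[seq_len(a + b)]
    B <- c(genes[seq_len(a)], genes[a + b + seq_len(c)])
    list(A = GeneSet("setA", A, "constructed"),
         B = GeneSet("setB", B, "constructed"),
         universe = GeneSet("universe", genes, "constructed"))
}
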