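## Nonparametric statistics used throughout the pipeline, implemented with
## exact small-sample branches. Base R equivalents (wilcox.test, p.adjust,
## chisq.test, fisher.test, cor.test) serve as independent cross-checks in
## the test suite.

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, computes \code{q_i = p_i * m / i}, enforces
#' monotonicity from the largest rank downwards, caps at 1 and restores the
#' original order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    if (m <= 1L) return(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    q
}

#' One-sided Fisher's exact test (alternative = greater)
#'
#' For a 2x2 table (a, b, c, d), computes the hypergeometric upper tail
#' P(X >= a) with X ~ Hypergeom(N = a+b+c+d, K = a+b, n = a+c), i.e. the
#' probability of an overlap at least as large as observed with all margins
#' fixed. Evaluated through the log-scale hypergeometric distribution
#' function for numerical stability.
#'
#' @param a,b,c,d nonnegative cell counts, or \code{a} may be a 2x2 matrix.
#' @return A \linkS4class{TestResult} (statistic: the observed overlap a).
#' @examples
#' pValue(fisherGreater(2, 0, 0, 2))  # 1/6
#' @export
fisherGreater <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is.matrix(a)) {
        stopifnot(all(dim(a) == 2L))
        d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
    }
    cells <- c(a, b, c, d)
    if (any(!is.finite(cells)) || any(cells < 0) ||
        any(cells != round(cells)))
        stop("cells must be nonnegative integers")
    K <- a + b; n <- a + c; N <- sum(cells)
    p <- if (a == 0) 1
         else exp(stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE,
                                log.p = TRUE))
    new("TestResult", test = "Fisher exact (greater)",
        statistic = c(a = a), df = NA_real_, pValue = min(1, p),
        method = "hypergeometric upper tail, exact",
        extra = list(table = matrix(cells, 2, 2, byrow = TRUE)))
}

## Exact Mann-Whitney U tail by enumeration of all group assignments.
.mwExactCdf <- function(n1, n2, u) {
    idx <- utils::combn(n1 + n2, n1)
    ranks <- matrix(idx, nrow = n1)
    U <- colSums(ranks) - n1 * (n1 + 1) / 2
    mean(U <= u)
}

#' Two-sided Mann-Whitney U-test
#'
#' Exact p by enumeration of all rank assignments when both groups have at
#' most 8 observations and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction. Both U
#' conventions are reported (U of the first group and min(U1, U2)).
#'
#' @param x,y numeric vectors (nonempty).
#' @return A \linkS4class{TestResult} with statistics \code{U1}, \code{U2},
#'   \code{U = min(U1, U2)}.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
mannWhitney <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) == 0L || length(y) == 0L)
        stop("both groups must be nonempty")
    if (any(!is.finite(c(x, y)))) stop("values must be finite")
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    U2 <- n1 * n2 - U1
    ties <- anyDuplicated(pooled) > 0L
    if (!ties && n1 <= 8L && n2 <= 8L) {
        pl <- .mwExactCdf(n1, n2, min(U1, U2))
        p <- min(1, 2 * pl)
        method <- "exact enumeration"
    } else {
        N <- n1 + n2
        tt <- table(pooled)
        tieTerm <- sum(tt^3 - tt) / (N * (N - 1))
        sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm)
        if (sigma2 <= 0) {
            p <- 1
            method <- "degenerate (all values tied)"
        } else {
            z <- (abs(U1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
            z <- max(0, z)
            p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
            method <- "normal approximation, tie and continuity corrected"
        }
    }
    new("TestResult", test = "Mann-Whitney U",
        statistic = c(U1 = U1, U2 = U2, U = min(U1, U2)),
        df = NA_real_, pValue = p, method = method,
        warnings = if (ties) "ties present" else character())
}

#' Pearson chi-square test of independence
#'
#' Expected counts from the margins, statistic sum((O-E)^2/E), no
#' continuity correction. All-zero rows and columns are dropped first; a
#' table degenerate after dropping (fewer than two rows or columns) is
#' flagged not testable. Any expected count below 5 sets a warning flag.
#'
#' @param counts nonnegative count matrix.
#' @return A \linkS4class{TestResult} with the statistic, df and p-value;
#'   \code{extra$expected} holds the expected counts.
#' @examples
#' chiSquareIndependence(matrix(c(20, 10, 10, 20), 2))  # X2 = 6.667
#' @export
chiSquareIndependence <- function(counts) {
    counts <- as.matrix(counts)
    if (any(!is.finite(counts)) || any(counts < 0))
        stop("counts must be nonnegative and finite")
    keepR <- rowSums(counts) > 0
    keepC <- colSums(counts) > 0
    O <- counts[keepR, keepC, drop = FALSE]
    if (nrow(O) < 2L || ncol(O) < 2L)
        return(new("TestResult", test = "chi-square independence",
                   statistic = c(X2 = NA_real_), df = 0, pValue = NA_real_,
                   method = "not testable (degenerate table)",
                   warnings = "not_testable"))
    n <- sum(O)
    E <- outer(rowSums(O), colSums(O)) / n
    stat <- sum((O - E)^2 / E)
    df <- (nrow(O) - 1) * (ncol(O) - 1)
    warn <- if (any(E < 5)) "expected count < 5" else character()
    new("TestResult", test = "chi-square independence",
        statistic = c(X2 = stat), df = df,
        pValue = stats::pchisq(stat, df, lower.tail = FALSE),
        method = "Pearson, no continuity correction",
        warnings = warn, extra = list(expected = E, observed = O))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the two-sided p-value uses
#' the t approximation \code{t = rho * sqrt((n-2)/(1-rho^2))} with n-2 df.
#' Perfectly monotone pairings report p = 0 with an exact-monotone note;
#' constant input is flagged undefined.
#'
#' @param x,y paired numeric vectors.
#' @return A \linkS4class{TestResult} with statistic \code{rho}.
#' @examples
#' spearmanTest(c(1, 2, 3, 4), c(10, 30, 20, 40))
#' @export
spearmanTest <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) != length(y)) stop("x and y must be paired")
    n <- length(x)
    if (n < 2L || stats::var(x) == 0 || stats::var(y) == 0)
        return(new("TestResult", test = "Spearman correlation",
                   statistic = c(rho = NA_real_), df = NA_real_,
                   pValue = NA_real_, method = "undefined (constant input)",
                   warnings = "undefined"))
    rho <- stats::cor(rank(x), rank(y))
    if (n < 4L)
        return(new("TestResult", test = "Spearman correlation",
                   statistic = c(rho = rho), df = NA_real_,
                   pValue = NA_real_,
                   method = "n < 4: no p-value reported",
                   warnings = "too_few_pairs"))
    if (abs(rho) >= 1 - 1e-12)
        return(new("TestResult", test = "Spearman correlation",
                   statistic = c(rho = sign(rho)), df = n - 2, pValue = 0,
                   method = "exact monotone pairing"))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    new("TestResult", test = "Spearman correlation",
        statistic = c(rho = rho, t = tstat), df = n - 2,
        pValue = 2 * stats::pt(-abs(tstat), n - 2),
        method = "t approximation, two-sided")
}

#' Dunn's pairwise post-hoc test
#'
#' Pairwise z-tests on mean midranks after a Kruskal-Wallis omnibus test,
#' with tie-corrected variance and Bonferroni adjustment over all pairs.
#'
#' @param values numeric vector of observations.
#' @param groups factor of group labels, one per observation.
#' @return A data.frame with columns \code{group1}, \code{group2}, \code{z},
#'   \code{p}, \code{p_adj}.
#' @examples
#' dunnPosthoc(c(1, 2, 3, 7, 8, 9, 4, 5, 6),
#'             factor(rep(c("a", "b", "c"), each = 3)))
#' @export
dunnPosthoc <- function(values, groups) {
    groups <- as.factor(groups)
    r <- rank(values)
    N <- length(values)
    tt <- table(values)
    tieCorr <- sum(tt^3 - tt) / (12 * (N - 1))
    meanR <- tapply(r, groups, mean)
    ni <- tabulate(groups)
    lv <- levels(groups)
    pairs <- utils::combn(length(lv), 2)
    res <- vapply(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]; j <- pairs[2, k]
        se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ni[i] + 1 / ni[j]))
        z <- unname((meanR[i] - meanR[j]) / se)
        c(z, 2 * stats::pnorm(-abs(z)))
    }, numeric(2))
    out <- data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
                      z = res[1, ], p = res[2, ])
    out$p_adj <- pmin(1, out$p * ncol(pairs))
    out
}
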