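## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
        seed != round(seed))
        stop("seed must be a single integer")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Paint a filled disk of `value` into matrix `m` (1-based row/col center).
## Returns the modified matrix. Pixels belong to the disk when their center
## lies within `radius` of (cy, cx).
paintDisk <- function(m, cy, cx, radius, value) {
    r0 <- max(1L, floor(cy - radius)); r1 <- min(nrow(m), ceiling(cy + radius))
    c0 <- max(1L, floor(cx - radius)); c1 <- min(ncol(m), ceiling(cx + radius))
    if (r0 > r1 || c0 > c1) return(m)
    rows <- r0:r1; cols <- c0:c1
    dd <- outer((rows - cy)^2, (cols - cx)^2, "+")
    sel <- dd <= radius^2
    sub <- m[rows, cols, drop = FALSE]
    sub[sel] <- value
    m[rows, cols] <- sub
    m
}

## Largest-remainder apportionment of n items to weights (sum 1).
apportion <- function(n, weights) {
    raw <- n * weights
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

## Assemble a LabeledImage from painted channel matrices.
newLabeledImage <- function(nuclei, krt14, krt19, labels, truth) {
    ch <- array(c(nuclei, krt14, krt19),
                dim = c(dim(nuclei), 3L),
                dimnames = list(NULL, NULL, c("nuclei", "KRT14", "KRT19")))
    new("LabeledImage", channels = ch,
        cellLabels = labels, truth = truth)
}

## Extract a named channel matrix from a LabeledImage / array / named list.
getChannel <- function(x, name) {
    if (is(x, "LabeledImage")) {
        if (length(x@channels) == 0L)
            stop("LabeledImage was generated truth-only (no channels)")
        return(x@channels[, , name])
    }
    if (is.array(x) && length(dim(x)) == 3L) {
        nms <- dimnames(x)[[3]]
        if (is.null(nms) || !name %in% nms)
            stop("channel '", name, "' not found in array")
        return(x[, , name])
    }
    if (is.list(x)) {
        if (!name %in% names(x))
            stop("channel '", name, "' not found in list")
        return(x[[name]])
    }
    stop("cannot extract channel from object of class ", class(x)[1])
}
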