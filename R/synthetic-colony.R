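## Synthetic progenitor-colony cells and images with ground-truth states.

.drawStates <- function(n, props) {
    factor(sample(STATE_LEVELS, n, replace = TRUE, prob = props),
           levels = STATE_LEVELS)
}

.drawIntensities <- function(states, model) {
    i <- as.integer(states)
    data.frame(
        mean_krt14 = stats::rlnorm(length(i), model[i, "meanlog14"],
                                   model[i, "sdlog14"]),
        mean_krt19 = stats::rlnorm(length(i), model[i, "meanlog19"],
                                   model[i, "sdlog19"]))
}

#' Generate per-cell keratin intensities for a colony experiment
#'
#' States are drawn multinomially from the spec's state proportions; each
#' cell's KRT14/KRT19 mean intensities are drawn from the state's
#' log-normal model. Identical \code{(spec, seed)} pairs give identical
#' tables.
#'
#' @param spec a \linkS4class{ColonySpec}.
#' @param seed integer seed.
#' @return A list with \code{$cells} (data.frame: cell_id, mean_krt14,
#'   mean_krt19, area) and \code{$truth} (data.frame: cell_id, state).
#' @examples
#' gc <- generateColonyCells(colonyPreset("AR-day2", nCells = 100), seed = 1)
#' table(gc$truth$state)
#' @export
generateColonyCells <- function(spec, seed) {
    stopifnot(is(spec, "ColonySpec"))
    validObject(spec)
    withSeed(seed, {
        states <- .drawStates(spec@nCells, spec@stateProportions)
        intens <- .drawIntensities(states, spec@intensityModel)
        area <- round(pi * spec@cellRadius^2)
        list(cells = data.frame(cell_id = seq_len(spec@nCells),
                                mean_krt14 = intens$mean_krt14,
                                mean_krt19 = intens$mean_krt19,
                                area = area),
             truth = data.frame(cell_id = seq_len(spec@nCells),
                                state = states))
    })
}

## Poisson-disk style placement by rejection; error after bounded retries.
.placeCells <- function(n, H, W, spacing, margin, maxTries = 5000L) {
    ys <- numeric(0); xs <- numeric(0)
    tries <- 0L
    while (length(ys) < n) {
        tries <- tries + 1L
        if (tries > maxTries)
            stop("could not place ", n, " cells at spacing ", spacing,
                 " within the canvas (placement error)")
        y <- runif(1, margin, H - margin)
        x <- runif(1, margin, W - margin)
        if (length(ys) == 0L ||
            min((ys - y)^2 + (xs - x)^2) >= spacing^2) {
            ys <- c(ys, y); xs <- c(xs, x)
        }
    }
    data.frame(y = ys, x = xs)
}

#' Render a synthetic colony image
#'
#' Disk-shaped cells with nuclear centers, placed uniformly at random with
#' a minimum center-to-center spacing; each cell's keratin disks carry its
#' drawn mean intensity. The truth table records the ground-truth state and
#' the noise-free mean intensities.
#'
#' @param spec a \linkS4class{ColonySpec}.
#' @param seed integer seed.
#' @return A \linkS4class{LabeledImage} whose truth has columns
#'   \code{cell_id}, \code{state}, \code{mean_krt14}, \code{mean_krt19},
#'   \code{y}, \code{x}.
#' @examples
#' img <- generateColonyImage(colonyPreset("AR-day2", nCells = 10,
#'                            imageSize = c(256, 256)), seed = 1)
#' img
#' @export
generateColonyImage <- function(spec, seed) {
    stopifnot(is(spec, "ColonySpec"))
    validObject(spec)
    withSeed(seed, {
        H <- spec@imageSize[1]; W <- spec@imageSize[2]
        n <- spec@nCells
        margin <- spec@cellRadius + 2
        truth <- data.frame(cell_id = integer(), state = factor(character(),
                            levels = STATE_LEVELS), mean_krt14 = numeric(),
                            mean_krt19 = numeric(), y = numeric(),
                            x = numeric())
        nuc <- matrix(spec@intensityBg, H, W)
        k14 <- matrix(spec@intensityBg, H, W)
        k19 <- matrix(spec@intensityBg, H, W)
        labels <- matrix(0L, H, W)
        if (n > 0L) {
            pos <- .placeCells(n, H, W, spec@minCellSpacing, margin)
            states <- .drawStates(n, spec@stateProportions)
            intens <- .drawIntensities(states, spec@intensityModel)
            truth <- data.frame(cell_id = seq_len(n), state = states,
                                mean_krt14 = intens$mean_krt14,
                                mean_krt19 = intens$mean_krt19,
                                y = pos$y, x = pos$x)
            nucHigh <- max(spec@intensityModel[, "meanlog14"])
            for (i in seq_len(n)) {
                k14 <- paintDisk(k14, pos$y[i], pos$x[i], spec@cellRadius,
                                 intens$mean_krt14[i])
                k19 <- paintDisk(k19, pos$y[i], pos$x[i], spec@cellRadius,
                                 intens$mean_krt19[i])
                nuc <- paintDisk(nuc, pos$y[i], pos$x[i],
                                 spec@nucleusRadius, exp(nucHigh))
                labels <- paintDisk(labels, pos$y[i], pos$x[i],
                                    spec@cellRadius, i)
            }
        }
        if (spec@noiseSd > 0) {
            nuc <- pmax(nuc + matrix(stats::rnorm(H * W, 0, spec@noiseSd),
                                     H, W), 0)
            k14 <- pmax(k14 + matrix(stats::rnorm(H * W, 0, spec@noiseSd),
                                     H, W), 0)
            k19 <- pmax(k19 + matrix(stats::rnorm(H * W, 0, spec@noiseSd),
                                     H, W), 0)
        }
        newLabeledImage(nuc, k14, k19, labels, truth)
    })
}
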