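stateFactor <- function(x, n) {
  factor(rep(c("undifferentiated", "K14_only", "K19_only",
               "double_positive"), n), levels =
           c("undifferentiated", "K14_only", "K19_only", "double_positive"))
}

test_that("watershed segmentation finds well-separated cells", {
  spec <- colonyPreset("AR-day2", nCells = 5, imageSize = c(192, 192),
                       minCellSpacing = 45)
  img <- generateColonyImage(spec, seed = 1)
  labs <- segmentCells(img)
  expect_equal(length(setdiff(unique(as.vector(labs)), 0L)), 5)
  m <- matchCentroids(labs, truthTable(img), maxDist = 10)
  expect_equal(m$tp, 5)
  blank <- generateColonyImage(ColonySpec(nCells = 0,
                                          imageSize = c(64, 64),
                                          noiseSd = 0), seed = 1)
  expect_warning(l0 <- segmentCells(blank), "blank")
  expect_true(all(l0 == 0L))
})

test_that("segmentation recall and precision reach 0.95 at 2-diameter spacing", {
  spec <- colonyPreset("HR-day7", nCells = 60, imageSize = c(512, 512),
                       minCellSpacing = 28)  # 2 cell diameters
  tp <- 0; fp <- 0; fn <- 0
  for (s in 1:3) {
    img <- generateColonyImage(spec, seed = s)
    m <- matchCentroids(segmentCells(img), truthTable(img), maxDist = 10)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  expect_gte(tp / (tp + fn), 0.95)  # recall
  expect_gte(tp / (tp + fp), 0.95)  # precision
})

test_that("touching cells with distinct nuclei are split", {
  spec <- colonyPreset("AR-day2", nCells = 2, imageSize = c(128, 128),
                       minCellSpacing = 15)  # just above nuclear diameter
  img <- generateColonyImage(spec, seed = 7)
  labs <- segmentCells(img)
  expect_equal(length(setdiff(unique(as.vector(labs)), 0L)), 2)
})

test_that("measureCells averages within labels and ignores background", {
  k14 <- matrix(5, 20, 20); k19 <- matrix(5, 20, 20)
  labs <- matrix(0L, 20, 20)
  labs[3:6, 3:6] <- 1L; k14[3:6, 3:6] <- 100; k19[3:6, 3:6] <- 40
  labs[12:15, 12:15] <- 2L; k14[12:15, 12:15] <- 7
  chans <- list(KRT14 = k14, KRT19 = k19)
  m <- measureCells(labs, chans)
  expect_equal(nrow(m), 2)
  expect_equal(m$mean_krt14, c(100, 7))
  expect_equal(m$mean_krt19[1], 40)
  expect_equal(m$area, c(16L, 16L))
  empty <- measureCells(matrix(0L, 4, 4),
                        list(KRT14 = matrix(0, 4, 4),
                             KRT19 = matrix(0, 4, 4)))
  expect_equal(nrow(empty), 0)
})

test_that("gates separate 20x log-normal modes with <2% misclassification", {
  gc <- generateColonyCells(colonyPreset("AR-day2"), seed = 11)
  gates <- fitGates(gc$cells)
  expect_false(any(gates@fallback))
  st <- classifyStates(gc$cells, gates)
  expect_lt(mean(as.character(st$state) !=
                 as.character(gc$truth$state)), 0.02)
  expect_identical(fitGates(gc$cells), gates)  # deterministic refit
})

test_that("unimodal intensities trigger the quantile fallback gate", {
  set.seed(2)
  v14 <- exp(rt(400, df = 2) * 0.5 + 4)  # heavy-tailed single mode
  tab <- data.frame(mean_krt14 = v14, mean_krt19 = v14)
  gates <- fitGates(tab)
  expect_true(any(gates@fallback))
  expect_equal(gates@t14[gates@fallback[["KRT14"]]],
               unname(quantile(v14, 0.75)), tolerance = 1e-9)
  expect_error(fitGates(tab[1:10, ]), "at least 20")
})

test_that("state classification follows the gate rules including ties", {
  g <- new("GateThresholds", t14 = 100, t19 = 100)
  tab <- data.frame(cell_id = 1:4,
                    mean_krt14 = c(50, 150, 150, 100),
                    mean_krt19 = c(50, 50, 150, 99))
  st <- classifyStates(tab, g)$state
  expect_equal(as.character(st),
               c("undifferentiated", "K14_only", "double_positive",
                 "K14_only"))
})

test_that("state distributions normalise and validate", {
  sd <- stateDistribution(stateFactor(NULL, c(5, 3, 2, 0)))
  expect_equal(unname(stateCounts(sd)), c(5, 3, 2, 0))
  expect_equal(unname(stateProps(sd)), c(0.5, 0.3, 0.2, 0))
  expect_equal(sum(stateProps(sd)), 1)
  expect_error(stateDistribution(factor(character())), "empty")
})

test_that("classification recovers every colony preset mixture at n = 2000", {
  for (preset in c("AR-day2", "HR-day2", "AR-day7", "HR-day7")) {
    gc <- generateColonyCells(colonyPreset(preset), seed = 19)
    st <- classifyStates(gc$cells, fitGates(gc$cells))
    props <- stateProps(stateDistribution(st))
    truthProps <- colonyPreset(preset)@stateProportions
    se <- sqrt(truthProps * (1 - truthProps) / 2000)
    expect_true(all(abs(props - truthProps) <= 3 * se + 0.02),
                info = preset)
  }
})

test_that("distribution comparison matches chi-square and flags degeneracy", {
  a <- stateDistribution(stateFactor(NULL, c(20, 10, 5, 5)))
  b <- stateDistribution(stateFactor(NULL, c(5, 10, 20, 5)))
  cmp <- compareDistributions(a, b)
  O <- rbind(stateCounts(a), stateCounts(b))
  expect_equal(unname(cmp@statistic[["X2"]]), bruteChiSquare(O))
  expect_equal(cmp@df, 3)
  same <- compareDistributions(a, a)
  expect_equal(unname(same@statistic[["X2"]]), 0)
  expect_equal(pValue(same), 1)
  degen <- compareDistributions(
    stateDistribution(stateFactor(NULL, c(5, 0, 0, 0))),
    stateDistribution(stateFactor(NULL, c(9, 0, 0, 0))))
  expect_true("not_testable" %in% degen@warnings)
  expect_equal(degen@df, 0)
})

test_that("image-to-distribution readout recovers the AR-day2 mixture", {
  spec <- colonyPreset("AR-day2", nCells = 80, imageSize = c(640, 640),
                       minCellSpacing = 26)
  counts <- integer(4)
  for (s in 1:4) {
    ro <- differentiationReadout(generateColonyImage(spec, seed = 40 + s))
    counts <- counts + stateCounts(ro$distribution)
  }
  undiff <- counts[[1]] / sum(counts)
  expect_lt(abs(undiff - 0.29), 0.03 + 3 * sqrt(0.29 * 0.71 / sum(counts)))
})
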