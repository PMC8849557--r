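test_that("Otsu thresholding matches an exhaustive candidate search", {
  m <- matrix(10, 8, 8); m[1, 1:4] <- 200
  bm <- autoThreshold(m)
  expect_equal(maskArea(bm), 4)
  expect_equal(maskArea(bm), bruteOtsuArea(as.numeric(m)))
  ramp <- matrix(0:255, 16, 16)
  area <- maskArea(autoThreshold(ramp))
  expect_lt(abs(area - 128), 0.02 * 256 + 1)
  expect_equal(area, bruteOtsuArea(as.numeric(ramp)))
  set.seed(3)
  for (i in 1:10) {  # bimodal random images
    v <- c(rnorm(80, 20, 3), rnorm(sample(10:40, 1), 200, 10))
    img <- matrix(sample(v), nrow = 1)
    expect_equal(maskArea(autoThreshold(img)), bruteOtsuArea(as.numeric(img)))
  }
})

test_that("constant channels yield an empty degenerate mask", {
  bm <- autoThreshold(matrix(7, 5, 5))
  expect_true(bm@degenerate)
  expect_equal(maskArea(bm), 0)
  expect_error(autoThreshold(matrix(numeric(), 0, 0)), "nonempty")
  expect_error(autoThreshold(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("mask algebra matches a per-pixel loop oracle and the union identity", {
  m14 <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE), 3, 3)
  m19 <- matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                  FALSE), 3, 3)
  expect_equal(unname(maskAreas(computeMaskSet(m14, m19))), c(4, 3, 1, 6))
  set.seed(9)
  for (i in 1:15) {
    n <- sample(2:64, 1)
    a <- matrix(runif(n * n) < runif(1), n, n)
    b <- matrix(runif(n * n) < runif(1), n, n)
    ms <- computeMaskSet(a, b)
    expect_equal(maskAreas(ms), bruteMaskSet(a, b))
    ar <- maskAreas(ms)
    expect_identical(ar[["a_or"]], ar[["a14"]] + ar[["a19"]] - ar[["a_and"]])
  }
  idm <- computeMaskSet(m14, m14)
  expect_equal(unname(maskAreas(idm)), c(4, 4, 4, 4))
  dis <- computeMaskSet(m14, !m14)
  expect_equal(maskAreas(dis)[["a_and"]], 0)
  expect_equal(maskAreas(dis)[["a_or"]], 9)
  expect_error(computeMaskSet(m14, matrix(TRUE, 2, 2)), "shape")
})

test_that("fidelity ratios follow the toy arithmetic and flag zero denominators", {
  r <- ratios(fidelityRatios(MaskSet(4, 3, 1)))
  expect_equal(unname(r), c(1 / 3, 1 / 6, 1 / 4))
  zero <- ratios(fidelityRatios(MaskSet(5, 4, 0)))
  expect_equal(unname(zero), c(0, 0, 0))
  no19 <- ratios(fidelityRatios(MaskSet(5, 0, 0)))
  expect_true(is.na(no19[["r_lep"]]))
  expect_equal(no19[["r_mep"]], 0)
  expect_error(MaskSet(2, 2, 3), "aAnd")
})

test_that("quantifyImage equals the manual three-stage composition", {
  img <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 0.5,
                                           luminalAreaFraction = 0.3),
                           seed = 42)
  k14 <- imageChannels(img)[, , "KRT14"]
  k19 <- imageChannels(img)[, , "KRT19"]
  manual <- fidelityRatios(computeMaskSet(autoThreshold(k14),
                                          autoThreshold(k19)))
  expect_identical(ratios(quantifyImage(img)), ratios(manual))
})

test_that("quantification recovers planted coexpression at the boundaries", {
  none <- generateDuctImage(TissueImageSpec(), seed = 1)
  expect_lte(ratios(quantifyImage(none))[["r_lep"]], 0.05)
  all <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 1), seed = 2)
  expect_gte(ratios(quantifyImage(all))[["r_lep"]], 0.95)
})

test_that("an ROI restricts quantification to its pixels", {
  img <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 0.5),
                           seed = 8)
  H <- dim(imageChannels(img))[1]
  roi <- matrix(FALSE, H, H); roi[seq_len(H / 2), ] <- TRUE
  rec <- quantifyImage(img, roi = roi)
  full <- quantifyImage(img)
  expect_lt(maskAreas(rec@maskSet)[["a_or"]],
            maskAreas(full@maskSet)[["a_or"]])
})

test_that("per-sample aggregation averages defined ratios only", {
  r1 <- fidelityRatios(MaskSet(10, 10, 2))   # r_lep 0.2
  r2 <- fidelityRatios(MaskSet(10, 10, 4))   # r_lep 0.4
  s <- aggregateSample(list(r1, r2), "S1")
  expect_equal(s$r_lep, 0.3)
  expect_equal(s$n_images, 2)
  one <- aggregateSample(list(r1), "S2")
  expect_equal(one$r_lep, ratios(r1)[["r_lep"]])
  miss <- fidelityRatios(MaskSet(10, 0, 0))  # r_lep missing
  s2 <- aggregateSample(list(r1, miss), "S3")
  expect_equal(s2$r_lep, 0.2)
  expect_equal(s2$n_lep, 1)
  allMiss <- aggregateSample(list(miss), "S4")
  expect_true(is.na(allMiss$r_lep))
})

test_that("group comparison picks the right test by group count", {
  two <- compareGroups(c(0.30, 0.31, 0.29, 0.05, 0.07, 0.06),
                       rep(c("HR", "AR"), each = 3))
  expect_equal(two@omnibus@test, "Mann-Whitney U")
  expect_equal(pValue(two@omnibus), 0.1)
  expect_equal(nrow(two@pairwise), 0)
  same <- compareGroups(rep(c(1, 2, 3), 3),
                        rep(c("a", "b", "c"), each = 3))
  expect_equal(same@omnibus@test, "Kruskal-Wallis")
  expect_equal(pValue(same@omnibus), 1, tolerance = 1e-6)
  expect_true(all(same@pairwise$p_adj == 1))
  expect_error(
    compareGroups(c(1, 2, NA, NA), c("a", "a", "b", "b")),
    "group\\(s\\): b")
})

test_that("age correlation delegates to Spearman and flags constants", {
  mono <- ageCorrelation(c(1, 2, 3, 5), c(30, 40, 50, 62))
  expect_equal(unname(mono@statistic[["rho"]]), 1)
  const <- ageCorrelation(rep(0.3, 5), c(30, 35, 40, 45, 50))
  expect_true("undefined" %in% const@warnings)
  expect_true(is.na(pValue(const)))
})

test_that("measured r_lep increases strictly with the coexpression probability", {
  levels <- c(0, 0.25, 0.5, 1)
  means <- vapply(seq_along(levels), function(i) {
    recs <- vapply(1:6, function(s) {
      img <- generateDuctImage(
        TissueImageSpec(pCoexpressLuminal = levels[i]), seed = 100 * i + s)
      ratios(quantifyImage(img))[["r_lep"]]
    }, numeric(1))
    mean(recs)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
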