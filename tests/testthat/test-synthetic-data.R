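test_that("generator specs validate their invariants", {
  expect_error(TissueImageSpec(pCoexpressLuminal = 1.2), "\\[0, 1\\]")
  expect_error(TissueImageSpec(ductRadius = -1), "> 0|smaller")
  expect_error(TissueImageSpec(intensityFg = 10, intensityBg = 20),
               "intensityFg")
  expect_error(ColonySpec(stateProportions = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(DETableSpec(fracUp = 0.7, fracDown = 0.6), "fracUp")
  expect_error(CohortSpec(list(), numeric(), nSamples = 3), "nonempty")
})

test_that("duct generator honours coexpression boundaries", {
  none <- generateDuctImage(TissueImageSpec(), seed = 4, render = FALSE)
  expect_equal(sum(truthTable(none)$coexpressing), 0)
  all <- generateDuctImage(TissueImageSpec(pCoexpressLuminal = 1),
                           seed = 4, render = FALSE)
  tt <- truthTable(all)
  expect_true(all(tt$coexpressing[tt$lineage == "LEp"]))
  expect_false(any(tt$coexpressing[tt$lineage == "MEp"]))
})

test_that("coexpressing counts follow the planted binomial law", {
  spec <- TissueImageSpec(pCoexpressLuminal = 0.5)
  nL <- sum(truthTable(generateDuctImage(spec, 1, render = FALSE))$lineage ==
              "LEp")
  counts <- vapply(1:200, function(s) {
    tt <- truthTable(generateDuctImage(spec, s, render = FALSE))
    sum(tt$coexpressing[tt$lineage == "LEp"])
  }, numeric(1))
  se <- sqrt(nL * 0.25 / 200)
  expect_lt(abs(mean(counts) - nL * 0.5), 3 * se)
})

test_that("generators are byte-identical under a repeated seed", {
  s <- TissueImageSpec(pCoexpressLuminal = 0.3,
                       pCoexpressMyoepithelial = 0.1)
  expect_identical(generateDuctImage(s, 99), generateDuctImage(s, 99))
  coh <- tissuePreset("HR", nSamples = 3)
  expect_identical(generateTissueCohort(coh, 5, render = FALSE),
                   generateTissueCohort(coh, 5, render = FALSE))
  cs <- colonyPreset("AR-day2", nCells = 300)
  expect_identical(generateColonyCells(cs, 12), generateColonyCells(cs, 12))
  ci <- colonyPreset("HR-day2", nCells = 20, imageSize = c(256, 256))
  expect_identical(generateColonyImage(ci, 3), generateColonyImage(ci, 3))
  de <- DETableSpec(nGenes = 500)
  expect_identical(generateDETable(de, 8), generateDETable(de, 8))
})

test_that("cohort generation fills metadata and honours degenerate weights", {
  coh <- generateTissueCohort(tissuePreset("HR", nSamples = 6), seed = 2,
                              render = FALSE)
  expect_length(coh, 6)
  md <- do.call(rbind, lapply(coh, `[[`, "metadata"))
  expect_true(all(md$risk_group == "HR"))
  expect_true(all(md$mutation %in% c("BRCA1", "BRCA2", "PALB2")))
  expect_true(all(md$age_group == ifelse(md$age <= 35, "young",
                                  ifelse(md$age >= 55, "old", "middle"))))
  arch <- tissuePreset("HR")@archetypes
  degen <- CohortSpec(arch, c(0, 0, 1), nSamples = 4, riskLabel = "HR")
  cd <- generateTissueCohort(degen, seed = 3, render = FALSE)
  expect_true(all(vapply(cd, function(s) s$metadata$archetype, 0) == 3))
})

test_that("HR preset expectation over the archetype mixture is calibrated", {
  # Monte-Carlo over >= 500 simulated samples, truth fast path:
  # cohort means of (r_lep, r_all, r_mep) must sit within 0.01 of the
  # calibration targets (0.31, 0.11, 0.18).
  coh <- generateTissueCohort(tissuePreset("HR", nSamples = 520), seed = 31,
                              render = FALSE)
  perSample <- vapply(coh, function(s)
    rowMeans(vapply(s$images, function(i) ratios(truthFidelity(i)),
                    numeric(3))), numeric(3))
  m <- rowMeans(perSample)
  expect_lt(abs(m[["r_lep"]] - 0.31), 0.01)
  expect_lt(abs(m[["r_all"]] - 0.11), 0.01)
  expect_lt(abs(m[["r_mep"]] - 0.18), 0.01)
})

test_that("AR preset expectation matches its closed-form calibration", {
  er <- expectedRatios(tissuePreset("AR")@archetypes[[1]])
  expect_equal(unname(er), c(0.069, 0.029, 0.048), tolerance = 0.015)
  coh <- generateTissueCohort(tissuePreset("AR", nSamples = 200), seed = 13,
                              render = FALSE)
  m <- rowMeans(vapply(coh, function(s)
    rowMeans(vapply(s$images, function(i) ratios(truthFidelity(i)),
                    numeric(3))), numeric(3)))
  expect_lt(abs(m[["r_lep"]] - er[["r_lep"]]), 0.01)
  expect_lt(abs(m[["r_all"]] - er[["r_all"]]), 0.01)
})

test_that("colony cell states follow the planted mixture", {
  one <- generateColonyCells(ColonySpec(nCells = 50,
                                        stateProportions = c(1, 0, 0, 0)),
                             seed = 1)
  expect_true(all(one$truth$state == "undifferentiated"))
  gc <- generateColonyCells(colonyPreset("AR-day2"), seed = 6)
  undiff <- mean(gc$truth$state == "undifferentiated")
  se <- sqrt(0.29 * 0.71 / 2000)
  expect_lt(abs(undiff - 0.29), 3 * se)
})

test_that("colony images carry one label per cell and round-trip intensities", {
  blank <- generateColonyImage(ColonySpec(nCells = 0,
                                          imageSize = c(64, 64)), seed = 1)
  expect_equal(nrow(truthTable(blank)), 0)
  expect_true(all(cellLabels(blank) == 0L))
  spec <- colonyPreset("HR-day2", nCells = 5, imageSize = c(192, 192),
                       minCellSpacing = 45)
  img <- generateColonyImage(spec, seed = 2)
  labs <- cellLabels(img)
  expect_equal(length(setdiff(unique(as.vector(labs)), 0L)), 5)
  m <- measureCells(labs, img)   # generator labels are exact
  tt <- truthTable(img)[order(truthTable(img)$cell_id), ]
  expect_equal(m$mean_krt14, tt$mean_krt14, tolerance = 0.05)
  expect_equal(m$mean_krt19, tt$mean_krt19, tolerance = 0.05)
  tight <- ColonySpec(nCells = 500, imageSize = c(96, 96),
                      minCellSpacing = 30)
  expect_error(generateColonyImage(tight, seed = 1), "placement")
})

test_that("DE tables plant effects and keep the null clean", {
  spec <- DETableSpec(nGenes = 400, fracUp = 0.5, fracDown = 0,
                      effectLog2fc = 3, plantedPMax = 1e-10)
  de <- generateDETable(spec, seed = 2)
  expect_equal(sum(de$planted == "up"), 200)
  sel <- lineageSpecificGenes(de)
  expect_setequal(geneIds(sel), de$gene[de$planted == "up"])
  # null-only tables never pass the lineage filter
  null <- DETableSpec(nGenes = 200, fracUp = 0, fracDown = 0,
                      nullLog2fcSd = 0.1)
  hits <- vapply(1:100, function(s) {
    d <- generateDETable(null, seed = s)
    sum(d$log2fc >= 1 & d$padj < 0.001)
  }, numeric(1))
  expect_equal(sum(hits), 0)
})

test_that("constructed overlap lists invert the overlap test exactly", {
  l <- constructOverlapLists(50, 50, 100, 2500)
  expect_length(geneIds(l$A), 100)
  expect_length(geneIds(l$B), 150)
  expect_length(intersect(geneIds(l$A), geneIds(l$B)), 50)
  expect_length(geneIds(l$universe), 2700)
  disj <- constructOverlapLists(0, 5, 5, 10)
  expect_length(intersect(geneIds(disj$A), geneIds(disj$B)), 0)
  set.seed(17)
  for (i in 1:20) {
    cells <- as.integer(rmultinom(1, sample(20:500, 1), runif(4)))
    l <- do.call(constructOverlapLists, as.list(cells))
    r <- overlapTest(l$A, l$B, l$universe)
    expect_identical(as.integer(t(r@table)), cells)
  }
})
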