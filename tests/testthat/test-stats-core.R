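test_that("BH step-up matches the hand-computed worked example", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_error(bhAdjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("BH adjustment is monotone, never decreases, and agrees with p.adjust", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, p.adjust(p, method = "BH"))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  # flat adjusted vectors (the step-up's fixed points) are left unchanged
  expect_equal(bhAdjust(rep(0.04, 4)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
})

test_that("one-sided Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(pValue(fisherGreater(2, 0, 0, 2)), 1 / 6)
  expect_equal(pValue(fisherGreater(0, 5, 7, 11)), 1)  # full upper tail
  set.seed(7)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(10:60, 1), runif(4, 0.05, 1)))
    got <- pValue(do.call(fisherGreater, as.list(cells)))
    expect_equal(got, bruteFisherGreater(cells[1], cells[2], cells[3],
                                         cells[4]), tolerance = 1e-12)
    ft <- fisher.test(matrix(cells, 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(got, ft$p.value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney reports both U conventions and the exact p", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r@statistic[c("U1", "U2")]), c(0, 9))
  expect_equal(pValue(r), 0.1)  # 2 / choose(6, 3)
  expect_match(r@method, "exact")
  hr <- mannWhitney(c(0.30, 0.31, 0.29), c(0.05, 0.07, 0.06))
  expect_equal(unname(hr@statistic["U1"]), 9)
  expect_equal(pValue(hr), 0.1)
})

test_that("Mann-Whitney matches enumeration oracle and wilcox.test", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1); y <- sample(seq_len(50) + 100, n2)
    # shuffle together so groups interleave
    pool <- sample(c(x, y)); x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    r <- mannWhitney(x, y)
    expect_equal(pValue(r), bruteMannWhitney(x, y))
    expect_equal(pValue(r), wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(pValue(r), pValue(mannWhitney(y, x)))  # symmetry
  }
})

test_that("Mann-Whitney handles identical multisets and ties", {
  x <- c(1, 2, 2, 3)
  r <- mannWhitney(x, x)
  expect_equal(pValue(r), 1)
  expect_true("ties present" %in% r@warnings)
  big <- mannWhitney(rnorm(20), rnorm(20) + 5)
  expect_match(big@method, "normal approximation")
  expect_lt(pValue(big), 0.001)
})

test_that("chi-square matches the 2x2 closed form and a first-principles oracle", {
  r <- chiSquareIndependence(matrix(c(20, 10, 10, 20), 2))
  expect_equal(unname(r@statistic["X2"]), 6.667, tolerance = 1e-3)
  expect_equal(r@df, 1)
  expect_equal(pValue(r), 0.0098, tolerance = 1e-2)
  expect_equal(pValue(chiSquareIndependence(matrix(10, 2, 2))), 1)
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:4, 1); m <- sample(2:4, 1)
    O <- matrix(rpois(k * m, 20) + 1, k, m)
    r <- chiSquareIndependence(O)
    expect_equal(unname(r@statistic["X2"]), bruteChiSquare(O))
    expect_equal(r@df, (k - 1) * (m - 1))
    cs <- suppressWarnings(chisq.test(O, correct = FALSE))
    expect_equal(pValue(r), cs$p.value)
  }
})

test_that("chi-square flags degenerate and low-expected-count tables", {
  r <- chiSquareIndependence(matrix(c(5, 0, 9, 0), 2))  # one nonzero column
  expect_true("not_testable" %in% r@warnings)
  expect_equal(r@df, 0)
  r2 <- chiSquareIndependence(matrix(c(3, 1, 2, 4), 2))
  expect_true("expected count < 5" %in% r2@warnings)
})

test_that("Spearman handles monotone, anti-monotone and constant input", {
  expect_equal(unname(spearmanTest(1:5, (1:5)^2)@statistic["rho"]), 1)
  r <- spearmanTest(c(1, 2, 3), c(3, 1, 2))
  expect_equal(unname(r@statistic["rho"]), -0.5)  # 1 - 6*6/(3*8)
  expect_true(is.na(pValue(r)))  # n < 4: no p reported
  const <- spearmanTest(rep(2, 6), 1:6)
  expect_true("undefined" %in% const@warnings)
  x <- c(3, 1, 4, 1.5, 9, 2.6); y <- c(2, 7, 1, 8, 2.8, 1.8)
  expect_equal(unname(spearmanTest(x, y)@statistic["rho"]),
               -unname(spearmanTest(x, -y)@statistic["rho"]))
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(unname(spearmanTest(x, y)@statistic["rho"]),
               unname(ct$estimate))
  expect_equal(pValue(spearmanTest(x, y)), ct$p.value)
})

test_that("Dunn post hoc detects separated groups and respects Bonferroni", {
  v <- c(1, 2, 3, 21, 22, 23, 41, 42, 43)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  d <- dunnPosthoc(v, g)
  expect_equal(nrow(d), 3)
  expect_equal(d$p_adj, pmin(1, d$p * 3))
  expect_lt(d$p[d$group1 == "a" & d$group2 == "c"],
            d$p[d$group1 == "a" & d$group2 == "b"])
  same <- dunnPosthoc(rep(1:3, 3), factor(rep(c("a", "b", "c"), each = 3)))
  expect_true(all(same$p_adj == 1))
})
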