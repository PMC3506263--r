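test_that("G-test matches the direct formula and behaves at independence", {
  g <- gTest2x2(10, 10, 10, 10)
  expect_equal(g@value, 0)
  g2 <- gTest2x2(10, 10, 5, 15)
  expect_equal(g2@value, oracleG(matrix(c(10, 10, 5, 15), 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(g2@df, 1)
  expect_error(gTest2x2(0, 0, 5, 10), "margin")
  expect_error(gTest2x2(-1, 2, 3, 4), "non-negative")
})

test_that("chi-square test matches the direct formula", {
  expect_equal(chiSquareRxC(matrix(c(10, 20, 5, 10), 2))@value, 0,
               tolerance = 1e-12)
  set.seed(21)
  tab <- matrix(rpois(6, 30) + 1, nrow = 3)
  r <- chiSquareRxC(tab)
  expect_equal(r@value, oracleChisq(tab), tolerance = 1e-12)
  expect_equal(r@df, 2)
  # 2x2 chi-square equals the squared two-proportion z
  t2 <- matrix(c(12, 30, 25, 40), 2, byrow = TRUE)
  n1 <- sum(t2[1, ]); n2 <- sum(t2[2, ])
  phat <- sum(t2[, 1]) / sum(t2)
  z <- (t2[1, 1] / n1 - t2[2, 1] / n2) /
    sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  expect_equal(chiSquareRxC(t2)@value, z^2, tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum: identical samples, combinatorial floor, exact enumeration", {
  x <- c(1, 2, 3, 4)
  expect_gt(wilcoxonRankSum(x, x + 0.0001)@p, 0.5)
  # x entirely below y, one-sided
  r <- wilcoxonRankSum(c(1, 2, 3, 4), c(5, 6, 7, 8), alternative = "less")
  expect_equal(r@p, 1 / choose(8, 4), tolerance = 1e-12)
  set.seed(22)
  for (i in 1:5) {
    a <- round(rnorm(4), 3); b <- round(rnorm(4) + 0.5, 3)
    expect_equal(wilcoxonRankSum(a, b)@p, oracleWilcoxonExact(a, b),
                 tolerance = 1e-12)
  }
})

test_that("pooled t-test df accounting and textbook formula", {
  set.seed(23)
  x <- rnorm(40); y <- rnorm(33)
  r <- twoSampleT(x, y)
  expect_equal(r@df, 71)
  sp2 <- ((39 * var(x) + 32 * var(y)) / 71)
  tman <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 40 + 1 / 33))
  expect_equal(r@value, tman, tolerance = 1e-12)
  expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))@value, 0)
  expect_error(twoSampleT(c(1, 1), c(1, 1)), "variance")
})

test_that("Pearson correlation: perfect fits and covariance formula", {
  x <- 1:10
  expect_equal(pearsonCorrelation(x, 2 * x + 1)@value, 1)
  expect_equal(pearsonCorrelation(x, -x)@value, -1)
  set.seed(24)
  a <- rnorm(20); b <- rnorm(20)
  r <- pearsonCorrelation(a, b)
  rman <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r@value, rman, tolerance = 1e-12)
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "variance")
})

test_that("partial correlations match the residual-regression oracle", {
  set.seed(25)
  # independent columns: partials near zero; exact identity-matrix case
  X <- matrix(rnorm(200), 50, 4)
  P <- partialCorrelation(X)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(P[i, j], oraclePartial(X, i, j), tolerance = 1e-10)
  # three variables with r_xy = r_xz * r_zy exactly: partial r_xy.z = 0.
  # Build x and y from exactly orthogonal components so the sample
  # correlations satisfy the product identity to machine precision.
  z <- rnorm(200)
  e1 <- resid(lm(rnorm(200) ~ z))          # exactly orthogonal to z
  e2 <- resid(lm(rnorm(200) ~ z + e1))     # orthogonal to z and e1
  zs <- drop(scale(z)); e1s <- drop(scale(e1)); e2s <- drop(scale(e2))
  xq <- 0.6 * zs + 0.8 * e1s
  yq <- 0.4 * zs + sqrt(1 - 0.16) * e2s
  Pq <- partialCorrelation(cbind(x = xq, y = yq, z = zs))
  expect_equal(unname(Pq["x", "y"]), 0, tolerance = 1e-10)
})

test_that("permutation partial test is seed-reproducible and calibrated-ish", {
  set.seed(26)
  X <- matrix(rnorm(240), 60, 4)
  r1 <- permutationPartialTest(X, nPerm = 200, seed = 99)
  r2 <- permutationPartialTest(X, nPerm = 200, seed = 99)
  expect_identical(r1, r2)
  # planted conditional dependence is detected
  n <- 80
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- 0.9 * x + z + 0.8 * rnorm(n)
  Xp <- cbind(x = x, y = y, z = z)
  rp <- permutationPartialTest(Xp, focal = rbind(c(1, 2)), nPerm = 400,
                               seed = 7)
  expect_true(rp$significant)
})

test_that("category-level derepression statistics behave at the extremes", {
  # equal proportions: all pairwise z near 0
  cats <- rep(c("A_biased", "B_biased", "nondifferential"), each = 40)
  flags <- rep(rep(c(TRUE, FALSE), c(8, 32)), 3)
  r <- derepressionByCategory(cats, flags)
  expect_true(all(abs(r$pairwise$z) < 1e-12))
  expect_equal(unname(r$proportions$proportion), rep(0.2, 3))
  # one category all derepressed, another none: that contrast has max |z|
  cats2 <- rep(c("a", "b", "c"), each = 30)
  flags2 <- c(rep(TRUE, 30), rep(FALSE, 30), rep(c(TRUE, FALSE), 15))
  r2 <- derepressionByCategory(cats2, flags2)
  ab <- abs(r2$pairwise$z[r2$pairwise$cat1 == "a" & r2$pairwise$cat2 == "b"])
  expect_equal(ab, max(abs(r2$pairwise$z)))
})

test_that("G and X2 agree in the weak-association regime", {
  # both statistics scale exactly linearly when a table is multiplied, so
  # their relative difference is scale-invariant; agreement is governed by
  # effect size and improves as the odds ratio approaches 1
  relFor <- function(tab) {
    g <- gTest2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])@value
    abs(g - chiSquareRxC(tab)@value) / chiSquareRxC(tab)@value
  }
  tabs <- list(strong = matrix(c(30, 70, 60, 40), 2, byrow = TRUE),
               mild = matrix(c(45, 55, 55, 45), 2, byrow = TRUE),
               weak = matrix(c(49, 51, 51, 49), 2, byrow = TRUE))
  rel <- vapply(tabs, relFor, 0)
  expect_true(rel[["mild"]] < rel[["strong"]])
  expect_true(rel[["weak"]] < rel[["mild"]])
  expect_lt(rel[["weak"]], 1e-3)
  # and exact scale invariance of both statistics
  t1 <- tabs$strong
  expect_equal(gTest2x2(t1[1, 1] * 10, t1[1, 2] * 10, t1[2, 1] * 10,
                        t1[2, 2] * 10)@value,
               10 * gTest2x2(t1[1, 1], t1[1, 2], t1[2, 1], t1[2, 2])@value,
               tolerance = 1e-12)
})
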