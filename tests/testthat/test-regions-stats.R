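test_that("HI/LO split uses a strict threshold and partitions the parent", {
  m <- array(c(5, 11, 11.5, 20, 1, 0), c(3, 2, 1))
  parent <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), c(3, 2, 1))
  rs <- splitHiLo(m, parent, threshold = 11)
  expect_equal(which(rs@hi), 3L)           # 11.5 only: strictly > 11
  expect_equal(sort(which(rs@lo)), c(1L, 2L))  # 5 and the boundary 11
  expect_true(all((rs@hi | rs@lo) == parent))
  expect_false(any(rs@hi & rs@lo))
  # all below threshold: HI empty is allowed
  low <- splitHiLo(array(1, c(3, 2, 1)), parent)
  expect_equal(sum(low@hi), 0)
  # threshold 0 on a positive map: HI = parent
  all_ <- splitHiLo(m + 100, parent, threshold = 0)
  expect_equal(which(all_@hi), which(parent))
  expect_error(splitHiLo(array(1, c(2, 2, 1)), parent), "grid")
})

test_that("partition invariant holds for every threshold", {
  set.seed(21)
  m <- array(runif(60, 0, 30), c(5, 4, 3))
  parent <- array(runif(60) > 0.4, c(5, 4, 3))
  for (thr in c(-1, 0, 5, 11, 29, 100)) {
    rs <- splitHiLo(m, parent, threshold = thr)
    expect_true(all((rs@hi | rs@lo) == parent))
    expect_false(any(rs@hi & rs@lo))
  }
})

test_that("region means match a brute-force loop and propagate missingness", {
  set.seed(22)
  m <- array(rnorm(24), c(4, 3, 2))
  mask <- array(runif(24) > 0.5, c(4, 3, 2))
  expect_equal(regionMean(m, mask), mean(m[which(mask)]))
  expect_equal(regionMean(array(3.3, c(2, 2, 1)), array(TRUE, c(2, 2, 1))),
               3.3)
  one <- array(FALSE, c(4, 3, 2)); one[2, 2, 2] <- TRUE
  expect_equal(regionMean(m, one), m[2, 2, 2])
  expect_true(is.na(regionMean(m, array(FALSE, c(4, 3, 2)))))
})

test_that("signed-rank test matches brute-force enumeration on random small samples", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties and zeros
    y <- round(rnorm(n), 1)
    res <- wilcoxonSignedRank(x, y)
    expect_equal(res$p, oracleWilcoxonP(x, y), tolerance = 1e-12)
    expect_gte(res$p, 0)
    expect_lte(res$p, 1)
  }
})

test_that("signed-rank agrees with the reference implementation when no ties or zeros", {
  set.seed(24)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    expect_equal(wilcoxonSignedRank(x, y)$p,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("signed-rank handles the textbook cases", {
  expect_equal(wilcoxonSignedRank(1:5, 1:5)$p, 1)        # all zero diffs
  # n = 6 all-positive differences, no ties: p = 2/64
  res <- wilcoxonSignedRank(11:16, rep(10, 6))
  expect_equal(res$p, 2 / 64)
  expect_equal(res$statistic, 21)
})

test_that("Spearman permutation p matches full enumeration at n = 7", {
  set.seed(25)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    res <- rankCorrelation(x, y)
    expect_equal(res$spearman$p, oracleSpearmanP(x, y), tolerance = 1e-12)
  }
  # and agrees with the reference rho
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(rankCorrelation(x, y)$spearman$rho,
               suppressWarnings(cor.test(x, y, method = "spearman"))$estimate,
               ignore_attr = TRUE)
})

test_that("correlation identities: monotone and reversed inputs", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(rankCorrelation(x, exp(x))$spearman$rho, 1)
  res <- rankCorrelation(x, -x)
  expect_equal(res$spearman$rho, -1)
  expect_equal(res$pearson$r, -1)
  # degenerate variance flags rather than errors
  flat <- rankCorrelation(x, rep(5, 6))
  expect_true(is.na(flat$spearman$rho))
  expect_equal(flat$note, "zero variance")
  expect_error(rankCorrelation(1:2, 2:3), "3 complete pairs")
})

test_that("Pearson p follows the t distribution (reference cross-check)", {
  set.seed(26)
  x <- rnorm(12); y <- x + rnorm(12)
  res <- rankCorrelation(x, y)
  ref <- cor.test(x, y, method = "pearson")
  expect_equal(res$pearson$r, unname(ref$estimate))
  expect_equal(res$pearson$p, ref$p.value)
})

test_that("repeatability CV matches hand arithmetic and is scale-free", {
  expect_equal(repeatabilityCv(80, 82), sqrt(2) / 81 * 100,
               tolerance = 1e-12)
  expect_equal(repeatabilityCv(c(80, 70), c(80, 70)), 0)
  a <- c(78, 82, 91); b <- c(80, 81, 89)
  expect_equal(repeatabilityCv(a, b), repeatabilityCv(3.7 * a, 3.7 * b))
  expect_gte(repeatabilityCv(a, b, method = "rms"),
             repeatabilityCv(a, b, method = "mean"))
  expect_warning(cvBad <- repeatabilityCv(c(80, -1), c(82, -3)),
                 "non-positive")
  expect_equal(cvBad, repeatabilityCv(80, 82))
})
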