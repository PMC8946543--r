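test_that("Mann-Whitney matches full enumeration on small samples", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_tailed, 0.1)
  expect_true(res$exact)

  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    got <- mann_whitney(a, b)
    want <- mw_oracle(a, b)
    expect_equal(got$U, want$U)
    expect_equal(got$p_two_tailed, want$p, tolerance = 1e-12)
  }
})

test_that("identical samples are maximally non-significant", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  res <- mann_whitney(x, x)
  expect_gte(res$p_two_tailed, 0.98)
})

test_that("U statistics of the two orderings sum to n_a * n_b", {
  set.seed(13)
  for (i in 1:10) {
    a <- sample(0:30, 12, TRUE) # ties included
    b <- sample(0:30, 9, TRUE)
    expect_equal(
      mann_whitney(a, b)$U + mann_whitney(b, a)$U,
      length(a) * length(b)
    )
  }
})

test_that("exact and approximate p agree for n = 8 tie-free samples", {
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(8)
    b <- rnorm(8, mean = runif(1, 0, 1.5))
    exact_p <- mann_whitney(a, b)$p_two_tailed
    approx_p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("p is invariant under common increasing transforms", {
  set.seed(15)
  a <- rgamma(15, 2)
  b <- rgamma(20, 3)
  f <- function(x) x^3 + 2 * x
  expect_equal(
    mann_whitney(a, b)$p_two_tailed,
    mann_whitney(f(a), f(b))$p_two_tailed
  )
})

test_that("the Shapiro gate records normality as specified", {
  expect_error(shapiro_gate(c(1, 2)), "3 <= n")
  set.seed(16)
  mixture <- c(rnorm(50, 0, 0.05), rnorm(50, 10, 0.05))
  expect_lt(shapiro_gate(mixture), 0.05)
  hits <- sum(vapply(1:50, function(s) {
    set.seed(s)
    shapiro_gate(rnorm(100)) > 0.05
  }, logical(1)))
  expect_gte(hits, 45) # normal samples pass at least 90% of the time
})

test_that("bootstrap median intervals behave like percentile intervals", {
  const <- rep(5, 20)
  ci <- median_ci(const, seed = 1)
  expect_equal(ci$ci_lo, 5)
  expect_equal(ci$ci_hi, 5)

  set.seed(17)
  x <- runif(100)
  ci <- median_ci(x, seed = 2)
  expect_lte(ci$ci_lo, ci$median)
  expect_gte(ci$ci_hi, ci$median)

  # interval width shrinks when the sample doubles
  set.seed(18)
  x2 <- runif(400)
  w1 <- with(median_ci(x2[1:100], seed = 3), ci_hi - ci_lo)
  w2 <- with(median_ci(x2, seed = 3), ci_hi - ci_lo)
  expect_lt(w2, w1)

  small <- median_ci(1:5, seed = 1)
  expect_false(small$ci_defined)
  expect_true(is.na(small$ci_lo))
})

test_that("compare_groups assembles the full nonparametric report", {
  set.seed(19)
  df <- data.frame(
    genotype = rep(c("Wt", "TrJ"), each = 30),
    volume = c(rnorm(30, 250, 30), rnorm(30, 160, 25))
  )
  cmp <- compare_groups(df, volume, genotype, ref = "Wt")
  expect_s3_class(cmp, "group_comparison")
  expect_equal(cmp$groups, c("Wt", "TrJ"))
  expect_lt(cmp$p_two_tailed, 0.001)
  expect_true(cmp$median[2] < cmp$median[1])
  expect_true(all(cmp$ci_lo <= cmp$median & cmp$median <= cmp$ci_hi))
  expect_true(cmp$U >= 0 && cmp$U <= 30 * 30)

  td <- tidy(cmp)
  expect_equal(nrow(td), 2L)
  expect_equal(td$group, c("Wt", "TrJ"))
  gl <- glance(cmp)
  expect_true(gl$significant)
  expect_s3_class(autoplot(cmp), "ggplot")

  expect_error(compare_groups(df[1:30, ], volume, genotype), "two groups")
})

test_that("type-I error is calibrated at the nominal level", {
  rejections <- vapply(1:400, function(s) {
    set.seed(s)
    mann_whitney(rnorm(20), rnorm(20))$p_two_tailed <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})
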