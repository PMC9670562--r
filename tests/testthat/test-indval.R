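test_that("indicator-value components match hand-computed examples", {
  g <- c("host", "host", "host", "rock", "rock")
  perfect <- indval_stat(c(0.1, 0.2, 0.1, 0, 0), g, "host")
  expect_equal(perfect, list(A = 1, B = 1, stat = 1))

  mid <- indval_stat(c(8, 4, 0, 2, 0), g, "host")
  expect_equal(mid$A, 0.8)
  expect_equal(mid$B, 2 / 3)
  expect_equal(mid$stat, sqrt(0.8 * 2 / 3))

  anti <- indval_stat(c(0, 0, 0, 5, 5), g, "host")
  expect_equal(anti, list(A = 0, B = 0, stat = 0))

  absent <- indval_stat(c(0, 0, 0, 0, 0), g, "host")
  expect_equal(absent$stat, 0)
})

test_that("components agree with a naive oracle on random data", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    g <- sample(c("host", "rock", "seawater"), n, replace = TRUE)
    while (length(unique(g)) < 3) g <- sample(c("host", "rock", "seawater"),
                                              n, replace = TRUE)
    ab <- rpois(n, 3) * runif(n)
    for (variant in c("sqrt", "product")) {
      got <- indval_stat(ab, g, "host", variant = variant)
      want <- oracle_indval(ab, g, "host", variant = variant)
      expect_equal(got$A, want$A, tolerance = 1e-12)
      expect_equal(got$B, want$B, tolerance = 1e-12)
      expect_equal(got$stat, want$stat, tolerance = 1e-12)
    }
  }
})

test_that("specificity A sums to 1 across groups and the statistic is scale invariant", {
  set.seed(5)
  g <- c(rep("host", 4), rep("rock", 3), rep("seawater", 3))
  for (i in 1:10) {
    ab <- rpois(10, 4)
    if (sum(ab) == 0) next
    As <- vapply(unique(g), function(t) indval_stat(ab, g, t)$A, numeric(1))
    expect_equal(sum(As), 1, tolerance = 1e-12)
    s1 <- indval_stat(ab, g, "host")$stat
    s2 <- indval_stat(ab * 17.3, g, "host")$stat
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("stat is 1 exactly when the taxon fills the target group and nothing else", {
  g <- c("host", "host", "rock", "rock", "seawater")
  expect_equal(indval_stat(c(3, 9, 0, 0, 0), g, "host")$stat, 1)
  # one target sample empty
  expect_lt(indval_stat(c(3, 0, 0, 0, 0), g, "host")$stat, 1)
  # leakage into the environment
  expect_lt(indval_stat(c(3, 9, 1, 0, 0), g, "host")$stat, 1)
})

test_that("exhaustive enumeration gives the exact permutation p", {
  x <- toy_counts(matrix(c(10, 10, 0, 0), ncol = 1),
                  samples = paste0("s", 1:4))
  g <- c("host", "host", "rock", "rock")
  res <- indval(x, g, "host", mode = "exhaustive")
  expect_equal(res$p_value, 1 / 6)
  expect_equal(res$n_perm, 6)

  # identical abundance everywhere: permutation-invariant, p = 1
  xc <- toy_counts(matrix(5, 4, 1), samples = paste0("s", 1:4))
  expect_equal(indval(xc, g, "host", mode = "exhaustive")$p_value, 1)
  expect_equal(indval(xc, g, "host", n_perm = 99, seed = 2)$p_value, 1)
})

test_that("Monte-Carlo p converges to the exhaustive p on small designs", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(6:9, 1)
    g <- c(rep("host", 3), sample(c("rock", "seawater"), n - 3,
                                  replace = TRUE))
    while (length(unique(g)) < 3) {
      g <- c(rep("host", 3), sample(c("rock", "seawater"), n - 3,
                                    replace = TRUE))
    }
    ab <- rpois(n, 2) + c(rep(3L, 3), rep(0L, n - 3)) * rbinom(n, 1, 0.8)
    x <- toy_counts(matrix(ab, ncol = 1), samples = paste0("s", 1:n))
    p_ex <- indval(x, g, "host", mode = "exhaustive")$p_value
    p_mc <- indval(x, g, "host", n_perm = 999, seed = i)$p_value
    se <- sqrt(p_ex * (1 - p_ex) / 999)
    expect_lt(abs(p_mc - p_ex), 3 * se + 2 / 1000)
  }
})

test_that("pooled and separate environments agree in the symmetric limit", {
  # rock and seawater with equal sample counts and identical within-group
  # values: pooling cannot change the group-equalized means
  g <- c("host", "host", "rock", "rock", "seawater", "seawater")
  ab <- c(6, 4, 2, 2, 2, 2)
  x <- toy_counts(matrix(ab, ncol = 1), samples = paste0("s", 1:6))
  sep <- indval(x, g, "host", n_perm = 9, seed = 1)
  pooled <- indval(x, g, "host", n_perm = 9, seed = 1, pool_env = TRUE)
  # A_sep = 5/(5+2+2), A_pool = 5/(5+2)
  expect_equal(sep$A, 5 / 9)
  expect_equal(pooled$A, 5 / 7)
  expect_equal(sep$B, pooled$B)
})

test_that("design validation catches missing abundances and empty designs", {
  x <- toy_counts(matrix(1:4, ncol = 1), samples = paste0("s", 1:4))
  g <- setNames(rep("host", 5), paste0("s", 1:5))
  expect_error(indval(x, g, "host"), "no abundances")
  expect_error(indval(x, rep("host", 4), "host"), "at least 2 groups")
  expect_error(indval(x, c("a", "a", "b", "b"), "zzz"), "not present")
})

test_that("permutation p-values are reproducible under a seed", {
  set.seed(3)
  x <- toy_counts(matrix(rpois(40, 3), 8, 5))
  g <- c(rep("host", 4), rep("rock", 4))
  r1 <- indval(x, g, "host", n_perm = 199, seed = 42)
  r2 <- indval(x, g, "host", n_perm = 199, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
})
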