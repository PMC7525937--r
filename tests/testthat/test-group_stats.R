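two_group_df <- function(x, y) {
  tibble::tibble(v = c(x, y), g = rep(c("x", "y"), c(length(x), length(y))))
}

test_that("Kruskal-Wallis reproduces the hand-computed H and exact p", {
  d <- two_group_df(c(1, 2, 3), c(4, 5, 6))
  res <- kruskal_wallis(d, v, g)
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 21
  expect_equal(res$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), 3.857)
  expect_equal(res$p_value, 0.1)  # 2 of the 20 assignments as extreme
  expect_error(kruskal_wallis(two_group_df(1:3, numeric()), v, g), "2 groups")
})

test_that("fully tied data give H = 0 with p = 1", {
  d <- two_group_df(rep(2, 3), rep(2, 4))
  res <- kruskal_wallis(d, v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the asymptotic Kruskal-Wallis path matches base R with ties", {
  set.seed(7)
  for (i in 1:10) {
    v <- sample(1:6, 15, replace = TRUE)  # forces midranks + tie correction
    g <- sample(c("a", "b", "c"), 15, replace = TRUE)
    if (length(unique(g)) < 3 || length(unique(v)) < 2) next
    mine <- kruskal_wallis(tibble::tibble(v = v, g = g), v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("small-sample Kruskal-Wallis p equals full-enumeration oracle", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    v <- round(runif(n), 2)
    g <- sample(rep(c("a", "b"), length.out = n))
    mine <- kruskal_wallis(tibble::tibble(v = v, g = g), v, g)
    expect_equal(mine$p_value, kw_exact_oracle(v, g), tolerance = 1e-10)
  }
})

test_that("rank-sum exact p matches enumeration and base R", {
  d <- two_group_df(c(1, 2, 3), c(4, 5, 6))
  res <- rank_sum_test(d, v, g)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value,
               stats::wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p.value)
  res2 <- rank_sum_test(two_group_df(c(1, 2, 4), c(3, 5, 6)), v, g)
  expect_equal(res2$p_value, rank_sum_exact_oracle(c(1, 2, 4), c(3, 5, 6)))
  expect_equal(res2$p_value,
               stats::wilcox.test(c(1, 2, 4), c(3, 5, 6), exact = TRUE)$p.value)
})

test_that("identical groups give the null-mean U and p = 1", {
  x <- c(5, 6, 7, 8, 9, 10, 11)
  d <- two_group_df(x, rev(x))   # same multisets, ties force asymptotic path
  res <- rank_sum_test(d, v, g)
  expect_equal(res$statistic, length(x)^2 / 2)
  expect_equal(res$p_value, 1)
})

test_that("the tie-corrected normal approximation matches base R", {
  set.seed(12)
  for (i in 1:10) {
    x <- sample(1:8, 12, replace = TRUE)
    y <- sample(2:9, 14, replace = TRUE)
    mine <- rank_sum_test(two_group_df(x, y), v, g)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher's exact test matches the frozen enumerations and base R", {
  r1 <- fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))
  expect_equal(r1$p_value, 1 / 3, tolerance = 1e-12)
  r2 <- fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))
  expect_equal(r2$p_value, 1)
  r3 <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r3$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(r3$p_value, 0.001)
  expect_true(is.infinite(r3$statistic))
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")

  set.seed(33)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    mine <- fisher_exact_2x2(tab)
    expect_equal(mine$p_value, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Kendall tau-b matches the pair-count oracle and base R", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(1, 3, 2))
  res <- kendall_tau_b(d, x, y)
  expect_equal(res$statistic, 1 / 3, tolerance = 1e-12)  # C=2, D=1
  expect_equal(kendall_tau_b(tibble::tibble(x = 1:5, y = 1:5), x, y)$statistic, 1)
  expect_equal(kendall_tau_b(tibble::tibble(x = 1:5, y = 5:1), x, y)$statistic, -1)
  expect_error(kendall_tau_b(tibble::tibble(x = rep(1, 4), y = 1:4), x, y),
               "tied")

  set.seed(9)
  for (i in 1:10) {
    x <- sample(1:6, 15, replace = TRUE)
    y <- x + sample(-2:2, 15, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    mine <- kendall_tau_b(tibble::tibble(x = x, y = y), x, y)
    expect_equal(mine$statistic, kendall_tau_oracle(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "kendall", exact = FALSE))
    expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("two-sided tests are invariant under group relabeling", {
  set.seed(5)
  x <- rnorm(9); y <- rnorm(11)
  a <- rank_sum_test(two_group_df(x, y), v, g)
  b <- rank_sum_test(two_group_df(y, x), v, g)
  expect_equal(a$p_value, b$p_value)
  ka <- kruskal_wallis(two_group_df(x, y), v, g)
  kb <- kruskal_wallis(two_group_df(y, x), v, g)
  expect_equal(ka$p_value, kb$p_value)
  tab <- matrix(c(8, 3, 2, 9), 2)
  expect_equal(fisher_exact_2x2(tab)$p_value,
               fisher_exact_2x2(tab[2:1, ])$p_value)
  expect_true(all(vapply(list(a, ka), function(t)
    t$p_value >= 0 && t$p_value <= 1, logical(1))))
})

test_that("tidy and glance return one-row summaries", {
  res <- fisher_exact_2x2(matrix(c(5, 1, 2, 6), 2))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_named(td, c("test_name", "statistic", "p.value", "n_total", "method"))
  expect_identical(glance(res), td)
})
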