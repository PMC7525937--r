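#' @rdname cmf_test
new_cmf_test <- function(test_name, statistic, p_value, n_per_group,
                         method_details, ...) {
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         n_per_group = n_per_group, method_details = method_details, ...),
    class = "cmf_test"
  )
}

#' Hypothesis-test results
#'
#' All univariate tests in the package return a `cmf_test` object: a list
#' with `test_name`, `statistic`, `p_value`, `n_per_group` and
#' `method_details` (exact vs asymptotic path, tie handling). [tidy()] and
#' [glance()] methods turn it into a one-row tibble.
#'
#' @param x A `cmf_test` object.
#' @param ... Unused.
#' @name cmf_test
#' @export
print.cmf_test <- function(x, ...) {
  cat(x$test_name, "\n")
  cat("  statistic =", format(x$statistic, digits = 5),
      "  p =", format.pval(x$p_value, digits = 4), "\n")
  cat("  n =", paste(x$n_per_group, collapse = " + "),
      " (", x$method_details, ")\n", sep = "")
  invisible(x)
}

rank_stats <- function(values) {
  r <- rank(values)
  tie_sizes <- as.integer(table(values))
  list(ranks = r, ties = tie_sizes[tie_sizes > 1L])
}

kw_statistic <- function(ranks, group_index, n_per_group, tie_sizes) {
  N <- length(ranks)
  rank_sums <- vapply(split(ranks, group_index), sum, numeric(1))
  h <- 12 / (N * (N + 1)) * sum(rank_sums^2 / n_per_group) - 3 * (N + 1)
  tie_term <- if (length(tie_sizes)) sum(tie_sizes^3 - tie_sizes) / (N^3 - N) else 0
  if (tie_term >= 1) return(0)  # all values identical
  h / (1 - tie_term)
}

#' Kruskal-Wallis rank test
#'
#' The Kruskal-Wallis H statistic with midrank ties and tie correction,
#' compared to a chi-square distribution with g-1 degrees of freedom. For
#' total N <= 8 an exact p-value is additionally computed by enumerating
#' every assignment of the pooled observations to groups of the observed
#' sizes; the exact p is then reported.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the numeric response and
#'   the grouping variable (>= 2 groups).
#' @return A [cmf_test] object (`statistic` is H).
#' @examples
#' d <- data.frame(a = c(1, 2, 3, 4, 5, 6), g = rep(c("x", "y"), each = 3))
#' kruskal_wallis(d, a, g)
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  levels <- unique(g)
  if (length(levels) < 2L) abort("Kruskal-Wallis needs >= 2 groups.")
  gi <- factor(g, levels = levels)
  n_per <- as.integer(table(gi))
  if (any(n_per < 1L) || length(v) < 3L) abort("Each group needs >= 1 value, total N >= 3.")
  rs <- rank_stats(v)
  h <- kw_statistic(rs$ranks, gi, n_per, rs$ties)
  N <- length(v)
  if (h == 0 && length(rs$ties) && sum(rs$ties) == N) {
    return(new_cmf_test("Kruskal-Wallis rank sum test", 0, 1, n_per,
                        "all values tied; H = 0"))
  }
  p_asym <- pchisq(h, df = length(levels) - 1L, lower.tail = FALSE)
  if (N <= 8L) {
    hs <- enumerate_group_statistics(rs$ranks, n_per, function(idx_groups) {
      rank_sums <- vapply(idx_groups, function(i) sum(rs$ranks[i]), numeric(1))
      12 / (N * (N + 1)) * sum(rank_sums^2 / n_per) - 3 * (N + 1)
    })
    tie_term <- if (length(rs$ties)) sum(rs$ties^3 - rs$ties) / (N^3 - N) else 0
    hs <- hs / (1 - tie_term)
    p_exact <- mean(hs >= h - 1e-12)
    return(new_cmf_test("Kruskal-Wallis rank sum test", h, p_exact, n_per,
                        "exact p by full enumeration of group assignments",
                        p_asymptotic = p_asym))
  }
  new_cmf_test("Kruskal-Wallis rank sum test", h, p_asym, n_per,
               paste0("chi-square approximation, df = ", length(levels) - 1L,
                      if (length(rs$ties)) ", tie-corrected" else ""))
}

# Apply `stat_fun` to every partition of 1..N into ordered groups of the
# given sizes. stat_fun receives a list of index vectors.
enumerate_group_statistics <- function(values, sizes, stat_fun) {
  out <- numeric(0)
  recurse <- function(remaining, chosen) {
    if (length(chosen) == length(sizes)) {
      out[[length(out) + 1L]] <<- stat_fun(chosen)
      return(invisible())
    }
    k <- sizes[length(chosen) + 1L]
    if (length(chosen) + 1L == length(sizes)) {
      out[[length(out) + 1L]] <<- stat_fun(c(chosen, list(remaining)))
      return(invisible())
    }
    picks <- combn(remaining, k, simplify = FALSE)
    for (p in picks) recurse(setdiff(remaining, p), c(chosen, list(p)))
  }
  recurse(seq_along(values), list())
  out
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' The Mann-Whitney U statistic with midranks. With `n_x + n_y <= 12` and
#' no ties the two-sided p-value is exact, by enumeration of all
#' `choose(n, n_x)` group assignments (assignments whose U deviates from
#' the null mean `n_x n_y / 2` at least as much as observed). Otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param data A data frame with exactly two groups.
#' @param value,group Columns (tidy-eval): numeric response and two-level
#'   grouping variable.
#' @return A [cmf_test] object (`statistic` is U for the first group in
#'   order of appearance).
#' @export
rank_sum_test <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  levels <- unique(g)
  if (length(levels) != 2L) abort("The rank-sum test needs exactly 2 groups.")
  x <- v[g == levels[1]]; y <- v[g == levels[2]]
  if (!length(x) || !length(y)) abort("Both groups must be non-empty.")
  nx <- length(x); ny <- length(y); N <- nx + ny
  rs <- rank_stats(v)
  u <- sum(rs$ranks[g == levels[1]]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  has_ties <- length(rs$ties) > 0L
  if (N <= 12L && !has_ties) {
    us <- combn(N, nx, FUN = function(i) sum(rs$ranks[i])) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    return(new_cmf_test("Mann-Whitney rank-sum test", u, p, c(nx, ny),
                        paste0("exact two-sided p by enumeration of choose(",
                               N, ", ", nx, ") assignments")))
  }
  tie_term <- if (has_ties) sum(rs$ties^3 - rs$ties) / (N * (N - 1)) else 0
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0 || u == mu) {
    return(new_cmf_test("Mann-Whitney rank-sum test", u, 1, c(nx, ny),
                        "normal approximation; statistic at its null mean"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  new_cmf_test("Mann-Whitney rank-sum test", u, p, c(nx, ny),
               paste0("normal approximation with continuity correction",
                      if (has_ties) " and tie-corrected variance" else ""))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with
#' relative tolerance 1e-7 on the comparison). The sample odds ratio
#' `ad/bc` is reported; a zero off-diagonal cell yields an infinite (or
#' zero) estimate, flagged in `method_details`.
#'
#' @param table A 2x2 matrix of non-negative integer counts with all
#'   margins positive.
#' @return A [cmf_test] object (`statistic` is the sample odds ratio).
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab))) {
    abort("`table` must be a 2x2 matrix of non-negative integer counts.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("All margins of the 2x2 table must be positive.")
  }
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  details <- "two-sided by point-probability ordering"
  if (!is.finite(or)) details <- paste0(details, "; odds ratio infinite (zero cell)")
  if (or == 0) details <- paste0(details, "; odds ratio zero (zero cell)")
  new_cmf_test("Fisher's exact test (2x2)", or, p, c(m, n), details,
               observed = tab)
}

#' Kendall's tau-b rank correlation
#'
#' Pair-counting tau-b with the standard tie terms:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` where `n0 = n(n-1)/2` and
#' `n1`, `n2` are the tied-pair counts in each variable. The p-value uses
#' the normal approximation on S = C - D with the tie-corrected variance.
#' Quadratic-time pair counting (vectorized), exact for the cohort sizes
#' this package targets.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval) holding the two numeric variables.
#' @return A [cmf_test] object (`statistic` is tau-b).
#' @export
kendall_tau_b <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 2L) abort("Kendall's tau needs >= 2 complete pairs.")
  if (length(unique(xv)) < 2L || length(unique(yv)) < 2L) {
    abort("Kendall's tau is undefined when all values of a variable are tied.")
  }
  sx <- sign(outer(xv, xv, "-")); sy <- sign(outer(yv, yv, "-"))
  s <- sum(sx * sy) / 2
  n0 <- n * (n - 1) / 2
  tx <- as.numeric(table(xv)); tx <- tx[tx > 1]
  ty <- as.numeric(table(yv)); ty <- ty[ty > 1]
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- s / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  p <- if (var_s <= 0) 1 else min(1, 2 * pnorm(-abs(s) / sqrt(var_s)))
  new_cmf_test("Kendall's tau-b", tau, p, n,
               paste0("normal approximation on S = C - D",
                      if (n1 + n2 > 0) ", tie-corrected" else ""),
               S = s)
}
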