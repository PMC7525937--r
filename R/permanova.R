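#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared distances among genomes into
#' between-group and within-group components and tests group separation
#' with a pseudo-F ratio whose null distribution is obtained by permuting
#' the group labels:
#' `SS_total = (1/N) * sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`,
#' `pseudo-F = (SS_between / (g - 1)) / (SS_within / (N - g))`, and
#' `p = (1 + #permutations with F >= F_obs) / (1 + n_permutations)`.
#'
#' @param dist A [stats::dist] object.
#' @param groups Group labels parallel to the distance object's ids
#'   (>= 2 groups, each with >= 2 members).
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed Integer seed for the permutation stream (required; the
#'   caller's RNG state is left untouched).
#' @return A `cmf_permanova` object: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`, `df`, `ss_between`, `ss_within`,
#'   `n_per_group`.
#' @export
permanova <- function(dist, groups, n_permutations = 999L, seed) {
  stopifnot(inherits(dist, "dist"))
  n <- attr(dist, "Size")
  if (length(groups) != n) abort("`groups` must be parallel to the distance object.")
  if (n_permutations < 99L) abort("Use at least 99 permutations.")
  if (missing(seed)) abort("`seed` is required for a reproducible permutation test.")
  g <- factor(groups)
  n_per <- as.integer(table(g))
  if (nlevels(g) < 2L || any(n_per < 2L)) {
    abort("PERMANOVA needs >= 2 groups with >= 2 members each.")
  }
  d2 <- as.matrix(dist)^2
  row_tot <- rowSums(d2)
  ss_total <- sum(d2) / (2 * n)
  ngroups <- nlevels(g)
  lvl <- levels(g)

  ss_within_for <- function(labels) {
    ss <- 0
    for (k in seq_len(ngroups)) {
      q <- as.numeric(labels == lvl[k])
      ss <- ss + drop(crossprod(q, d2 %*% q)) / (2 * n_per[k])
    }
    ss
  }

  ss_w <- ss_within_for(g)
  ss_b <- ss_total - ss_w
  df1 <- ngroups - 1L; df2 <- n - ngroups
  if (ss_w <= 1e-12 * ss_total) {
    warn("Within-group sum of squares is zero; pseudo-F is infinite and p is the minimum attainable.")
    return(new_cmf_permanova(Inf, 1 / (n_permutations + 1), n_permutations,
                             seed, c(df1, df2), ss_b, ss_w, n_per))
  }
  f_obs <- (ss_b / df1) / (ss_w / df2)

  # with few distinct label assignments, enumerate them all: the p-value is
  # then exact (the observed assignment is part of the enumeration)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(n_per + 1)))
  if (n_assign <= n_permutations + 1) {
    fs <- enumerate_group_statistics(seq_len(n), n_per, function(idx_groups) {
      ss <- 0
      for (k in seq_along(idx_groups)) {
        ii <- idx_groups[[k]]
        ss <- ss + sum(d2[ii, ii]) / (2 * n_per[k])
      }
      ((ss_total - ss) / df1) / (ss / df2)
    })
    return(new_cmf_permanova(f_obs, mean(fs >= f_obs - 1e-12),
                             length(fs), seed, c(df1, df2), ss_b, ss_w, n_per,
                             method = "complete enumeration of label assignments"))
  }

  exceed <- with_local_seed(seed, {
    count <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- g[sample.int(n)]
      ss_w_p <- ss_within_for(perm)
      f_p <- ((ss_total - ss_w_p) / df1) / (ss_w_p / df2)
      if (f_p >= f_obs - 1e-12) count <- count + 1L
    }
    count
  })
  new_cmf_permanova(f_obs, (1 + exceed) / (1 + n_permutations),
                    n_permutations, seed, c(df1, df2), ss_b, ss_w, n_per)
}

new_cmf_permanova <- function(pseudo_F, p_value, n_permutations, seed, df,
                              ss_between, ss_within, n_per_group,
                              method = "random label permutations") {
  structure(list(pseudo_F = pseudo_F, p_value = p_value,
                 n_permutations = n_permutations, seed = seed, df = df,
                 ss_between = ss_between, ss_within = ss_within,
                 n_per_group = n_per_group, method = method),
            class = "cmf_permanova")
}

#' @export
print.cmf_permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_permutations, " permutations, seed ", x$seed, ")\n",
      sep = "")
  cat("  pseudo-F =", format(x$pseudo_F, digits = 5),
      " df =", paste(x$df, collapse = ", "),
      " p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}
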