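# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: statistics are recomputed from definitions (or via the
# corresponding base-R test) and null distributions by explicit enumeration.

# all distinct assignments of labels (with the observed multiplicities) to
# positions, via expand.grid filtering — independent of the package's
# combination-based enumeration
enumerate_label_assignments <- function(labels) {
  lv <- unique(labels)
  grid <- do.call(expand.grid,
                  c(rep(list(lv), length(labels)),
                    list(stringsAsFactors = FALSE)))
  counts <- table(factor(labels, levels = lv))
  keep <- apply(grid, 1, function(row) {
    all(table(factor(row, levels = lv)) == counts)
  })
  grid[keep, , drop = FALSE]
}

# Kruskal-Wallis H as base R computes it
kw_h_oracle <- function(values, labels) {
  unname(stats::kruskal.test(values, factor(labels))$statistic)
}

# exact two-sided Mann-Whitney p by enumeration over label assignments
rank_sum_exact_oracle <- function(x, y) {
  values <- c(x, y)
  labels <- c(rep("x", length(x)), rep("y", length(y)))
  grid <- enumerate_label_assignments(labels)
  r <- rank(values)
  u_for <- function(lab) sum(r[lab == "x"]) - length(x) * (length(x) + 1) / 2
  mu <- length(x) * length(y) / 2
  u_obs <- u_for(labels)
  us <- apply(grid, 1, u_for)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# exact Kruskal-Wallis p by enumeration over label assignments
kw_exact_oracle <- function(values, labels) {
  grid <- enumerate_label_assignments(labels)
  h_obs <- kw_h_oracle(values, labels)
  hs <- apply(grid, 1, function(lab) kw_h_oracle(values, as.character(lab)))
  mean(hs >= h_obs - 1e-12)
}

# PERMANOVA pseudo-F from the definition, straight from a distance matrix
permanova_f_oracle <- function(dmat, labels) {
  n <- nrow(dmat); lv <- unique(labels); g <- length(lv)
  d2 <- dmat^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (l in lv) {
    ii <- which(labels == l)
    sub <- d2[ii, ii, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(ii)
  }
  ((ss_total - ss_w) / (g - 1)) / (ss_w / (n - g))
}

# exact PERMANOVA p by enumeration over label assignments
permanova_exact_oracle <- function(dmat, labels) {
  grid <- enumerate_label_assignments(labels)
  f_obs <- permanova_f_oracle(dmat, labels)
  fs <- apply(grid, 1, function(lab) permanova_f_oracle(dmat, as.character(lab)))
  mean(fs >= f_obs - 1e-12)
}

# Kendall pair-counting oracle: explicit double loop over pairs
kendall_tau_oracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}
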