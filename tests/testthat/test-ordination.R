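random_binary_matrix <- function(n, p, prob = 0.5, groups = rep("A", n)) {
  cells <- matrix(rbinom(n * p, 1L, prob), n, p)
  manual_matrix(cells, groups = groups)
}

test_that("binary distances match the counting definitions and base R", {
  mat <- manual_matrix(rbind(c(1L, 1L, 0L), c(1L, 0L, 1L)))
  dj <- distance_matrix(mat, "jaccard_binary")
  de <- distance_matrix(mat, "euclidean_binary")
  expect_equal(as.numeric(dj), 2 / 3, tolerance = 1e-12)   # a=1, b=1, c=1
  expect_equal(as.numeric(de), sqrt(2), tolerance = 1e-12) # hamming 2
  # identical rows and complementary rows
  m2 <- manual_matrix(rbind(c(1L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 0L)))
  dj2 <- as.matrix(distance_matrix(m2, "jaccard_binary"))
  expect_equal(dj2[1, 2], 0)
  expect_equal(dj2[1, 3], 1)

  set.seed(31)
  m3 <- random_binary_matrix(12, 20)
  keep <- rowSums(as.matrix(m3[, -(1:2)])) > 0
  m3 <- m3[keep, ]
  x <- as.matrix(m3[, -(1:2)])
  expect_equal(as.numeric(distance_matrix(m3, "jaccard_binary")),
               as.numeric(stats::dist(x, method = "binary")), tolerance = 1e-12)
  expect_equal(as.numeric(distance_matrix(m3, "euclidean_binary")),
               as.numeric(stats::dist(x, method = "euclidean")), tolerance = 1e-12)
  # all-absent pair convention
  m0 <- manual_matrix(rbind(c(0L, 0L), c(0L, 0L)))
  expect_warning(d0 <- distance_matrix(m0, "jaccard_binary"), "all-absent")
  expect_equal(as.numeric(d0), 0)
})

test_that("distances are symmetric with zero diagonal; euclidean obeys the triangle inequality", {
  set.seed(8)
  for (i in 1:5) {
    m <- random_binary_matrix(8, 15, prob = runif(1, 0.2, 0.8))
    for (metric in c("jaccard_binary", "euclidean_binary")) {
      d <- suppressWarnings(as.matrix(distance_matrix(m, metric)))
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0))
    }
    de <- as.matrix(distance_matrix(m, "euclidean_binary"))
    n <- nrow(de)
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      expect_lte(de[a, b], de[a, cc] + de[cc, b] + 1e-12)
    }
  }
})

test_that("Ward clustering recovers planted groups and matches hclust heights", {
  blockA <- matrix(rep(c(1L, 0L), c(10, 10)), 6, 20, byrow = TRUE)
  blockB <- matrix(rep(c(0L, 1L), c(10, 10)), 6, 20, byrow = TRUE)
  mat <- manual_matrix(rbind(blockA, blockB),
                       groups = rep(c("A", "B"), each = 6))
  d <- distance_matrix(mat, "euclidean_binary")
  cl <- ward_cluster(d, k = 2)
  expect_equal(length(unique(cl$labels)), 2L)
  expect_true(all(cl$labels[1:6] == cl$labels[1]))
  expect_true(all(cl$labels[7:12] == cl$labels[7]))
  expect_false(cl$labels[1] == cl$labels[7])
  # linkage heights non-decreasing
  expect_true(all(diff(cl$tree$height) >= -1e-9))

  set.seed(41)
  # continuous data: distances are tie-free, so the tie-break cannot differ
  dd <- stats::dist(matrix(rnorm(10 * 6), 10,
                           dimnames = list(paste0("g", 1:10), NULL)))
  ref <- stats::hclust(dd, method = "ward.D2")
  mine <- ward_cluster(dd, k = 3)
  expect_equal(sort(mine$tree$height), sort(ref$height), tolerance = 1e-9)
  expect_equal(stats::cutree(mine$tree, 3)[order(names(stats::cutree(mine$tree, 3)))],
               stats::cutree(ref, 3)[order(names(stats::cutree(ref, 3)))])
})

test_that("degenerate and permuted clustering inputs behave predictably", {
  m2 <- manual_matrix(rbind(c(1L, 0L), c(0L, 1L)))
  cl2 <- ward_cluster(distance_matrix(m2, "euclidean_binary"), k = 2)
  expect_equal(sort(unname(cl2$labels)), c(1L, 2L))
  expect_error(ward_cluster(distance_matrix(m2, "euclidean_binary"), k = 3), "k")

  set.seed(6)
  m <- random_binary_matrix(9, 12)
  perm <- sample(nrow(m))
  l1 <- ward_cluster(distance_matrix(m, "euclidean_binary"), k = 2)$labels
  l2 <- ward_cluster(distance_matrix(m[perm, ], "euclidean_binary"), k = 2)$labels
  # same partition up to relabeling
  agree <- outer(l1[perm], l1[perm], "==") == outer(l2, l2, "==")
  expect_true(all(agree))
})

test_that("the cluster-source table cross-tabulates and transposition keeps Fisher p", {
  labels <- rep(c(1L, 2L), each = 10)
  src <- rep(c("NCBI", "UMGS"), each = 10)
  tab <- cluster_source_table(labels, src)
  expect_equal(unname(tab), matrix(c(10L, 0L, 0L, 10L), 2))
  swapped <- cluster_source_table(3L - labels, src)
  expect_equal(fisher_exact_2x2(tab)$p_value, fisher_exact_2x2(swapped)$p_value)
  expect_error(cluster_source_table(rep(1L, 20), src), "2 clusters")
})

test_that("PCA scores preserve binary-Euclidean distances and order axes", {
  set.seed(14)
  m <- random_binary_matrix(15, 24)
  full <- pca_binary(m, n_axes = 14)
  d_scores <- stats::dist(full$scores)
  d_direct <- distance_matrix(m, "euclidean_binary")
  expect_equal(as.numeric(d_scores), as.numeric(d_direct), tolerance = 1e-9)
  expect_true(all(diff(full$explained_variance) <= 1e-12))
  expect_lte(sum(full$explained_variance), 1 + 1e-12)
  # sign convention: leading loading positive
  for (a in seq_len(ncol(full$loadings))) {
    expect_gte(full$loadings[which.max(abs(full$loadings[, a])), a], 0)
  }
})

test_that("a rank-1 pattern loads entirely on axis 1 and separates planted groups", {
  pattern <- c(1L, 1L, 1L, 0L, 0L)
  cells <- rbind(matrix(rep(pattern, 4), 4, byrow = TRUE),
                 matrix(0L, 4, 5))
  m <- manual_matrix(cells)
  ord <- pca_binary(m, n_axes = 2)
  expect_equal(ord$explained_variance[1], 1, tolerance = 1e-12)
  expect_true(all(sign(ord$scores[1:4, 1]) != sign(ord$scores[5:8, 1])))
  expect_error(pca_binary(manual_matrix(matrix(1L, 3, 4))), "constant")
})

test_that("logistic PCA descends monotonically and separates planted blocks", {
  set.seed(23)
  n <- 40; p <- 60
  block <- rep(c(0.9, 0.1), each = p / 2)
  cells <- rbind(
    matrix(rbinom(n / 2 * p, 1, rep(block, each = n / 2)), n / 2, p),
    matrix(rbinom(n / 2 * p, 1, rep(rev(block), each = n / 2)), n / 2, p)
  )
  m <- manual_matrix(cells, groups = rep(c("A", "B"), each = n / 2))
  fit <- logistic_pca(m, rank = 1, max_iter = 200)
  expect_true(all(diff(fit$objective) <= 1e-8))
  # final fit is at least as good as its linear-PCA-derived starting point
  expect_lte(fit$objective[length(fit$objective)], fit$objective[1])
  s <- fit$scores[, 1]
  expect_true(max(s[1:20]) < min(s[21:40]) || min(s[1:20]) > max(s[21:40]))

  expect_error(logistic_pca(m, rank = 60), "rank")
  bad <- m; bad$k1[1] <- 2L
  expect_error(logistic_pca(bad, rank = 1), "0 or 1")
})

test_that("logistic PCA is deterministic and seeds its random start", {
  set.seed(2)
  m <- random_binary_matrix(12, 10, prob = 0.4)
  f1 <- logistic_pca(m, rank = 2, max_iter = 50)
  f2 <- logistic_pca(m, rank = 2, max_iter = 50)
  expect_identical(f1$scores, f2$scores)
  r1 <- logistic_pca(m, rank = 2, max_iter = 50, random_init = TRUE, seed = 99)
  r2 <- logistic_pca(m, rank = 2, max_iter = 50, random_init = TRUE, seed = 99)
  expect_identical(r1$scores, r2$scores)
  expect_error(logistic_pca(m, rank = 2, random_init = TRUE), "seed")
})

test_that("PERMANOVA matches the definition, vegan, and its invariances", {
  set.seed(19)
  m <- random_binary_matrix(16, 20, groups = rep(c("A", "B"), each = 8))
  d <- distance_matrix(m, "euclidean_binary")
  res <- permanova(d, m$source_group, n_permutations = 199, seed = 3)
  expect_equal(res$pseudo_F,
               permanova_f_oracle(as.matrix(d), m$source_group),
               tolerance = 1e-10)
  ref <- vegan::adonis2(d ~ grp, data = data.frame(grp = m$source_group),
                        permutations = 199)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 1)

  # permuting labels and distance rows together leaves F unchanged
  perm <- sample(16)
  dperm <- stats::as.dist(as.matrix(d)[perm, perm])
  res2 <- permanova(dperm, m$source_group[perm], n_permutations = 199, seed = 3)
  expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-10)

  # two zero-diameter groups at distance 1: maximal separation
  z <- manual_matrix(rbind(matrix(c(1L, 0L), 3, 2, byrow = TRUE),
                           matrix(c(0L, 1L), 3, 2, byrow = TRUE)),
                     groups = rep(c("A", "B"), each = 3))
  dz <- distance_matrix(z, "euclidean_binary")
  expect_warning(rz <- permanova(dz, z$source_group, n_permutations = 999, seed = 1),
                 "infinite")
  expect_equal(rz$p_value, 1 / 1000)
})

test_that("small-sample PERMANOVA p equals complete enumeration", {
  set.seed(27)
  for (i in 1:10) {
    n <- sample(6:8, 1)
    groups <- sample(rep(c("A", "B"), length.out = n))
    if (min(table(groups)) < 2) next
    m <- random_binary_matrix(n, 12, groups = groups)
    d <- suppressWarnings(distance_matrix(m, "jaccard_binary"))
    res <- permanova(d, groups, n_permutations = 999, seed = 5)
    expect_equal(res$p_value, permanova_exact_oracle(as.matrix(d), groups),
                 tolerance = 1e-10)
  }
})

test_that("axis scores correlate with completeness as constructed", {
  set.seed(3)
  m <- random_binary_matrix(10, 14)
  ord <- pca_binary(m, n_axes = 2)
  q <- tibble::tibble(genome_id = m$genome_id,
                      completeness = 50 + 5 * ord$scores[, 1])
  r <- axis_quality_correlation(ord, 1, q)
  expect_equal(r$statistic, 1)
  q$completeness <- 50 - 5 * ord$scores[, 1]
  expect_equal(axis_quality_correlation(ord, 1, q)$statistic, -1)
  expect_error(axis_quality_correlation(ord, 5, q), "does not exist")
})
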