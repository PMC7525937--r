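#' Binary distances between genome presence profiles
#'
#' Pairwise distances between the 0/1 rows of a presence matrix.
#' `jaccard_binary` is `1 - a / (a + b + c)` with `a` the shared presences
#' and `b`, `c` the mismatches; joint absences are uninformative. Two
#' all-zero profiles get distance 0 by convention, with a warning.
#' `euclidean_binary` is the square root of the Hamming mismatch count.
#'
#' @param matrix A presence matrix tibble with >= 2 genomes.
#' @param metric `"jaccard_binary"` or `"euclidean_binary"`.
#' @return A [stats::dist] object labelled with the genome ids.
#' @export
distance_matrix <- function(matrix, metric = c("jaccard_binary", "euclidean_binary")) {
  metric <- match.arg(metric)
  check_presence_matrix(matrix)
  if (nrow(matrix) < 2L) abort("Distances need >= 2 genomes.")
  x <- as.matrix(matrix[presence_keys(matrix)])
  storage.mode(x) <- "double"
  a <- tcrossprod(x)                      # shared presences
  r <- rowSums(x)
  union <- outer(r, r, "+") - a           # a + b + c
  d <- if (metric == "jaccard_binary") {
    if (any(union[upper.tri(union)] == 0)) {
      warn("Pairs of all-absent profiles found; their Jaccard distance is set to 0.")
    }
    ifelse(union == 0, 0, 1 - a / union)
  } else {
    sqrt(pmax(union - a, 0))              # b + c = Hamming count
  }
  stats::as.dist(structure(d, dimnames = list(matrix$genome_id, matrix$genome_id)))
}

#' Ward clustering of a distance matrix
#'
#' Agglomerative clustering with the Ward.D2 convention: the Lance-Williams
#' update is applied to squared input distances and merge heights are the
#' (unsquared) cluster distances. Ties are broken deterministically by
#' merging the candidate pair with the smallest (i, j) cluster-slot indices.
#' With a non-Euclidean input (e.g. Jaccard) the variance interpretation is
#' heuristic but the algorithm is well-defined.
#'
#' @param dist A [stats::dist] object.
#' @param k Number of clusters to cut the tree into (2 <= k <= n).
#' @return A `cmf_cluster` object: `tree` (an [stats::hclust]-compatible
#'   object), `labels` (named cluster memberships at `k`) and `k`.
#' @export
ward_cluster <- function(dist, k = 2L) {
  stopifnot(inherits(dist, "dist"))
  n <- attr(dist, "Size")
  if (k < 2L || k > n) abort("`k` must satisfy 2 <= k <= n.")
  labels <- attr(dist, "Labels") %||% as.character(seq_len(n))

  d2 <- as.matrix(dist)^2
  diag(d2) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  slot_node <- -seq_len(n)                # hclust convention: -obs or +step
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    # first minimum in column-major order of the symmetric masked matrix =
    # the candidate pair with lexicographically smallest (i, j), i < j
    flat <- which.min(d2)
    col <- (flat - 1L) %/% n + 1L
    row <- (flat - 1L) %% n + 1L
    i <- min(row, col); j <- max(row, col)

    merge[step, ] <- sort(c(slot_node[i], slot_node[j]))
    height[step] <- sqrt(d2[i, j])

    others <- which(active); others <- others[others != i & others != j]
    if (length(others)) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      upd <- ((ni + nk) * d2[i, others] + (nj + nk) * d2[j, others] -
                nk * d2[i, j]) / (ni + nj + nk)
      d2[i, others] <- upd; d2[others, i] <- upd
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    d2[j, ] <- Inf; d2[, j] <- Inf
    slot_node[i] <- step
  }

  tree <- structure(
    list(merge = merge, height = height, order = hclust_order(merge),
         labels = labels, method = "ward.D2",
         call = match.call(), dist.method = attr(dist, "method")),
    class = "hclust"
  )
  structure(list(tree = tree, labels = stats::cutree(tree, k = k), k = k),
            class = "cmf_cluster")
}

# leaf order for plotting, by recursive expansion of the merge table
hclust_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.cmf_cluster <- function(x, ...) {
  cat("Ward.D2 clustering of", length(x$labels), "genomes, cut at k =", x$k, "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Cluster-by-source contingency table
#'
#' Cross-tabulates cluster membership at k = 2 against the two genome
#' source groups, for Fisher's exact test of cluster/source association.
#'
#' @param labels Cluster labels (exactly 2 distinct, none empty).
#' @param source_groups Parallel vector of source groups (exactly 2
#'   distinct).
#' @return A 2x2 integer matrix (rows: clusters, columns: sources).
#' @export
cluster_source_table <- function(labels, source_groups) {
  if (length(labels) != length(source_groups)) {
    abort("`labels` and `source_groups` must be parallel vectors.")
  }
  tab <- table(cluster = labels, source = source_groups)
  if (!all(dim(tab) == c(2L, 2L))) {
    abort("Exactly 2 clusters and 2 source groups are required (none empty).")
  }
  unclass(tab)
}

new_cmf_ordination <- function(ids, scores, loadings, explained_variance,
                               method, ...) {
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(ids = ids, scores = scores, loadings = loadings,
                 explained_variance = explained_variance, method = method, ...),
            class = "cmf_ordination")
}

#' @export
print.cmf_ordination <- function(x, ...) {
  cat(x$method, "ordination:", length(x$ids), "genomes,",
      ncol(x$scores), "axes\n")
  cat("explained variance fraction:",
      paste(format(x$explained_variance, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' PCA of a binary presence matrix
#'
#' Principal component analysis of the column-centered (unscaled) 0/1
#' matrix via singular value decomposition. Because centering preserves
#' pairwise row distances, Euclidean distances among the full set of
#' scores equal the binary-Euclidean distances of [distance_matrix()]
#' exactly — this is the "PCA based on Euclidean distances" of a classical
#' ordination. Each axis is oriented so that its largest-magnitude loading
#' is positive.
#'
#' @param matrix A presence matrix tibble (>= 2 genomes, >= 2 keys).
#' @param n_axes Number of axes to return (capped at the matrix rank).
#' @return A `cmf_ordination` object: `ids`, `scores`, `loadings`,
#'   per-axis `explained_variance` fractions, `method = "pca_binary"`.
#' @export
pca_binary <- function(matrix, n_axes = 2L) {
  check_presence_matrix(matrix)
  keys <- presence_keys(matrix)
  if (nrow(matrix) < 2L || length(keys) < 2L) {
    abort("PCA needs >= 2 genomes and >= 2 keys.")
  }
  x <- as.matrix(matrix[keys])
  storage.mode(x) <- "double"
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  pos <- sv$d > max(sv$d) * 1e-12
  if (!any(pos)) abort("The presence matrix is constant; PCA variance is zero.")
  rank <- sum(pos)
  k <- min(n_axes, rank)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {   # orient: largest-|loading| positive
    lead <- which.max(abs(loadings[, a]))
    if (loadings[lead, a] < 0) {
      loadings[, a] <- -loadings[, a]; scores[, a] <- -scores[, a]
    }
  }
  rownames(loadings) <- keys
  new_cmf_ordination(matrix$genome_id, scores, loadings,
                     explained_variance = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                     method = "pca_binary",
                     singular_values = sv$d[pos])
}

#' Correlate an ordination axis with genome completeness
#'
#' Kendall tau-b ([kendall_tau_b()]) between the scores of one ordination
#' axis and the completeness estimates of the same genomes, e.g. to test
#' for a completeness gradient across the ordination space.
#'
#' @param ordination A `cmf_ordination` object.
#' @param axis Axis number.
#' @param quality A tibble with `genome_id` and `completeness`.
#' @return A [cmf_test] object.
#' @export
axis_quality_correlation <- function(ordination, axis, quality) {
  stopifnot(inherits(ordination, "cmf_ordination"))
  if (axis < 1L || axis > ncol(ordination$scores)) {
    abort(paste0("Axis ", axis, " does not exist in this ordination."))
  }
  stopifnot(is.data.frame(quality),
            all(c("genome_id", "completeness") %in% names(quality)))
  d <- tibble(genome_id = ordination$ids,
              score = ordination$scores[, axis]) |>
    dplyr::inner_join(select(quality, "genome_id", "completeness"),
                      by = "genome_id") |>
    filter(!is.na(.data$completeness))
  if (nrow(d) < 3L) abort("Need >= 3 genomes with completeness estimates.")
  kendall_tau_b(d, .data$score, .data$completeness)
}
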