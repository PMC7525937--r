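#' Logistic PCA of a binary matrix
#'
#' Low-rank factorization of a 0/1 matrix under a Bernoulli likelihood in
#' natural-parameter space: the model is `Theta = 1 mu' + U V'` with
#' rank-constrained `U V'`, fitted by minimizing the negative
#' log-likelihood `sum(log(1 + exp(Theta)) - X * Theta)`.
#'
#' Optimization is majorization-minimization with the quadratic bound on
#' the logistic loss (curvature 1/4): each iteration forms the working
#' response `Z = Theta + 4 (X - sigmoid(Theta))`, sets `mu` to the column
#' means of `Z` and the low-rank part to the truncated SVD of the
#' column-centered `Z`. Every step provably does not increase the
#' objective, and the fit is deterministic: the default initialization is
#' the truncated SVD of the centered natural-parameter surrogate
#' `4 (2 X - 1)`; a random initialization is available and uses `seed`.
#'
#' @param matrix A presence matrix tibble (binary cells).
#' @param rank Rank of the factorization, `1 <= rank < min(n, p)`.
#' @param max_iter Maximum number of MM iterations.
#' @param tol Stop when the relative objective decrease falls below this.
#' @param seed Integer seed, used only when `random_init = TRUE`.
#' @param random_init Start from small random factors instead of the SVD
#'   surrogate.
#' @return A `cmf_ordination` object with `method = "logistic_pca"`, plus
#'   fields `mu`, `objective` (per-iteration trace, non-increasing),
#'   `n_iter` and `converged`. `explained_variance` gives each axis's
#'   share of the fitted low-rank natural-parameter energy.
#' @export
logistic_pca <- function(matrix, rank = 2L, max_iter = 200L, tol = 1e-7,
                         seed = NULL, random_init = FALSE) {
  check_presence_matrix(matrix)
  keys <- presence_keys(matrix)
  x <- as.matrix(matrix[keys])
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (rank < 1L || rank >= min(n, p)) {
    abort("`rank` must satisfy 1 <= rank < min(n, p).")
  }

  log1pexp <- function(t) pmax(t, 0) + log1p(exp(-abs(t)))
  objective <- function(theta) sum(log1pexp(theta) - x * theta)

  trunc_svd_parts <- function(z) {
    mu <- colMeans(z)
    zc <- sweep(z, 2L, mu)
    sv <- svd(zc, nu = rank, nv = rank)
    d <- sv$d[seq_len(rank)]
    list(mu = mu, u = sv$u, v = sv$v, d = d,
         low = sv$u %*% (d * t(sv$v)))
  }

  if (random_init) {
    if (is.null(seed)) abort("Random initialization requires `seed`.")
    parts <- with_local_seed(seed, {
      u0 <- matrix(rnorm(n * rank, sd = 0.1), n)
      v0 <- matrix(rnorm(p * rank, sd = 0.1), p)
      list(mu = qlogis(pmin(pmax(colMeans(x), 0.02), 0.98)),
           low = u0 %*% t(v0))
    })
  } else {
    parts <- trunc_svd_parts(4 * (2 * x - 1))
  }
  theta <- outer(rep(1, n), parts$mu) + parts$low
  obj <- objective(theta)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    z <- theta + 4 * (x - plogis(theta))
    parts <- trunc_svd_parts(z)
    theta <- outer(rep(1, n), parts$mu) + parts$low
    obj_new <- objective(theta)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) < tol * (abs(obj) + 1e-12)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }

  scores <- parts$u %*% diag(parts$d, rank)
  loadings <- parts$v
  for (a in seq_len(rank)) {
    lead <- which.max(abs(loadings[, a]))
    if (loadings[lead, a] < 0) {
      loadings[, a] <- -loadings[, a]; scores[, a] <- -scores[, a]
    }
  }
  rownames(loadings) <- keys
  new_cmf_ordination(matrix$genome_id, scores, loadings,
                     explained_variance = parts$d^2 / sum(parts$d^2),
                     method = "logistic_pca",
                     mu = parts$mu, objective = trace,
                     n_iter = length(trace) - 1L, converged = converged)
}
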