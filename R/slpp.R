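#' Fit Supervised Locality Preserving Projections
#'
#' Learns a linear map to a low-dimensional space that preserves
#' within-class neighbourhood structure. The supervised adjacency graph
#' connects samples i and j with weight `exp(-||xi - xj||^2 / t)` only when
#' they share a class label and one is among the other's `k` nearest
#' neighbours (symmetrised by the maximum); between-class weights are zero,
#' so the embedding pulls same-class neighbours together. With the graph
#' Laplacian `L = D - W` (`D` the diagonal row-sum matrix), the projection
#' directions solve the generalized eigenproblem
#' `X L X' a = lambda X D X' a`, keeping the `d_out` smallest-eigenvalue
#' directions.
#'
#' Numerical pipeline: features are standardized (per-dimension zero mean,
#' unit variance; constant dimensions left at scale 1), then pre-projected
#' by PCA retaining `pca_variance` of the variance so that `X D X'` is
#' nonsingular; the generalized problem is solved by Cholesky reduction to
#' an ordinary symmetric eigenproblem. The achievable output rank is the
#' number of retained principal components; requesting more is an error.
#'
#' @param X n x d numeric matrix of training vectors (rows = samples).
#' @param y Binary labels (factor or character/integer), both classes
#'   present.
#' @param d_out Output dimensionality (>= 1).
#' @param k Neighbourhood size (default 5).
#' @param t_mode Kernel width: `"auto"` (mean squared pairwise distance of
#'   the standardized training data) or a positive number.
#' @param pca_variance Fraction of variance retained by the PCA
#'   pre-projection (default 0.98).
#' @return An object of class `slpp_model` with the standardization
#'   statistics, PCA pre-projection, projection matrix (columns ordered by
#'   ascending eigenvalue), eigenvalues, and the parameters used.
#' @export
fit_slpp <- function(X, y, d_out = 30L, k = 5L, t_mode = "auto",
                     pca_variance = 0.98) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("SLPP needs at least 4 training samples")
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("SLPP needs both classes present")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  d_out <- as.integer(d_out)
  if (d_out < 1L) stop("d_out must be >= 1")

  # standardize
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  # PCA pre-projection retaining pca_variance of the variance
  Zc <- sweep(Z, 2, colMeans(Z))
  sv <- svd(Zc, nu = 0)
  pos <- sv$d > max(sv$d) * 1e-10
  var_expl <- cumsum(sv$d[pos]^2) / sum(sv$d[pos]^2)
  n_pc <- max(1L, min(which(var_expl >= pca_variance)))
  P <- sv$v[, seq_len(n_pc), drop = FALSE]
  if (d_out > n_pc) {
    stop("d_out = ", d_out, " exceeds the achievable rank ", n_pc,
         " of the pre-projected training data")
  }
  U <- Zc %*% P  # n x n_pc

  # supervised kNN adjacency
  D2 <- as.matrix(stats::dist(U))^2
  t_ <- if (identical(t_mode, "auto")) mean(D2[upper.tri(D2)]) else as.numeric(t_mode)
  if (!is.finite(t_) || t_ <= 0) t_ <- 1
  W <- matrix(0, n, n)
  same <- outer(y, y, "==")
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nn <- setdiff(ord, i)[seq_len(min(k, n - 1L))]
    W[i, nn] <- exp(-D2[i, nn] / t_)
  }
  W <- pmax(W, t(W))        # symmetrize by max
  W[!same] <- 0             # no between-class edges
  diag(W) <- 0

  dvec <- rowSums(W)
  L <- diag(dvec) - W
  A <- crossprod(U, L %*% U)
  B <- crossprod(U, dvec * U)
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  # B can lose definiteness when the graph has isolated nodes; jitter only then
  R <- tryCatch(chol(B), error = function(e) {
    chol(B + diag(1e-8 * max(diag(B), 1), nrow(B)))
  })
  Rinv <- backsolve(R, diag(nrow(B)))
  C <- t(Rinv) %*% A %*% Rinv
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  ord <- order(eg$values)   # ascending
  vals <- eg$values[ord][seq_len(d_out)]
  vecs <- (Rinv %*% eg$vectors[, ord, drop = FALSE])[, seq_len(d_out), drop = FALSE]

  structure(list(center = ctr, scale = scl, pca = P, pca_center = colMeans(Z),
                 projection = vecs, eigenvalues = vals,
                 d_out = d_out, k = as.integer(k), t = t_,
                 pca_variance = pca_variance, d_in = ncol(X)),
            class = "slpp_model")
}

#' Project data through a fitted SLPP model
#'
#' Applies the stored standardization, PCA pre-projection and SLPP
#' projection. Purely linear and deterministic.
#'
#' @param model An [fit_slpp()] model.
#' @param X Matrix (rows = samples) or a single vector, with the training
#'   dimensionality.
#' @return n x `d_out` matrix of embedded vectors.
#' @export
transform_slpp <- function(model, X) {
  stopifnot(inherits(model, "slpp_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$d_in) {
    stop("input dimension ", ncol(X), " does not match training dimension ",
         model$d_in)
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Zc <- sweep(Z, 2, model$pca_center)
  (Zc %*% model$pca) %*% model$projection
}
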