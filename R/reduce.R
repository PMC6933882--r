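#' Fit a principal component analysis model
#'
#' Mean-centers the feature matrix, eigendecomposes its sample covariance and
#' keeps the top `n_components` eigenvectors by eigenvalue. The decomposition
#' is made deterministic by fixing each component's sign so that its
#' largest-magnitude loading is positive. No variance scaling is applied -
#' features are centered only.
#'
#' If `n_components` exceeds the numerical rank of the centered data (as
#' happens when fewer than 301 samples are reduced to 300 dimensions), the
#' model is truncated to the rank, with a message.
#'
#' @param features Numeric `n x p` matrix, `n >= 2`.
#' @param n_components Number of components to keep; default 300, the
#'   pipeline's reduced dimension for 400-dim Gram features.
#' @return Object of class `"sip_pca"` with fields `mean` (length `p`),
#'   `components` (`k x p`, orthonormal rows), `explained_variance`
#'   (nonincreasing, length `k`).
#' @export
#' @examples
#' m <- fit_pca(matrix(rnorm(40), 10, 4), n_components = 2)
#' m$explained_variance
fit_pca <- function(features, n_components = 300L) {
  features <- as.matrix(features)
  n <- nrow(features); p <- ncol(features)
  if (n < 2L) stop("PCA needs at least 2 samples")
  if (n_components > min(n - 1L, p))
    stop(sprintf("n_components = %d exceeds min(n - 1, p) = %d",
                 n_components, min(n - 1L, p)))
  mu <- colMeans(features)
  xc <- sweep(features, 2L, mu)
  cov <- crossprod(xc) / (n - 1L)
  eig <- eigen(cov, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rank <- sum(ev > max(ev[1], .Machine$double.eps) * 1e-10)
  k <- as.integer(n_components)
  if (k > rank) {
    message(sprintf("requested %d components but data rank is %d; keeping %d",
                    k, rank, rank))
    k <- rank
  }
  comp <- t(eig$vectors[, seq_len(k), drop = FALSE])
  # deterministic sign: largest-magnitude loading of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(mean = mu, components = comp,
                 explained_variance = ev[seq_len(k)]),
            class = "sip_pca")
}

#' @export
print.sip_pca <- function(x, ...) {
  cat(sprintf("PCA model: %d -> %d dims, total explained variance %.4g\n",
              length(x$mean), nrow(x$components), sum(x$explained_variance)))
  invisible(x)
}

#' Project features with a fitted PCA model
#'
#' Applies `(x - mean) %*% t(components)` row-wise.
#'
#' @param model A [fit_pca()] model.
#' @param features Numeric `m x p` matrix with `p` matching the model.
#' @return Numeric `m x k` matrix of scores.
#' @export
apply_pca <- function(model, features) {
  stopifnot(inherits(model, "sip_pca"))
  features <- if (is.null(dim(features))) matrix(features, nrow = 1L)
              else as.matrix(features)
  if (ncol(features) != length(model$mean))
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(features), length(model$mean)))
  sweep(features, 2L, model$mean) %*% t(model$components)
}
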