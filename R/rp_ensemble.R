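# Run code under a temporary RNG state seeded with `seed`; NULL leaves the
# global stream untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a random projection matrix
#'
#' Draws a `q x n` projection whose `n` columns all have unit l2 norm.
#' `"gaussian_sphere"` draws each column i.i.d. standard normal and normalizes
#' it, so columns are uniform on the `q`-dimensional unit sphere;
#' `"bernoulli_pm1"` draws entries from {+1, -1} equiprobably and scales
#' columns by `1 / sqrt(q)`.
#'
#' @param q Projected dimension, `1 <= q < n`.
#' @param n Input dimension.
#' @param kind `"gaussian_sphere"` or `"bernoulli_pm1"`.
#' @param seed Optional integer; identical seeds give identical matrices.
#' @return Object of class `"random_projection"` with fields `matrix`
#'   (`q x n`) and `kind`.
#' @export
sample_projection <- function(q, n, kind = c("gaussian_sphere", "bernoulli_pm1"),
                              seed = NULL) {
  kind <- match.arg(kind)
  if (q < 1L || q >= n) stop("projection requires 1 <= q < n")
  R <- .with_seed(seed, {
    if (kind == "gaussian_sphere") {
      m <- matrix(stats::rnorm(q * n), q, n)
      sweep(m, 2L, sqrt(colSums(m^2)), "/")
    } else {
      matrix(sample(c(-1, 1), q * n, replace = TRUE) / sqrt(q), q, n)
    }
  })
  structure(list(matrix = R, kind = kind), class = "random_projection")
}

#' Project data through a random projection
#'
#' Maps each row of `data` by the projection matrix: row `i` of the result is
#' `R %*% data[i, ]`. Linear and deterministic.
#'
#' @param projection A [sample_projection()] object.
#' @param data Numeric `N x n` matrix (or length-`n` vector).
#' @return Numeric `N x q` matrix.
#' @export
project <- function(projection, data) {
  stopifnot(inherits(projection, "random_projection"))
  data <- if (is.null(dim(data))) matrix(data, nrow = 1L) else as.matrix(data)
  if (ncol(data) != ncol(projection$matrix))
    stop(sprintf("data width %d does not match projection width %d",
                 ncol(data), ncol(projection$matrix)))
  data %*% t(projection$matrix)
}

# Squared Euclidean cross-distances between the rows of two matrices.
.cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# Deterministic kNN votes: for each row of the distance matrix, the majority
# label among the k nearest training points; distance ties broken by smaller
# training index, vote ties called positive.
.knn_votes <- function(d2, labels, k) {
  apply(d2, 1L, function(d) {
    nb <- order(d, seq_along(d))[seq_len(k)]
    as.integer(2L * sum(labels[nb]) >= k)
  })
}

#' Leave-one-out k-nearest-neighbour error
#'
#' For each sample, predicts its label as the majority among its `k` nearest
#' Euclidean neighbours excluding itself (distance ties by smaller index, vote
#' ties positive), and returns the misclassification fraction. This is the
#' test-error estimate the ensemble uses to select one projection and one `k`
#' per block.
#'
#' @param projected Numeric `N x q` matrix of (projected) training samples.
#' @param labels Binary vector of length `N` (1 = SIP).
#' @param k Neighbour count, `1 <= k <= N - 1`.
#' @return Misclassification fraction in `[0, 1]`.
#' @export
loo_knn_error <- function(projected, labels, k) {
  projected <- as.matrix(projected)
  N <- nrow(projected)
  if (N < 2L) stop("leave-one-out needs at least 2 samples")
  if (k < 1L || k >= N) stop("k must satisfy 1 <= k <= N - 1")
  labels <- as.integer(labels)
  d2 <- .cross_dist2(projected, projected)
  diag(d2) <- Inf
  pred <- .knn_votes(d2, labels, k)
  mean(pred != labels)
}

# LOO errors for every k in `ks` from a single self-distance matrix.
.loo_errors <- function(d2, labels, ks) {
  N <- nrow(d2)
  kmax <- max(ks)
  # neighbor labels in distance order (ties by index), first kmax per sample
  nb_lab <- apply(d2, 1L, function(d)
    labels[order(d, seq_along(d))[seq_len(kmax)]])
  nb_lab <- matrix(nb_lab, nrow = kmax)        # kmax x N
  cum <- apply(nb_lab, 2L, cumsum)
  cum <- t(matrix(cum, nrow = kmax))           # N x kmax
  vapply(ks, function(k) {
    pred <- as.integer(2L * cum[, k] >= k)
    mean(pred != labels)
  }, numeric(1))
}

#' Fit the random-projection ensemble classifier
#'
#' Samples `B1 * B2` random projections, partitions them in sampling order
#' into `B1` non-overlapping blocks of `B2`, and in each block scores every
#' (projection, k) pair on the grid by the leave-one-out kNN error of the
#' projected training set, keeping the pair with the smallest error (ties go
#' to the earlier projection, then the smaller k). The voting threshold is set
#' to the positive-class fraction of the training labels - the prior
#' probability of a self-interaction - so that on heavily imbalanced data a
#' minority of block votes already flags a positive.
#'
#' @param features Numeric `N x n` training matrix.
#' @param labels Binary vector of length `N` (1 = SIP); both classes required.
#' @param B1 Number of blocks (ensemble size); default 10.
#' @param B2 Candidate projections per block; default 30.
#' @param q Projected dimension, `< n`; default 5.
#' @param k_grid Candidate neighbour counts; default `seq(1, 30, by = 8)`,
#'   i.e. 1, 9, 17, 25 (capped at `N - 1`).
#' @param kind Projection kind, see [sample_projection()].
#' @param seed Optional integer seed; fixes the whole ensemble.
#' @return Object of class `"rp_ensemble"`: `blocks` (each with `projection`,
#'   `k`, `loo_error`, projected training set), `vote_threshold`, `k_grid`,
#'   `dims`, plus the stored training labels.
#' @export
rp_fit <- function(features, labels, B1 = 10L, B2 = 30L, q = 5L,
                   k_grid = seq(1L, 30L, by = 8L),
                   kind = c("gaussian_sphere", "bernoulli_pm1"), seed = NULL) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  N <- nrow(features); n <- ncol(features)
  if (length(labels) != N) stop("features and labels lengths differ")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop("training labels must contain both classes")
  if (B1 < 1L || B2 < 1L) stop("B1 and B2 must be positive")
  k_grid <- sort(unique(as.integer(k_grid)))
  k_grid <- k_grid[k_grid >= 1L & k_grid <= N - 1L]
  if (length(k_grid) == 0L) stop("no usable k in k_grid for this sample size")

  projections <- .with_seed(seed, lapply(seq_len(B1 * B2), function(i)
    sample_projection(q, n, kind)))

  blocks <- lapply(seq_len(B1), function(b) {
    best <- NULL
    for (j in seq_len(B2)) {
      pr <- projections[[(b - 1L) * B2 + j]]
      Tproj <- project(pr, features)
      d2 <- .cross_dist2(Tproj, Tproj)
      diag(d2) <- Inf
      errs <- .loo_errors(d2, labels, k_grid)
      for (m in seq_along(k_grid)) {
        if (is.null(best) || errs[m] < best$loo_error) {
          best <- list(projection = pr, k = k_grid[m], loo_error = errs[m],
                       train = Tproj)
        }
      }
    }
    best
  })

  structure(list(blocks = blocks,
                 vote_threshold = mean(labels == 1L),
                 labels = labels,
                 k_grid = k_grid,
                 kind = kind,
                 dims = c(n = n, q = as.integer(q))),
            class = "rp_ensemble")
}

#' @export
print.rp_ensemble <- function(x, ...) {
  cat(sprintf("Random-projection ensemble: %d blocks, %d -> %d dims, voting threshold %.4f\n",
              length(x$blocks), x$dims["n"], x$dims["q"], x$vote_threshold))
  cat("per-block (k, LOO error):",
      paste(sprintf("(%d, %.3f)",
                    vapply(x$blocks, `[[`, integer(1), "k"),
                    vapply(x$blocks, `[[`, numeric(1), "loo_error")),
            collapse = " "), "\n")
  invisible(x)
}

#' Positive-vote fraction of the ensemble
#'
#' For each sample, each block classifies it by kNN (with the block's selected
#' `k`) against the block's projected training set; the returned score is the
#' fraction of blocks voting positive, a multiple of `1 / B1` in `[0, 1]`.
#' These fractions are the ROC scores of the model.
#'
#' @param model A fitted [rp_fit()] ensemble.
#' @param samples Numeric `m x n` matrix.
#' @return Numeric vector of length `m`.
#' @export
vote_fraction <- function(model, samples) {
  stopifnot(inherits(model, "rp_ensemble"))
  samples <- if (is.null(dim(samples))) matrix(samples, nrow = 1L)
             else as.matrix(samples)
  if (ncol(samples) != model$dims["n"])
    stop(sprintf("sample width %d does not match model width %d",
                 ncol(samples), model$dims["n"]))
  votes <- vapply(model$blocks, function(b) {
    proj <- project(b$projection, samples)
    d2 <- .cross_dist2(proj, b$train)
    .knn_votes(d2, model$labels, b$k)
  }, integer(nrow(samples)))
  votes <- matrix(votes, nrow = nrow(samples))
  rowMeans(votes)
}

#' Predict SIP labels with the ensemble
#'
#' A sample is called positive when its block-vote fraction reaches the
#' model's voting threshold (the training positive-class prior); the
#' comparison is `>=`, so a fraction exactly at the threshold is positive.
#'
#' @param object A fitted [rp_fit()] ensemble.
#' @param samples Numeric `m x n` matrix.
#' @param type `"class"` for binary labels, `"fraction"` for vote fractions.
#' @param ... Unused.
#' @return Integer labels or numeric fractions of length `m`.
#' @export
predict.rp_ensemble <- function(object, samples, type = c("class", "fraction"), ...) {
  type <- match.arg(type)
  fr <- vote_fraction(object, samples)
  if (type == "fraction") return(fr)
  as.integer(fr >= object$vote_threshold)
}
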