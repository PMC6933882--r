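# Shared fixtures and independent brute-force oracles used across the suite.

# A random PSSM with integer-ish or continuous scores.
random_pssm <- function(H, integer_scores = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scores <- if (integer_scores) matrix(sample(-9:9, H * 20, replace = TRUE), H, 20)
            else matrix(rnorm(H * 20), H, 20)
  seq <- paste0(sample(amino_alphabet(), H, replace = TRUE), collapse = "")
  pssm(seq, scores, source = "synthetic")
}

# Eq-style profile-to-score oracle: nested loops, no matrix algebra.
profile_score_oracle <- function(profile, mutation) {
  H <- nrow(profile)
  out <- matrix(0, H, 20)
  for (a in seq_len(H))
    for (b in 1:20)
      for (k in 1:20)
        out[a, b] <- out[a, b] + profile[a, k] * mutation[b, k]
  out
}

# Triple-loop Gram oracle for the 400-dim feature (identity filter case).
gram_oracle <- function(M) {
  G <- matrix(0, 20, 20)
  for (i in 1:20)
    for (j in 1:20)
      for (h in seq_len(nrow(M)))
        G[i, j] <- G[i, j] + M[h, i] * M[h, j]
  as.numeric(t(G))
}

# O(N^2) leave-one-out kNN oracle with the package's documented tie rules:
# distance ties -> smaller training index, vote ties -> positive.
loo_knn_oracle <- function(X, labels, k) {
  X <- as.matrix(X)
  N <- nrow(X)
  wrong <- 0L
  for (i in seq_len(N)) {
    d <- apply(X, 1L, function(r) sqrt(sum((r - X[i, ])^2)))
    others <- setdiff(seq_len(N), i)
    ord <- others[order(d[others], others)]
    nb <- ord[seq_len(k)]
    pred <- as.integer(2 * sum(labels[nb]) >= k)
    if (pred != labels[i]) wrong <- wrong + 1L
  }
  wrong / N
}

# Mann-Whitney concordance oracle for the AUC: exhaustive pair counting,
# ties counted half.
mw_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos)
    for (n in neg)
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Small separable two-class feature set for classifier tests.
separable_set <- function(n_per_class = 30, dim = 20, gap = 6, seed = 99) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * dim, mean = gap), n_per_class, dim),
             matrix(rnorm(n_per_class * dim, mean = -gap), n_per_class, dim))
  list(X = X, y = rep(c(1L, 0L), each = n_per_class))
}
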