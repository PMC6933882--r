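#' Configuration for the synthetic PSSM generator
#'
#' Describes a class-imbalanced collection of synthetic protein profiles. The
#' two classes share a baseline 20-dimensional amino-acid propensity vector;
#' the positive (SIP) class shifts five designated "signal" residues by
#' `effect_size` before renormalization, and every position's score row is
#' the class propensity plus Gaussian noise, multiplied by `score_scale` to
#' put the values on the integer log-odds magnitude of real PSSMs (kNN and
#' PCA are invariant to this overall scaling, but it keeps the integer-rounded
#' fixture files informative). Sequence lengths are uniform on
#' `length_range`.
#'
#' Defaults emulate the curated study compositions at desk scale: class ratios
#' can be taken from [imbalance_preset()] (about 1:11.1 for the human set,
#' 1:7.8 for the yeast set).
#'
#' @param n_pos,n_neg Class sizes (both at least 1).
#' @param length_range Integer `c(min, max)` within `[50, 5000]`.
#' @param effect_size Nonnegative propensity shift delta applied to the 5
#'   signal residues in the positive class; 0 makes the classes exchangeable.
#' @param noise_sd Positive standard deviation of per-position score noise,
#'   on the propensity scale (before `score_scale` is applied).
#' @param score_scale Positive overall score multiplier; default 10.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the config.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(n_pos = 20L, n_neg = 220L,
                         length_range = c(50L, 200L),
                         effect_size = 0.5, noise_sd = 0.1,
                         score_scale = 10, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L)
  if (length_range[1] > length_range[2] ||
      length_range[1] < 50L || length_range[2] > 5000L)
    stop("length_range must be ordered and within [50, 5000]")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (score_scale <= 0) stop("score_scale must be positive")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 effect_size = effect_size, noise_sd = noise_sd,
                 score_scale = score_scale,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' The five designated signal residues
#'
#' The fixed set of amino acids whose propensity the positive class shifts by
#' `effect_size`; fixed so the Gram features can pick up the class contrast.
#'
#' @return Character vector of 5 residue codes.
#' @export
signal_residues <- function() c("A", "C", "H", "S", "V")

#' Class sizes reproducing the study imbalance at a requested total
#'
#' `"human_like"` reproduces a 1441:15938 positive:negative composition
#' (about 1:11.06), `"yeast_like"` 710:5511 (about 1:7.76), scaled to `total`
#' samples. The positive count is the rounded share (at least 1).
#'
#' @param preset `"human_like"` or `"yeast_like"`.
#' @param total Total number of samples.
#' @return Named integer vector `c(n_pos, n_neg)`.
#' @export
#' @examples
#' imbalance_preset("human_like", 240)  # 20 positives, 220 negatives
imbalance_preset <- function(preset = c("human_like", "yeast_like"), total = 240L) {
  preset <- match.arg(preset)
  comp <- switch(preset, human_like = c(1441, 15938), yeast_like = c(710, 5511))
  n_pos <- max(1L, as.integer(round(total * comp[1] / sum(comp))))
  c(n_pos = n_pos, n_neg = as.integer(total) - n_pos)
}

#' Generate a labelled synthetic PSSM dataset
#'
#' Draws `n_pos` positive and `n_neg` negative synthetic proteins per the
#' config: uniform lengths, class-conditional propensity vectors (baseline
#' `1/20` per residue; positives get `+effect_size` on the 5
#' [signal_residues()] and are renormalized), and score rows equal to the
#' scaled propensity vector plus i.i.d. Gaussian noise. Scores are continuous;
#' [write_fixture_pssm_files()] rounds them to the integer PSI-BLAST dialect.
#'
#' @param config A [synth_config()].
#' @return List with `pssms` (list of [pssm()] objects, `source =
#'   "synthetic"`), `labels` (binary vector), and `manifest` (data frame `id`,
#'   `label`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  aa <- amino_alphabet()
  base <- rep(1 / 20, 20)
  pos_prop <- base + config$effect_size * (aa %in% signal_residues())
  pos_prop <- pos_prop / sum(pos_prop)
  labels <- rep(c(1L, 0L), c(config$n_pos, config$n_neg))
  pssms <- .with_seed(config$seed, lapply(seq_along(labels), function(i) {
    H <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
    prop <- if (labels[i] == 1L) pos_prop else base
    scores <- config$score_scale *
      (matrix(rep(prop, each = H), H, 20) +
         matrix(stats::rnorm(H * 20, sd = config$noise_sd), H, 20))
    seq_letters <- sample(aa, H, replace = TRUE, prob = prop)
    pssm(paste0(seq_letters, collapse = ""), scores, source = "synthetic")
  }))
  ids <- sprintf("SYN%04d", seq_along(labels))
  list(pssms = pssms, labels = labels,
       manifest = data.frame(id = ids, label = labels, stringsAsFactors = FALSE))
}

#' Write a synthetic dataset as PSI-BLAST-style fixture files
#'
#' Writes one ASCII PSSM file per protein (scores rounded to integers, the
#' PSI-BLAST dialect) plus a `labels.tsv` manifest in `directory`. All files
#' parse cleanly with [parse_psiblast_pssm()]; parsed scores equal the rounded
#' generator scores.
#'
#' @param dataset Result of [generate_dataset()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, the manifest data frame with a `path` column added.
#' @export
write_fixture_pssm_files <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))
  paths <- vapply(seq_along(dataset$pssms), function(i) {
    p <- dataset$pssms[[i]]
    rounded <- pssm(p$sequence, round(p$scores), source = "synthetic")
    path <- file.path(directory, paste0(dataset$manifest$id[i], ".pssm"))
    write_psiblast_pssm(rounded, path)
    path
  }, character(1))
  write_label_manifest(dataset$manifest, file.path(directory, "labels.tsv"))
  out <- dataset$manifest
  out$path <- paths
  invisible(out)
}
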