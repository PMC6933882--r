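#' Pipeline configuration with the method's default parameters
#'
#' Collects every tunable of the SIP-prediction pipeline in one place.
#' Defaults are the method's operating point: a 7-tap Hamming low-pass filter
#' at cutoff `0.3 * pi` along the sequence, 400-dim Gram features reduced to
#' 300 principal components fit per training fold, and a random-projection
#' ensemble with `B1 = 10` blocks of `B2 = 30` candidates, projected dimension
#' `q = 5`, neighbour grid `seq(1, 30, by = 8)` and the training prior as
#' voting threshold, evaluated with stratified five-fold cross-validation.
#'
#' @param firf_cutoff,firf_order,firf_window FIR filter design settings.
#' @param firf_apply_to `"pssm_columns"` (filter along the sequence, then form
#'   the Gram matrix - the default) or `"gram_rows"` (form the Gram matrix of
#'   the raw PSSM first and filter its 20 rows).
#' @param pca_components PCA target dimension (0 disables reduction).
#' @param pca_global Fit PCA on all samples instead of per training fold.
#' @param rp_B1,rp_B2,rp_q,rp_k_grid,rp_kind Ensemble settings, see [rp_fit()].
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer master seed for fold splits and projection sampling.
#' @return Object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(firf_cutoff = 0.3 * pi, firf_order = 7L,
                            firf_window = "hamming",
                            firf_apply_to = c("pssm_columns", "gram_rows"),
                            pca_components = 300L, pca_global = FALSE,
                            rp_B1 = 10L, rp_B2 = 30L, rp_q = 5L,
                            rp_k_grid = seq(1L, 30L, by = 8L),
                            rp_kind = "gaussian_sphere",
                            cv_folds = 5L, seed = 1L) {
  firf_apply_to <- match.arg(firf_apply_to)
  structure(list(firf_cutoff = firf_cutoff, firf_order = as.integer(firf_order),
                 firf_window = firf_window, firf_apply_to = firf_apply_to,
                 pca_components = as.integer(pca_components),
                 pca_global = isTRUE(pca_global),
                 rp_B1 = as.integer(rp_B1), rp_B2 = as.integer(rp_B2),
                 rp_q = as.integer(rp_q), rp_k_grid = as.integer(rp_k_grid),
                 rp_kind = rp_kind, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("SIP prediction pipeline configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Feature matrix under a pipeline configuration
#'
#' Turns a list of PSSMs into the fixed 400-dim feature matrix using the
#' configured filter. With `firf_apply_to = "gram_rows"` the Gram matrix of
#' the unfiltered PSSM is formed first and the filter runs over its 20 rows
#' instead (the alternative reading of the method; sequence length then plays
#' no role in the filtering).
#'
#' @param pssms List of [pssm()] objects.
#' @param config A [pipeline_config()].
#' @return `length(pssms) x 400` matrix.
#' @export
pipeline_features <- function(pssms, config = pipeline_config()) {
  filt <- design_fir(config$firf_cutoff, config$firf_order, config$firf_window)
  if (config$firf_apply_to == "pssm_columns")
    return(extract_feature_matrix(pssms, filt))
  t(vapply(pssms, function(p) {
    G <- crossprod(p$scores)
    gp <- pssm(paste(rep("A", 20), collapse = ""), G, source = "synthetic")
    as.numeric(t(filter_columns(gp, filt)))
  }, numeric(400)))
}

#' Run the full prediction pipeline
#'
#' PSSMs to features to (per-fold) PCA to random-projection-ensemble
#' cross-validation, all seeded from the config. This is the programmatic
#' equivalent of the command-line `cv` subcommand.
#'
#' @param pssms List of [pssm()] objects.
#' @param labels Binary labels aligned with `pssms`.
#' @param config A [pipeline_config()].
#' @return List with the resolved `config`, the feature matrix `features`,
#'   and the [run_cv()] `report`.
#' @export
run_pipeline <- function(pssms, labels, config = pipeline_config()) {
  features <- pipeline_features(pssms, config)
  report <- run_cv(features, labels,
                   folds = config$cv_folds,
                   n_components = config$pca_components,
                   pca_global = config$pca_global,
                   B1 = config$rp_B1, B2 = config$rp_B2, q = config$rp_q,
                   k_grid = config$rp_k_grid, kind = config$rp_kind,
                   seed = config$seed)
  list(config = config, features = features, report = report)
}

#' Read PSSM files listed in a manifest directory
#'
#' Companion to [write_fixture_pssm_files()]: reads `labels.tsv` and every
#' referenced `<id>.pssm` file from `directory`.
#'
#' @param directory Directory holding `labels.tsv` and per-protein PSSM files.
#' @return List with `pssms`, `labels`, `manifest`.
#' @export
read_pssm_directory <- function(directory) {
  manifest <- read_label_manifest(file.path(directory, "labels.tsv"))
  pssms <- lapply(manifest$id, function(id)
    parse_psiblast_pssm(file.path(directory, paste0(id, ".pssm"))))
  list(pssms = pssms, labels = manifest$label, manifest = manifest)
}

#' Write a feature table as TSV
#'
#' One row per protein: `id` followed by the 400 feature columns `f1..f400`
#' (or however many columns `features` has).
#'
#' @param ids Identifier vector.
#' @param features Numeric matrix, rows aligned with `ids`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(ids, features, path) {
  features <- as.matrix(features)
  df <- data.frame(id = ids, features, stringsAsFactors = FALSE)
  names(df) <- c("id", paste0("f", seq_len(ncol(features))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return List with `ids` and numeric `features` matrix.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  list(ids = as.character(df[[1]]),
       features = as.matrix(df[, -1, drop = FALSE]))
}
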