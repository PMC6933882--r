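#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in PSI-BLAST column order. Every PSSM score
#' matrix, residue profile and mutation matrix in this package indexes its 20
#' columns in this fixed order, so that position-score computations are
#' consistent across modules.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
#' @examples
#' amino_alphabet()
amino_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Construct a position-specific scoring matrix object
#'
#' A PSSM couples a residue sequence of length `H` with an `H x 20` matrix of
#' per-position amino-acid scores (one column per residue type, in
#' [amino_alphabet()] order). Non-standard residues (X, B, Z, ...) are allowed
#' in the sequence; their score rows are kept exactly as given.
#'
#' @param sequence Single string of residue letters (length `H`).
#' @param scores Numeric `H x 20` matrix of finite position scores.
#' @param source One of `"parsed"`, `"profile-derived"`, `"synthetic"`;
#'   records where the matrix came from.
#' @return An object of class `"pssm"` with elements `sequence`, `scores`,
#'   `source`.
#' @export
#' @examples
#' p <- pssm("MK", matrix(0, 2, 20))
#' nrow(p$scores)
pssm <- function(sequence, scores, source = c("parsed", "profile-derived", "synthetic")) {
  source <- match.arg(source)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  H <- nchar(sequence)
  if (H < 1L) stop("PSSM sequence must contain at least one residue")
  if (nrow(scores) != H)
    stop(sprintf("score matrix has %d rows but sequence has %d residues",
                 nrow(scores), H))
  if (ncol(scores) != 20L)
    stop("score matrix must have exactly 20 columns")
  if (!all(is.finite(scores))) stop("PSSM scores must all be finite")
  dimnames(scores) <- list(NULL, amino_alphabet())
  structure(list(sequence = sequence, scores = scores, source = source),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: %d residues (%s), source=%s\n",
              nchar(x$sequence),
              if (nchar(x$sequence) > 12)
                paste0(substr(x$sequence, 1, 12), "...") else x$sequence,
              x$source))
  invisible(x)
}

# A PSI-BLAST matrix row starts with a position index and a residue letter,
# followed by at least the 20 log-odds columns.
.starts_pssm_row <- function(tokens) {
  length(tokens) >= 2L &&
    grepl("^[0-9]+$", tokens[1]) &&
    grepl("^[A-Za-z*]$", tokens[2])
}

#' Parse a PSI-BLAST ASCII PSSM document
#'
#' Reads the format written by `psiblast -out_ascii_pssm`: header lines, one
#' row per residue carrying the position index, the residue letter, 20
#' log-odds columns and (usually) 20 weighted-percentage columns plus two
#' per-position statistics, then trailing K/lambda lines. Only the first 20
#' numeric columns (the log-odds scores) are kept; percentage columns and the
#' trailing statistics block are ignored.
#'
#' @param text Either a path to a PSSM file or a character vector of lines.
#' @return A [pssm()] object with `source = "parsed"`.
#' @export
#' @examples
#' p <- pssm("MK", matrix(1:40, 2, 20))
#' q <- parse_psiblast_pssm(write_psiblast_pssm(p))
#' identical(unname(q$scores), unname(p$scores))
parse_psiblast_pssm <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]

  residues <- character(0)
  rows <- list()
  expected_len <- NA_integer_
  for (i in seq_along(text)) {
    tokens <- strsplit(trimws(text[i]), "\\s+")[[1]]
    if (length(tokens) == 0L || tokens[1] == "") next
    if (!.starts_pssm_row(tokens)) {
      # header and trailing K/lambda statistics lines are ignored
      next
    }
    if (length(tokens) < 22L)
      stop(sprintf("malformed PSSM row at line %d: expected at least 22 fields, found %d",
                   i, length(tokens)))
    if (is.na(expected_len)) expected_len <- length(tokens)
    if (length(tokens) != expected_len)
      stop(sprintf("malformed PSSM row at line %d: expected %d fields, found %d",
                   i, expected_len, length(tokens)))
    vals <- suppressWarnings(as.numeric(tokens[3:22]))
    if (anyNA(vals))
      stop(sprintf("non-numeric score cell in PSSM row at line %d", i))
    residues <- c(residues, tokens[2])
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("no PSSM rows found in document")
  pssm(paste0(residues, collapse = ""),
       do.call(rbind, rows), source = "parsed")
}

#' Write a PSSM as a PSI-BLAST-style ASCII document
#'
#' Emits a document in the `-out_ascii_pssm` dialect that
#' [parse_psiblast_pssm()] accepts: a two-line header, one row per residue
#' with the 1-based position index, the residue letter, the 20 score columns
#' at full precision and 20 zero percentage columns, and a trailing statistics
#' line. Formatting is deterministic, so equal PSSMs produce identical
#' documents and the parse-of-write round trip is the identity on scores and
#' sequence.
#'
#' @param pssm A [pssm()] object.
#' @param path Optional file path; when given the lines are written there.
#' @return Invisibly (if `path` given) or visibly, the character vector of lines.
#' @export
write_psiblast_pssm <- function(pssm, path = NULL) {
  stopifnot(inherits(pssm, "pssm"))
  aa <- amino_alphabet()
  header <- c(
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%6s", c(aa, aa)), collapse = ""))
  )
  residues <- strsplit(pssm$sequence, "")[[1]]
  body <- vapply(seq_along(residues), function(i) {
    scores <- vapply(pssm$scores[i, ], function(v) {
      if (v == round(v) && abs(v) < 1e9) sprintf("%6d", as.integer(v))
      else paste0(" ", formatC(v, digits = 17, format = "g"))
    }, character(1))
    paste0(sprintf("%5d %s ", i, residues[i]),
           paste(scores, collapse = ""),
           paste(rep(sprintf("%4d", 0L), 20), collapse = ""),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, character(1))
  trailer <- c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176")
  lines <- c(header, body, trailer)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Default mutation matrix for profile-derived PSSM scores
#'
#' Returns a 20 x 20 amino-acid substitution scoring matrix in
#' [amino_alphabet()] order, used as the `q(beta, k)` term when a PSSM is
#' computed from a residue-frequency profile. The default is the Dayhoff-model
#' PAM250 log-odds matrix taken from Biostrings, subset to the 20 standard
#' residues.
#'
#' @return Numeric 20 x 20 matrix with residue dimnames.
#' @export
dayhoff_matrix <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for the built-in Dayhoff (PAM250) matrix")
  env <- new.env()
  utils::data("PAM250", package = "Biostrings", envir = env)
  aa <- amino_alphabet()
  m <- env$PAM250[aa, aa]
  storage.mode(m) <- "double"
  m
}

#' Compute PSSM scores from a residue-frequency profile
#'
#' Given per-position occurrence frequencies `p(alpha, k)` and a 20 x 20
#' mutation matrix `q(beta, k)`, the position score for residue type `beta` at
#' position `alpha` is `sum_k p(alpha, k) * q(beta, k)` - the
#' profile-weighted average substitution score. High values mark strongly
#' conserved positions.
#'
#' @param profile `H x 20` matrix of occurrence frequencies; each row must be
#'   nonnegative and sum to 1 (tolerance `1e-9`).
#' @param mutation 20 x 20 mutation matrix; defaults to [dayhoff_matrix()].
#' @param sequence Optional residue string of length `H`; when missing, the
#'   most frequent residue per position is used.
#' @return A [pssm()] with `source = "profile-derived"`.
#' @export
#' @examples
#' prof <- matrix(1 / 20, 3, 20)
#' pssm_from_profile(prof, diag(20))$scores[1, 1]
pssm_from_profile <- function(profile, mutation = dayhoff_matrix(), sequence = NULL) {
  profile <- as.matrix(profile)
  mutation <- as.matrix(mutation)
  if (ncol(profile) != 20L) stop("profile must have 20 columns")
  if (!all(dim(mutation) == c(20L, 20L))) stop("mutation matrix must be 20 x 20")
  if (any(profile < 0)) stop("profile frequencies must be nonnegative")
  if (any(abs(rowSums(profile) - 1) > 1e-9))
    stop("each profile row must sum to 1")
  # C[alpha, beta] = sum_k p(alpha, k) q(beta, k)  ==  P %*% t(Q)
  scores <- profile %*% t(mutation)
  if (is.null(sequence))
    sequence <- paste0(amino_alphabet()[max.col(profile, ties.method = "first")],
                       collapse = "")
  pssm(sequence, scores, source = "profile-derived")
}

#' Read a label manifest
#'
#' Reads a two-column tab-separated file mapping protein identifiers to binary
#' SIP labels (1 = self-interacting, 0 = not).
#'
#' @param path Path to a TSV with columns `id` and `label` (header optional).
#' @return Data frame with character `id` and integer `label`.
#' @export
read_label_manifest <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("id", "label"),
                          colClasses = c("character", "character"))
  if (identical(tolower(df$id[1]), "id")) df <- df[-1, , drop = FALSE]
  lab <- as.integer(df$label)
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  data.frame(id = df$id, label = lab, stringsAsFactors = FALSE)
}

#' Write a label manifest
#'
#' @param manifest Data frame with columns `id` and `label`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_label_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
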