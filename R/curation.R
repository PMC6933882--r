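#' Construct an annotation record for dataset curation
#'
#' Holds the per-protein annotation fields the curation rules inspect:
#' sequence length, self-interaction experimental evidences (each a
#' small-scale or large-scale experiment of a named type), any declared
#' homo-oligomeric state, the number of publications reporting the
#' self-interaction, and whether the protein carries any self-interaction
#' annotation at all (including weaker "physical association" evidence that
#' disqualifies it from the negative set without qualifying it as a positive).
#'
#' @param protein_id Identifier string.
#' @param length Residue count.
#' @param evidences Data frame (or NULL) with columns `scale`
#'   (`"small"`/`"large"`) and `experiment_type` (string).
#' @param oligomer_state One of `"homodimer"`, `"homotrimer"`,
#'   `"other_homo_oligomer"`, `"none"`.
#' @param publications Count of publications reporting self-interaction.
#' @param has_any_sip_annotation Logical; defaults to TRUE when any evidence,
#'   oligomer state or publication is present.
#' @return Object of class `"annotation_record"`.
#' @export
annotation_record <- function(protein_id, length, evidences = NULL,
                              oligomer_state = c("none", "homodimer", "homotrimer",
                                                 "other_homo_oligomer"),
                              publications = 0L,
                              has_any_sip_annotation = NULL) {
  oligomer_state <- match.arg(oligomer_state)
  if (length < 0) stop("length must be nonnegative")
  if (publications < 0) stop("publication count must be nonnegative")
  if (!is.null(evidences)) {
    evidences <- as.data.frame(evidences)
    stopifnot(all(c("scale", "experiment_type") %in% names(evidences)),
              all(evidences$scale %in% c("small", "large")))
  }
  if (is.null(has_any_sip_annotation))
    has_any_sip_annotation <- (!is.null(evidences) && nrow(evidences) > 0) ||
      oligomer_state != "none" || publications > 0
  structure(list(protein_id = protein_id, length = as.integer(length),
                 evidences = evidences, oligomer_state = oligomer_state,
                 publications = as.integer(publications),
                 has_any_sip_annotation = isTRUE(has_any_sip_annotation)),
            class = "annotation_record")
}

#' Sequence-length filter for curation
#'
#' Proteins shorter than 50 or longer than 5000 residues are treated as
#' fragments or outliers and excluded before any labelling; bounds are
#' inclusive.
#'
#' @param record An [annotation_record()].
#' @return TRUE iff `50 <= length <= 5000`.
#' @export
passes_length_filter <- function(record) {
  record$length >= 50L && record$length <= 5000L
}

.n_large_sorts <- function(record) {
  ev <- record$evidences
  if (is.null(ev) || nrow(ev) == 0) return(0L)
  length(unique(ev$experiment_type[ev$scale == "large"]))
}

.n_small <- function(record) {
  ev <- record$evidences
  if (is.null(ev) || nrow(ev) == 0) return(0L)
  sum(ev$scale == "small")
}

#' High-confidence positive (SIP) criterion
#'
#' A length-passing protein is a positive when at least one of the following
#' holds: (a) its self-interaction is supported by one or more small-scale
#' experiments, or by large-scale experiments of at least two distinct types
#' (two runs of the same type do not count); (b) it is annotated as a
#' homo-oligomer (homodimer, homotrimer or other homo-oligomer); (c) its
#' self-interaction is reported by more than two publications.
#'
#' @param record An [annotation_record()] that already passes the length
#'   filter (caller contract).
#' @return TRUE iff the record meets any of (a), (b), (c).
#' @export
is_positive_sip <- function(record) {
  a <- .n_small(record) >= 1L || .n_large_sorts(record) >= 2L
  b <- record$oligomer_state %in% c("homodimer", "homotrimer", "other_homo_oligomer")
  cc <- record$publications > 2L
  a || b || cc
}

#' Negative-candidate criterion
#'
#' The negative set is the proteome with every trace of self-interaction
#' removed: a length-passing protein is a negative candidate only when it
#' carries no self-interaction annotation of any kind - not even a single
#' large-scale evidence that falls short of the positive criteria.
#'
#' @param record An [annotation_record()] passing the length filter.
#' @return TRUE iff the record is annotation-free.
#' @export
is_negative_candidate <- function(record) {
  no_ev <- is.null(record$evidences) || nrow(record$evidences) == 0
  no_ev && !record$has_any_sip_annotation &&
    record$oligomer_state == "none" && record$publications == 0L
}

#' Build a labelled dataset from annotation records
#'
#' Applies the length filter, then partitions the surviving records into
#' positives ([is_positive_sip()]), negatives ([is_negative_candidate()]) and
#' excluded (records with some self-interaction annotation that is too weak
#' for the positive set - these belong to neither class). Returns the label
#' manifest and an exclusion log.
#'
#' @param records List of [annotation_record()] objects.
#' @return List with `manifest` (data frame `id`, `label`), `excluded` (data
#'   frame `id`, `reason` in `"length"`/`"ambiguous"`), and `counts`.
#' @export
build_dataset <- function(records) {
  ids <- vapply(records, `[[`, character(1), "protein_id")
  man_id <- character(0); man_lab <- integer(0)
  exc_id <- character(0); exc_reason <- character(0)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (!passes_length_filter(r)) {
      exc_id <- c(exc_id, ids[i]); exc_reason <- c(exc_reason, "length")
    } else if (is_positive_sip(r)) {
      man_id <- c(man_id, ids[i]); man_lab <- c(man_lab, 1L)
    } else if (is_negative_candidate(r)) {
      man_id <- c(man_id, ids[i]); man_lab <- c(man_lab, 0L)
    } else {
      exc_id <- c(exc_id, ids[i]); exc_reason <- c(exc_reason, "ambiguous")
    }
  }
  list(manifest = data.frame(id = man_id, label = man_lab,
                             stringsAsFactors = FALSE),
       excluded = data.frame(id = exc_id, reason = exc_reason,
                             stringsAsFactors = FALSE),
       counts = c(positive = sum(man_lab == 1L),
                  negative = sum(man_lab == 0L),
                  excluded = length(exc_id)))
}
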