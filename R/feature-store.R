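#' Predictor input containers
#'
#' A \code{feature_set} is the complete input handed to an
#' AlphaFold2-style predictor: the query features, one MSA block, a stack
#' of aligned templates, an optional assembly plan mapping a concatenated
#' multi-chain query back to chains, and an append-only provenance log of
#' every edit.  It is the in-memory analog of the predictor's serialized
#' feature container.
#'
#' @name feature-store
NULL

#' Query features for a single (possibly concatenated) sequence
#'
#' @param sequence residue string (one-letter codes, \code{X} allowed).
#' @param residue_index 0-based integer index per residue; strictly
#'   increasing, may jump at chain breaks.  Defaults to \code{0:(L-1)}.
#' @param between_segment_flags 0/1 vector marking inserted linker
#'   residues; defaults to all zero.
#' @return an object of class \code{query_features}.
#' @export
query_features <- function(sequence,
                           residue_index = NULL,
                           between_segment_flags = NULL) {
  aatype <- encode_sequence(sequence)
  L <- length(aatype)
  if (L == 0L) stop("sequence must be non-empty", call. = FALSE)
  if (is.null(residue_index)) residue_index <- seq_len(L) - 1L
  if (is.null(between_segment_flags)) between_segment_flags <- rep(0L, L)
  structure(list(sequence = toupper(sequence), aatype = aatype,
                 residue_index = as.integer(residue_index),
                 between_segment_flags = as.integer(between_segment_flags)),
            class = "query_features")
}

#' MSA block aligned to a query
#'
#' Integer-encoded alignment rows (values 0--21, 21 = gap/mask) plus the
#' per-cell deletion counts accumulated from insertions relative to the
#' query.  Row 1 is always the query itself.
#'
#' @param rows integer matrix, N_seq x L.
#' @param deletion_counts non-negative integer matrix, N_seq x L;
#'   defaults to all zero.
#' @param row_labels identifiers, length N_seq.
#' @return an object of class \code{msa_block}.
#' @export
msa_block <- function(rows, deletion_counts = NULL, row_labels = NULL) {
  rows <- as.matrix(rows)
  storage.mode(rows) <- "integer"
  if (is.null(deletion_counts))
    deletion_counts <- matrix(0L, nrow(rows), ncol(rows))
  deletion_counts <- as.matrix(deletion_counts)
  storage.mode(deletion_counts) <- "integer"
  if (is.null(row_labels))
    row_labels <- c("query", sprintf("seq%03d", seq_len(nrow(rows) - 1L)))
  stopifnot(identical(dim(rows), dim(deletion_counts)),
            length(row_labels) == nrow(rows))
  structure(list(rows = unname(rows),
                 deletion_counts = unname(deletion_counts),
                 row_labels = as.character(row_labels)),
            class = "msa_block")
}

msa_depth <- function(msa) nrow(msa$rows)

#' One aligned template in the query frame
#'
#' @param labels integer vector length L, values 0--21; 21 marks
#'   positions the template does not cover.
#' @param atom_positions numeric array L x 37 x 3 (Angstrom).
#' @param atom_mask 0/1 matrix L x 37.
#' @param name template identifier.
#' @param sum_prob confidence weight in \code{[0, 1]}; defaults to 1
#'   when no search score is available.
#' @return an object of class \code{template_feature}.
#' @export
template_feature <- function(labels, atom_positions, atom_mask,
                             name = "template", sum_prob = 1.0) {
  labels <- as.integer(labels)
  L <- length(labels)
  stopifnot(identical(dim(atom_positions)[1:3], as.integer(c(L, 37, 3))),
            identical(dim(atom_mask)[1:2], as.integer(c(L, 37))))
  structure(list(labels = labels, atom_positions = atom_positions,
                 atom_mask = (atom_mask != 0) * 1L,
                 name = as.character(name), sum_prob = as.numeric(sum_prob)),
            class = "template_feature")
}

template_coverage <- function(t) which(t$labels != AA_GAP)

#' Assemble a feature set
#'
#' Most users will start from [empty_features()] or
#' [concatenate_chains()] rather than call this directly.
#'
#' @param query a [query_features()].
#' @param msa an [msa_block()]; defaults to the query-only block.
#' @param templates list of [template_feature()].
#' @param assembly optional [assembly_plan()] describing the chain
#'   layout of a concatenated query.
#' @param provenance list of edit records (append-only).
#' @return an object of class \code{feature_set}.
#' @export
feature_set <- function(query, msa = NULL, templates = list(),
                        assembly = NULL, provenance = list()) {
  if (is.null(msa))
    msa <- msa_block(matrix(query$aatype, nrow = 1L),
                     row_labels = "query")
  structure(list(query = query, msa = msa, templates = templates,
                 assembly = assembly, provenance = provenance),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: L=%d, %d MSA row(s), %d template(s)\n",
              length(x$query$aatype), msa_depth(x$msa),
              length(x$templates)))
  if (!is.null(x$assembly))
    cat(sprintf("  assembly: %d segment(s), linker mode '%s'\n",
                nrow(x$assembly$segment_map), x$assembly$linker_mode))
  cat(sprintf("  provenance: %d edit(s)\n", length(x$provenance)))
  invisible(x)
}

# Append one provenance record; every mutating operation goes through
# this so the audit log grows by exactly one entry per edit.
record_edit <- function(fs, op, ...) {
  fs$provenance <- c(fs$provenance, list(list(op = op, params = list(...))))
  fs
}

#' Minimal-information feature set for a query sequence
#'
#' The uninformed baseline: only the query row in the MSA and no
#' templates, so a prediction is driven by learned parameters alone.
#'
#' @param sequence residue string.
#' @return a [feature_set()] that passes [validate_features()].
#' @examples
#' fs <- empty_features("ACDEF")
#' nrow(validate_features(fs)) == 0
#' @export
empty_features <- function(sequence) {
  q <- query_features(sequence)
  record_edit(feature_set(q), "empty_features", sequence = sequence)
}

#' Replace the MSA block of a feature set
#'
#' @param fs a [feature_set()].
#' @param msa an [msa_block()] of matching width whose first row is the
#'   query.
#' @param note free-text provenance note.
#' @return the updated feature set.
#' @export
fs_set_msa <- function(fs, msa, note = "set_msa") {
  stopifnot(inherits(msa, "msa_block"))
  if (ncol(msa$rows) != length(fs$query$aatype))
    stop("MSA width does not match query length", call. = FALSE)
  fs$msa <- msa
  record_edit(fs, note, n_rows = msa_depth(msa))
}

#' Append a template to a feature set
#'
#' @param fs a [feature_set()].
#' @param template a [template_feature()] of matching width.
#' @return the updated feature set.
#' @export
fs_add_template <- function(fs, template) {
  stopifnot(inherits(template, "template_feature"))
  if (length(template$labels) != length(fs$query$aatype))
    stop("template width does not match query length", call. = FALSE)
  fs$templates <- c(fs$templates, list(template))
  record_edit(fs, "add_template", name = template$name,
              n_covered = length(template_coverage(template)))
}

violation <- function(array, index, rule) {
  data.frame(array = array, index = as.integer(index), rule = rule,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(array = character(), index = integer(), rule = character(),
             stringsAsFactors = FALSE)
}

#' Validate a feature set against the container invariants
#'
#' Violations are returned as data, not raised: each row names the
#' offending array, the (1-based) index where the rule failed, and the
#' rule itself.  A well-formed set yields a zero-row frame.
#'
#' @param fs a [feature_set()].
#' @return data.frame with columns \code{array}, \code{index},
#'   \code{rule}; zero rows iff all invariants hold.
#' @export
validate_features <- function(fs) {
  v <- list(no_violations())
  q <- fs$query
  L <- length(q$aatype)
  if (nchar(q$sequence) != L)
    v <- c(v, list(violation("query.sequence", NA,
                             "length(sequence) == length(aatype)")))
  else if (!identical(encode_sequence(q$sequence), q$aatype)) {
    bad <- which(encode_sequence(q$sequence) != q$aatype)[1]
    v <- c(v, list(violation("query.aatype", bad,
                             "aatype[i] equals alphabet index of sequence[i]")))
  }
  if (length(q$residue_index) != L)
    v <- c(v, list(violation("query.residue_index", NA, "length == L")))
  else if (L > 1 && any(diff(q$residue_index) <= 0L))
    v <- c(v, list(violation("query.residue_index",
                             which(diff(q$residue_index) <= 0L)[1],
                             "strictly increasing")))
  if (length(q$between_segment_flags) != L)
    v <- c(v, list(violation("query.between_segment_flags", NA,
                             "length == L")))
  else if (!all(q$between_segment_flags %in% c(0L, 1L)))
    v <- c(v, list(violation("query.between_segment_flags",
                             which(!q$between_segment_flags %in% c(0L, 1L))[1],
                             "flags are 0/1")))
  if (any(q$aatype < 0L | q$aatype > AA_UNKNOWN))
    v <- c(v, list(violation("query.aatype",
                             which(q$aatype < 0L | q$aatype > AA_UNKNOWN)[1],
                             "values in [0, 20]")))

  m <- fs$msa
  if (ncol(m$rows) != L)
    v <- c(v, list(violation("msa.rows", NA, "width equals query length L")))
  if (any(m$rows < 0L | m$rows > AA_GAP))
    v <- c(v, list(violation("msa.rows",
                             which(m$rows < 0L | m$rows > AA_GAP)[1],
                             "cells in [0, 21]")))
  if (ncol(m$rows) == L && !identical(m$rows[1, ], q$aatype))
    v <- c(v, list(violation("msa.rows", 1L,
                             "row 1 is the gapless query")))
  if (any(m$deletion_counts < 0L))
    v <- c(v, list(violation("msa.deletion_counts",
                             which(m$deletion_counts < 0L)[1],
                             "non-negative")))
  if (any(m$deletion_counts[1, ] != 0L))
    v <- c(v, list(violation("msa.deletion_counts", 1L,
                             "query row has zero deletions")))
  if (!identical(dim(m$rows), dim(m$deletion_counts)))
    v <- c(v, list(violation("msa.deletion_counts", NA,
                             "same shape as rows")))
  if (length(m$row_labels) != nrow(m$rows))
    v <- c(v, list(violation("msa.row_labels", NA, "one label per row")))

  for (ti in seq_along(fs$templates)) {
    t <- fs$templates[[ti]]
    arr <- sprintf("templates[%d]", ti)
    if (length(t$labels) != L) {
      v <- c(v, list(violation(paste0(arr, ".labels"), NA,
                               "width equals query length L")))
      next
    }
    if (any(t$labels < 0L | t$labels > AA_GAP))
      v <- c(v, list(violation(paste0(arr, ".labels"),
                               which(t$labels < 0L | t$labels > AA_GAP)[1],
                               "values in [0, 21]")))
    uncov <- t$labels == AA_GAP
    if (any(uncov & rowSums(t$atom_mask) > 0))
      v <- c(v, list(violation(paste0(arr, ".atom_mask"),
                               which(uncov & rowSums(t$atom_mask) > 0)[1],
                               "mask all zero where labels == 21")))
    ca_on <- t$atom_mask[, SLOT_CA] == 1L
    ca_bad <- ca_on & !apply(is.finite(t$atom_positions[, SLOT_CA, ,
                                                        drop = FALSE]),
                             1, all)
    if (any(ca_bad))
      v <- c(v, list(violation(paste0(arr, ".atom_positions"),
                               which(ca_bad)[1],
                               "finite coordinates under CA mask")))
    if (is.na(t$sum_prob) || t$sum_prob < 0 || t$sum_prob > 1)
      v <- c(v, list(violation(paste0(arr, ".sum_prob"), NA,
                               "in [0, 1]")))
  }

  if (!is.null(fs$assembly)) {
    plan_len <- assembly_concat_length(fs$assembly)
    if (plan_len != L)
      v <- c(v, list(violation("assembly.segment_map", NA,
                               "concatenated length equals L")))
  }
  do.call(rbind, v)
}
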