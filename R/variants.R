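#' Query-sequence variants and the two-step revert cycle
#'
#' Point variants change residue propensities (e.g. prolines to break a
#' spurious helix) without touching templates or homolog rows.  The
#' revert cycle runs a prediction with the mutated query, then builds a
#' new feature set whose query is the original sequence and whose
#' template is the (unrelaxed) mutant prediction annotated with the
#' original sequence, so the mutation steers geometry but never
#' survives into the final model.
#'
#' @name variants
NULL

#' Parse a variant specification
#'
#' @param x character vector of entries \code{"chain:OrigPosRepl"}
#'   (e.g. \code{"A:I31P"}); positions are 1-based chain coordinates.
#' @return object of class \code{variant_spec} (a data.frame with
#'   columns chain, orig, pos, repl).
#' @examples
#' variant_spec("A:I31P")
#' @export
variant_spec <- function(x) {
  if (length(x) == 0L)
    return(structure(data.frame(chain = character(), orig = character(),
                                pos = integer(), repl = character(),
                                stringsAsFactors = FALSE),
                     class = c("variant_spec", "data.frame")))
  m <- regmatches(x, regexec("^([A-Za-z*]):([A-Z])([0-9]+)([A-Z])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("malformed variant '", x[bad][1],
         "' (expected e.g. \"A:I31P\")", call. = FALSE)
  structure(data.frame(chain = vapply(m, `[`, "", 2),
                       orig = vapply(m, `[`, "", 3),
                       pos = as.integer(vapply(m, `[`, "", 4)),
                       repl = vapply(m, `[`, "", 5),
                       stringsAsFactors = FALSE),
            class = c("variant_spec", "data.frame"))
}

#' Reverse a variant specification
#' @param v a [variant_spec()].
#' @return the [variant_spec()] with original and replacement swapped.
#' @export
revert_spec <- function(v) {
  out <- v
  out$orig <- v$repl
  out$repl <- v$orig
  out
}

#' Apply point variants to the query
#'
#' The query sequence, aatype and the MSA query row are updated;
#' non-query MSA rows and templates are untouched.  The stated original
#' residue must match the current sequence, guarding against coordinate
#' drift.
#'
#' @param fs a [feature_set()].
#' @param v a [variant_spec()].
#' @return the edited [feature_set()] (one provenance entry).
#' @export
apply_variants <- function(fs, v) {
  if (nrow(v) == 0L) return(fs)
  L <- length(fs$query$aatype)
  plan <- fs$assembly
  chars <- strsplit(fs$query$sequence, "")[[1]]
  for (i in seq_len(nrow(v))) {
    col <- resolve_region(region_selection(v$chain[i], v$pos[i],
                                           v$pos[i]),
                          plan, L)
    if (length(col) != 1L)
      stop(sprintf("variant %s:%s%d%s resolves to %d positions (need exactly 1; use an output chain letter for one copy)",
                   v$chain[i], v$orig[i], v$pos[i], v$repl[i],
                   length(col)), call. = FALSE)
    pos <- col + 1L
    if (chars[pos] != v$orig[i])
      stop(sprintf("variant %s:%s%d%s: sequence has %s at that position",
                   v$chain[i], v$orig[i], v$pos[i], v$repl[i],
                   chars[pos]), call. = FALSE)
    chars[pos] <- v$repl[i]
  }
  new_seq <- paste(chars, collapse = "")
  fs$query <- query_features(new_seq,
                             residue_index = fs$query$residue_index,
                             between_segment_flags =
                               fs$query$between_segment_flags)
  fs$msa$rows[1, ] <- fs$query$aatype
  record_edit(fs, "apply_variants",
              variants = sprintf("%s:%s%d%s", v$chain, v$orig, v$pos,
                                 v$repl))
}

#' Build the reverted feature set of a mutation cycle
#'
#' @param fs_mutant the [feature_set()] carrying the mutated query.
#' @param predicted the (unrelaxed) [structure_model()] predicted from
#'   it; must have the query length.
#' @param original_sequence the pre-mutation residue string.
#' @return a [feature_set()] whose query is the original sequence and
#'   whose template stack gains the mutant-derived prediction with
#'   query-sequence labels.
#' @export
revert_cycle <- function(fs_mutant, predicted, original_sequence) {
  L <- length(fs_mutant$query$aatype)
  if (model_length(predicted) != L)
    stop(sprintf("predicted model length %d does not match query length %d",
                 model_length(predicted), L), call. = FALSE)
  q <- query_features(original_sequence,
                      residue_index = fs_mutant$query$residue_index,
                      between_segment_flags =
                        fs_mutant$query$between_segment_flags)
  msa <- fs_mutant$msa
  msa$rows[1, ] <- q$aatype
  tmpl <- structure_to_template(predicted, q,
                                mapping = align_map(seq_len(L) - 1L,
                                                    seq_len(L) - 1L,
                                                    identity = 1),
                                name = paste0(predicted$name,
                                              "_reverted"))
  tmpl <- relabel_template(tmpl, "query", query = q)
  fs <- feature_set(q, msa,
                    templates = c(fs_mutant$templates, list(tmpl)),
                    assembly = fs_mutant$assembly,
                    provenance = fs_mutant$provenance)
  record_edit(fs, "revert_cycle", template = tmpl$name)
}
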