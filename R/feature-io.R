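# On-disk formats for feature sets.
#
# Native format: one JSON file carrying named arrays plus the provenance
# log.  Real-valued arrays are serialized as "%.17g" strings so that
# save -> load is bit-exact for doubles (plain JSON numbers are not).
#
# The stock AlphaFold2 v2.2 container layout (field names aatype,
# residue_index, msa, deletion_matrix_int, template_aatype,
# template_all_atom_positions, template_all_atom_masks,
# template_sequence, template_domain_names, template_sum_probs; one-hot
# residue encodings) is accepted as an import/export dialect carried in
# JSON.  The original binary pickle cannot be read in R; converting
# pickle -> JSON is a one-line numpy script left to the user.

FMT_NATIVE <- "foldsteer-features"

enc_real <- function(x) sprintf("%.17g", as.numeric(x))

dec_real <- function(x) as.numeric(x)

#' Save a feature set
#'
#' @param fs a [feature_set()]; must pass [validate_features()].
#' @param path output file path (JSON).
#' @param dialect \code{"native"} (bit-exact round trip) or \code{"af2"}
#'   (stock AlphaFold2 v2.2 field layout with one-hot encodings).
#' @return \code{path}, invisibly.
#' @seealso [read_features()]
#' @export
write_features <- function(fs, path, dialect = c("native", "af2")) {
  dialect <- match.arg(dialect)
  viol <- validate_features(fs)
  if (nrow(viol) > 0L)
    stop("refusing to save an invalid feature_set: ", viol$rule[1],
         " (", viol$array[1], ")", call. = FALSE)
  obj <- if (dialect == "native") fs_to_native(fs) else fs_to_af2(fs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

fs_to_native <- function(fs) {
  list(
    format = FMT_NATIVE, version = 1L,
    query = list(sequence = fs$query$sequence,
                 residue_index = fs$query$residue_index,
                 between_segment_flags = fs$query$between_segment_flags),
    msa = list(dims = dim(fs$msa$rows),
               rows = as.vector(fs$msa$rows),
               deletion_counts = as.vector(fs$msa$deletion_counts),
               row_labels = fs$msa$row_labels),
    templates = lapply(fs$templates, function(t) list(
      name = t$name,
      sum_prob = enc_real(t$sum_prob),
      labels = t$labels,
      atom_positions = enc_real(as.vector(t$atom_positions)),
      atom_mask = as.vector(t$atom_mask))),
    assembly = if (is.null(fs$assembly)) NULL
               else serialize_plan(fs$assembly),
    provenance = fs$provenance)
}

native_to_fs <- function(obj) {
  q <- query_features(obj$query$sequence,
                      residue_index = obj$query$residue_index,
                      between_segment_flags =
                        obj$query$between_segment_flags)
  L <- length(q$aatype)
  md <- as.integer(obj$msa$dims)
  msa <- msa_block(matrix(as.integer(obj$msa$rows), md[1], md[2]),
                   matrix(as.integer(obj$msa$deletion_counts),
                          md[1], md[2]),
                   as.character(obj$msa$row_labels))
  tmpl <- lapply(obj$templates, function(t) template_feature(
    labels = as.integer(t$labels),
    atom_positions = array(dec_real(t$atom_positions),
                           dim = c(L, 37L, 3L)),
    atom_mask = matrix(as.integer(t$atom_mask), L, 37L),
    name = t$name, sum_prob = dec_real(t$sum_prob)))
  plan <- if (is.null(obj$assembly)) NULL
          else deserialize_plan(obj$assembly)
  prov <- lapply(obj$provenance, function(p)
    list(op = p$op, params = as.list(p$params)))
  feature_set(q, msa, tmpl, assembly = plan, provenance = prov)
}

one_hot <- function(idx, n_classes) {
  m <- matrix(0L, length(idx), n_classes)
  m[cbind(seq_along(idx), idx + 1L)] <- 1L
  m
}

fs_to_af2 <- function(fs) {
  L <- length(fs$query$aatype)
  nt <- length(fs$templates)
  t_aa <- array(0L, dim = c(max(nt, 1L), L, 22L))
  t_pos <- array(0, dim = c(max(nt, 1L), L, 37L, 3L))
  t_msk <- array(0L, dim = c(max(nt, 1L), L, 37L))
  for (i in seq_len(nt)) {
    t <- fs$templates[[i]]
    t_aa[i, , ] <- one_hot(t$labels, 22L)
    t_pos[i, , , ] <- t$atom_positions
    t_msk[i, , ] <- t$atom_mask
  }
  out <- list(
    aatype = one_hot(fs$query$aatype, 21L),
    between_segment_residues = fs$query$between_segment_flags,
    residue_index = fs$query$residue_index,
    seq_length = rep(L, L),
    sequence = fs$query$sequence,
    msa = fs$msa$rows,
    deletion_matrix_int = fs$msa$deletion_counts,
    num_alignments = rep(msa_depth(fs$msa), L),
    template_sequence = vapply(fs$templates, function(t)
      decode_sequence(t$labels), character(1)),
    template_domain_names = vapply(fs$templates, function(t) t$name,
                                   character(1)),
    template_sum_probs = matrix(vapply(fs$templates, function(t)
      t$sum_prob, numeric(1)), ncol = 1L))
  if (nt > 0L) {
    out$template_aatype <- t_aa
    out$template_all_atom_positions <- t_pos
    out$template_all_atom_masks <- t_msk
  } else {
    out$template_aatype <- array(0L, dim = c(0L, L, 22L))
    out$template_all_atom_positions <- array(0, dim = c(0L, L, 37L, 3L))
    out$template_all_atom_masks <- array(0L, dim = c(0L, L, 37L))
  }
  out
}

AF2_REQUIRED <- c("aatype", "residue_index", "msa", "deletion_matrix_int")

af2_to_fs <- function(obj, path) {
  missing <- setdiff(AF2_REQUIRED, names(obj))
  if (length(missing) > 0L)
    stop("dialect error reading ", path, ": unknown field layout, ",
         "missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  aat <- obj$aatype
  aatype <- if (is.matrix(aat)) {
    # one-hot rows -> integer indices (0-based argmax)
    as.integer(max.col(aat, ties.method = "first") - 1L)
  } else as.integer(aat)
  sequence <- if (!is.null(obj$sequence)) obj$sequence
              else decode_sequence(aatype)
  q <- query_features(sequence, residue_index = obj$residue_index,
                      between_segment_flags =
                        if (is.null(obj$between_segment_residues))
                          NULL else obj$between_segment_residues)
  L <- length(q$aatype)
  msa_rows <- matrix(as.integer(obj$msa), nrow = NROW(obj$msa))
  dmi <- matrix(as.integer(obj$deletion_matrix_int),
                nrow = NROW(obj$deletion_matrix_int))
  msa <- msa_block(msa_rows, dmi)
  nt <- 0L
  ta_dim <- dim(obj$template_aatype)
  if (!is.null(ta_dim) && !is.na(ta_dim[1])) nt <- ta_dim[1]
  tmpl <- vector("list", nt)
  for (i in seq_len(nt)) {
    ta <- obj$template_aatype[i, , ]
    labels <- if (is.matrix(ta))
      as.integer(max.col(ta, ties.method = "first") - 1L)
    else as.integer(ta)
    labels[labels > AA_GAP] <- AA_GAP
    nm <- if (!is.null(obj$template_domain_names))
      as.character(obj$template_domain_names[i]) else sprintf("tmpl%d", i)
    sp <- if (!is.null(obj$template_sum_probs))
      as.numeric(obj$template_sum_probs)[i] else 1.0
    tmpl[[i]] <- template_feature(
      labels,
      array(obj$template_all_atom_positions[i, , , ],
            dim = c(L, 37L, 3L)),
      matrix(obj$template_all_atom_masks[i, , ], L, 37L),
      name = nm, sum_prob = sp)
  }
  fs <- feature_set(q, msa, tmpl)
  record_edit(fs, "import_af2_dialect", source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a feature set
#'
#' Accepts the native container written by [write_features()] (bit-exact
#' round trip) and the stock AlphaFold2 v2.2 field layout carried in
#' JSON, converting one-hot residue encodings to the internal integer
#' form.
#'
#' @param path file path.
#' @return a [feature_set()].
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e)
                    stop("dialect error reading ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (identical(obj$format, FMT_NATIVE)) return(native_to_fs(obj))
  af2_to_fs(obj, path)
}
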