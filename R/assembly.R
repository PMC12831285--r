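#' Multi-chain assembly as a concatenated monomer
#'
#' Oligomeric targets are predicted as a single concatenated sequence and
#' split back into chains afterwards.  Two linker devices are offered:
#' \code{index_gap} (default) leaves the sequence untouched and offsets
#' the residue index between segments so the predictor perceives a chain
#' break, while \code{physical} inserts real linker residues flagged in
#' \code{between_segment_flags}.
#'
#' @name assembly
NULL

#' Specify one chain of an assembly
#'
#' @param chain_id single-letter identifier, unique within a plan.
#' @param sequence residue string.
#' @param copies number of copies (\eqn{\ge} 1); copies are expanded in
#'   plan order and receive consecutive output chain letters.
#' @param first_resno author numbering of the first residue, used when a
#'   prediction is disengaged back into chains (e.g. 32 for a construct
#'   whose first modeled residue is residue 32).
#' @return an object of class \code{chain_spec}.
#' @export
chain_spec <- function(chain_id, sequence, copies = 1L, first_resno = 1L) {
  stopifnot(nchar(chain_id) == 1L, copies >= 1L)
  encode_sequence(sequence)  # reject illegal characters early
  structure(list(chain_id = chain_id, sequence = toupper(sequence),
                 copies = as.integer(copies),
                 first_resno = as.integer(first_resno)),
            class = "chain_spec")
}

LINKER_CHAIN <- "-"

#' Build an assembly plan
#'
#' @param chains list of [chain_spec()] objects (ordered).
#' @param linker_mode \code{"index_gap"} or \code{"physical"}.
#' @param index_gap residue-index offset inserted between segments in
#'   \code{index_gap} mode (default 200).
#' @param physical_linker linker residue string used in \code{physical}
#'   mode.
#' @return an object of class \code{assembly_plan} whose
#'   \code{segment_map} covers the concatenated length exactly once.
#' @examples
#' plan <- assembly_plan(list(chain_spec("A", "ACDEFGHIKL", copies = 2)))
#' plan$segment_map
#' @export
assembly_plan <- function(chains, linker_mode = c("index_gap", "physical"),
                          index_gap = 200L, physical_linker = "GGGGS") {
  linker_mode <- match.arg(linker_mode)
  if (length(chains) == 0L) stop("empty assembly plan", call. = FALSE)
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  ids <- vapply(chains, function(s) s$chain_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate chain_id in assembly plan: ",
         ids[duplicated(ids)][1], call. = FALSE)
  stopifnot(index_gap >= 1L)
  # expand copies in plan order
  seg <- list()
  for (s in chains)
    for (cp in seq_len(s$copies))
      seg[[length(seg) + 1L]] <- list(chain_id = s$chain_id, copy = cp,
                                      len = nchar(s$sequence),
                                      first_resno = s$first_resno)
  n_seg <- length(seg)
  if (n_seg > 26L) stop("more than 26 chain segments", call. = FALSE)
  linker_len <- if (linker_mode == "physical") nchar(physical_linker)
                else 0L
  rows <- list()
  off <- 0L
  for (i in seq_len(n_seg)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chain_id = seg[[i]]$chain_id, copy = seg[[i]]$copy,
      out_chain = LETTERS[i], start = off, length = seg[[i]]$len,
      first_resno = seg[[i]]$first_resno, stringsAsFactors = FALSE)
    off <- off + seg[[i]]$len
    if (i < n_seg && linker_len > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = LINKER_CHAIN, copy = i, out_chain = LINKER_CHAIN,
        start = off, length = linker_len, first_resno = 1L,
        stringsAsFactors = FALSE)
      off <- off + linker_len
    }
  }
  structure(list(chains = chains, linker_mode = linker_mode,
                 index_gap = as.integer(index_gap),
                 physical_linker = toupper(physical_linker),
                 segment_map = do.call(rbind, rows)),
            class = "assembly_plan")
}

assembly_concat_length <- function(plan) {
  sm <- plan$segment_map
  sum(sm$length)
}

#' @export
print.assembly_plan <- function(x, ...) {
  sm <- x$segment_map
  real <- sm[sm$chain_id != LINKER_CHAIN, ]
  cat(sprintf("assembly_plan: %d segment(s), total length %d, linker '%s'\n",
              nrow(real), assembly_concat_length(x), x$linker_mode))
  for (i in seq_len(nrow(real)))
    cat(sprintf("  %s (copy %d of %s): columns %d-%d, numbered from %d\n",
                real$out_chain[i], real$copy[i], real$chain_id[i],
                real$start[i] + 1L, real$start[i] + real$length[i],
                real$first_resno[i]))
  invisible(x)
}

serialize_plan <- function(plan) {
  list(chains = lapply(plan$chains, unclass),
       linker_mode = plan$linker_mode, index_gap = plan$index_gap,
       physical_linker = plan$physical_linker)
}

deserialize_plan <- function(obj) {
  chains <- lapply(obj$chains, function(s)
    chain_spec(s$chain_id, s$sequence, s$copies, s$first_resno))
  assembly_plan(chains, linker_mode = obj$linker_mode,
                index_gap = obj$index_gap,
                physical_linker = obj$physical_linker)
}

#' Concatenate an assembly plan into a single-query feature set
#'
#' In \code{index_gap} mode no residues are inserted and the residue
#' index jumps by \code{index_gap + 1} between consecutive segments; in
#' \code{physical} mode the linker residues are inserted with
#' \code{between_segment_flags = 1} and the index stays contiguous.
#'
#' @param plan an [assembly_plan()].
#' @return a [feature_set()] carrying the plan in its \code{assembly}
#'   slot.
#' @export
concatenate_chains <- function(plan) {
  stopifnot(inherits(plan, "assembly_plan"))
  sm <- plan$segment_map
  seqs <- character(nrow(sm))
  for (i in seq_len(nrow(sm))) {
    seqs[i] <- if (sm$chain_id[i] == LINKER_CHAIN) plan$physical_linker
    else {
      spec <- plan$chains[[match(sm$chain_id[i],
                                 vapply(plan$chains, `[[`, "", "chain_id"))]]
      spec$sequence
    }
  }
  sequence <- paste(seqs, collapse = "")
  L <- nchar(sequence)
  residue_index <- integer(L)
  flags <- integer(L)
  if (plan$linker_mode == "physical") {
    residue_index <- seq_len(L) - 1L
    for (i in seq_len(nrow(sm)))
      if (sm$chain_id[i] == LINKER_CHAIN)
        flags[sm$start[i] + seq_len(sm$length[i])] <- 1L
  } else {
    next_idx <- 0L
    for (i in seq_len(nrow(sm))) {
      pos <- sm$start[i] + seq_len(sm$length[i])
      residue_index[pos] <- next_idx + seq_len(sm$length[i]) - 1L
      next_idx <- residue_index[pos[length(pos)]] + 1L + plan$index_gap
    }
  }
  q <- query_features(sequence, residue_index = residue_index,
                      between_segment_flags = flags)
  fs <- feature_set(q, assembly = plan)
  record_edit(fs, "concatenate", linker_mode = plan$linker_mode,
              n_segments = sum(sm$chain_id != LINKER_CHAIN))
}

#' Split a concatenated prediction back into chains
#'
#' Residues are relabeled with the output chain letters of the plan's
#' segment map and renumbered per chain starting at the chain's
#' \code{first_resno}; physical-mode linker residues are dropped.
#'
#' @param model a [structure_model()] over the concatenated query.
#' @param plan the [assembly_plan()] used to build the query.
#' @return a chain-annotated [structure_model()].
#' @export
disengage <- function(model, plan) {
  stopifnot(inherits(model, "structure_model"),
            inherits(plan, "assembly_plan"))
  L <- assembly_concat_length(plan)
  if (model_length(model) != L)
    stop(sprintf("model length %d does not match plan length %d",
                 model_length(model), L), call. = FALSE)
  sm <- plan$segment_map
  keep <- integer(0)
  chain <- character(0)
  resno <- integer(0)
  for (i in seq_len(nrow(sm))) {
    if (sm$chain_id[i] == LINKER_CHAIN) next
    idx <- sm$start[i] + seq_len(sm$length[i])
    keep <- c(keep, idx)
    chain <- c(chain, rep(sm$out_chain[i], sm$length[i]))
    resno <- c(resno, sm$first_resno[i] + seq_len(sm$length[i]) - 1L)
  }
  out <- subset_model(model, keep, name = model$name)
  out$chain <- chain
  out$resno <- resno
  out
}

#' Select residue regions in chain coordinates
#'
#' A region is a set of 1-based inclusive intervals, each attached to a
#' chain of an assembly plan (or \code{"*"} for every chain).  Positions
#' count along the chain sequence (1 = first residue of the chain,
#' independent of author numbering).
#'
#' @param chain chain identifier or \code{"*"}.
#' @param start,end 1-based inclusive interval bounds.
#' @return an object of class \code{region_selection}; combine several
#'   with \code{c()}.
#' @export
region_selection <- function(chain = "*", start, end) {
  stopifnot(length(start) == length(end), all(start >= 1L),
            all(start <= end))
  structure(list(data.frame(chain = rep(chain, length.out = length(start)),
                            start = as.integer(start),
                            end = as.integer(end),
                            stringsAsFactors = FALSE)),
            class = "region_selection")
}

#' @export
c.region_selection <- function(...) {
  parts <- list(...)
  structure(list(do.call(rbind, lapply(parts, function(p) p[[1]]))),
            class = "region_selection")
}

# Resolve a region to 0-based concatenated columns.  Without a plan the
# query is treated as one chain matching any identifier.
resolve_region <- function(region, plan = NULL, L) {
  if (is.null(region)) return(integer(0))
  stopifnot(inherits(region, "region_selection"))
  iv <- region[[1]]
  cols <- integer(0)
  for (r in seq_len(nrow(iv))) {
    if (is.null(plan)) {
      if (iv$end[r] > L)
        stop(sprintf("region %d-%d outside [1, %d]", iv$start[r],
                     iv$end[r], L), call. = FALSE)
      cols <- c(cols, (iv$start[r]:iv$end[r]) - 1L)
      next
    }
    sm <- plan$segment_map
    hit <- sm$chain_id != LINKER_CHAIN &
      (iv$chain[r] == "*" | sm$chain_id == iv$chain[r] |
         sm$out_chain == iv$chain[r])
    if (!any(hit))
      stop("region names unknown chain '", iv$chain[r], "'",
           call. = FALSE)
    for (i in which(hit)) {
      if (iv$end[r] > sm$length[i])
        stop(sprintf("region %d-%d outside chain %s length %d",
                     iv$start[r], iv$end[r], sm$chain_id[i],
                     sm$length[i]), call. = FALSE)
      cols <- c(cols, sm$start[i] + (iv$start[r]:iv$end[r]) - 1L)
    }
  }
  sort(unique(cols))
}
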