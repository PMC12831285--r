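#' Mosaic mode: split large targets, merge overlapping predictions
#'
#' Targets too large for one prediction are decomposed into overlapping
#' segments (preferring chain boundaries, falling back to intra-chain
#' windows), each segment is predicted independently, and the pieces
#' are reassembled by rigid-body superposition on the shared anchor
#' regions.
#'
#' @name mosaic
NULL

#' Split an assembly plan into an overlapping mosaic
#'
#' Whole chains are packed left-to-right into segments of at most
#' \code{max_len} residues; consecutive segments share the previous
#' segment's last chain when it fits, otherwise an \code{overlap}-long
#' tail window.  A single chain longer than \code{max_len} is cut into
#' overlapping windows.
#'
#' @param plan an [assembly_plan()] (index-gap linker mode).
#' @param max_len maximum segment length (residues).
#' @param overlap shared anchor length, at least 30 and below
#'   \code{max_len}.
#' @param seed_policy \code{"independent"} or \code{"best_of_previous"}
#'   (later segments are seeded with a template built from the shared
#'   anchors of the best earlier prediction).
#' @return object of class \code{mosaic_plan}: \code{segments} (list of
#'   0-based concatenated column vectors), \code{anchors} (list of
#'   \code{(i, j, cols)}), \code{seed_policy} and the source plan.
#' @export
mosaic_split <- function(plan, max_len, overlap = 30L,
                         seed_policy = c("independent",
                                         "best_of_previous")) {
  seed_policy <- match.arg(seed_policy)
  stopifnot(inherits(plan, "assembly_plan"), max_len > overlap,
            overlap >= 30L)
  if (plan$linker_mode != "index_gap")
    stop("mosaic mode requires index_gap linkers", call. = FALSE)
  sm <- plan$segment_map
  L <- assembly_concat_length(plan)
  if (L <= max_len) {
    return(structure(list(segments = list(seq_len(L) - 1L),
                          anchors = list(), seed_policy = seed_policy,
                          plan = plan),
                     class = "mosaic_plan"))
  }
  # units: whole chains; oversized chains are subdivided into windows
  # that already carry their mutual overlap
  units <- list()
  for (i in seq_len(nrow(sm))) {
    cols <- sm$start[i] + seq_len(sm$length[i]) - 1L
    if (length(cols) <= max_len) {
      units[[length(units) + 1L]] <- list(cols = cols,
                                          windowed = FALSE)
    } else {
      step <- max_len - overlap
      starts <- seq(1L, length(cols) - overlap, by = step)
      for (s in starts) {
        e <- min(s + max_len - 1L, length(cols))
        units[[length(units) + 1L]] <- list(cols = cols[s:e],
                                            windowed = TRUE)
        if (e == length(cols)) break
      }
    }
  }
  segments <- list()
  current <- NULL
  last_unit <- NULL
  flush <- function() {
    if (!is.null(current))
      segments[[length(segments) + 1L]] <<- current
    current <<- NULL
  }
  for (u in units) {
    if (u$windowed) {
      # pre-anchored window: stands alone
      flush()
      segments[[length(segments) + 1L]] <- u$cols
    } else if (is.null(current)) {
      if (length(segments) > 0L) {
        # anchor a fresh segment on the tail of the previous one
        prev <- segments[[length(segments)]]
        anchor <- prev[seq(max(1L, length(prev) - overlap + 1L),
                           length(prev))]
        current <- if (length(anchor) + length(u$cols) <= max_len)
          c(anchor, u$cols) else u$cols
      } else {
        current <- u$cols
      }
    } else if (length(current) + length(u$cols) <= max_len) {
      current <- c(current, u$cols)
    } else {
      prev <- current
      prev_unit <- last_unit
      flush()
      # anchor the next segment on the previous one: the whole last
      # chain when it fits, otherwise its overlap-long tail
      anchor <- if (!is.null(prev_unit) &&
                    length(prev_unit) + length(u$cols) <= max_len)
        prev_unit
      else prev[seq(max(1L, length(prev) - overlap + 1L),
                    length(prev))]
      current <- c(anchor, u$cols)
    }
    last_unit <- u$cols
  }
  flush()
  segments <- lapply(segments, function(s) sort(unique(s)))
  anchors <- list()
  for (i in seq_len(length(segments) - 1L)) {
    shared <- intersect(segments[[i]], segments[[i + 1L]])
    if (length(shared) < 30L)
      stop(sprintf("adjacent mosaic segments %d and %d share only %d residues (need 30)",
                   i, i + 1L, length(shared)), call. = FALSE)
    anchors[[length(anchors) + 1L]] <- list(i = i, j = i + 1L,
                                            cols = sort(shared))
  }
  structure(list(segments = segments, anchors = anchors,
                 seed_policy = seed_policy, plan = plan),
            class = "mosaic_plan")
}

#' @export
print.mosaic_plan <- function(x, ...) {
  cat(sprintf("mosaic_plan: %d segment(s), seed policy '%s'\n",
              length(x$segments), x$seed_policy))
  for (i in seq_along(x$segments))
    cat(sprintf("  segment %d: %d residues (columns %d-%d)\n", i,
                length(x$segments[[i]]), min(x$segments[[i]]) + 1L,
                max(x$segments[[i]]) + 1L))
  invisible(x)
}

# Restrict a feature set to a 0-based column window (segment frame).
fs_slice <- function(fs, cols) {
  idx <- cols + 1L
  q <- fs$query
  sub_q <- query_features(
    paste(strsplit(q$sequence, "")[[1]][idx], collapse = ""),
    residue_index = q$residue_index[idx],
    between_segment_flags = q$between_segment_flags[idx])
  msa <- msa_block(fs$msa$rows[, idx, drop = FALSE],
                   fs$msa$deletion_counts[, idx, drop = FALSE],
                   fs$msa$row_labels)
  templates <- list()
  for (t in fs$templates) {
    labels <- t$labels[idx]
    if (all(labels == AA_GAP)) next
    templates[[length(templates) + 1L]] <-
      template_feature(labels, t$atom_positions[idx, , , drop = FALSE],
                       t$atom_mask[idx, , drop = FALSE],
                       name = t$name, sum_prob = t$sum_prob)
  }
  out <- feature_set(sub_q, msa, templates, assembly = NULL,
                     provenance = fs$provenance)
  record_edit(out, "mosaic_slice", n_cols = length(cols),
              first_col = cols[1])
}

#' Merge per-segment models into one structure
#'
#' Segment 1 fixes the frame; every later segment is rigid-body
#' superposed (Kabsch on the anchor CA atoms) onto the growing
#' assembly.  Residues in an overlap are taken from the segment with
#' the higher mean confidence over that overlap (earlier segment on
#' ties).  Merging is refused when an anchor superposes worse than
#' \code{threshold}.
#'
#' @param models list of [structure_model()]s, one per segment, with
#'   residue numbers equal to their segment's concatenated columns + 1.
#' @param mplan a [mosaic_plan()].
#' @param threshold anchor CA RMSD acceptance threshold (Angstrom,
#'   default 5).
#' @return merged [structure_model()] with attribute
#'   \code{anchor_rmsd}.
#' @export
mosaic_merge <- function(models, mplan, threshold = 5) {
  stopifnot(length(models) == length(mplan$segments))
  for (s in seq_along(models)) {
    want <- sort(mplan$segments[[s]]) + 1L
    if (!identical(sort(models[[s]]$resno), as.integer(want)))
      stop(sprintf("segment %d model does not cover its segment columns",
                   s), call. = FALSE)
  }
  placed <- models[[1]]
  src_plddt <- function(m, resnos) {
    p <- if (is.null(m$plddt)) rep(100, model_length(m)) else m$plddt
    mean(p[match(resnos, m$resno)])
  }
  anchor_rmsd <- numeric(0)
  for (s in seq_along(models)[-1]) {
    anc <- Filter(function(a) a$j == s && a$i < s, mplan$anchors)
    if (length(anc) == 0L)
      stop("no anchor connects segment ", s, call. = FALSE)
    acols <- sort(unique(unlist(lapply(anc, `[[`, "cols")))) + 1L
    ia <- match(acols, placed$resno)
    ib <- match(acols, models[[s]]$resno)
    if (anyNA(ia) || anyNA(ib) ||
        any(placed$mask[ia, SLOT_CA] == 0) ||
        any(models[[s]]$mask[ib, SLOT_CA] == 0))
      stop("anchor residues lack CA coverage", call. = FALSE)
    fit <- kabsch(ca_coords(models[[s]])[ib, ], ca_coords(placed)[ia, ])
    if (fit$rmsd > threshold)
      stop(sprintf("merge refused: anchor RMSD %.2f A between segments %d and %d exceeds threshold %.2f A",
                   fit$rmsd, anc[[1]]$i, s, threshold), call. = FALSE)
    anchor_rmsd <- c(anchor_rmsd, fit$rmsd)
    moved <- transform_model(models[[s]], fit$rotation, fit$translation)
    overlap <- intersect(placed$resno, moved$resno)
    new_res <- setdiff(moved$resno, placed$resno)
    take_new <- new_res
    if (length(overlap) > 0L &&
        src_plddt(moved, overlap) > src_plddt(placed, overlap)) {
      placed <- subset_model(placed,
                             which(!placed$resno %in% overlap),
                             name = placed$name)
      take_new <- c(overlap, new_res)
    }
    add <- subset_model(moved, which(moved$resno %in% take_new))
    la <- model_length(placed)
    lb <- model_length(add)
    coords <- array(0, dim = c(la + lb, 37L, 3L))
    coords[seq_len(la), , ] <- placed$coords
    coords[la + seq_len(lb), , ] <- add$coords
    placed <- structure_model(
      c(placed$chain, add$chain), c(placed$resno, add$resno),
      c(placed$aatype, add$aatype), coords,
      rbind(placed$mask, add$mask),
      c(placed$plddt %||% rep(100, la),
        add$plddt %||% rep(100, lb)),
      name = "merged")
  }
  ord <- order(placed$resno)
  out <- subset_model(placed, ord, name = "merged")
  attr(out, "anchor_rmsd") <- anchor_rmsd
  out
}

#' Seed later mosaic segments from the best earlier prediction
#'
#' Builds, for every segment after the first, a template carrying the
#' anchor-region geometry of the best-scored earlier model, relabeled
#' with the query sequence.  With \code{seed_policy = "independent"}
#' nothing is produced.
#'
#' @param mplan a [mosaic_plan()].
#' @param best_model a [structure_model()] in the concatenated frame
#'   (residue numbers = columns + 1) covering the anchors.
#' @param segments optional integer vector restricting which segments
#'   to seed (default: all after the first).
#' @return list of [template_feature()]s (segment-local frame), NULL
#'   for segment 1 or unseeded segments.
#' @export
seed_next <- function(mplan, best_model, segments = NULL) {
  out <- vector("list", length(mplan$segments))
  if (mplan$seed_policy == "independent") return(out)
  todo <- segments %||% seq_along(mplan$segments)[-1]
  for (s in intersect(todo, seq_along(mplan$segments)[-1])) {
    anc <- Filter(function(a) a$j == s, mplan$anchors)
    if (length(anc) == 0L) next
    acols <- sort(unique(unlist(lapply(anc, `[[`, "cols"))))
    idx <- match(acols + 1L, best_model$resno)
    if (anyNA(idx) || any(best_model$mask[idx, SLOT_CA] == 0))
      stop("best model does not cover the shared anchor of segment ",
           s, call. = FALSE)
    seg <- sort(mplan$segments[[s]])
    local <- match(acols, seg)
    Lseg <- length(seg)
    labels <- rep(AA_GAP, Lseg)
    ec <- empty_coords(Lseg)
    labels[local] <- best_model$aatype[idx]
    ec$coords[local, , ] <- best_model$coords[idx, , , drop = FALSE]
    ec$mask[local, ] <- best_model$mask[idx, , drop = FALSE]
    out[[s]] <- template_feature(labels, ec$coords, ec$mask,
                                 name = sprintf("seed_segment%d", s))
  }
  out
}
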