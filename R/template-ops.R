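#' Template construction and editing
#'
#' Structures become [template_feature()]s aligned to the query frame.
#' Relabeling (polyalanine / query / custom, with an exception window)
#' and C-beta truncation tune how strongly a template's sequence ties
#' the prediction, while multi-chain assignment reconstructs interfaces
#' by pasting several source structures into disjoint regions of a
#' concatenated query.
#'
#' @name template-ops
NULL

#' Explicit query/template alignment map
#'
#' @param query_pos,template_pos 0-based positions, strictly increasing
#'   and duplicate-free on both sides.
#' @param identity aligned-pair identity fraction, when known.
#' @return an object of class \code{alignment_map}.
#' @export
align_map <- function(query_pos, template_pos, identity = NA_real_) {
  stopifnot(length(query_pos) == length(template_pos))
  query_pos <- as.integer(query_pos)
  template_pos <- as.integer(template_pos)
  if (length(query_pos) > 1L &&
      (any(diff(query_pos) <= 0L) || any(diff(template_pos) <= 0L)))
    stop("alignment map positions must be strictly increasing",
         call. = FALSE)
  structure(list(query_pos = query_pos, template_pos = template_pos,
                 identity = identity),
            class = "alignment_map")
}

# Global alignment of template sequence vs query via Biostrings
# (BLOSUM62, affine gaps), returning an alignment_map.
auto_align_map <- function(query_seq, template_seq) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("X", "A", query_seq)),
    Biostrings::AAString(gsub("X", "A", template_seq)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- ti <- 0L
  qp <- tp <- integer(0)
  ident <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") qi <- qi + 1L
    if (s[k] != "-") ti <- ti + 1L
    if (p[k] != "-" && s[k] != "-") {
      qp <- c(qp, qi - 1L)
      tp <- c(tp, ti - 1L)
      if (p[k] == s[k]) ident <- ident + 1L
    }
  }
  if (length(qp) == 0L)
    stop("no alignable residues between template and query",
         call. = FALSE)
  align_map(qp, tp, identity = ident / length(qp))
}

#' Convert a structure into a template aligned to the query
#'
#' Coordinates and atom masks are copied verbatim (no superposition)
#' into the query frame at mapped positions; unmapped positions get
#' label 21 and zero mask.  Automatic mapping uses a global sequence
#' alignment and is rejected below \code{min_identity} (default 20
#' percent) so that remote-homolog templates must be supplied
#' deliberately through an explicit [align_map()].
#'
#' @param structure a [structure_model()].
#' @param query [query_features()] of the prediction target.
#' @param mapping \code{"auto"} or an [align_map()] between the
#'   placement window (0-based) and the structure's residues (0-based).
#' @param placement optional [region_selection()] restricting where in
#'   the query frame the template may land; default everywhere.
#' @param plan optional [assembly_plan()] for resolving \code{placement}.
#' @param min_identity auto-alignment acceptance floor.
#' @param sum_prob template confidence weight in \code{[0,1]}.
#' @param name template name; defaults to the structure name.
#' @return a [template_feature()].
#' @export
structure_to_template <- function(structure, query, mapping = "auto",
                                  placement = NULL, plan = NULL,
                                  min_identity = 0.2, sum_prob = 1.0,
                                  name = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  L <- length(query$aatype)
  qcols <- if (is.null(placement)) seq_len(L) - 1L
           else resolve_region(placement, plan, L)
  sub_seq <- decode_sequence(query$aatype[qcols + 1L])
  if (identical(mapping, "auto")) {
    tseq <- decode_sequence(structure$aatype)
    mapping <- auto_align_map(sub_seq, tseq)
    if (is.na(mapping$identity) || mapping$identity < min_identity)
      stop(sprintf(paste0("automatic alignment identity %.1f%% is below the ",
                          "%.0f%% floor; supply an explicit align_map to use ",
                          "this template deliberately"),
                   100 * mapping$identity, 100 * min_identity),
           call. = FALSE)
  }
  stopifnot(inherits(mapping, "alignment_map"))
  if (any(mapping$query_pos >= length(qcols)) ||
      any(mapping$template_pos >= model_length(structure)))
    stop("alignment map positions out of range", call. = FALSE)
  tpos <- mapping$template_pos + 1L
  if (any(structure$mask[tpos, SLOT_CA] == 0))
    stop("structure lacks CA coordinates for mapped residues",
         call. = FALSE)
  qpos <- qcols[mapping$query_pos + 1L] + 1L   # 1-based query frame
  labels <- rep(AA_GAP, L)
  ec <- empty_coords(L)
  labels[qpos] <- structure$aatype[tpos]
  ec$coords[qpos, , ] <- structure$coords[tpos, , , drop = FALSE]
  ec$mask[qpos, ] <- structure$mask[tpos, , drop = FALSE]
  template_feature(labels, ec$coords, ec$mask,
                   name = name %||% structure$name,
                   sum_prob = sum_prob)
}

#' Relabel a template's residue annotation
#'
#' Only covered positions (label != 21) are touched, so coverage is
#' invariant.  \code{polyalanine} weakens the sequence tie while keeping
#' the geometry; \code{query} annotates the geometry with the query
#' sequence (the strong tie); \code{custom} writes a user sequence over
#' the covered positions.  An exception \code{region} may override the
#' base mode (e.g. polyalanine everywhere except query labels across a
#' hinge).
#'
#' @param t a [template_feature()].
#' @param mode \code{"keep"}, \code{"polyalanine"}, \code{"query"} or
#'   \code{"custom"}.
#' @param query [query_features()] (required for \code{query} mode or a
#'   \code{region_mode = "query"} window).
#' @param replacement residue string for \code{custom}; its length must
#'   equal the number of covered positions.
#' @param region optional exception window ([region_selection()]).
#' @param region_mode mode applied inside the exception window
#'   (default \code{"query"}).
#' @param plan optional [assembly_plan()] for resolving \code{region}.
#' @return the relabeled [template_feature()].
#' @export
relabel_template <- function(t, mode = c("keep", "polyalanine", "query",
                                         "custom"),
                             query = NULL, replacement = NULL,
                             region = NULL, region_mode = "query",
                             plan = NULL) {
  mode <- match.arg(mode)
  covered <- template_coverage(t)
  L <- length(t$labels)
  new_labels <- t$labels
  apply_mode <- function(idx, m) {
    if (length(idx) == 0L) return()
    if (m == "keep") return()
    if (m == "polyalanine") {
      new_labels[idx] <<- 0L
    } else if (m == "query") {
      if (is.null(query))
        stop("query features required for 'query' relabeling",
             call. = FALSE)
      new_labels[idx] <<- query$aatype[idx]
    } else if (m == "custom") {
      if (is.null(replacement))
        stop("custom relabeling requires a replacement sequence",
             call. = FALSE)
      enc <- encode_sequence(replacement)
      if (length(enc) != length(covered))
        stop(sprintf("replacement length %d does not match the %d covered positions",
                     length(enc), length(covered)), call. = FALSE)
      new_labels[idx] <<- enc[match(idx, covered)]
    }
  }
  exc <- if (is.null(region)) integer(0)
         else intersect(resolve_region(region, plan, L) + 1L, covered)
  apply_mode(setdiff(covered, exc), mode)
  apply_mode(exc, region_mode)
  template_feature(new_labels, t$atom_positions, t$atom_mask,
                   name = t$name, sum_prob = t$sum_prob)
}

GLY <- 7L

#' Truncate a template's side chains to C-beta
#'
#' Zeroes the atom mask for every slot except N, CA, C, O and CB;
#' coordinates are untouched where the mask survives.  Glycine keeps no
#' CB.  Idempotent.
#'
#' @param t a [template_feature()].
#' @return the truncated [template_feature()].
#' @export
truncate_to_cbeta <- function(t) {
  keep <- c(SLOT_N, SLOT_CA, SLOT_C, SLOT_O, SLOT_CB)
  mask <- matrix(0L, length(t$labels), 37L)
  mask[, keep] <- t$atom_mask[, keep]
  mask[t$labels == GLY, SLOT_CB] <- 0L
  template_feature(t$labels, t$atom_positions, mask,
                   name = t$name, sum_prob = t$sum_prob)
}

#' Compose one template from several source structures
#'
#' Each source contributes its own rigid block at its assigned region;
#' inter-region geometry is preserved exactly as found in the sources
#' (no re-superposition), so interfaces present in a source structure
#' are encoded verbatim.
#'
#' @param assignments list of entries, each a list with
#'   \code{structure} (a [structure_model()]), \code{region} (a
#'   [region_selection()]) and optional \code{mapping} (default
#'   \code{"auto"}).
#' @param query [query_features()] of the concatenated target.
#' @param plan optional [assembly_plan()].
#' @param min_identity auto-alignment floor passed through.
#' @param name template name.
#' @param sum_prob confidence weight.
#' @return a [template_feature()] covering the union of the regions.
#' @export
multi_chain_template <- function(assignments, query, plan = NULL,
                                 min_identity = 0.2, name = "composite",
                                 sum_prob = 1.0) {
  L <- length(query$aatype)
  seen <- integer(0)
  for (a in assignments) {
    cols <- resolve_region(a$region, plan, L)
    if (length(intersect(cols, seen)) > 0L)
      stop("overlapping template region assignments", call. = FALSE)
    seen <- c(seen, cols)
  }
  labels <- rep(AA_GAP, L)
  ec <- empty_coords(L)
  for (a in assignments) {
    part <- structure_to_template(a$structure, query,
                                  mapping = a$mapping %||% "auto",
                                  placement = a$region, plan = plan,
                                  min_identity = min_identity)
    cov <- template_coverage(part)
    labels[cov] <- part$labels[cov]
    ec$coords[cov, , ] <- part$atom_positions[cov, , , drop = FALSE]
    ec$mask[cov, ] <- part$atom_mask[cov, , drop = FALSE]
  }
  template_feature(labels, ec$coords, ec$mask, name = name,
                   sum_prob = sum_prob)
}

# View a template as a structure over its covered query positions so
# the ensemble analytics can run on template stacks.
template_to_model <- function(t, name = t$name) {
  cov <- template_coverage(t)
  structure_model(rep("A", length(cov)), cov, t$labels[cov],
                  t$atom_positions[cov, , , drop = FALSE],
                  t$atom_mask[cov, , drop = FALSE], name = name)
}

#' Cluster a template stack into structural state groups
#'
#' Templates are compared over their common covered CA positions via
#' the structural-correlation machinery ([cc_matrix()] plus the
#' [embed_cc()] embedding) and partitioned into \code{k} groups
#' (default 2, the two-state working assumption; \code{k = "auto"}
#' lets the angular-gap heuristic choose).
#'
#' @param templates list of [template_feature()]s (at least 2) sharing
#'   at least 20 common covered CA positions.
#' @param k number of groups, or \code{"auto"}.
#' @param seed seed for the embedding optimizer.
#' @param min_common minimum shared CA coverage.
#' @return list with \code{groups} (list of template lists),
#'   \code{labels} (integer per template) and \code{analysis} (the
#'   [state_analysis()] object).
#' @export
cluster_templates <- function(templates, k = 2L, seed = 1L,
                              min_common = 20L) {
  stopifnot(length(templates) >= 2L)
  models <- lapply(templates, template_to_model)
  common <- Reduce(intersect, lapply(models, function(m)
    m$resno[m$mask[, SLOT_CA] == 1L]))
  if (length(common) < min_common)
    stop(sprintf("templates share only %d common covered CA positions (need %d)",
                 length(common), min_common), call. = FALSE)
  frame <- build_frame(models)
  cc <- cc_matrix(frame)
  kk <- if (identical(k, "auto")) NULL else as.integer(k)
  emb <- embed_cc(cc, d = 2L, seed = seed, k = kk)
  labels <- emb$cluster
  groups <- lapply(sort(unique(labels)), function(g)
    templates[labels == g])
  list(groups = groups, labels = labels,
       analysis = state_analysis(frame, cc, emb))
}
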