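#' Ensemble analytics: structural correlation, embedding, hinges
#'
#' An ensemble of structures sharing common CA positions is placed in a
#' common frame by iterative mean superposition.  Pairwise structural
#' correlation coefficients (the cosine between deviation vectors from
#' the ensemble mean) feed a low-dimensional embedding whose dot
#' products reproduce the correlations; angular clustering of the
#' embedded vectors separates systematic (state) differences from
#' random ones.  A difference-distance decomposition partitions the
#' residues into rigid groups separated by hinges.
#'
#' @name structclust
NULL

#' Build a common ensemble frame
#'
#' Common positions are the (chain, residue-number) pairs carrying a CA
#' atom in every member.  Every member is superposed onto the running
#' mean (Kabsch), the mean is recomputed, and the loop repeats until
#' the mean moves by less than 1e-6 Angstrom RMSD or 50 iterations.
#' The first structure initializes the mean, making the result
#' deterministic.
#'
#' @param structures list of [structure_model()]s (at least 2).
#' @param selection optional integer vector of residue numbers to
#'   restrict the common positions.
#' @param min_common minimum number of common CA positions (default 10).
#' @return an object of class \code{ensemble_frame} with elements
#'   \code{coords} (n x m x 3 aligned CA coordinates), \code{mean}
#'   (m x 3), \code{positions} (data.frame chain/resno), \code{names}
#'   and \code{member_rmsd}.
#' @export
build_frame <- function(structures, selection = NULL, min_common = 10L) {
  stopifnot(length(structures) >= 2L)
  keys <- lapply(structures, function(m) {
    ok <- m$mask[, SLOT_CA] == 1L
    paste(m$chain[ok], m$resno[ok], sep = "\r")
  })
  common <- Reduce(intersect, keys)
  if (!is.null(selection)) {
    resno <- as.integer(sub(".*\r", "", common))
    common <- common[resno %in% selection]
  }
  if (length(common) < min_common)
    stop(sprintf("only %d common CA positions (need at least %d)",
                 length(common), min_common), call. = FALSE)
  m <- length(common)
  n <- length(structures)
  coords <- array(NA_real_, dim = c(n, m, 3L))
  for (i in seq_len(n)) {
    s <- structures[[i]]
    key <- paste(s$chain, s$resno, sep = "\r")
    coords[i, , ] <- ca_coords(s)[match(common, key), ]
  }
  mean_c <- coords[1, , ]
  for (iter in seq_len(50L)) {
    for (i in seq_len(n)) {
      fit <- kabsch(coords[i, , ], mean_c)
      coords[i, , ] <- fit$fitted
    }
    new_mean <- apply(coords, c(2, 3), mean)
    shift <- sqrt(mean(rowSums((new_mean - mean_c)^2)))
    mean_c <- new_mean
    if (shift < 1e-6) break
  }
  member_rmsd <- vapply(seq_len(n), function(i)
    sqrt(mean(rowSums((coords[i, , ] - mean_c)^2))), numeric(1))
  pos <- data.frame(chain = sub("\r.*", "", common),
                    resno = as.integer(sub(".*\r", "", common)),
                    stringsAsFactors = FALSE)
  structure(list(coords = coords, mean = mean_c, positions = pos,
                 names = vapply(structures, function(s) s$name,
                                character(1)),
                 member_rmsd = member_rmsd),
            class = "ensemble_frame")
}

#' Pairwise structural correlation matrix
#'
#' With deviation vectors d_i = vec(coords_i - mean) over the common
#' positions, CC_ij = (d_i . d_j) / (|d_i||d_j|).  A member identical to
#' the mean (|d_i| = 0) gets CC 1 with other such members and 0
#' elsewhere, and is flagged in the \code{"degenerate"} attribute.
#'
#' @param frame an [build_frame()] result.
#' @return symmetric n x n matrix of class \code{cc_matrix}, diagonal 1,
#'   entries in \code{[-1, 1]}.
#' @export
cc_matrix <- function(frame) {
  n <- dim(frame$coords)[1]
  dev <- matrix(NA_real_, n, dim(frame$coords)[2] * 3L)
  for (i in seq_len(n))
    dev[i, ] <- as.vector(frame$coords[i, , ] - frame$mean)
  norms <- sqrt(rowSums(dev^2))
  zero <- norms < 1e-9
  cc <- matrix(0, n, n)
  nz <- which(!zero)
  if (length(nz) > 0L) {
    u <- dev[nz, , drop = FALSE] / norms[nz]
    cc[nz, nz] <- tcrossprod(u)
  }
  if (any(zero)) cc[zero, zero] <- 1
  diag(cc) <- 1
  cc <- pmin(pmax(cc, -1), 1)
  dimnames(cc) <- list(frame$names, frame$names)
  structure(cc, class = c("cc_matrix", "matrix", "array"),
            degenerate = which(zero))
}

embed_objective <- function(x, cc, d, lambda = 10) {
  n <- nrow(cc)
  X <- matrix(x, n, d)
  G <- tcrossprod(X)
  E <- cc - G
  diag(E) <- 0
  nrm2 <- rowSums(X^2)
  over <- pmax(0, nrm2 - 1)
  0.5 * sum(E^2) + lambda * sum(over^2)
}

embed_gradient <- function(x, cc, d, lambda = 10) {
  n <- nrow(cc)
  X <- matrix(x, n, d)
  G <- tcrossprod(X)
  E <- cc - G
  diag(E) <- 0
  nrm2 <- rowSums(X^2)
  over <- pmax(0, nrm2 - 1)
  as.vector(-2 * (E %*% X) + 4 * lambda * over * X)
}

embed_residual <- function(X, cc) {
  G <- tcrossprod(X)
  E <- cc - G
  sum(E[upper.tri(E)]^2)
}

#' Embed a correlation matrix in low dimension
#'
#' Finds unit-disk vectors x_i minimizing
#' \eqn{\sum_{i<j} (CC_{ij} - x_i \cdot x_j)^2} by multi-start
#' quasi-Newton optimization (best of \code{n_starts} seeded starts,
#' norms clipped to 1).  The embedded vectors are then clustered by
#' angular separation: complete linkage on the pairwise angle, cut at
#' the requested \code{k} or at the largest angular gap.
#'
#' @param cc a [cc_matrix()] (any symmetric matrix with unit diagonal
#'   works).
#' @param d embedding dimension (default 2).
#' @param seed integer seed for the multi-start initialization.
#' @param k number of clusters, or \code{NULL} for the angular-gap
#'   heuristic.
#' @param n_starts number of random starts (default 10).
#' @return object of class \code{state_embedding}: \code{vectors}
#'   (n x d), \code{residual}, \code{cluster} (integer labels),
#'   \code{names}.
#' @export
embed_cc <- function(cc, d = 2L, seed = 1L, k = NULL, n_starts = 10L) {
  n <- nrow(cc)
  best <- NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (s in seq_len(n_starts)) {
    x0 <- as.vector(matrix(stats::runif(n * d, -0.7, 0.7), n, d))
    fit <- stats::optim(x0, embed_objective, embed_gradient,
                        cc = unclass(cc), d = d, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    X <- matrix(fit$par, n, d)
    nrm <- sqrt(rowSums(X^2))
    X <- X / pmax(1, nrm)
    res <- embed_residual(X, unclass(cc))
    if (is.null(best) || res < best$residual)
      best <- list(vectors = X, residual = res)
  }
  cl <- cluster_by_angle(best$vectors, k)
  structure(list(vectors = best$vectors, residual = best$residual,
                 cluster = cl,
                 names = rownames(cc) %||% sprintf("m%d", seq_len(n))),
            class = "state_embedding")
}

angle_matrix <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  n <- nrow(X)
  cosm <- matrix(1, n, n)
  nz <- nrm > 1e-9
  if (sum(nz) > 1L) {
    u <- X[nz, , drop = FALSE] / nrm[nz]
    cosm[nz, nz] <- tcrossprod(u)
  }
  # zero-norm vectors sit at the origin: treat as aligned with everything
  acos(pmin(pmax(cosm, -1), 1))
}

cluster_by_angle <- function(X, k = NULL, gap_floor = 0.3) {
  n <- nrow(X)
  if (n == 1L) return(1L)
  ang <- angle_matrix(X)
  hc <- stats::hclust(stats::as.dist(ang), method = "complete")
  if (!is.null(k)) return(unname(stats::cutree(hc, k = min(k, n))))
  h <- hc$height
  if (max(h) < gap_floor) return(rep(1L, n))
  if (length(h) == 1L) return(unname(stats::cutree(hc, k = 2L)))
  gaps <- diff(h)
  cut_at <- which.max(gaps)
  kk <- length(h) - cut_at + 1L
  unname(stats::cutree(hc, k = kk))
}

#' @export
print.state_embedding <- function(x, ...) {
  cat(sprintf("state_embedding: %d members in %d dimension(s), residual %.4g\n",
              nrow(x$vectors), ncol(x$vectors), x$residual))
  cat("  clusters:", paste(table(x$cluster), collapse = " / "), "\n")
  invisible(x)
}

#' @export
plot.state_embedding <- function(x, ...) {
  X <- x$vectors
  if (ncol(X) < 2L) X <- cbind(X, 0)
  graphics::plot(X[, 1], X[, 2], col = x$cluster, pch = 19, asp = 1,
                 xlab = "dimension 1", ylab = "dimension 2",
                 main = "state embedding", xlim = c(-1.1, 1.1),
                 ylim = c(-1.1, 1.1), ...)
  graphics::symbols(0, 0, circles = 1, inherit = FALSE, add = TRUE,
                    fg = "grey70")
  invisible(x)
}

#' Rigid-group / hinge decomposition of an ensemble
#'
#' For every structure pair the difference-distance matrix
#' |d_ab(i) - d_ab(j)| over the common CA positions is aggregated as a
#' maximum.  Contiguous sequence segments are merged bottom-up while
#' the mean aggregated difference between adjacent segments stays
#' within \code{tol}; segments shorter than \code{min_segment} are then
#' absorbed into their cheaper neighbor.  Hinges are the boundaries
#' between the final groups.
#'
#' @param frame an [build_frame()] result.
#' @param tol co-rigidity tolerance in Angstrom (default 1.5);
#'   \code{Inf} collapses everything into one group.
#' @param min_segment minimum group segment length (default 5).
#' @return object of class \code{rigid_decomposition}: \code{groups}
#'   (integer label per common position), \code{positions},
#'   \code{boundaries} (residue numbers opening each new group),
#'   \code{group_rmsd_range} (per group, after group-wise
#'   superposition) and \code{tol}.
#' @export
find_hinges <- function(frame, tol = 1.5, min_segment = 5L) {
  n <- dim(frame$coords)[1]
  m <- dim(frame$coords)[2]
  dmax <- matrix(0, m, m)
  dm <- lapply(seq_len(n), function(i)
    as.matrix(stats::dist(frame$coords[i, , ])))
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n))
      dmax <- pmax(dmax, abs(dm[[i]] - dm[[j]]))
  segs <- as.list(seq_len(m))
  seg_cost <- function(a, b) mean(dmax[a, b])
  repeat {
    if (length(segs) == 1L) break
    costs <- vapply(seq_len(length(segs) - 1L), function(i)
      seg_cost(segs[[i]], segs[[i + 1L]]), numeric(1))
    i <- which.min(costs)
    if (costs[i] > tol) break
    segs[[i]] <- c(segs[[i]], segs[[i + 1L]])
    segs[[i + 1L]] <- NULL
  }
  repeat {
    lens <- vapply(segs, length, 1L)
    if (length(segs) == 1L || all(lens >= min_segment)) break
    i <- which.min(lens)
    left <- if (i > 1L) seg_cost(segs[[i - 1L]], segs[[i]]) else Inf
    right <- if (i < length(segs)) seg_cost(segs[[i]], segs[[i + 1L]])
             else Inf
    j <- if (left <= right) i - 1L else i + 1L
    segs[[min(i, j)]] <- c(segs[[min(i, j)]], segs[[max(i, j)]])
    segs[[max(i, j)]] <- NULL
  }
  labels <- integer(m)
  for (g in seq_along(segs)) labels[segs[[g]]] <- g
  rng <- t(vapply(seq_along(segs), function(g) {
    idx <- segs[[g]]
    if (length(idx) < 3L) return(c(0, 0))
    mean_g <- frame$mean[idx, , drop = FALSE]
    r <- vapply(seq_len(n), function(i)
      kabsch(frame$coords[i, idx, ], mean_g)$rmsd, numeric(1))
    range(r)
  }, numeric(2)))
  colnames(rng) <- c("min_rmsd", "max_rmsd")
  starts <- vapply(segs, function(s) s[1], 1L)
  boundaries <- frame$positions$resno[starts[-1]]
  structure(list(groups = labels, positions = frame$positions,
                 boundaries = boundaries, group_rmsd_range = rng,
                 tol = tol),
            class = "rigid_decomposition")
}

#' @export
print.rigid_decomposition <- function(x, ...) {
  ng <- length(unique(x$groups))
  cat(sprintf("rigid_decomposition: %d group(s) over %d positions (tol %.2f A)\n",
              ng, length(x$groups), x$tol))
  for (g in seq_len(ng)) {
    idx <- which(x$groups == g)
    cat(sprintf("  group %d: residues %d-%d, RMSD range %.2f-%.2f A\n",
                g, x$positions$resno[idx[1]],
                x$positions$resno[idx[length(idx)]],
                x$group_rmsd_range[g, 1], x$group_rmsd_range[g, 2]))
  }
  if (length(x$boundaries) > 0L)
    cat("  hinge boundaries before residues:",
        paste(x$boundaries, collapse = ", "), "\n")
  invisible(x)
}

#' Bundle of ensemble analytics
#'
#' @param frame an [build_frame()] result.
#' @param cc a [cc_matrix()].
#' @param embedding a [embed_cc()] result.
#' @param hinges optional [find_hinges()] result.
#' @return object of class \code{state_analysis}.
#' @export
state_analysis <- function(frame, cc, embedding, hinges = NULL) {
  structure(list(frame = frame, cc = cc, embedding = embedding,
                 hinges = hinges),
            class = "state_analysis")
}

#' @export
print.state_analysis <- function(x, ...) {
  cat("state_analysis of", length(x$frame$names), "structures over",
      nrow(x$frame$positions), "common positions\n")
  print(x$embedding)
  if (!is.null(x$hinges)) print(x$hinges)
  invisible(x)
}

#' Assign conformational-state labels from an embedding
#'
#' Cluster labels come from the embedding.  When reference members with
#' known states are part of the ensemble, every cluster inherits the
#' majority state of its references and unlabeled members follow their
#' cluster.  A reference state spread across several clusters raises an
#' ambiguity flag instead of silently assigning.
#'
#' @param embedding a [embed_cc()] result.
#' @param reference_labels optional named character vector mapping
#'   member names to known state names.
#' @return list with \code{states} (character per member, named),
#'   \code{cluster}, \code{ambiguous} (logical) and \code{report}.
#' @export
classify_states <- function(embedding, reference_labels = NULL) {
  cl <- embedding$cluster
  nms <- embedding$names
  states <- paste0("state", cl)
  ambiguous <- FALSE
  notes <- character(0)
  if (!is.null(reference_labels)) {
    ref_idx <- match(names(reference_labels), nms)
    if (anyNA(ref_idx))
      stop("reference members not found in the ensemble: ",
           paste(names(reference_labels)[is.na(ref_idx)], collapse = ", "),
           call. = FALSE)
    for (st in unique(reference_labels)) {
      in_cl <- unique(cl[ref_idx[reference_labels == st]])
      if (length(in_cl) > 1L) {
        ambiguous <- TRUE
        notes <- c(notes, sprintf(
          "reference state '%s' is spread across clusters %s", st,
          paste(in_cl, collapse = ", ")))
      }
    }
    for (g in unique(cl[ref_idx])) {
      sts <- unique(reference_labels[cl[ref_idx] == g])
      if (length(sts) > 1L) {
        ambiguous <- TRUE
        notes <- c(notes, sprintf(
          "cluster %d carries conflicting reference states: %s", g,
          paste(sts, collapse = ", ")))
      }
    }
    if (!ambiguous) {
      for (g in unique(cl)) {
        refs <- reference_labels[names(reference_labels) %in%
                                   nms[cl == g]]
        if (length(refs) > 0L) {
          tab <- sort(table(refs), decreasing = TRUE)
          states[cl == g] <- names(tab)[1]
        }
      }
    }
  }
  names(states) <- nms
  list(states = states, cluster = cl, ambiguous = ambiguous,
       report = notes)
}

#' Write ensemble analytics to CSV/JSON files
#'
#' @param sa a [state_analysis()].
#' @param outdir output directory (created if needed).
#' @return character vector of paths written, invisibly.
#' @export
write_state_analysis <- function(sa, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(outdir, "cc_matrix.csv")
  utils::write.csv(as.data.frame(unclass(sa$cc)), p1, row.names = TRUE)
  p2 <- file.path(outdir, "embedding.csv")
  emb <- data.frame(name = sa$embedding$names, sa$embedding$vectors,
                    cluster = sa$embedding$cluster)
  utils::write.csv(emb, p2, row.names = FALSE)
  p3 <- file.path(outdir, "clusters.json")
  jsonlite::write_json(list(residual = sa$embedding$residual,
                            cluster = sa$embedding$cluster,
                            names = sa$embedding$names),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
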