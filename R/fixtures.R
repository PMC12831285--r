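#' Synthetic fixtures: ideal secondary structure, hinge proteins,
#' two-state ensembles, toy complexes and toy MSAs
#'
#' Geometric stand-ins built from ideal backbone torsions (helix
#' phi = -57, psi = -47; strand phi = -120, psi = +120; extended
#' phi = -150, psi = +150) with C-beta at the ideal tetrahedral
#' position.  Everything is deterministic given the seed, so tests and
#' demo recipes never require a download.
#'
#' @name fixtures
NULL

FIXTURE_AA_POOL <- c("A", "L", "E", "K", "S", "V", "D", "T", "I", "R",
                     "N", "Q", "F", "Y", "M", "W", "H", "C")

fixture_sequence <- function(n, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  paste(sample(FIXTURE_AA_POOL, n, replace = TRUE), collapse = "")
}

TORSIONS <- list(helix = c(-57, -47), strand = c(-120, 120),
                 extended = c(-150, 150))

add_noise <- function(m, noise, seed) {
  if (noise <= 0) return(m)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  on <- which(m$mask == 1L, arr.ind = TRUE)
  for (d in 1:3)
    m$coords[cbind(on, d)] <- m$coords[cbind(on, d)] +
      stats::rnorm(nrow(on), 0, noise)
  m
}

build_torsion_model <- function(phi, psi, sequence, chain = "A",
                                resno = NULL, name = "fixture") {
  aatype <- encode_sequence(sequence)
  bb <- build_backbone(phi, psi, glycine = aatype == GLY)
  backbone_to_model(bb, aatype, chain = chain,
                    resno = resno %||% seq_along(aatype), name = name)
}

#' Generate a synthetic structure
#'
#' Kinds: \code{helix}, \code{strand}, \code{extended} (single ideal
#' chains); \code{two_block_hinge} (two helical blocks joined by an
#' extended linker, the second block rotated by \code{hinge_angle}
#' about an axis through the linker midpoint); \code{toy_complex} (two
#' identical helices packed side by side as chains A and B, providing a
#' genuine contact interface); \code{strand_pair} (two antiparallel
#' strands docked at canonical backbone hydrogen-bond geometry, chains
#' A and B).
#'
#' @param kind fixture kind (see above).
#' @param length chain length (per chain for the two-chain kinds).
#' @param block_lengths two helical block lengths for
#'   \code{two_block_hinge} (default 40, 40).
#' @param linker_length extended linker length between the blocks
#'   (default 5).
#' @param hinge_angle bend angle in degrees applied to the second
#'   block.
#' @param separation axis separation of the \code{toy_complex} helices
#'   (Angstrom).
#' @param noise per-coordinate Gaussian noise sigma (Angstrom).
#' @param seed integer seed (sequence sampling and noise).
#' @param sequence optional residue string overriding the sampled one.
#' @param name model name.
#' @return a [structure_model()].
#' @examples
#' h <- make_structure("helix", length = 20)
#' ramachandran_outliers(h)$fraction
#' @export
make_structure <- function(kind = c("helix", "strand", "extended",
                                    "two_block_hinge", "toy_complex",
                                    "strand_pair"),
                           length = 60L, block_lengths = c(40L, 40L),
                           linker_length = 5L, hinge_angle = 0,
                           separation = 9, noise = 0, seed = 1L,
                           sequence = NULL, name = kind) {
  kind <- match.arg(kind)
  name <- name
  m <- switch(kind,
    helix = ,
    strand = ,
    extended = {
      tor <- TORSIONS[[kind]]
      seqn <- sequence %||% fixture_sequence(length, seed)
      build_torsion_model(rep(tor[1], length), rep(tor[2], length),
                          seqn, name = name)
    },
    two_block_hinge = make_two_block_hinge(block_lengths, linker_length,
                                           hinge_angle, seed, sequence,
                                           name),
    toy_complex = make_toy_complex(length, separation, seed, sequence,
                                   name),
    strand_pair = make_strand_pair(if (missing(length)) 5L else length,
                                   seed, sequence, name))
  add_noise(m, noise, seed + 104729L)
}

make_two_block_hinge <- function(block_lengths, linker_length,
                                 hinge_angle, seed, sequence, name) {
  b1 <- block_lengths[1]
  b2 <- block_lengths[2]
  L <- b1 + linker_length + b2
  seqn <- sequence %||% fixture_sequence(L, seed)
  phi <- c(rep(TORSIONS$helix[1], b1), rep(TORSIONS$extended[1],
                                           linker_length),
           rep(TORSIONS$helix[1], b2))
  psi <- c(rep(TORSIONS$helix[2], b1), rep(TORSIONS$extended[2],
                                           linker_length),
           rep(TORSIONS$helix[2], b2))
  m <- build_torsion_model(phi, psi, seqn, name = name)
  if (hinge_angle != 0) {
    pivot_res <- b1 + ceiling(linker_length / 2)   # linker midpoint
    pivot <- m$coords[pivot_res, SLOT_CA, ]
    dir <- m$coords[min(pivot_res + 2L, L), SLOT_CA, ] -
      m$coords[pivot_res - 2L, SLOT_CA, ]
    ref <- if (abs(unit(dir)[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    axis <- unit(cross3(dir, ref))
    R <- rotation_about_axis(axis, hinge_angle)
    moving <- seq(pivot_res, L)
    for (i in moving) {
      on <- which(m$mask[i, ] == 1L)
      for (s in on)
        m$coords[i, s, ] <- as.vector(
          R %*% (m$coords[i, s, ] - pivot)) + pivot
    }
  }
  m
}

make_toy_complex <- function(length, separation, seed, sequence, name) {
  seqn <- sequence %||% fixture_sequence(length, seed)
  a <- build_torsion_model(rep(TORSIONS$helix[1], length),
                           rep(TORSIONS$helix[2], length), seqn,
                           chain = "A", name = name)
  axis <- unit(a$coords[length, SLOT_CA, ] - a$coords[1, SLOT_CA, ])
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  shift <- unit(cross3(axis, ref)) * separation
  b <- a
  b$chain <- rep("B", length)
  for (d in 1:3) b$coords[, , d] <- b$coords[, , d] + shift[d]
  combine_chain_models(a, zero_unmasked(b), name)
}

combine_chain_models <- function(a, b, name) {
  la <- model_length(a)
  lb <- model_length(b)
  coords <- array(0, dim = c(la + lb, 37L, 3L))
  coords[seq_len(la), , ] <- a$coords
  coords[la + seq_len(lb), , ] <- b$coords
  structure_model(c(a$chain, b$chain), c(a$resno, b$resno),
                  c(a$aatype, b$aatype), coords,
                  rbind(a$mask, b$mask), NULL, name)
}

# Antiparallel strand pair at canonical backbone hydrogen-bond
# geometry.  Chain B is a rigid copy of the ideal strand placed by
# least-squares fit of its four bonding atoms (N/O of residues mid-1
# and mid+1) onto ideal targets computed from chain A: the acceptor O
# sits 2.9 A from the donor N along the amide-H bisector, the donor N
# sits 2.9 A from the acceptor O along the extended C=O direction.
# This realizes exactly four inter-chain N-H...O=C bonds (the
# antiparallel ladder of the narrow ring) with no extra polar contact.
make_strand_pair <- function(length = 5L, seed = 1L, sequence = NULL,
                             name = "strand_pair") {
  length <- max(length, 5L)
  seqn <- sequence %||% fixture_sequence(length, seed)
  # true antiparallel-sheet torsions, slightly twisted
  a <- build_torsion_model(rep(-139, length), rep(135, length), seqn,
                           chain = "A", name = name)
  N <- a$coords[, SLOT_N, ]
  CA <- a$coords[, SLOT_CA, ]
  C <- a$coords[, SLOT_C, ]
  O <- a$coords[, SLOT_O, ]
  hdir <- function(i) unit(unit(N[i, ] - CA[i, ]) +
                             unit(N[i, ] - C[i - 1L, ]))
  odir <- function(i) unit(O[i, ] - C[i, ])
  i1 <- (length + 1L) %/% 2L - 1L
  i2 <- i1 + 2L
  # bonds: A:N(i1)-B:O(i2), A:N(i2)-B:O(i1), B:N(i1)-A:O(i2),
  # B:N(i2)-A:O(i1)
  targets <- rbind(N[i1, ] + 2.9 * hdir(i1),   # lands B:O(i2)
                   N[i2, ] + 2.9 * hdir(i2),   # lands B:O(i1)
                   O[i2, ] + 2.9 * odir(i2),   # lands B:N(i1)
                   O[i1, ] + 2.9 * odir(i1))   # lands B:N(i2)
  source <- rbind(O[i2, ], O[i1, ], N[i1, ], N[i2, ])
  fit <- kabsch(source, targets)
  b <- a
  b$chain <- rep("B", length)
  flat <- matrix(b$coords, nrow = length * 37L)
  flat <- apply_rigid(flat, fit$rotation, fit$translation)
  b$coords <- array(flat, dim = c(length, 37L, 3L))
  combine_chain_models(a, zero_unmasked(b), name)
}

#' Generate a two-state hinge ensemble with known labels
#'
#' Members are split between hinge angles \code{base_angle} and
#' \code{base_angle + delta} (first half / second half) with
#' per-member coordinate noise, emulating an ensemble drawn from two
#' conformational states.
#'
#' @param n_members ensemble size (at least 4).
#' @param delta hinge-angle difference between the states (degrees,
#'   default 30).
#' @param base_angle hinge angle of state 1 (degrees).
#' @param noise per-coordinate Gaussian sigma (Angstrom, default 0.2).
#' @param seed integer seed.
#' @param block_lengths,linker_length geometry of the underlying
#'   [make_structure()] \code{two_block_hinge} fixture.
#' @return list with \code{members} (list of [structure_model()]s) and
#'   \code{labels} (integer state per member, 1 or 2).
#' @export
make_two_state_ensemble <- function(n_members = 8L, delta = 30,
                                    base_angle = 0, noise = 0.2,
                                    seed = 1L,
                                    block_lengths = c(40L, 40L),
                                    linker_length = 5L) {
  stopifnot(n_members >= 4L)
  n1 <- ceiling(n_members / 2)
  labels <- rep(c(1L, 2L), c(n1, n_members - n1))
  seqn <- fixture_sequence(sum(block_lengths) + linker_length, seed)
  members <- lapply(seq_len(n_members), function(i) {
    ang <- if (labels[i] == 1L) base_angle else base_angle + delta
    make_structure("two_block_hinge", block_lengths = block_lengths,
                   linker_length = linker_length, hinge_angle = ang,
                   noise = noise, seed = seed + 131L * i,
                   sequence = seqn,
                   name = sprintf("member%02d", i))
  })
  list(members = members, labels = labels)
}

#' Generate a toy MSA around a query
#'
#' Rows are sampled per column: with probability \code{conservation}
#' the query residue is kept, otherwise a uniformly random different
#' residue is drawn.  Row 1 is the query itself.
#'
#' @param query residue string.
#' @param n_rows total rows including the query.
#' @param conservation scalar or per-column probability of keeping the
#'   query residue (default 0.8).
#' @param seed integer seed.
#' @return an [msa_block()].
#' @export
make_toy_msa <- function(query, n_rows, conservation = 0.8, seed = 1L) {
  aatype <- encode_sequence(query)
  L <- length(aatype)
  conservation <- rep(conservation, length.out = L)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rows <- matrix(0L, n_rows, L)
  rows[1, ] <- aatype
  for (i in seq_len(n_rows)[-1]) {
    keep <- stats::runif(L) < conservation
    alt <- sample.int(20L, L, replace = TRUE) - 1L
    clash <- alt == aatype
    alt[clash] <- (alt[clash] + 1L) %% 20L
    rows[i, ] <- ifelse(keep, aatype, alt)
  }
  msa_block(rows, row_labels = c("query",
                                 sprintf("toy%03d", seq_len(n_rows - 1L))))
}

#' Write a named fixture bundle to disk
#'
#' Emits the standard PDB/A3M files used by the shipped demo recipes
#' and the command-line interface: a two-chain toy complex, a
#' two-state hinge ensemble with a label table, and a toy alignment.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @return character vector of files written, invisibly.
#' @export
make_fixture_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tc <- make_structure("toy_complex", length = 30, seed = seed)
  p <- file.path(dir, "toy_complex.pdb")
  write_pdb(tc, p)
  files <- c(files, p)
  ens <- make_two_state_ensemble(8L, seed = seed)
  for (i in seq_along(ens$members)) {
    p <- file.path(dir, sprintf("two_state_%02d.pdb", i))
    write_pdb(ens$members[[i]], p)
    files <- c(files, p)
  }
  p <- file.path(dir, "two_state_labels.csv")
  utils::write.csv(data.frame(member = sprintf("two_state_%02d",
                                               seq_along(ens$members)),
                              state = ens$labels),
                   p, row.names = FALSE)
  files <- c(files, p)
  seqn <- fixture_sequence(40, seed)
  msa <- make_toy_msa(seqn, 20, seed = seed)
  p <- file.path(dir, "toy.a3m")
  write_a3m(msa, p)
  files <- c(files, p)
  invisible(files)
}
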