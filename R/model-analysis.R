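#' Model evaluation and ranking
#'
#' Predictions are scored on confidence (mean pLDDT), stereochemical
#' soundness (Ramachandran outliers against a coarse rectangle table,
#' compactness against an Rg power law), consistency with the provided
#' information (RMSD to templates/references, presence of declared
#' interfaces) and interface metrics (buried surface area by
#' Shrake-Rupley, geometric hydrogen bonds).
#'
#' @name model-analysis
NULL

#' Rigid-body superposition of two structures
#'
#' CA atoms are paired by (chain, residue number); when fewer than
#' three positions match, pairing falls back to a global sequence
#' alignment.  The optimal proper rotation is found by Kabsch
#' (SVD with determinant correction).
#'
#' @param a,b [structure_model()]s; \code{a} is moved onto \code{b}.
#' @param selection optional integer residue numbers restricting the
#'   paired positions.
#' @return list with \code{rotation} (3 x 3), \code{translation},
#'   \code{rmsd} (Angstrom) and \code{n_aligned}.
#' @export
superpose <- function(a, b, selection = NULL) {
  ka <- paste(a$chain, a$resno, sep = "\r")
  kb <- paste(b$chain, b$resno, sep = "\r")
  ok_a <- a$mask[, SLOT_CA] == 1L
  ok_b <- b$mask[, SLOT_CA] == 1L
  common <- intersect(ka[ok_a], kb[ok_b])
  if (!is.null(selection)) {
    resno <- as.integer(sub(".*\r", "", common))
    common <- common[resno %in% selection]
  }
  if (length(common) >= 3L) {
    ia <- match(common, ka)
    ib <- match(common, kb)
  } else {
    map <- auto_align_map(decode_sequence(a$aatype),
                          decode_sequence(b$aatype))
    ia <- map$query_pos + 1L
    ib <- map$template_pos + 1L
    keep <- ok_a[ia] & ok_b[ib]
    ia <- ia[keep]
    ib <- ib[keep]
  }
  if (length(ia) < 3L)
    stop("fewer than 3 CA pairs available for superposition",
         call. = FALSE)
  fit <- kabsch(ca_coords(a)[ia, , drop = FALSE],
                ca_coords(b)[ib, , drop = FALSE])
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, n_aligned = length(ia))
}

# Coarse allowed phi/psi rectangles (degrees).  This is a soundness
# heuristic, not a validation-grade contour: alpha and beta basins plus
# the left-handed helix region for all residues, everything allowed for
# glycine, and a restricted phi band for proline.
RAMA_GENERAL <- list(
  c(-180, -30, -80, 60),     # alpha basin: phi_min, phi_max, psi_min, psi_max
  c(-180, -30, 60, 180),     # beta basin
  c(-180, -30, -180, -150),  # beta basin (psi wrap)
  c(30, 100, -20, 90))       # left-handed helix
RAMA_PRO <- list(
  c(-110, -30, -75, 80),
  c(-110, -30, 100, 180),
  c(-110, -30, -180, -150))

in_rects <- function(phi, psi, rects) {
  for (r in rects)
    if (phi >= r[1] && phi <= r[2] && psi >= r[3] && psi <= r[4])
      return(TRUE)
  FALSE
}

PRO <- 14L

#' Backbone dihedrals of a structure
#'
#' @param m a [structure_model()].
#' @return data.frame with per-residue \code{phi}, \code{psi} (degrees,
#'   NA where undefined by termini or chain breaks).
#' @export
backbone_dihedrals <- function(m) {
  L <- model_length(m)
  phi <- psi <- rep(NA_real_, L)
  has_bb <- m$mask[, SLOT_N] == 1L & m$mask[, SLOT_CA] == 1L &
    m$mask[, SLOT_C] == 1L
  linked <- function(i, j) {
    # peptide bond between C(i) and N(j) must be intact
    if (!has_bb[i] || !has_bb[j] || m$chain[i] != m$chain[j]) return(FALSE)
    d <- vnorm(m$coords[j, SLOT_N, ] - m$coords[i, SLOT_C, ])
    d < 2.5
  }
  for (i in seq_len(L)) {
    if (!has_bb[i]) next
    if (i > 1L && linked(i - 1L, i))
      phi[i] <- dihedral_angle(m$coords[i - 1L, SLOT_C, ],
                               m$coords[i, SLOT_N, ],
                               m$coords[i, SLOT_CA, ],
                               m$coords[i, SLOT_C, ])
    if (i < L && linked(i, i + 1L))
      psi[i] <- dihedral_angle(m$coords[i, SLOT_N, ],
                               m$coords[i, SLOT_CA, ],
                               m$coords[i, SLOT_C, ],
                               m$coords[i + 1L, SLOT_N, ])
  }
  data.frame(phi = phi, psi = psi)
}

#' Ramachandran outlier fraction
#'
#' Residues with both dihedrals defined are classified against the
#' documented rectangle table (see \code{RAMA_GENERAL} in the source):
#' glycine is never an outlier, proline uses its restricted phi band.
#' With no classifiable residues the fraction is reported as 0 with
#' \code{classifiable = 0}.
#'
#' @param m a [structure_model()].
#' @return list with \code{fraction}, \code{outliers} (logical per
#'   residue) and \code{classifiable} (count).
#' @export
ramachandran_outliers <- function(m) {
  di <- backbone_dihedrals(m)
  L <- model_length(m)
  out <- rep(FALSE, L)
  classifiable <- which(!is.na(di$phi) & !is.na(di$psi))
  for (i in classifiable) {
    if (m$aatype[i] == GLY) next
    rects <- if (m$aatype[i] == PRO) RAMA_PRO else RAMA_GENERAL
    if (!in_rects(di$phi[i], di$psi[i], rects)) out[i] <- TRUE
  }
  frac <- if (length(classifiable) == 0L) 0
          else sum(out) / length(classifiable)
  list(fraction = frac, outliers = out,
       classifiable = length(classifiable))
}

# Expected radius of gyration for a globular chain of N residues:
# Rg0 = 2.0 * N^0.4 Angstrom (documented power law; exponent 0.4).
RG_PREFACTOR <- 2.0
RG_EXPONENT <- 0.4

#' Compactness score
#'
#' Radius of gyration of the CA trace divided by the expected globular
#' Rg (power law \code{2.0 * N^0.4} Angstrom).  About 1 for compact
#' globular chains, much larger for extended ones, 0 for a degenerate
#' collapsed model.
#'
#' @param m a [structure_model()] with at least 5 CA atoms.
#' @return numeric score.
#' @export
compactness <- function(m) {
  xyz <- ca_coords(m)
  xyz <- xyz[stats::complete.cases(xyz), , drop = FALSE]
  if (nrow(xyz) < 5L)
    stop("compactness needs at least 5 CA atoms", call. = FALSE)
  rg <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  rg / (RG_PREFACTOR * nrow(xyz)^RG_EXPONENT)
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Shrake-Rupley solvent-accessible surface area with a golden-spiral
# point set (default 100 points/atom, probe 1.4 A).  atoms: data.frame
# with x, y, z, element.
shrake_rupley <- function(atoms, probe = 1.4, n_points = 100L) {
  n <- nrow(atoms)
  if (n == 0L) return(0)
  r <- VDW_RADII[atoms$element]
  r[is.na(r)] <- 1.70
  r <- r + probe
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  sphere <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  total <- 0
  for (i in seq_len(n)) {
    pts <- sweep(sphere * r[i], 2, xyz[i, ], "+")
    nb <- which(rowSums(sweep(xyz, 2, xyz[i, ])^2) < (r + r[i])^2)
    nb <- setdiff(nb, i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      acc <- acc & d2 > r[j]^2
      if (!any(acc)) break
    }
    total <- total + 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  total
}

model_atoms <- function(m, chains = NULL) {
  idx <- if (is.null(chains)) seq_len(model_length(m))
         else which(m$chain %in% chains)
  rows <- list()
  for (i in idx) {
    slots <- which(m$mask[i, ] == 1L)
    if (length(slots) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      residue = i, slot = slots,
      element = atom_element(slots),
      x = m$coords[i, slots, 1], y = m$coords[i, slots, 2],
      z = m$coords[i, slots, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Geometric hydrogen bonds between two chains: donor N, acceptor O,
# heavy-atom distance <= 3.5 A; when the amide H can be inferred from
# the backbone (bisector of N-CA and N-C_prev), the D-H...A angle must
# be >= 120 degrees.
count_hbonds <- function(m, chain_a, chain_b, max_da = 3.5,
                         min_angle = 120) {
  donors <- acceptors <- list()
  L <- model_length(m)
  for (i in seq_len(L)) {
    ch <- m$chain[i]
    if (!ch %in% c(chain_a, chain_b)) next
    for (s in which(m$mask[i, ] == 1L)) {
      el <- atom_element(s)
      if (el == "N") {
        h <- NULL
        if (s == SLOT_N && m$mask[i, SLOT_CA] == 1L && i > 1L &&
            m$chain[i - 1L] == ch && m$mask[i - 1L, SLOT_C] == 1L &&
            m$aatype[i] != PRO) {
          npos <- m$coords[i, SLOT_N, ]
          d1 <- unit(npos - m$coords[i, SLOT_CA, ])
          d2 <- unit(npos - m$coords[i - 1L, SLOT_C, ])
          h <- npos + 1.01 * unit(d1 + d2)
        }
        if (!(s == SLOT_N && m$aatype[i] == PRO))
          donors[[length(donors) + 1L]] <-
            list(chain = ch, pos = m$coords[i, s, ], h = h)
      } else if (el == "O") {
        acceptors[[length(acceptors) + 1L]] <-
          list(chain = ch, pos = m$coords[i, s, ])
      }
    }
  }
  count <- 0L
  for (d in donors) {
    for (a in acceptors) {
      if (d$chain == a$chain) next
      if (!((d$chain == chain_a && a$chain == chain_b) ||
            (d$chain == chain_b && a$chain == chain_a))) next
      if (vnorm(d$pos - a$pos) > max_da) next
      if (!is.null(d$h)) {
        ang <- acos(pmin(pmax(sum(unit(d$pos - d$h) *
                                    unit(a$pos - d$h)), -1), 1)) *
          180 / pi
        if (ang < min_angle) next
      }
      count <- count + 1L
    }
  }
  count
}

INTERFACE_TIERS <- c(none = 0, small = 50, intermediate = 400,
                     large = 800)

#' Interface metrics for a chain pair
#'
#' Buried surface area is SASA(A) + SASA(B) - SASA(AB) over heavy atoms
#' (Shrake-Rupley, probe 1.4 Angstrom, 100 points per atom); hydrogen
#' bonds are counted geometrically.  An externally computed interface
#' energy can be supplied through \code{pisa_xml} (a PISA-style XML
#' file whose \code{<deltaG>} value is read); no energy is ever
#' computed internally.
#'
#' @param m a [structure_model()] containing both chains.
#' @param chains character vector of two chain identifiers.
#' @param probe probe radius (Angstrom).
#' @param n_points sphere points per atom.
#' @param pisa_xml optional path to an external interface-energy XML.
#' @return object of class \code{interface_report}: \code{chains},
#'   \code{buried_area} (A^2), \code{h_bonds}, \code{delta_g}
#'   (kcal/mol or NA) and \code{tier}.
#' @export
interface_metrics <- function(m, chains, probe = 1.4, n_points = 100L,
                              pisa_xml = NULL) {
  stopifnot(length(chains) == 2L)
  for (ch in chains)
    if (!ch %in% m$chain)
      stop("chain '", ch, "' not present in model", call. = FALSE)
  aa <- model_atoms(m, chains[1])
  ab <- model_atoms(m, chains[2])
  # quick reject: chains further apart than any possible contact
  gap <- min_pair_distance(aa, ab)
  if (gap > 2 * (max(VDW_RADII) + probe)) {
    buried <- 0
    hb <- 0L
  } else {
    sasa_a <- shrake_rupley(aa, probe, n_points)
    sasa_b <- shrake_rupley(ab, probe, n_points)
    sasa_ab <- shrake_rupley(rbind(aa, ab), probe, n_points)
    buried <- max(0, sasa_a + sasa_b - sasa_ab)
    hb <- count_hbonds(m, chains[1], chains[2])
  }
  dg <- NA_real_
  if (!is.null(pisa_xml) && file.exists(pisa_xml)) {
    txt <- paste(readLines(pisa_xml, warn = FALSE), collapse = " ")
    mm <- regmatches(txt, regexpr("<deltaG>\\s*[-0-9.eE+]+\\s*</deltaG>",
                                  txt))
    if (length(mm) == 1L)
      dg <- as.numeric(gsub("[^-0-9.eE+]", "", mm))
  }
  tier <- names(INTERFACE_TIERS)[findInterval(buried, INTERFACE_TIERS)]
  structure(list(chains = chains, buried_area = buried, h_bonds = hb,
                 delta_g = dg, tier = tier),
            class = "interface_report")
}

min_pair_distance <- function(aa, ab) {
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  min(vapply(seq_len(nrow(xa)), function(i)
    min(sqrt(rowSums(sweep(xb, 2, xa[i, ])^2))), numeric(1)))
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface %s-%s: buried %.1f A^2, %d H-bond(s), tier '%s'",
              x$chains[1], x$chains[2], x$buried_area, x$h_bonds,
              x$tier))
  if (!is.na(x$delta_g)) cat(sprintf(", external dG %.1f kcal/mol",
                                     x$delta_g))
  cat("\n")
  invisible(x)
}

# buried-area threshold above which a declared interface counts as
# present (A^2)
INTERFACE_PRESENT_MIN <- 50

#' Rank predicted models
#'
#' The composite order is lexicographic: models satisfying more of the
#' declared (required) interfaces rank first, then higher mean pLDDT,
#' then lower Ramachandran outlier fraction, then compactness closer to
#' 1, with the model name as the deterministic tie-break.  Every
#' component is reported so users can re-weight.  Models without
#' confidence values (e.g. experimental references) default to pLDDT
#' 100.
#'
#' @param models list of [structure_model()]s.
#' @param fs optional [feature_set()]; RMSD to each of its templates is
#'   reported.
#' @param references optional list of [structure_model()]s to compare
#'   against.
#' @param declared_interfaces optional list of chain pairs (each a
#'   length-2 character vector) whose presence (buried area >= 50 A^2)
#'   is required.
#' @return object of class \code{rank_report}; its \code{table} element
#'   is a data.frame ordered by rank.
#' @export
rank_models <- function(models, fs = NULL, references = NULL,
                        declared_interfaces = NULL) {
  stopifnot(length(models) >= 1L)
  rows <- list()
  iface_details <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    plddt <- if (is.null(m$plddt)) 100 else mean(m$plddt)
    rama <- ramachandran_outliers(m)$fraction
    comp <- tryCatch(compactness(m), error = function(e) NA_real_)
    n_present <- 0L
    n_required <- length(declared_interfaces %||% list())
    ifaces <- list()
    for (di in seq_len(n_required)) {
      pair <- declared_interfaces[[di]]
      rep_i <- tryCatch(interface_metrics(m, pair),
                        error = function(e) NULL)
      present <- !is.null(rep_i) &&
        rep_i$buried_area >= INTERFACE_PRESENT_MIN
      if (present) n_present <- n_present + 1L
      ifaces[[di]] <- list(pair = pair, present = present,
                           report = rep_i)
    }
    iface_details[[m$name]] <- ifaces
    row <- data.frame(model = m$name, mean_plddt = plddt,
                      rama_outlier_fraction = rama, compactness = comp,
                      interfaces_present = n_present,
                      interfaces_required = n_required,
                      stringsAsFactors = FALSE)
    if (!is.null(fs)) {
      for (ti in seq_along(fs$templates)) {
        tm <- template_to_model(fs$templates[[ti]])
        r <- tryCatch(superpose(m, tm)$rmsd, error = function(e)
          NA_real_)
        row[[sprintf("rmsd_template_%s", fs$templates[[ti]]$name)]] <- r
      }
    }
    for (ref in references %||% list()) {
      r <- tryCatch(superpose(m, ref)$rmsd, error = function(e)
        NA_real_)
      row[[sprintf("rmsd_ref_%s", ref$name)]] <- r
    }
    rows[[mi]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (nm in miss) r[[nm]] <- NA_real_
    r
  }))
  ord <- order(-tab$interfaces_present, -tab$mean_plddt,
               tab$rama_outlier_fraction, abs(tab$compactness - 1),
               tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, interfaces = iface_details),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat("rank_report (best first):\n")
  print(x$table[, c("rank", "model", "mean_plddt",
                    "rama_outlier_fraction", "compactness",
                    "interfaces_present", "interfaces_required")],
        row.names = FALSE)
  invisible(x)
}
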