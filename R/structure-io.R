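#' Per-residue structure container
#'
#' A \code{structure_model} stores one predicted or experimental structure
#' as parallel per-residue vectors plus dense atom37 coordinate/mask
#' arrays: \code{chain} (character), \code{resno} (integer author
#' numbering), \code{aatype} (integer 0--20), \code{coords}
#' (L x 37 x 3, Angstrom), \code{mask} (L x 37, 0/1) and optional
#' \code{plddt} (0--100 per residue).
#'
#' @param chain character vector of chain identifiers, length L.
#' @param resno integer vector of residue numbers, length L.
#' @param aatype integer vector of residue type indices (0--20), length L.
#' @param coords numeric array L x 37 x 3.
#' @param mask numeric/integer matrix L x 37 of 0/1 atom-present flags.
#' @param plddt optional numeric vector of per-residue confidences
#'   (0--100); \code{NULL} when unknown.
#' @param name model identifier used in reports and rankings.
#' @return an object of class \code{structure_model}.
#' @export
structure_model <- function(chain, resno, aatype, coords, mask,
                            plddt = NULL, name = "model") {
  L <- length(resno)
  stopifnot(length(chain) == L, length(aatype) == L,
            identical(dim(coords), c(L, 37L, 3L)) ||
              identical(dim(coords), as.integer(c(L, 37, 3))),
            identical(dim(mask)[1:2], dim(coords)[1:2]))
  if (!is.null(plddt)) {
    stopifnot(length(plddt) == L)
    if (any(plddt < 0 | plddt > 100, na.rm = TRUE))
      stop("plddt values must lie in [0, 100]", call. = FALSE)
  }
  if (L < 1 || sum(mask[, SLOT_CA]) < 1)
    stop("a structure_model needs at least one residue with a CA atom",
         call. = FALSE)
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 aatype = as.integer(aatype), coords = coords,
                 mask = (mask != 0) * 1L, plddt = plddt,
                 name = as.character(name)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$chain)
  cat(sprintf("structure_model '%s': %d residues, %d chain(s) [%s]\n",
              x$name, length(x$resno), length(ch),
              paste(sprintf("%s:%d", names(ch), ch), collapse = ", ")))
  if (!is.null(x$plddt))
    cat(sprintf("  mean confidence %.1f\n", mean(x$plddt)))
  invisible(x)
}

#' @export
length.structure_model <- function(x) length(x$resno)

model_length <- function(m) length(m$resno)

#' CA coordinates of a structure
#' @param m a [structure_model()].
#' @return L x 3 matrix; rows without a CA atom are NA.
#' @export
ca_coords <- function(m) {
  out <- m$coords[, SLOT_CA, , drop = FALSE]
  dim(out) <- c(dim(m$coords)[1], 3L)
  out[m$mask[, SLOT_CA] == 0, ] <- NA_real_
  out
}

#' Subset a structure by residue index
#' @param m a [structure_model()].
#' @param idx integer positions (1-based rows) to keep, in order.
#' @param name name of the subset model.
#' @return a [structure_model()].
#' @export
subset_model <- function(m, idx, name = m$name) {
  structure_model(m$chain[idx], m$resno[idx], m$aatype[idx],
                  m$coords[idx, , , drop = FALSE],
                  m$mask[idx, , drop = FALSE],
                  if (is.null(m$plddt)) NULL else m$plddt[idx],
                  name = name)
}

transform_model <- function(m, rotation, translation) {
  L <- model_length(m)
  flat <- matrix(aperm(m$coords, c(1, 2, 3)), nrow = L * 37L, ncol = 3L)
  flat <- apply_rigid(flat, rotation, translation)
  m$coords <- array(flat, dim = c(L, 37L, 3L))
  zero_unmasked(m)
}

# absent atoms carry zero coordinates by convention
zero_unmasked <- function(m) {
  off <- m$mask == 0L
  for (d in 1:3) {
    slab <- m$coords[, , d]
    slab[off] <- 0
    m$coords[, , d] <- slab
  }
  m
}

empty_coords <- function(L) {
  list(coords = array(0, dim = c(L, 37L, 3L)),
       mask = matrix(0L, L, 37L))
}

# Assemble a structure_model from build_backbone() output.
backbone_to_model <- function(bb, aatype, chain = "A",
                              resno = seq_along(aatype),
                              plddt = NULL, name = "model") {
  L <- length(aatype)
  ec <- empty_coords(L)
  slots <- c(N = SLOT_N, CA = SLOT_CA, C = SLOT_C, O = SLOT_O,
             CB = SLOT_CB)
  parts <- list(N = bb$N, CA = bb$CA, C = bb$C, O = bb$O, CB = bb$CB)
  for (nm in names(slots)) {
    p <- parts[[nm]]
    ok <- !is.na(p[, 1])
    ec$coords[ok, slots[[nm]], ] <- p[ok, , drop = FALSE]
    ec$mask[ok, slots[[nm]]] <- 1L
  }
  structure_model(rep(chain, length.out = L), resno, aatype,
                  ec$coords, ec$mask, plddt, name)
}

#' Read a structure from a PDB file
#'
#' Minimal fixed-column PDB parser: first model only, \code{ATOM} records,
#' alternate locations \code{' '} or \code{'A'}.  Heavy atoms are mapped
#' into the atom37 layout; atoms outside it (hydrogens, nonstandard
#' names) are ignored.  B-factors are read as per-residue confidence when
#' they look like pLDDTs (all within 0--100).
#'
#' @param path file path.
#' @param name model name; defaults to the file stem.
#' @return a [structure_model()].
#' @export
read_pdb <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  end <- match(TRUE, startsWith(lines, "ENDMDL"), nomatch = 0L)
  if (end > 0L) lines <- lines[seq_len(end - 1L)]
  at <- lines[startsWith(lines, "ATOM  ")]
  if (length(at) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  alt <- substr(at, 17, 17)
  at <- at[alt %in% c(" ", "A")]
  rec <- data.frame(
    atom = trimws(substr(at, 13, 16)),
    resname = trimws(substr(at, 18, 20)),
    chain = substr(at, 22, 22),
    resno = as.integer(substr(at, 23, 26)),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    b = suppressWarnings(as.numeric(substr(at, 61, 66))),
    stringsAsFactors = FALSE)
  atoms_to_model(rec, name)
}

atoms_to_model <- function(rec, name) {
  key <- paste(rec$chain, rec$resno, sep = "\r")
  ures <- !duplicated(key)
  chain <- rec$chain[ures]
  resno <- rec$resno[ures]
  aatype <- aa_from_three(rec$resname[ures])
  L <- length(resno)
  ec <- empty_coords(L)
  plddt <- rep(NA_real_, L)
  ridx <- match(key, key[ures])
  slot <- atom_slot(rec$atom)
  keep <- which(!is.na(slot))
  for (i in keep) {
    r <- ridx[i]
    s <- slot[i]
    if (ec$mask[r, s] == 1L) next  # keep first occurrence
    ec$coords[r, s, ] <- c(rec$x[i], rec$y[i], rec$z[i])
    ec$mask[r, s] <- 1L
    if (s == SLOT_CA) plddt[r] <- rec$b[i]
  }
  if (anyNA(plddt) || any(plddt < 0 | plddt > 100)) plddt <- NULL
  structure_model(chain, resno, aatype, ec$coords, ec$mask, plddt, name)
}

#' Read a structure from an mmCIF file
#'
#' Minimal \code{_atom_site} loop reader (first model, altloc \code{.} or
#' \code{A}); auth numbering is preferred over label numbering.
#'
#' @inheritParams read_pdb
#' @return a [structure_model()].
#' @export
read_cif <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^_atom_site\\.", lines)
  if (length(hdr) == 0L) stop("no _atom_site loop in ", path, call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr]))
  body_start <- max(hdr) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    body <- c(body, ln)
  }
  tok <- strsplit(body, "[[:space:]]+")
  n <- length(fields)
  tok <- tok[vapply(tok, length, 1L) == n]
  if (length(tok) == 0L) stop("malformed _atom_site loop in ", path,
                              call. = FALSE)
  tab <- do.call(rbind, tok)
  colnames(tab) <- fields
  g <- function(nm, alt = NULL) {
    if (nm %in% fields) tab[, nm]
    else if (!is.null(alt) && alt %in% fields) tab[, alt]
    else rep(NA_character_, nrow(tab))
  }
  keep <- g("group_PDB") %in% c("ATOM", NA_character_)
  if ("pdbx_PDB_model_num" %in% fields) {
    mn <- g("pdbx_PDB_model_num")
    keep <- keep & mn == mn[1]
  }
  altloc <- g("label_alt_id")
  keep <- keep & (is.na(altloc) | altloc %in% c(".", "A", "?"))
  tab <- tab[keep, , drop = FALSE]
  g2 <- function(nm, alt = NULL) {
    if (nm %in% fields) tab[, nm]
    else if (!is.null(alt) && alt %in% fields) tab[, alt]
    else rep(NA_character_, nrow(tab))
  }
  rec <- data.frame(
    atom = gsub('"', "", g2("auth_atom_id", "label_atom_id")),
    resname = g2("auth_comp_id", "label_comp_id"),
    chain = g2("auth_asym_id", "label_asym_id"),
    resno = as.integer(g2("auth_seq_id", "label_seq_id")),
    x = as.numeric(g2("Cartn_x")),
    y = as.numeric(g2("Cartn_y")),
    z = as.numeric(g2("Cartn_z")),
    b = suppressWarnings(as.numeric(g2("B_iso_or_equiv"))),
    stringsAsFactors = FALSE)
  atoms_to_model(rec, name)
}

#' Read a structure file (PDB or mmCIF, chosen by extension)
#' @inheritParams read_pdb
#' @return a [structure_model()].
#' @export
read_structure <- function(path, name = NULL) {
  if (grepl("\\.cif$", path, ignore.case = TRUE)) read_cif(path, name)
  else read_pdb(path, name)
}

#' Write a structure to a PDB file
#'
#' Per-residue confidence (when present) is written in the B-factor
#' column; chains are separated by \code{TER} records.
#'
#' @param m a [structure_model()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(m, path) {
  L <- model_length(m)
  b <- if (is.null(m$plddt)) rep(0, L) else m$plddt
  three <- aa_three_letter(m$aatype)
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_len(L)) {
    for (s in which(m$mask[i, ] == 1L)) {
      serial <- serial + 1L
      nm <- ATOM37[s]
      pad <- if (nchar(nm) < 4L) paste0(" ", formatC(nm, width = -3)) else nm
      writeLines(sprintf(
        "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, pad, three[i], m$chain[i], m$resno[i],
        m$coords[i, s, 1], m$coords[i, s, 2], m$coords[i, s, 3],
        1.00, b[i], atom_element(s)), con)
    }
    if (i == L || m$chain[i + 1L] != m$chain[i])
      writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}
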