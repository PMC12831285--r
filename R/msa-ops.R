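#' Alignment parsing and MSA editing
#'
#' Alignments are held as integer [msa_block()]s aligned to the query.
#' Editing operations never change the alignment width and never touch
#' the query row: depth reduction keeps the query, masking substitutes
#' the gap/mask index 21 in non-query rows only, merging stacks blocks
#' under a single query row, and fragment libraries add rows that are
#' gap everywhere outside their target window.
#'
#' @name msa-ops
NULL

# encode one aligned character: '-' -> gap, unknown letters -> X
encode_cell <- function(ch) {
  ifelse(ch == "-", AA_GAP,
         {
           i <- match(ch, AA_LETTERS)
           ifelse(is.na(i), AA_UNKNOWN, i - 1L)
         })
}

# Convert one A3M-style row (lowercase = insertion) into match-column
# integers plus per-column deletion counts; insertions accumulate into
# the next match column.
a3m_row <- function(s, L, label) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  is_ins <- chars %in% letters
  n_match <- sum(!is_ins)
  if (n_match != L)
    stop(sprintf("alignment row '%s' has %d match columns, expected %d",
                 label, n_match, L), call. = FALSE)
  enc <- integer(L)
  del <- integer(L)
  col <- 0L
  pending <- 0L
  for (ch in chars) {
    if (ch %in% letters) {
      pending <- pending + 1L
    } else {
      col <- col + 1L
      enc[col] <- encode_cell(toupper(ch))
      del[col] <- pending
      pending <- 0L
    }
  }
  list(enc = enc, del = del)
}

read_fasta_records <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records found", call. = FALSE)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- vapply(strsplit(labels, "[[:space:]]+"), `[`, "", 1)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    paste(body[!startsWith(body, ">")], collapse = "")
  }, character(1))
  list(labels = labels, seqs = gsub("[[:space:]]", "", seqs))
}

read_stockholm_records <- function(lines) {
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//")]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no Stockholm records found", call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  labels <- vapply(parts, `[`, "", 1)
  seqs <- vapply(parts, `[`, "", 2)
  # multi-block Stockholm: concatenate by label, keeping first-seen order
  ord <- unique(labels)
  seqs <- vapply(ord, function(l)
    paste(seqs[labels == l], collapse = ""), character(1))
  list(labels = ord, seqs = gsub("\\.", "-", seqs))
}

#' Parse an alignment file into an MSA block
#'
#' A3M semantics throughout: uppercase letters and \code{-} occupy match
#' columns, lowercase letters are insertions accumulated into the
#' deletion count of the next match column.  For aligned FASTA and
#' Stockholm input, columns where the reference row carries a gap are
#' treated as insertion columns for the other rows.
#'
#' @param path alignment file.
#' @param format \code{"a3m"}, \code{"stockholm"} or \code{"fasta"}
#'   (aligned FASTA).
#' @param query residue string the alignment must be consistent with:
#'   the reference row, gaps removed, has to equal it.
#' @return an [msa_block()] whose first row is the query.
#' @export
read_alignment <- function(path, format = c("a3m", "stockholm", "fasta"),
                           query) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- if (format == "stockholm") read_stockholm_records(lines)
         else read_fasta_records(lines)
  parse_alignment_rows(rec$seqs, rec$labels, query, a3m = format == "a3m")
}

parse_alignment_rows <- function(seqs, labels, query, a3m = TRUE) {
  aatype <- encode_sequence(query)
  L <- length(aatype)
  ref_degap <- gsub("-", "", toupper(seqs[1]))
  if (!a3m) ref_degap <- gsub("\\.", "", ref_degap)
  if (ref_degap != toupper(query))
    stop("reference row of the alignment does not match the query ",
         "after removing gaps", call. = FALSE)
  if (!a3m) {
    # column-aligned input: reference gap columns become insertions
    w <- unique(nchar(seqs))
    if (length(w) != 1L)
      stop("aligned rows have inconsistent widths", call. = FALSE)
    ref_chars <- strsplit(seqs[1], "", fixed = TRUE)[[1]]
    is_match <- ref_chars != "-"
    seqs <- vapply(seqs, function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      chars[!is_match] <- ifelse(chars[!is_match] == "-", "",
                                 tolower(chars[!is_match]))
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  parsed <- lapply(seq_along(seqs), function(i)
    a3m_row(seqs[i], L, labels[i]))
  rows <- do.call(rbind, lapply(parsed, `[[`, "enc"))
  dels <- do.call(rbind, lapply(parsed, `[[`, "del"))
  rows[1, ] <- aatype          # reference row is the query, gapless
  dels[1, ] <- 0L
  msa_block(rows, dels, labels)
}

#' Write an MSA block as A3M
#'
#' Deletion counts are emitted as lowercase \code{x} insertions before
#' their match column (residue identity of insertions is not stored in
#' the integer form).
#'
#' @param msa an [msa_block()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_a3m <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(msa_depth(msa))) {
    writeLines(paste0(">", msa$row_labels[i]), con)
    cells <- c(AA_LETTERS, "-")[msa$rows[i, ] + 1L]
    ins <- vapply(msa$deletion_counts[i, ], function(d)
      paste(rep("x", d), collapse = ""), character(1))
    writeLines(paste0(ins, cells, collapse = ""), con)
  }
  invisible(path)
}

#' Reduce MSA depth
#'
#' The query row is always retained.  \code{top} keeps the first
#' \code{n - 1} non-query rows in stored order (assumed to be search
#' ranking); \code{diverse} greedily selects rows maximizing the minimum
#' Hamming distance (over match columns) to the rows already kept.
#'
#' @param msa an [msa_block()].
#' @param n target number of rows including the query; \code{n} at or
#'   above the current depth returns the input unchanged.
#' @param strategy \code{"top"} or \code{"diverse"}.
#' @param seed integer seed used to break ties in \code{diverse}.
#' @return an [msa_block()] with \code{min(n, N_seq)} rows.
#' @export
reduce_depth <- function(msa, n, strategy = c("top", "diverse"),
                         seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(n >= 1L)
  N <- msa_depth(msa)
  if (n >= N) return(msa)
  keep <- if (strategy == "top") {
    seq_len(n)
  } else {
    pool <- setdiff(seq_len(N), 1L)
    sel <- 1L
    set.seed(as.integer(seed) %% .Machine$integer.max)
    jitter <- stats::runif(N) * 1e-9
    dist_to_sel <- rep(Inf, N)
    while (length(sel) < n) {
      last <- sel[length(sel)]
      h <- colSums(t(msa$rows[pool, , drop = FALSE]) != msa$rows[last, ])
      dist_to_sel[pool] <- pmin(dist_to_sel[pool], h)
      pick <- pool[which.max(dist_to_sel[pool] + jitter[pool])]
      sel <- c(sel, pick)
      pool <- setdiff(pool, pick)
    }
    sort(sel)
  }
  msa_block(msa$rows[keep, , drop = FALSE],
            msa$deletion_counts[keep, , drop = FALSE],
            msa$row_labels[keep])
}

#' Mask an MSA region
#'
#' In every non-query row the selected columns are replaced by the
#' gap/mask index 21 and their deletion counts zeroed; the query row and
#' the column count are untouched.  Masking is idempotent.
#'
#' @param msa an [msa_block()].
#' @param region a [region_selection()] (or \code{NULL} for identity).
#' @param plan optional [assembly_plan()] used to resolve chain
#'   coordinates into concatenated columns.
#' @return the masked [msa_block()].
#' @export
mask_region <- function(msa, region, plan = NULL) {
  L <- ncol(msa$rows)
  cols <- resolve_region(region, plan, L)
  if (length(cols) == 0L || msa_depth(msa) == 1L) return(msa)
  rows <- msa$rows
  dels <- msa$deletion_counts
  rows[-1, cols + 1L] <- AA_GAP
  dels[-1, cols + 1L] <- 0L
  msa_block(rows, dels, msa$row_labels)
}

#' Merge MSA blocks onto one target query
#'
#' Rows from every block are stacked under a single query row.  A block
#' narrower than the target must come with a region of matching resolved
#' width that places its columns; cells outside a block's region are set
#' to gap.  Duplicate integer rows are removed keeping the first.
#'
#' @param blocks list of entries, each a list with elements \code{msa}
#'   (an [msa_block()]) and optional \code{region} (a
#'   [region_selection()]).
#' @param query [query_features()] of the merge target.
#' @param plan optional [assembly_plan()] for resolving regions.
#' @return an [msa_block()] of the target width.
#' @export
merge_msas <- function(blocks, query, plan = NULL) {
  L <- length(query$aatype)
  rows <- list(matrix(query$aatype, nrow = 1L))
  dels <- list(matrix(0L, 1L, L))
  labels <- "query"
  for (b in blocks) {
    msa <- b$msa
    cols <- if (is.null(b$region)) seq_len(ncol(msa$rows)) - 1L
            else resolve_region(b$region, plan, L)
    if (is.null(b$region) && ncol(msa$rows) != L)
      stop(sprintf("block width %d conflicts with target width %d and no placement region was given",
                   ncol(msa$rows), L), call. = FALSE)
    if (!is.null(b$region) && length(cols) != ncol(msa$rows) &&
        ncol(msa$rows) != L)
      stop(sprintf("block width %d does not match its region width %d",
                   ncol(msa$rows), length(cols)), call. = FALSE)
    take <- setdiff(seq_len(msa_depth(msa)), 1L)  # skip block query rows
    if (length(take) == 0L) next
    r <- matrix(AA_GAP, length(take), L)
    d <- matrix(0L, length(take), L)
    if (ncol(msa$rows) == L) {
      r[, cols + 1L] <- msa$rows[take, cols + 1L, drop = FALSE]
      d[, cols + 1L] <- msa$deletion_counts[take, cols + 1L, drop = FALSE]
    } else {
      r[, cols + 1L] <- msa$rows[take, , drop = FALSE]
      d[, cols + 1L] <- msa$deletion_counts[take, , drop = FALSE]
    }
    rows <- c(rows, list(r))
    dels <- c(dels, list(d))
    labels <- c(labels, msa$row_labels[take])
  }
  rows <- do.call(rbind, rows)
  dels <- do.call(rbind, dels)
  dup <- duplicated(apply(rows, 1, paste, collapse = ","))
  msa_block(rows[!dup, , drop = FALSE], dels[!dup, , drop = FALSE],
            labels[!dup])
}

#' Inject a fragment library into an MSA
#'
#' Each fragment contributes one new row carrying its letters at the
#' target columns and gap everywhere else, the device used to promote a
#' local interaction (e.g. a disulfide-bridge strand pair) without
#' supplying full-length homologs.
#'
#' @param msa an [msa_block()].
#' @param fragments list of entries, each a list with \code{sequence}
#'   (residue string) and \code{region} (a [region_selection()] whose
#'   resolved width equals the fragment length).
#' @param plan optional [assembly_plan()] for resolving regions.
#' @return the extended [msa_block()].
#' @export
add_fragment_library <- function(msa, fragments, plan = NULL) {
  if (length(fragments) == 0L) return(msa)
  L <- ncol(msa$rows)
  rows <- msa$rows
  dels <- msa$deletion_counts
  labels <- msa$row_labels
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    enc <- encode_sequence(f$sequence)
    cols <- resolve_region(f$region, plan, L)
    if (length(cols) != length(enc))
      stop(sprintf("fragment %d length %d does not match its %d-column target region",
                   i, length(enc), length(cols)), call. = FALSE)
    r <- rep(AA_GAP, L)
    r[cols + 1L] <- enc
    rows <- rbind(rows, r)
    dels <- rbind(dels, rep(0L, L))
    labels <- c(labels, sprintf("fragment%03d", i))
  }
  msa_block(rows, dels, labels)
}
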