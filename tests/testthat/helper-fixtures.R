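# Shared fixtures and generators for the test suite.  Expensive
# fixtures are built once per session and memoized.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")
}

# A random but valid feature set exercising every container field.
random_feature_set <- function(seed) {
  set.seed(seed)
  L <- sample(5:30, 1)
  seqn <- random_sequence(L, seed + 1)
  fs <- empty_features(seqn)
  n_rows <- sample(1:6, 1)
  if (n_rows > 1)
    fs <- fs_set_msa(fs, make_toy_msa(seqn, n_rows,
                                      conservation = stats::runif(1, 0.3, 1),
                                      seed = seed + 2))
  # random deletion counts in non-query rows
  if (nrow(fs$msa$rows) > 1) {
    dc <- fs$msa$deletion_counts
    dc[-1, ] <- matrix(sample(0:3, (nrow(dc) - 1) * ncol(dc),
                              replace = TRUE),
                       nrow(dc) - 1)
    fs$msa$deletion_counts <- dc
  }
  for (t in seq_len(sample(0:3, 1))) {
    covered <- sort(sample(L, max(2, sample(L, 1))))
    labels <- rep(21L, L)
    labels[covered] <- sample(0:20, length(covered), replace = TRUE)
    pos <- array(0, dim = c(L, 37, 3))
    mask <- matrix(0L, L, 37)
    mask[covered, 1:5] <- 1L
    pos[covered, 1:5, ] <- stats::rnorm(length(covered) * 5 * 3) * 10
    fs <- fs_add_template(fs, template_feature(
      labels, pos, mask, name = sprintf("t%d_%d", seed, t),
      sum_prob = stats::runif(1)))
  }
  fs
}

expect_fs_equal <- function(a, b) {
  expect_identical(a$query$sequence, b$query$sequence)
  expect_identical(a$query$aatype, b$query$aatype)
  expect_identical(a$query$residue_index, b$query$residue_index)
  expect_identical(a$query$between_segment_flags,
                   b$query$between_segment_flags)
  expect_identical(a$msa$rows, b$msa$rows)
  expect_identical(a$msa$deletion_counts, b$msa$deletion_counts)
  expect_identical(a$msa$row_labels, b$msa$row_labels)
  expect_equal(length(a$templates), length(b$templates))
  for (i in seq_along(a$templates)) {
    expect_identical(a$templates[[i]]$labels, b$templates[[i]]$labels)
    expect_identical(a$templates[[i]]$atom_positions,
                     b$templates[[i]]$atom_positions)
    expect_identical(a$templates[[i]]$atom_mask,
                     b$templates[[i]]$atom_mask)
    expect_identical(a$templates[[i]]$sum_prob,
                     b$templates[[i]]$sum_prob)
    expect_identical(a$templates[[i]]$name, b$templates[[i]]$name)
  }
  expect_identical(vapply(a$provenance, `[[`, "", "op"),
                   vapply(b$provenance, `[[`, "", "op"))
  if (is.null(a$assembly)) expect_null(b$assembly)
  else expect_identical(foldsteer:::serialize_plan(a$assembly),
                        foldsteer:::serialize_plan(b$assembly))
}

# Cut a model into the segments of a mosaic plan and scatter each
# fragment with a random rigid motion (seeded).
self_fragments <- function(model, mplan, seed = 1) {
  set.seed(seed)
  lapply(seq_along(mplan$segments), function(s) {
    cols <- sort(mplan$segments[[s]])
    frag <- subset_model(model, cols + 1L)
    frag$resno <- cols + 1L
    R <- foldsteer:::rotation_from_euler(runif(1, 0, 360),
                                         runif(1, 0, 360),
                                         runif(1, 0, 360))
    foldsteer:::transform_model(frag, R, runif(3, -30, 30))
  })
}

canonical_strand_pair <- function() {
  cached("strand_pair", make_structure("strand_pair", seed = 1))
}

two_state_fixture <- function(seed = 3) {
  cached(paste0("two_state_", seed),
         make_two_state_ensemble(8L, seed = seed))
}
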