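write_a3m_file <- function(rows) {
  path <- withr::local_tempfile(fileext = ".a3m",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(seq_along(rows), function(i)
    c(sprintf(">seq%d", i), rows[i]))), path)
  path
}

test_that("A3M rows parse with insertion counts at the next match column", {
  path <- write_a3m_file(c("ACDEF", "AC-dEF"))
  msa <- read_alignment(path, "a3m", query = "ACDEF")
  expect_identical(msa$rows[2, ], c(0L, 4L, 21L, 6L, 13L))
  expect_identical(msa$deletion_counts[2, ], c(0L, 0L, 0L, 1L, 0L))
  expect_identical(msa$rows[1, ], encode_sequence("ACDEF"))

  # query-only file reproduces the uninformed baseline MSA
  p2 <- write_a3m_file("ACDEF")
  one <- read_alignment(p2, "a3m", query = "ACDEF")
  expect_identical(one$rows, empty_features("ACDEF")$msa$rows)

  # wrong match-column count
  p3 <- write_a3m_file(c("ACDEF", "AC-EF-"))
  expect_error(read_alignment(p3, "a3m", query = "ACDEF"),
               "match columns")
  # reference inconsistent with the query
  p4 <- write_a3m_file(c("ACDEG", "ACDEG"))
  expect_error(read_alignment(p4, "a3m", query = "ACDEF"),
               "does not match the query")
})

test_that("Stockholm and aligned FASTA parse through the same semantics", {
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "q    ACDEF", "r2   AC.EF", "//"),
             sto)
  msa <- read_alignment(sto, "stockholm", query = "ACDEF")
  expect_identical(msa$rows[2, ], c(0L, 4L, 21L, 6L, 13L))

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "AC-DEF", ">r", "ACXDE-"), fa)
  msa2 <- read_alignment(fa, "fasta", query = "ACDEF")
  # the reference gap column becomes an insertion for row 2
  expect_identical(ncol(msa2$rows), 5L)
  expect_identical(msa2$rows[2, ], c(0L, 4L, 3L, 6L, 21L))
  expect_identical(msa2$deletion_counts[2, ], c(0L, 0L, 1L, 0L, 0L))
})

test_that("reduce_depth keeps the query and honors both strategies", {
  msa <- make_toy_msa(random_sequence(25, 1), 50, conservation = 0.7,
                      seed = 2)
  top <- reduce_depth(msa, 30, "top")
  expect_identical(nrow(top$rows), 30L)
  expect_identical(top$rows, msa$rows[1:30, ])   # prefix property

  expect_identical(reduce_depth(msa, 1)$rows,
                   msa$rows[1, , drop = FALSE])
  expect_identical(reduce_depth(msa, 50), msa)   # n >= N unchanged
  expect_identical(reduce_depth(msa, 99), msa)

  d1 <- reduce_depth(msa, 10, "diverse", seed = 7)
  d2 <- reduce_depth(msa, 10, "diverse", seed = 7)
  expect_identical(d1, d2)
  expect_identical(d1$rows[1, ], msa$rows[1, ])
  expect_identical(nrow(d1$rows), 10L)
})

test_that("mask_region substitutes gap in non-query rows only", {
  msa <- make_toy_msa(random_sequence(50, 3), 50, conservation = 1,
                      seed = 3)
  region <- region_selection("*", 10, 28)   # a 19-residue loop window
  masked <- mask_region(msa, region)
  expect_identical(dim(masked$rows), dim(msa$rows))
  expect_identical(masked$rows[1, ], msa$rows[1, ])
  expect_true(all(masked$rows[-1, 10:28] == 21L))
  expect_true(all(masked$deletion_counts[-1, 10:28] == 0L))
  expect_identical(sum(masked$rows[2, ] == 21L), 19L)

  # idempotent, identity on empty region, commutes for disjoint regions
  expect_identical(mask_region(masked, region), masked)
  expect_identical(mask_region(msa, NULL), msa)
  r1 <- region_selection("*", 1, 5)
  r2 <- region_selection("*", 40, 45)
  expect_identical(mask_region(mask_region(msa, r1), r2),
                   mask_region(mask_region(msa, r2), r1))

  all_cols <- mask_region(msa, region_selection("*", 1, 50))
  expect_identical(nrow(all_cols$rows), nrow(msa$rows))
  expect_true(all(all_cols$rows[-1, ] == 21L))
  expect_error(mask_region(msa, region_selection("*", 40, 60)),
               "outside")
})

test_that("merge stacks blocks under one query row with placement and dedup", {
  plan <- assembly_plan(list(chain_spec("A", random_sequence(12, 4)),
                             chain_spec("B", random_sequence(10, 5))))
  fs <- concatenate_chains(plan)
  msa_a <- make_toy_msa(substr(fs$query$sequence, 1, 12), 4, seed = 6)
  msa_b <- make_toy_msa(substr(fs$query$sequence, 13, 22), 3, seed = 7)
  merged <- merge_msas(list(
    list(msa = msa_a, region = region_selection("A", 1, 12)),
    list(msa = msa_b, region = region_selection("B", 1, 10))),
    fs$query, plan)
  expect_identical(ncol(merged$rows), 22L)
  expect_identical(merged$rows[1, ], fs$query$aatype)
  # block rows are gap-padded outside their chain
  expect_true(all(merged$rows[2:4, 13:22] == 21L))
  expect_true(all(merged$rows[5:6, 1:12] == 21L))

  # merging a block with itself adds no duplicate rows
  twice <- merge_msas(list(
    list(msa = msa_a, region = region_selection("A", 1, 12)),
    list(msa = msa_a, region = region_selection("A", 1, 12))),
    fs$query, plan)
  expect_identical(nrow(twice$rows), 4L)

  expect_error(merge_msas(list(list(msa = msa_b)), fs$query, plan),
               "width")
})

test_that("fragment libraries add one gap-padded row per fragment", {
  msa <- make_toy_msa(random_sequence(110, 8), 5, seed = 8)
  frag_seq <- random_sequence(15, 9)
  out <- add_fragment_library(msa, list(
    list(sequence = frag_seq, region = region_selection("*", 20, 34))))
  expect_identical(nrow(out$rows), 6L)
  expect_identical(sum(out$rows[6, ] != 21L), 15L)
  expect_identical(out$rows[6, 20:34], encode_sequence(frag_seq))

  expect_identical(add_fragment_library(msa, list()), msa)
  expect_error(add_fragment_library(msa, list(
    list(sequence = "ACD", region = region_selection("*", 1, 5)))),
    "does not match")
  expect_error(add_fragment_library(msa, list(
    list(sequence = "AC9DE", region = region_selection("*", 1, 5)))),
    "illegal")
})
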