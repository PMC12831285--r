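test_that("index-gap concatenation offsets the residue index between chains", {
  plan <- assembly_plan(list(chain_spec("A", random_sequence(50, 1)),
                             chain_spec("B", random_sequence(60, 2))),
                        index_gap = 200)
  fs <- concatenate_chains(plan)
  expect_identical(length(fs$query$aatype), 110L)
  expect_identical(fs$query$residue_index[1:50], 0:49)
  expect_identical(fs$query$residue_index[51:110], 250:309)
  expect_identical(sum(fs$query$between_segment_flags), 0L)
  expect_identical(nrow(validate_features(fs)), 0L)
})

test_that("homodimer copies expand into two segments with chain letters", {
  # the S-layer-like case: one 277-residue chain, two copies, authored
  # numbering starting at residue 32
  seqn <- random_sequence(277, 3)
  plan <- assembly_plan(list(chain_spec("M", seqn, copies = 2,
                                        first_resno = 32)))
  fs <- concatenate_chains(plan)
  expect_identical(length(fs$query$aatype), 554L)
  sm <- plan$segment_map
  expect_identical(nrow(sm), 2L)
  expect_identical(sm$out_chain, c("A", "B"))

  mods <- mock_predict(fs, 1, seed = 1)
  dm <- disengage(mods[[1]], plan)
  expect_identical(sort(unique(dm$chain)), c("A", "B"))
  expect_identical(dm$resno[dm$chain == "A"], 32:308)
  expect_identical(dm$resno[dm$chain == "B"], 32:308)
})

test_that("physical linkers are inserted, flagged, and dropped on disengage", {
  plan <- assembly_plan(list(chain_spec("A", "ACD"),
                             chain_spec("B", "EFG")),
                        linker_mode = "physical",
                        physical_linker = "GGGGS")
  fs <- concatenate_chains(plan)
  expect_identical(length(fs$query$aatype), 11L)
  expect_identical(fs$query$between_segment_flags,
                   c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_identical(substr(fs$query$sequence, 4, 8), "GGGGS")

  mods <- mock_predict(fs, 1, seed = 1)
  dm <- disengage(mods[[1]], plan)
  expect_identical(length(dm), 6L)
  expect_false(any(dm$chain == "-"))
})

test_that("disengage recovers chain identity for arbitrary random plans", {
  for (seed in 1:8) {
    set.seed(seed)
    n_chains <- sample(1:3, 1)
    chains <- lapply(seq_len(n_chains), function(i)
      chain_spec(LETTERS[i], random_sequence(sample(10:40, 1),
                                             seed * 10 + i),
                 copies = sample(1:2, 1),
                 first_resno = sample(c(1, 20), 1)))
    mode <- sample(c("index_gap", "physical"), 1)
    plan <- assembly_plan(chains, linker_mode = mode)
    fs <- concatenate_chains(plan)
    expect_identical(nrow(validate_features(fs)), 0L)
    sm <- plan$segment_map
    real <- sm[sm$chain_id != "-", ]
    n_linkers <- sum(sm$chain_id == "-")
    base_len <- sum(real$length)
    if (mode == "physical")
      expect_identical(length(fs$query$aatype),
                       base_len + n_linkers * 5L)
    else
      expect_identical(length(fs$query$aatype), base_len)
    dm <- disengage(mock_predict(fs, 1, seed = 1)[[1]], plan)
    expect_identical(length(dm), base_len)
    for (r in seq_len(nrow(real))) {
      seg <- dm$chain == real$out_chain[r]
      expect_identical(sum(seg), real$length[r])
      expect_identical(dm$resno[seg],
                       seq(real$first_resno[r],
                           length.out = real$length[r]))
    }
  }
})

test_that("plan validation rejects duplicates and empty plans", {
  expect_error(assembly_plan(list()), "empty")
  expect_error(assembly_plan(list(chain_spec("A", "ACD"),
                                  chain_spec("A", "EFG"))),
               "duplicate")
  expect_error(disengage(make_structure("helix", length = 10),
                         assembly_plan(list(chain_spec("A", "ACDEF")))),
               "length")
})

test_that("regions resolve chain coordinates to concatenated columns", {
  plan <- assembly_plan(list(chain_spec("A", random_sequence(20, 1)),
                             chain_spec("B", random_sequence(20, 2))))
  expect_identical(foldsteer:::resolve_region(
    region_selection("B", 1, 5), plan, 40), 20:24)
  expect_identical(foldsteer:::resolve_region(
    region_selection("*", 1, 2), plan, 40), c(0L, 1L, 20L, 21L))
  expect_error(foldsteer:::resolve_region(
    region_selection("B", 15, 25), plan, 40), "outside")
  expect_error(foldsteer:::resolve_region(
    region_selection("C", 1, 5), plan, 40), "unknown chain")
})
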