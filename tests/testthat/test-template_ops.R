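test_that("identical sequences give an identity mapping covering all of L", {
  seqn <- random_sequence(30, 1)
  q <- query_features(seqn)
  h <- make_structure("helix", length = 30, sequence = seqn)
  t <- structure_to_template(h, q)
  expect_identical(foldsteer:::template_coverage(t), 1:30)
  expect_identical(t$labels, q$aatype)
  # coordinates are copied verbatim, no rotation applied
  expect_identical(t$atom_positions[5, 2, ], h$coords[5, 2, ])
  expect_identical(nrow(validate_features(
    fs_add_template(empty_features(seqn), t))), 0L)
})

test_that("low-identity templates need an explicit mapping to be accepted", {
  # all-L vs all-I: leucine/isoleucine score positively so the global
  # alignment pairs every position, yet the identity is 0%
  q <- query_features(strrep("L", 20))
  h <- make_structure("helix", length = 20, sequence = strrep("I", 20))
  expect_error(structure_to_template(h, q), "below")
  # the deliberate route: a user-supplied map (the remote-homolog case)
  t <- structure_to_template(h, q, mapping = align_map(0:19, 0:19))
  expect_identical(length(foldsteer:::template_coverage(t)), 20L)
})

test_that("auto alignment matches the exhaustive monotone-mapping oracle", {
  # hand-made toy: a 6-residue template that matches a unique window
  # of an 8-residue query
  q <- query_features("WACDEFGH")
  h <- make_structure("helix", length = 6, sequence = "ACDEFG")
  t <- structure_to_template(h, q, min_identity = 0.5)
  got <- which(t$labels != 21L) - 1L
  oracle <- oracle_best_monotone_mapping("WACDEFGH", "ACDEFG")
  expect_length(oracle$maps, 1)     # the optimum is unique
  expect_identical(got, oracle$maps[[1]][, 1])
  expect_identical(t$labels[got + 1L], encode_sequence("ACDEFG"))
})

test_that("relabeling changes labels but never coverage", {
  seqn <- random_sequence(100, 2)
  q <- query_features(seqn)
  h <- make_structure("helix", length = 100, sequence =
                        random_sequence(100, 3))
  t <- structure_to_template(h, q, mapping = align_map(0:99, 0:99))
  cov <- foldsteer:::template_coverage(t)

  poly <- relabel_template(t, "polyalanine")
  expect_true(all(poly$labels[cov] == 0L))
  expect_identical(foldsteer:::template_coverage(poly), cov)

  # polyalanine with query labels across the hinge window 81-91
  hinge <- relabel_template(t, "polyalanine", query = q,
                            region = region_selection("*", 81, 91))
  expect_identical(hinge$labels[81:91], q$aatype[81:91])
  expect_identical(length(81:91), 11L)   # 11 positions carry query labels
  expect_true(all(hinge$labels[setdiff(cov, 81:91)] == 0L))
  expect_identical(foldsteer:::template_coverage(hinge), cov)

  expect_identical(relabel_template(t, "keep")$labels, t$labels)
  qq <- relabel_template(t, "query", query = q)
  expect_identical(qq$labels[cov], q$aatype[cov])
  cust <- relabel_template(t, "custom",
                           replacement = random_sequence(100, 4))
  expect_identical(foldsteer:::template_coverage(cust), cov)
  expect_error(relabel_template(t, "custom", replacement = "ACD"),
               "replacement length")
})

test_that("C-beta truncation keeps backbone+CB only and is idempotent", {
  seqn <- paste0("AG", random_sequence(18, 5))
  q <- query_features(seqn)
  h <- make_structure("helix", length = 20, sequence = seqn)
  t <- structure_to_template(h, q)
  tr <- truncate_to_cbeta(t)
  keep <- c(1L, 2L, 3L, 4L, 5L)
  expect_true(all(tr$atom_mask[, -keep] == 0L))
  expect_identical(foldsteer:::template_coverage(tr),
                   foldsteer:::template_coverage(t))
  # glycine (position 2) keeps 4 atoms, others keep 5
  expect_identical(sum(tr$atom_mask[2, ]), 4L)
  expect_identical(sum(tr$atom_mask[1, ]), 5L)
  expect_identical(truncate_to_cbeta(tr), tr)
})

test_that("multi-chain templates paste sources into disjoint regions", {
  seqn <- random_sequence(30, 6)
  plan <- assembly_plan(list(chain_spec("M", seqn, copies = 2)))
  fs <- concatenate_chains(plan)
  tc <- make_structure("toy_complex", length = 30, sequence = seqn)
  t <- multi_chain_template(list(
    list(structure = subset_model(tc, 1:30),
         region = region_selection("A", 1, 30)),
    list(structure = subset_model(tc, 31:60),
         region = region_selection("B", 1, 30))),
    fs$query, plan, name = "dimer")
  expect_identical(length(foldsteer:::template_coverage(t)), 60L)
  # inter-region geometry preserved exactly (no re-superposition)
  expect_identical(t$atom_positions[31, 2, ], tc$coords[31, 2, ])

  single <- multi_chain_template(list(
    list(structure = subset_model(tc, 1:30),
         region = region_selection("A", 1, 30))),
    fs$query, plan)
  expect_true(all(single$labels[31:60] == 21L))

  expect_error(multi_chain_template(list(
    list(structure = subset_model(tc, 1:30),
         region = region_selection("A", 1, 30)),
    list(structure = subset_model(tc, 31:60),
         region = region_selection("A", 25, 30))),
    fs$query, plan), "overlapping")
})

test_that("template clustering recovers planted two-state groups", {
  ens <- two_state_fixture()
  q <- query_features(decode_sequence(ens$members[[1]]$aatype))
  templates <- lapply(ens$members, function(m)
    structure_to_template(m, q, name = m$name))
  cl <- cluster_templates(templates, k = 2, seed = 1)
  expect_length(cl$groups, 2)
  expect_true(all(table(cl$labels, ens$labels) %in%
                    c(0L, table(ens$labels))))

  # identical templates collapse into one group under k = auto
  same <- lapply(1:4, function(i) templates[[1]])
  cl2 <- cluster_templates(same, k = "auto", seed = 1)
  expect_length(cl2$groups, 1)

  # k = 3 on a 2-state set: deterministic under a fixed seed
  cl3a <- cluster_templates(templates, k = 3, seed = 5)
  cl3b <- cluster_templates(templates, k = 3, seed = 5)
  expect_identical(cl3a$labels, cl3b$labels)
  expect_identical(length(unique(cl3a$labels)), 3L)

  expect_error(cluster_templates(templates[1:2], min_common = 1000),
               "common")
})
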