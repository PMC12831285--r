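test_that("fixtures are deterministic down to the written bytes", {
  a <- make_structure("two_block_hinge", hinge_angle = 30, seed = 7,
                      noise = 0.2)
  b <- make_structure("two_block_hinge", hinge_angle = 30, seed = 7,
                      noise = 0.2)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(a, p1)
  write_pdb(b, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("ideal builders satisfy their geometric contracts", {
  expect_identical(ramachandran_outliers(
    make_structure("helix", length = 20))$fraction, 0)

  # zero hinge angle: the two-block fixture is one rigid body
  flat <- make_structure("two_block_hinge", hinge_angle = 0, seed = 1)
  straight <- foldsteer:::build_torsion_model(
    c(rep(-57, 40), rep(-150, 5), rep(-57, 40)),
    c(rep(-47, 40), rep(150, 5), rep(-47, 40)),
    decode_sequence(flat$aatype))
  expect_lt(superpose(flat, straight)$rmsd, 1e-9)

  # CB sits at ~1.52 A from CA for non-glycine
  h <- make_structure("helix", length = 10, sequence = "ALSERTKVIW")
  d <- sqrt(sum((h$coords[3, 4, ] - h$coords[3, 2, ])^2))
  expect_equal(d, 1.52, tolerance = 0.02)
})

test_that("two-state ensembles carry recoverable labels", {
  ens <- make_two_state_ensemble(8, delta = 30, noise = 0, seed = 5)
  expect_identical(ens$labels, rep(c(1L, 2L), each = 4))
  frame <- build_frame(ens$members)
  cc <- cc_matrix(frame)
  # noise-free duplicates within each state correlate perfectly
  expect_equal(cc[1, 2], 1, tolerance = 1e-9)
  expect_equal(cc[5, 6], 1, tolerance = 1e-9)

  # a degenerate delta = 0 ensemble has no systematic structure
  flat <- make_two_state_ensemble(4, delta = 0, noise = 0.1, seed = 6)
  fr <- build_frame(flat$members)
  emb <- embed_cc(cc_matrix(fr), seed = 1)
  expect_lt(emb$residual, 1)
})

test_that("toy MSAs follow their conservation profile", {
  q <- random_sequence(30, 1)
  all_same <- make_toy_msa(q, 10, conservation = 1, seed = 2)
  expect_true(all(t(all_same$rows) == encode_sequence(q)))
  expect_identical(nrow(make_toy_msa(q, 1, seed = 3)$rows), 1L)
  m1 <- make_toy_msa(q, 10, conservation = 0.5, seed = 4)
  m2 <- make_toy_msa(q, 10, conservation = 0.5, seed = 4)
  expect_identical(m1, m2)
  expect_identical(nrow(validate_features(
    fs_set_msa(empty_features(q), m1))), 0L)
})

test_that("fixture bundles write valid standard files", {
  dir <- withr::local_tempdir()
  files <- make_fixture_bundle(dir, seed = 1)
  expect_true(all(file.exists(files)))
  tc <- read_pdb(file.path(dir, "toy_complex.pdb"))
  expect_identical(sort(unique(tc$chain)), c("A", "B"))
  m <- read_alignment(file.path(dir, "toy.a3m"), "a3m",
                      query = foldsteer:::fixture_sequence(40, 1))
  expect_identical(nrow(m$rows), 20L)
  labels <- utils::read.csv(file.path(dir, "two_state_labels.csv"))
  expect_identical(nrow(labels), 8L)
})

test_that("PDB and mmCIF round-trips preserve structure content", {
  tc <- make_structure("toy_complex", length = 15, seed = 9)
  tc$plddt <- rep(77.5, length(tc))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tc, p)
  back <- read_pdb(p)
  expect_identical(back$chain, tc$chain)
  expect_identical(back$aatype, tc$aatype)
  expect_equal(back$coords, tc$coords, tolerance = 1e-2)
  expect_equal(back$plddt, tc$plddt, tolerance = 1e-6)

  # minimal mmCIF with the same content
  cif <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_test", "loop_", "_atom_site.group_PDB",
           "_atom_site.label_atom_id", "_atom_site.label_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y",
           "_atom_site.Cartn_z", "_atom_site.B_iso_or_equiv")
  rows <- character(0)
  for (i in seq_len(length(tc)))
    for (s in which(tc$mask[i, ] == 1)) {
      rows <- c(rows, sprintf("ATOM %s %s %s %d %.3f %.3f %.3f %.2f",
                              foldsteer:::ATOM37[s],
                              foldsteer:::aa_three_letter(tc$aatype[i]),
                              tc$chain[i], tc$resno[i],
                              tc$coords[i, s, 1], tc$coords[i, s, 2],
                              tc$coords[i, s, 3], 77.5))
    }
  writeLines(c(hdr, rows, "#"), cif)
  cback <- read_cif(cif)
  expect_identical(cback$chain, tc$chain)
  expect_equal(cback$coords, tc$coords, tolerance = 1e-2)
})
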