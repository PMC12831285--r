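test_that("the ensemble frame removes rigid motions deterministically", {
  h <- make_structure("helix", length = 30, seed = 1)
  h2 <- h
  h2$name <- "copy"
  frame <- build_frame(list(h, h2))
  expect_equal(frame$member_rmsd, c(0, 0), tolerance = 1e-9)
  expect_equal(frame$mean, ca_coords(h), tolerance = 1e-9,
               ignore_attr = TRUE)

  # a translated + rotated copy superposes exactly
  h3 <- foldsteer:::transform_model(
    h, foldsteer:::rotation_from_euler(40, 10, 70), c(5, -3, 12))
  h3$name <- "moved"
  frame2 <- build_frame(list(h, h3))
  expect_equal(frame2$member_rmsd, c(0, 0), tolerance = 1e-7)

  expect_error(build_frame(list(h, make_structure("helix", length = 5,
                                                  seed = 2))),
               "common CA")
})

test_that("structural correlation matches its closed-form cases", {
  h <- make_structure("helix", length = 30, seed = 1)
  bump <- function(res, dim, delta, name) {
    m <- h
    m$coords[res, 2, dim] <- m$coords[res, 2, dim] + delta
    m$name <- name
    m
  }
  # mean-preserving construction: +x/-x on residue 1 and +y/-y on
  # residue 15, so deviations from the mean are along orthogonal
  # coordinate directions and CC(+x, +y) = 0
  members <- list(bump(1, 1, 2, "xp"), bump(1, 1, -2, "xm"),
                  bump(15, 2, 2, "yp"), bump(15, 2, -2, "ym"))
  frame <- build_frame(members)
  cc <- cc_matrix(frame)
  expect_identical(unname(diag(cc)), rep(1, 4))
  expect_true(all(cc >= -1 - 1e-9 & cc <= 1 + 1e-9))
  expect_equal(cc, t(cc), ignore_attr = TRUE)
  expect_equal(cc["xp", "yp"], 0, tolerance = 0.02)
  # mirror-displaced pair: d_j = -d_i gives CC -1
  expect_equal(cc["xp", "xm"], -1, tolerance = 1e-3)
  expect_equal(cc["yp", "ym"], -1, tolerance = 1e-3)

  # a duplicated member correlates perfectly with its twin
  dup <- h
  dup$name <- "dup"
  frame2 <- build_frame(list(members[[1]], members[[3]], h, dup))
  cc2 <- cc_matrix(frame2)
  expect_equal(cc2[3, 4], 1, tolerance = 1e-6)
})

test_that("the embedding reproduces correlations and finds planted clusters", {
  # all-correlated: vectors coincide, residual ~ 0
  cc1 <- matrix(1, 3, 3)
  e1 <- embed_cc(cc1, seed = 1)
  expect_lt(e1$residual, 1e-8)
  expect_lt(max(dist(e1$vectors)), 1e-3)
  expect_identical(unique(e1$cluster), 1L)

  # planted 2-cluster structure (within 0.95, between 0.2)
  cc2 <- matrix(0.2, 6, 6)
  cc2[1:3, 1:3] <- 0.95
  cc2[4:6, 4:6] <- 0.95
  diag(cc2) <- 1
  e2 <- embed_cc(cc2, seed = 1)
  expect_identical(length(unique(e2$cluster)), 2L)
  expect_identical(length(unique(e2$cluster[1:3])), 1L)
  expect_identical(length(unique(e2$cluster[4:6])), 1L)
  expect_true(e2$cluster[1] != e2$cluster[4])

  # residual is non-increasing with embedding dimension
  set.seed(42)
  r <- matrix(rnorm(5 * 2), 5, 2)
  ccr <- tcrossprod(r / sqrt(rowSums(r^2) + 1))
  diag(ccr) <- 1
  res_d2 <- embed_cc(ccr, d = 2, seed = 2)$residual
  res_d4 <- embed_cc(ccr, d = 4, seed = 2)$residual
  expect_lte(res_d4, res_d2 + 1e-9)

  # unit-disk constraint holds
  expect_true(all(sqrt(rowSums(e2$vectors^2)) <= 1 + 1e-6))
})

test_that("3x3 embedding reaches the brute-force grid optimum", {
  cases <- list(
    matrix(c(1, .9, .2, .9, 1, .3, .2, .3, 1), 3, 3),
    matrix(c(1, -.5, .4, -.5, 1, -.1, .4, -.1, 1), 3, 3),
    matrix(c(1, .99, .98, .99, 1, .97, .98, .97, 1), 3, 3))
  for (cc in cases) {
    ours <- embed_cc(cc, seed = 3)$residual
    oracle <- oracle_embed_residual_3(cc)
    expect_lt(abs(ours - oracle), 1e-3)
  }
})

test_that("hinge decomposition recovers planted rigid blocks", {
  ens <- two_state_fixture()
  frame <- build_frame(ens$members)
  dec <- find_hinges(frame)
  groups <- dec$groups
  expect_identical(length(unique(groups)), 2L)
  # planted blocks: 1-40 and 46-85 each uniform, and distinct
  expect_identical(length(unique(groups[1:40])), 1L)
  expect_identical(length(unique(groups[46:85])), 1L)
  expect_true(groups[1] != groups[85])
  expect_true(all(dec$boundaries >= 41 & dec$boundaries <= 46))
  expect_true(all(diff(match(unique(groups), groups)) > 0))
  expect_true(all(dec$group_rmsd_range >= 0))

  # tol -> Inf collapses to one group
  one <- find_hinges(frame, tol = Inf)
  expect_identical(length(unique(one$groups)), 1L)

  # a rigid structure duplicated has a single group at any tolerance
  h <- make_structure("helix", length = 30, seed = 4)
  h2 <- h
  h2$name <- "dup"
  rigid <- find_hinges(build_frame(list(h, h2)), tol = 0.5)
  expect_identical(length(unique(rigid$groups)), 1L)
})

test_that("state classification propagates reference labels by cluster", {
  ens <- two_state_fixture()
  frame <- build_frame(ens$members)
  emb <- embed_cc(cc_matrix(frame), seed = 1, k = 2)
  refs <- c(member01 = "inward", member05 = "outward")
  cl <- classify_states(emb, refs)
  expect_false(cl$ambiguous)
  want <- ifelse(ens$labels == ens$labels[1], "inward", "outward")
  expect_identical(unname(cl$states), want)

  # single cluster: all one state
  ccu <- matrix(1, 4, 4)
  embu <- embed_cc(ccu, seed = 1)
  clu <- classify_states(embu)
  expect_identical(length(unique(clu$states)), 1L)

  # conflicting references raise the ambiguity flag, nothing assigned
  bad_refs <- c(member01 = "inward", member02 = "outward")
  clb <- classify_states(emb, bad_refs)
  expect_true(clb$ambiguous)
  expect_true(length(clb$report) > 0)
  expect_error(classify_states(emb, c(nosuch = "x")), "not found")
})

test_that("analysis bundles serialize to CSV/JSON", {
  ens <- two_state_fixture()
  frame <- build_frame(ens$members)
  cc <- cc_matrix(frame)
  emb <- embed_cc(cc, seed = 1, k = 2)
  sa <- state_analysis(frame, cc, emb, hinges = find_hinges(frame))
  dir <- withr::local_tempdir()
  files <- write_state_analysis(sa, dir)
  expect_true(all(file.exists(files)))
  emb_csv <- utils::read.csv(file.path(dir, "embedding.csv"))
  expect_identical(nrow(emb_csv), 8L)
})
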