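test_that("superposition is exact on rigid copies and matches the grid oracle", {
  h <- make_structure("helix", length = 25, seed = 1)
  expect_lt(superpose(h, h)$rmsd, 1e-12)

  moved <- foldsteer:::transform_model(
    h, foldsteer:::rotation_from_euler(33, -70, 141), c(4, 18, -9))
  fit <- superpose(moved, h)
  expect_lt(fit$rmsd, 1e-6)
  expect_identical(fit$n_aligned, 25L)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # small random point sets against the Euler-grid brute force
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1)
    x <- matrix(rnorm(3 * n, sd = 4), n, 3)
    y <- matrix(rnorm(3 * n, sd = 4), n, 3)
    expect_lt(abs(foldsteer:::kabsch(x, y)$rmsd -
                    oracle_superpose_rmsd(x, y)), 1e-4)
  }

  expect_error(superpose(subset_model(h, 1:2), subset_model(h, 1:2)),
               "fewer than 3")
})

test_that("superpose pairs by sequence alignment when numbering differs", {
  h <- make_structure("helix", length = 30, seed = 2)
  shifted <- h
  shifted$resno <- h$resno + 500L
  fit <- superpose(shifted, h)
  expect_lt(fit$rmsd, 1e-6)
})

test_that("Ramachandran classification flags the documented regions", {
  helix <- make_structure("helix", length = 20, seed = 1)
  expect_identical(ramachandran_outliers(helix)$fraction, 0)
  strand <- make_structure("strand", length = 20, seed = 1)
  expect_identical(ramachandran_outliers(strand)$fraction, 0)

  # force one residue to phi = +60, psi = -120 (non-Gly): outside every
  # documented allowed rectangle
  phi <- rep(-57, 20)
  psi <- rep(-47, 20)
  phi[10] <- 60
  psi[10] <- -120
  bad <- foldsteer:::build_torsion_model(phi, psi, strrep("A", 20))
  ro <- ramachandran_outliers(bad)
  expect_true(ro$outliers[10])
  expect_identical(sum(ro$outliers), 1L)

  # degenerate 2-residue chain: nothing classifiable, fraction 0
  two <- subset_model(helix, 1:2)
  ro2 <- ramachandran_outliers(two)
  expect_identical(ro2$classifiable, 0L)
  expect_identical(ro2$fraction, 0)
})

test_that("compactness compares Rg to the globular power law", {
  ext <- make_structure("extended", length = 50, seed = 1)
  expect_gt(compactness(ext), 2)

  collapsed <- ext
  collapsed$coords[, 2, ] <- 0   # all CA coincident
  expect_identical(compactness(collapsed), 0)

  rot <- foldsteer:::transform_model(
    ext, foldsteer:::rotation_from_euler(12, 34, 56), c(1, 2, 3))
  expect_equal(compactness(rot), compactness(ext), tolerance = 1e-9)

  expect_error(compactness(subset_model(ext, 1:4)), "at least 5")
})

test_that("interface metrics: separation, symmetry, and the H-bond ladder", {
  tc <- make_structure("toy_complex", length = 30, seed = 5)
  far <- tc
  bidx <- far$chain == "B"
  far$coords[bidx, , 1] <- far$coords[bidx, , 1] + 100
  rep_far <- interface_metrics(far, c("A", "B"))
  expect_identical(rep_far$buried_area, 0)
  expect_identical(rep_far$h_bonds, 0L)
  expect_identical(rep_far$tier, "none")

  rep_ab <- interface_metrics(tc, c("A", "B"))
  rep_ba <- interface_metrics(tc, c("B", "A"))
  expect_gt(rep_ab$buried_area, 0)
  expect_equal(rep_ab$buried_area, rep_ba$buried_area,
               tolerance = 1e-9)

  sp <- canonical_strand_pair()
  rep_sp <- interface_metrics(sp, c("A", "B"))
  expect_identical(rep_sp$h_bonds, 4L)

  expect_error(interface_metrics(tc, c("A", "Z")), "not present")
})

test_that("buried area grows as chains approach along a fixed axis", {
  tc <- make_structure("toy_complex", length = 20, seed = 7,
                       separation = 30)
  bidx <- tc$chain == "B"
  areas <- vapply(c(0, 16, 21, 24), function(pull) {
    m <- tc
    m$coords[bidx, , ] <- m$coords[bidx, , ] -
      pull / 30 * (m$coords[bidx, , ] - m$coords[!bidx, , ])
    interface_metrics(m, c("A", "B"))$buried_area
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_identical(areas[1], 0)
  expect_gt(areas[4], 0)
})

test_that("ranking is lexicographic with interface presence first", {
  tc <- make_structure("toy_complex", length = 30, seed = 5)
  tc$plddt <- rep(69, length(tc))
  tc$name <- "complexed_low"
  tc2 <- tc
  tc2$plddt <- rep(88, length(tc2))
  tc2$name <- "complexed_high"
  apart <- tc
  bidx <- apart$chain == "B"
  apart$coords[bidx, , 1] <- apart$coords[bidx, , 1] + 100
  apart$plddt <- rep(95, length(apart))
  apart$name <- "apart_high"

  rk <- rank_models(list(apart, tc, tc2),
                    declared_interfaces = list(c("A", "B")))
  expect_identical(rk$table$model,
                   c("complexed_high", "complexed_low", "apart_high"))
  # the 88 vs 69 pLDDT pair orders by confidence; the missing declared
  # interface loses regardless of its higher pLDDT

  # permutation invariance and single-model case
  rk2 <- rank_models(list(tc2, apart, tc),
                     declared_interfaces = list(c("A", "B")))
  expect_identical(rk$table$model, rk2$table$model)
  single <- rank_models(list(tc))
  expect_identical(single$table$rank, 1L)

  # experimental references without confidence default to pLDDT 100
  noconf <- tc
  noconf$plddt <- NULL
  noconf$name <- "experimental"
  rk3 <- rank_models(list(noconf, tc))
  expect_identical(rk3$table$model[1], "experimental")
})

test_that("reports round-trip through their JSON twin", {
  tc <- make_structure("toy_complex", length = 20, seed = 5)
  tc$plddt <- rep(80, length(tc))
  rk <- rank_models(list(tc), declared_interfaces = list(c("A", "B")))
  dir <- withr::local_tempdir()
  files <- write_report(rk, outdir = dir,
                        fs = empty_features("ACDEF"))
  expect_true(all(file.exists(files)))
  twin <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(twin$table$model, rk$table$model)
  expect_equal(twin$table$mean_plddt, rk$table$mean_plddt,
               tolerance = 1e-9)
  expect_equal(twin$table$rank, rk$table$rank)
  # provenance is listed in full
  raw <- jsonlite::read_json(file.path(dir, "report.json"),
                             simplifyVector = FALSE)
  expect_length(raw$provenance, 1)
  expect_identical(raw$provenance[[1]]$op, "empty_features")
  html <- readLines(file.path(dir, "report.html"))
  expect_true(any(grepl("empty_features", html)))
})
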