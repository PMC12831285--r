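test_that("the mock backend is template-faithful, deterministic, and total", {
  seqn <- random_sequence(30, 1)
  fs <- empty_features(seqn)
  h <- make_structure("helix", length = 30, sequence = seqn)
  fs_t <- fs_add_template(fs, structure_to_template(h, fs$query))

  exact <- mock_predict(fs_t, 1, seed = 1, sigma = 0)[[1]]
  expect_equal(exact$coords, h$coords, tolerance = 1e-12)
  expect_identical(mean(exact$plddt), 90)

  bare <- mock_predict(fs, 1, seed = 1)[[1]]
  expect_identical(mean(bare$plddt), 50)
  expect_identical(model_length(bare), 30L)

  a <- mock_predict(fs_t, 3, seed = 9)
  b <- mock_predict(fs_t, 3, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$coords, a[[2]]$coords))

  # the highest-sum_prob template wins
  rot <- foldsteer:::transform_model(
    h, foldsteer:::rotation_from_euler(0, 0, 90), c(50, 0, 0))
  fs_2 <- fs_add_template(fs_t, structure_to_template(
    rot, fs$query, name = "rotated", sum_prob = 0.5))
  m <- mock_predict(fs_2, 1, seed = 1, sigma = 0)[[1]]
  expect_equal(m$coords, h$coords, tolerance = 1e-12)
})

test_that("configs are schema-validated with config errors", {
  expect_error(validate_run_config(list(mode = "nope")),
               class = "config_error")
  expect_error(validate_run_config(list(mode = "guided")),
               class = "config_error")
  expect_error(validate_run_config(list(
    mode = "mutation",
    chains = list(list(chain_id = "A", sequence = "ACD")))),
    class = "config_error")
  ok <- validate_run_config(list(
    mode = "guided",
    chains = list(list(chain_id = "A", sequence = "ACD"))))
  expect_s3_class(ok, "run_config")
  expect_identical(ok$backend, "mock")
  expect_error(read_run_config(tempfile()), class = "config_error")
})

test_that("guided runs produce a complete, reproducible artifact set", {
  seqn <- random_sequence(30, 5)
  cfg <- list(
    mode = "guided", seed = 1, n_models = 2,
    chains = list(list(chain_id = "M", sequence = seqn, copies = 2)),
    templates = list(list(
      source = list(fixture = list(kind = "toy_complex", length = 30,
                                   seed = 5, sequence = seqn)),
      assignments = list(
        list(chain = "A", start = 1, end = 30, source_chain = "A"),
        list(chain = "B", start = 1, end = 30, source_chain = "B")),
      relabel = list(mode = "polyalanine"), name = "dimer")),
    declared_interfaces = list(list("A", "B")))

  out1 <- run_prediction(cfg, outdir = withr::local_tempdir())
  expect_length(out1$models, 2)
  expect_identical(sort(unique(out1$models[[1]]$chain)), c("A", "B"))
  expect_identical(out1$rank$table$interfaces_present[1], 1L)
  expect_true(file.exists(file.path(out1$outdir,
                                    "resolved_config.json")))
  expect_true(file.exists(file.path(out1$outdir, "report",
                                    "report.json")))
  expect_true(file.exists(file.path(out1$outdir, "features.json")))

  out2 <- run_prediction(cfg, outdir = withr::local_tempdir())
  expect_identical(out1$models, out2$models)
  expect_identical(out1$rank$table, out2$rank$table)
})

test_that("naive mode branches per template cluster with a joint analysis", {
  ens <- two_state_fixture()
  seqn <- decode_sequence(ens$members[[1]]$aatype)
  dir <- withr::local_tempdir()
  paths <- vapply(seq_along(ens$members), function(i) {
    p <- file.path(dir, sprintf("t%02d.pdb", i))
    write_pdb(ens$members[[i]], p)
    p
  }, character(1))
  cfg <- list(mode = "naive", seed = 1,
              chains = list(list(chain_id = "A", sequence = seqn)),
              templates = lapply(paths, function(p)
                list(source = list(file = p))),
              naive = list(k = 2))
  out <- run_prediction(cfg, outdir = withr::local_tempdir())
  expect_length(out$models, 2)
  expect_s3_class(out$state, "state_analysis")
  expect_identical(length(unique(out$state$embedding$cluster)), 2L)
})

test_that("mutation and mosaic modes run end to end", {
  seqn <- random_sequence(40, 7)
  cfg <- list(mode = "mutation", seed = 2,
              chains = list(list(chain_id = "A", sequence = seqn)),
              variants = list(sprintf("A:%s5P", substr(seqn, 5, 5))))
  out <- run_prediction(cfg, outdir = withr::local_tempdir())
  expect_identical(decode_sequence(out$models[[1]]$aatype), seqn)

  seq85 <- random_sequence(85, 8)
  cfg2 <- list(
    mode = "mosaic", seed = 3,
    chains = list(list(chain_id = "A", sequence = seq85)),
    templates = list(list(source = list(
      fixture = list(kind = "two_block_hinge", hinge_angle = 20,
                     seed = 2, sequence = seq85)))),
    mosaic = list(max_len = 45, overlap = 30,
                  seed_policy = "best_of_previous"))
  out2 <- run_prediction(cfg2, outdir = withr::local_tempdir())
  expect_identical(model_length(out2$models[[1]]), 85L)
  ref <- make_structure("two_block_hinge", hinge_angle = 20, seed = 2,
                        sequence = seq85)
  expect_lt(superpose(out2$models[[1]], ref)$rmsd, 1)
})

test_that("unknown backends degrade to mock with a warning", {
  cfg <- list(mode = "guided", backend = "alphafold2",
              chains = list(list(chain_id = "A",
                                 sequence = random_sequence(20, 9))))
  expect_warning(run_prediction(cfg, outdir = withr::local_tempdir()),
                 "mock")
})

test_that("packaged recipes parse and run", {
  recipes <- list.files(system.file("extdata", "recipes",
                                    package = "foldsteer"),
                        full.names = TRUE, pattern = "\\.json$")
  expect_gte(length(recipes), 2)
  for (r in recipes) {
    cfg <- read_run_config(r)
    expect_s3_class(cfg, "run_config")
  }
})
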