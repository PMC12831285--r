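#' Run modes, predictor backends and configuration
#'
#' A predictor backend is a function \code{f(fs, n_models, seed)}
#' returning \code{n_models} [structure_model()]s of the query length
#' with per-residue confidence, never mutating \code{fs}.  The package
#' ships a deterministic mock backend for desk-scale work; a real
#' AlphaFold2-style predictor is attached as an external-process
#' adapter via [register_backend()] when available, and its absence
#' degrades to the mock with a loud warning.
#'
#' Four run modes steer a prediction: \code{guided} builds the feature
#' channels from the configuration and predicts; \code{naive} clusters
#' the supplied template stack into structural states (default two)
#' and runs one guided branch per cluster; \code{mutation} applies the
#' query variants, predicts, reverts them through the prediction-as-
#' template cycle and predicts again; \code{mosaic} splits a large
#' target into overlapping segments, predicts each and merges them.
#'
#' @name runtime
NULL

backend_registry <- new.env(parent = emptyenv())

#' Register a predictor backend
#'
#' @param name backend name used in run configurations.
#' @param fn function \code{(fs, n_models, seed)} returning a list of
#'   [structure_model()]s.
#' @return invisibly, the previous registration (or NULL).
#' @export
register_backend <- function(name, fn) {
  old <- backend_registry[[name]]
  backend_registry[[name]] <- fn
  invisible(old)
}

get_backend <- function(name) {
  fn <- backend_registry[[name]]
  if (is.null(fn)) {
    if (name != "mock")
      warning("backend '", name,
              "' is not available; degrading to the mock backend",
              call. = FALSE)
    fn <- mock_predict
  }
  fn
}

# confidence assigned by the mock backend
MOCK_PLDDT_COVERED <- 90
MOCK_PLDDT_UNCOVERED <- 50
MOCK_SIGMA <- 0.2

#' Deterministic mock predictor backend
#'
#' Positions covered by the highest-\code{sum_prob} template copy that
#' template's coordinates plus seeded Gaussian noise (sigma 0.2
#' Angstrom) and receive confidence 90; uncovered positions are built
#' as an extended chain placed clear of the covered part and receive
#' confidence 50.  Identical \code{(fs, n_models, seed)} give
#' bit-identical output.
#'
#' @param fs a valid [feature_set()].
#' @param n_models number of models to produce.
#' @param seed integer seed.
#' @param sigma noise level (Angstrom); 0 reproduces the template
#'   exactly.
#' @return list of [structure_model()]s of the query length.
#' @export
mock_predict <- function(fs, n_models = 1L, seed = 1L,
                         sigma = MOCK_SIGMA) {
  viol <- validate_features(fs)
  if (nrow(viol) > 0L)
    stop("mock backend refuses an invalid feature_set: ",
         viol$rule[1], call. = FALSE)
  L <- length(fs$query$aatype)
  best <- NULL
  if (length(fs$templates) > 0L) {
    sp <- vapply(fs$templates, function(t) t$sum_prob, numeric(1))
    best <- fs$templates[[which.max(sp)]]
  }
  covered <- integer(0)
  if (!is.null(best)) {
    covered <- template_coverage(best)
    covered <- covered[best$atom_mask[covered, SLOT_CA] == 1L]
  }
  uncovered <- setdiff(seq_len(L), covered)
  base <- empty_coords(L)
  plddt <- rep(MOCK_PLDDT_UNCOVERED, L)
  if (length(covered) > 0L) {
    base$coords[covered, , ] <- best$atom_positions[covered, , ,
                                                    drop = FALSE]
    base$mask[covered, ] <- best$atom_mask[covered, , drop = FALSE]
    plddt[covered] <- MOCK_PLDDT_COVERED
  }
  if (length(uncovered) > 0L) {
    ext <- build_backbone(rep(TORSIONS$extended[1], length(uncovered)),
                          rep(TORSIONS$extended[2], length(uncovered)),
                          glycine = fs$query$aatype[uncovered] == GLY)
    offset <- if (length(covered) > 0L)
      c(max(base$coords[covered, SLOT_CA, 1]) + 10, 0, 0)
    else c(0, 0, 0)
    slots <- c(N = SLOT_N, CA = SLOT_CA, C = SLOT_C, O = SLOT_O,
               CB = SLOT_CB)
    parts <- list(N = ext$N, CA = ext$CA, C = ext$C, O = ext$O,
                  CB = ext$CB)
    for (nm in names(slots)) {
      p <- parts[[nm]]
      ok <- which(!is.na(p[, 1]))
      rows <- uncovered[ok]
      base$coords[rows, slots[[nm]], ] <-
        sweep(p[ok, , drop = FALSE], 2, offset, "+")
      base$mask[rows, slots[[nm]]] <- 1L
    }
  }
  models <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    set.seed((as.integer(seed) + 7919L * (k - 1L)) %%
               .Machine$integer.max)
    coords <- base$coords
    if (sigma > 0 && length(covered) > 0L) {
      on <- which(base$mask[covered, , drop = FALSE] == 1L,
                  arr.ind = TRUE)
      for (d in 1:3)
        coords[cbind(covered[on[, 1]], on[, 2], d)] <-
          coords[cbind(covered[on[, 1]], on[, 2], d)] +
          stats::rnorm(nrow(on), 0, sigma)
    }
    models[[k]] <- structure_model(rep("A", L), seq_len(L),
                                   fs$query$aatype, coords, base$mask,
                                   plddt,
                                   name = sprintf("model_%d", k))
  }
  models
}

config_error <- function(msg) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read and validate a run configuration (JSON)
#'
#' @param path JSON file; see the packaged recipes under
#'   \code{inst/extdata/recipes} for the schema.
#' @return a validated config list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(paste("no such config:", path))
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_run_config(cfg)
}

#' Validate a run configuration list
#' @param cfg a config list (e.g. from JSON).
#' @return the config with defaults filled, classed \code{run_config}.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("guided", "naive", "mutation", "mosaic"))
    config_error("config: mode must be one of guided/naive/mutation/mosaic")
  if (is.null(cfg$chains) || length(cfg$chains) == 0L)
    config_error("config: at least one chain is required")
  for (ch in cfg$chains)
    if (is.null(ch$chain_id) || is.null(ch$sequence))
      config_error("config: every chain needs chain_id and sequence")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_models <- as.integer(cfg$n_models %||% 1L)
  cfg$backend <- cfg$backend %||% "mock"
  cfg$linker_mode <- cfg$linker_mode %||% "index_gap"
  cfg$index_gap <- as.integer(cfg$index_gap %||% 200L)
  cfg$physical_linker <- cfg$physical_linker %||% "GGGGS"
  if (cfg$mode == "mosaic" && is.null(cfg$mosaic))
    config_error("config: mosaic mode needs a mosaic section")
  if (cfg$mode == "mutation" &&
      length(cfg$variants %||% list()) == 0L)
    config_error("config: mutation mode needs variants")
  class(cfg) <- c("run_config", "list")
  cfg
}

cfg_region <- function(r) {
  if (is.null(r)) return(NULL)
  region_selection(r$chain %||% "*", r$start, r$end)
}

# Materialize a structure source: a file path or an inline fixture spec.
cfg_structure <- function(src, base_dir = ".") {
  if (!is.null(src$file)) {
    p <- src$file
    if (!file.exists(p)) p <- file.path(base_dir, src$file)
    if (!file.exists(p))
      stop("structure source not found: ", src$file, call. = FALSE)
    return(read_structure(p))
  }
  if (!is.null(src$fixture)) {
    fx <- src$fixture
    return(do.call(make_structure, fx))
  }
  stop("template source needs 'file' or 'fixture'", call. = FALSE)
}

cfg_build_plan <- function(cfg) {
  chains <- lapply(cfg$chains, function(ch)
    chain_spec(ch$chain_id, ch$sequence,
               copies = as.integer(ch$copies %||% 1L),
               first_resno = as.integer(ch$first_resno %||% 1L)))
  assembly_plan(chains, linker_mode = cfg$linker_mode,
                index_gap = cfg$index_gap,
                physical_linker = cfg$physical_linker)
}

cfg_build_template <- function(tc, query, plan, base_dir) {
  if (!is.null(tc$assignments)) {
    assignments <- lapply(tc$assignments, function(a) {
      src <- cfg_structure(tc$source, base_dir)
      if (!is.null(a$source_chain))
        src <- subset_model(src, which(src$chain %in% a$source_chain))
      list(structure = src, region = cfg_region(a),
           mapping = a$mapping %||% "auto")
    })
    t <- multi_chain_template(assignments, query, plan,
                              name = tc$name %||% "composite",
                              sum_prob = tc$sum_prob %||% 1.0)
  } else {
    src <- cfg_structure(tc$source, base_dir)
    if (!is.null(tc$source_chain))
      src <- subset_model(src, which(src$chain %in% tc$source_chain))
    mapping <- tc$mapping %||% "auto"
    if (is.list(mapping))
      mapping <- align_map(unlist(mapping$query_pos),
                           unlist(mapping$template_pos))
    t <- structure_to_template(src, query, mapping = mapping,
                               placement = cfg_region(tc$placement),
                               plan = plan,
                               min_identity = tc$min_identity %||% 0.2,
                               sum_prob = tc$sum_prob %||% 1.0,
                               name = tc$name %||% NULL)
  }
  if (!is.null(tc$relabel))
    t <- relabel_template(t, tc$relabel$mode %||% "keep", query = query,
                          replacement = tc$relabel$replacement,
                          region = cfg_region(tc$relabel$region),
                          region_mode = tc$relabel$region_mode %||%
                            "query",
                          plan = plan)
  if (isTRUE(tc$truncate_cbeta)) t <- truncate_to_cbeta(t)
  t
}

cfg_build_msa <- function(mc, query, plan, base_dir) {
  msa <- if (!is.null(mc$source$file)) {
    p <- mc$source$file
    if (!file.exists(p)) p <- file.path(base_dir, mc$source$file)
    read_alignment(p, format = mc$source$format %||% "a3m",
                   query = mc$query_override %||%
                     decode_sequence(query$aatype))
  } else if (!is.null(mc$source$toy)) {
    toy <- mc$source$toy
    make_toy_msa(decode_sequence(query$aatype),
                 n_rows = as.integer(toy$n_rows %||% 20L),
                 conservation = toy$conservation %||% 0.8,
                 seed = as.integer(toy$seed %||% 1L))
  } else stop("msa source needs 'file' or 'toy'", call. = FALSE)
  if (!is.null(mc$depth))
    msa <- reduce_depth(msa, as.integer(mc$depth$n),
                        strategy = mc$depth$strategy %||% "top",
                        seed = as.integer(mc$depth$seed %||% 1L))
  for (mk in mc$mask %||% list())
    msa <- mask_region(msa, cfg_region(mk), plan)
  msa
}

# Build the full feature set a configuration describes.
build_features_from_config <- function(cfg, base_dir = ".") {
  plan <- cfg_build_plan(cfg)
  fs <- concatenate_chains(plan)
  q <- fs$query
  msa_entries <- cfg$msa %||% list()
  if (length(msa_entries) == 1L && is.null(msa_entries[[1]]$region)) {
    fs <- fs_set_msa(fs, cfg_build_msa(msa_entries[[1]], q, plan,
                                       base_dir))
  } else if (length(msa_entries) > 0L) {
    blocks <- lapply(msa_entries, function(mc)
      list(msa = cfg_build_msa(mc, q, plan, base_dir),
           region = cfg_region(mc$region)))
    fs <- fs_set_msa(fs, merge_msas(blocks, q, plan), note = "merge_msas")
  }
  if (length(cfg$fragments %||% list()) > 0L) {
    frags <- lapply(cfg$fragments, function(f)
      list(sequence = f$sequence, region = cfg_region(f$region)))
    fs <- fs_set_msa(fs, add_fragment_library(fs$msa, frags, plan),
                     note = "add_fragment_library")
  }
  for (tc in cfg$templates %||% list())
    fs <- fs_add_template(fs, cfg_build_template(tc, q, plan, base_dir))
  fs
}

run_log <- function(state, ...) {
  state$lines <- c(state$lines, sprintf(...))
  state
}

#' Execute a run configuration
#'
#' Builds the feature set, dispatches the configured mode over the
#' configured backend, evaluates and ranks the resulting models, and
#' writes all artifacts (models as PDB, ranking report, state analysis
#' when computed, the resolved configuration and a log) to the output
#' directory.  Runs are bit-reproducible from the resolved config and
#' seed with the mock backend.
#'
#' @param cfg a [read_run_config()]/[validate_run_config()] result (a
#'   plain list is validated first).
#' @param outdir output directory; overrides \code{cfg$outdir}.
#' @param base_dir directory against which relative source paths are
#'   resolved.
#' @return (invisibly) list with \code{models} (disengaged
#'   [structure_model()]s), \code{rank} (a [rank_models()] report),
#'   \code{state} (a [state_analysis()] or NULL), \code{fs} (the final
#'   [feature_set()]) and \code{outdir}.
#' @export
run_prediction <- function(cfg, outdir = NULL, base_dir = ".") {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  outdir <- outdir %||% cfg$outdir %||%
    stop("an output directory is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  backend <- get_backend(cfg$backend)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("mode=%s backend=%s seed=%d n_models=%d", cfg$mode, cfg$backend,
      cfg$seed, cfg$n_models)

  fs <- build_features_from_config(cfg, base_dir)
  plan <- fs$assembly
  for (p in fs$provenance)
    say("provenance: %s", p$op)
  state <- NULL
  branch_models <- list()   # concatenated-frame models per branch

  if (cfg$mode == "guided") {
    branch_models$guided <- backend(fs, cfg$n_models, cfg$seed)
  } else if (cfg$mode == "mutation") {
    v <- variant_spec(unlist(cfg$variants))
    fs_mut <- apply_variants(fs, v)
    first <- backend(fs_mut, cfg$n_models, cfg$seed)
    best1 <- first[[which.max(vapply(first, function(m)
      mean(m$plddt %||% 100), numeric(1)))]]
    say("mutation step 1 best model: %s", best1$name)
    fs <- revert_cycle(fs_mut, best1, fs$query$sequence)
    branch_models$reverted <- backend(fs, cfg$n_models, cfg$seed + 1L)
  } else if (cfg$mode == "naive") {
    if (length(fs$templates) < 2L)
      config_error("naive mode needs at least 2 templates to cluster")
    k <- cfg$naive$k %||% 2L
    cl <- cluster_templates(fs$templates, k = k, seed = cfg$seed)
    state <- cl$analysis
    say("naive mode: %d template group(s)", length(cl$groups))
    for (g in seq_along(cl$groups)) {
      fs_g <- fs
      fs_g$templates <- cl$groups[[g]]
      fs_g <- record_edit(fs_g, "naive_branch", group = g,
                          n_templates = length(cl$groups[[g]]))
      branch_models[[sprintf("state%d", g)]] <-
        backend(fs_g, cfg$n_models, cfg$seed + g)
    }
  } else if (cfg$mode == "mosaic") {
    mp <- mosaic_split(plan, max_len = as.integer(cfg$mosaic$max_len),
                       overlap = as.integer(cfg$mosaic$overlap %||% 30L),
                       seed_policy = cfg$mosaic$seed_policy %||%
                         "independent")
    say("mosaic: %d segment(s)", length(mp$segments))
    seg_models <- vector("list", length(mp$segments))
    seeds <- vector("list", length(mp$segments))
    for (s in seq_along(mp$segments)) {
      sub <- fs_slice(fs, mp$segments[[s]])
      if (!is.null(seeds[[s]])) sub <- fs_add_template(sub, seeds[[s]])
      preds <- backend(sub, cfg$n_models, cfg$seed + s)
      best <- preds[[which.max(vapply(preds, function(m)
        mean(m$plddt %||% 100), numeric(1)))]]
      best$resno <- sort(mp$segments[[s]]) + 1L
      seg_models[[s]] <- best
      if (mp$seed_policy == "best_of_previous" &&
          s < length(mp$segments)) {
        st <- seed_next(mp, best_model = seg_models[[s]],
                        segments = s + 1L)
        if (!is.null(st[[s + 1L]])) seeds[[s + 1L]] <- st[[s + 1L]]
      }
    }
    merged <- mosaic_merge(seg_models, mp,
                           threshold = cfg$mosaic$threshold %||% 5)
    say("mosaic anchors RMSD: %s",
        paste(sprintf("%.3f", attr(merged, "anchor_rmsd")),
              collapse = ", "))
    merged$name <- "model_1"
    branch_models$mosaic <- list(merged)
  }

  # disengage every model into chains and evaluate
  models <- list()
  for (br in names(branch_models)) {
    for (m in branch_models[[br]]) {
      dm <- if (!is.null(plan) && model_length(m) ==
                assembly_concat_length(plan)) disengage(m, plan) else m
      dm$name <- if (length(branch_models) > 1L)
        paste(br, m$name, sep = "_") else m$name
      models[[dm$name]] <- dm
    }
  }
  if (cfg$mode == "naive" && length(models) >= 2L) {
    # joint state analysis over all branch predictions
    frame <- build_frame(unname(models))
    cc <- cc_matrix(frame)
    emb <- embed_cc(cc, seed = cfg$seed,
                    k = cfg$naive$k %||% 2L)
    state <- state_analysis(frame, cc, emb, hinges = find_hinges(frame))
  }
  references <- lapply(cfg$references %||% list(), function(p)
    read_structure(if (file.exists(p)) p else file.path(base_dir, p)))
  declared <- lapply(cfg$declared_interfaces %||% list(),
                     function(p) unlist(p))
  rank <- rank_models(unname(models), fs = fs,
                      references = references,
                      declared_interfaces = if (length(declared))
                        declared else NULL)

  model_paths <- character(0)
  for (nm in names(models)) {
    p <- file.path(outdir, paste0(nm, ".pdb"))
    write_pdb(models[[nm]], p)
    model_paths[nm] <- p
  }
  write_features(fs, file.path(outdir, "features.json"))
  jsonlite::write_json(unclass(cfg),
                       file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report(rank, state = state, outdir = file.path(outdir,
                                                       "report"),
               fs = fs, model_paths = model_paths)
  writeLines(log, file.path(outdir, "run.log"))
  invisible(list(models = models, rank = rank, state = state, fs = fs,
                 outdir = outdir))
}
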