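# ---- configuration presets and the end-to-end pipeline ---------------------

#' Full pipeline configuration with physiological presets
#'
#' Bundles the parameter blocks of every stage.  The `"pulmonary"` and
#' `"aorta"` presets carry the standard parameter sets for a rapidly
#' branching pulmonary arterial network and an aortic network: cardiac
#' period, blood density and viscosity, large- and small-vessel stiffness
#' constants, structured-tree scaling (alpha, beta), length-to-radius
#' ratio, termination radius, junction-smoothing weight.
#'
#' @param preset "pulmonary" or "aorta".
#' @param ... named overrides of individual fields (e.g. `grid = 16`),
#'   applied after the preset.
#' @return list of class `pipeline_config` with blocks `hemo`
#'   ([hemo_params()]), `structured` ([structured_tree_params()]),
#'   `junction` ([junction_adjust_params()]), `selection`
#'   ([selection_params()]), and scalars `taper`, `prune_target`,
#'   `n_samples`, `seed`.
#' @export
pipeline_config <- function(preset = c("pulmonary", "aorta"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    pulmonary = list(
      hemo = hemo_params(T = 0.85, rho = 1.055, mu_L = 0.032,
                         k1L = 2.5e6, k2L = -15, k3L = 6.4e4),
      structured = structured_tree_params(alpha = 0.88, beta = 0.697,
                                          lrr = 15.75, r_min = 0.001,
                                          k1S = 2.5e7, k2S = -15, k3S = 8e5),
      junction = junction_adjust_params(w = 2),
      selection = selection_params(),
      taper = FALSE),
    aorta = list(
      hemo = hemo_params(T = 0.8, rho = 1.055, mu_L = 0.032,
                         k1L = 5e6, k2L = -25, k3L = 6e5),
      structured = structured_tree_params(alpha = 0.90, beta = 0.60,
                                          lrr = 50, r_min = 0.001,
                                          k1S = 5e6, k2S = -20, k3S = 1e5),
      junction = junction_adjust_params(w = 100),
      selection = selection_params(),
      taper = TRUE))
  cfg <- c(base, list(preset = preset, prune_target = NA_integer_,
                      n_samples = 0L, seed = 1L))
  dots <- list(...)
  for (nm in names(dots)) {
    hit <- FALSE
    for (blk in c("hemo", "structured", "junction", "selection")) {
      if (nm %in% names(cfg[[blk]])) { cfg[[blk]][[nm]] <- dots[[nm]]; hit <- TRUE }
    }
    if (!hit) cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may name a `preset` and override any field.
#'
#' @param path YAML or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  preset <- cfg$preset %||% "pulmonary"
  cfg$preset <- NULL
  do.call(pipeline_config, c(list(preset = preset), cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full post-processing and simulation pipeline
#'
#' Stages, in order: build the labeled tree from centerlines, optional
#' pruning to a standard size, junction adjustment, change-point radius
#' extraction, network consistency check, hemodynamic simulation with
#' structured-tree outflow, and (optionally) radius-uncertainty sampling
#' with ensemble simulation.  Every stage writes its report under
#' `out_dir` and a manifest records the configuration, seed and stage
#' log.
#'
#' @param centerlines named list of x/y/z/r data.frames (e.g. from
#'   [read_centerlines()] or [make_synthetic_network()]).
#' @param inflow a `flow_waveform` or (t, q) data.frame.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param simulate run the hemodynamic stages (default TRUE).
#' @return list with `tree` (final), `solution`, `reports`, and
#'   `ensemble` (when sampling was requested), invisibly; artifacts on
#'   disk under `out_dir`.
#' @export
run_pipeline <- function(centerlines, inflow, config = pipeline_config(),
                         out_dir = tempfile("vasctrees_run_"),
                         simulate = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    log[[name]] <<- "ok"
    res
  }
  tree <- stage("build", build_labeled_tree(centerlines))
  write_tree_csv(tree, file.path(out_dir, "tree_raw.csv"))
  if (!is.na(config$prune_target)) {
    if (config$prune_target > length(tree$vessels)) {
      warning("prune target exceeds network size; continuing unpruned")
      log[["prune"]] <- "skipped: target exceeds size"
    } else {
      tree <- stage("prune", prune_to_size(tree, config$prune_target))
    }
  }
  adj <- stage("adjust-junctions", adjust_all_junctions(tree, config$junction))
  tree <- adj$tree
  if (!is.null(adj$report))
    utils::write.csv(adj$report, file.path(out_dir, "junctions.csv"),
                     row.names = FALSE)
  tree <- stage("extract-radii",
                extract_tree_radii(tree, taper = config$taper,
                                   params = config$selection))
  cons <- stage("consistency",
                consistency_check(tree, config$structured$alpha,
                                  config$structured$beta))
  tree <- cons$tree
  utils::write.csv(radius_report(tree), file.path(out_dir, "radii.csv"),
                   row.names = FALSE)
  utils::write.csv(cons$report, file.path(out_dir, "consistency.csv"),
                   row.names = FALSE)
  write_tree_json(tree, file.path(out_dir, "tree.json"))

  sol <- NULL; ens <- NULL
  if (simulate) {
    sol <- stage("simulate",
                 solve_large_vessels(tree, inflow, config$hemo,
                                     outflow = "structured",
                                     st_params = config$structured))
    utils::write.csv(ensemble_summaries(list(sol))$per_solution,
                     file.path(out_dir, "hemo_summary.csv"), row.names = FALSE)
    if (config$n_samples > 0L) {
      smp <- stage("uq-sample",
                   sample_radii(tree, config$n_samples, config$seed))
      sols <- lapply(seq_len(config$n_samples), function(i)
        solve_large_vessels(tree, inflow, config$hemo,
                            outflow = "structured",
                            st_params = config$structured,
                            radii = sampled_radii(tree, smp, i)))
      ens <- ensemble_summaries(sols)
      utils::write.csv(ens$envelope, file.path(out_dir, "uq_envelope.csv"),
                       row.names = FALSE)
    }
  }
  manifest <- list(package_version = as.character(utils::packageVersion("vasctrees")),
                   preset = config$preset, seed = config$seed,
                   n_vessels = length(tree$vessels), stages = log,
                   config_hash = digest_config(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, solution = sol, ensemble = ens,
                 reports = list(junctions = adj$report,
                                consistency = cons$report,
                                radii = radius_report(tree)),
                 out_dir = out_dir))
}

# stable hash of a configuration (no external digest dependency)
digest_config <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12, force = TRUE)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}
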