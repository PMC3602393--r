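# Experiment orchestration: config loading, validation, execution and
# result persistence. One YAML config describes one named experiment;
# every output carries the master seed and the config in a JSON sidecar,
# and re-running the same config reproduces the CSVs byte for byte.

.hg_experiments <- c("baseline", "lesion_sweep", "gaba_decomposition",
                     "drug_trial", "control_scan", "cohort", "smoke")

#' Load and validate an experiment configuration
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config list (class `hg_config`).
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  problems <- validate_config(cfg)
  abort_if(length(problems) > 0, "invalid config:\n%s",
           paste("  -", problems, collapse = "\n"))
  cfg$master_seed <- as.integer(cfg$master_seed %||% 1L)
  structure(cfg, class = c("hg_config", "list"))
}

# returns a character vector of violations (empty when valid)
validate_config <- function(cfg) {
  problems <- character(0)
  note <- function(fmt, ...) c(problems, sprintf(fmt, ...))
  if (is.null(cfg$experiment) || !cfg$experiment %in% .hg_experiments) {
    problems <- note("experiment must be one of: %s",
                     paste(.hg_experiments, collapse = ", "))
  }
  params <- tryCatch(default_params(cfg$params), error = function(e) {
    problems <<- note("params: %s", conditionMessage(e)); NULL
  })
  if (!is.null(cfg$lesion) && !is.null(params)) {
    g <- params$lesion_grid
    if (!is.null(cfg$lesion$nmda_reduction) &&
        !on_grid(cfg$lesion$nmda_reduction, as.numeric(g$nmda))) {
      problems <- note("lesion axis 'nmda': level %g is not on the grid (%s)",
                       cfg$lesion$nmda_reduction,
                       paste(g$nmda, collapse = ", "))
    }
    if (!is.null(cfg$lesion$spine_reduction) &&
        !on_grid(cfg$lesion$spine_reduction, as.numeric(g$spine))) {
      problems <- note("lesion axis 'spine': level %g is not on the grid (%s)",
                       cfg$lesion$spine_reduction,
                       paste(g$spine, collapse = ", "))
    }
    if (!is.null(cfg$lesion$gaba_pair) &&
        (cfg$lesion$gaba_pair < 0 ||
         cfg$lesion$gaba_pair >= length(g$gaba_pairs$tone))) {
      problems <- note("lesion axis 'gaba_pair': index %d outside 0..%d",
                       cfg$lesion$gaba_pair,
                       length(g$gaba_pairs$tone) - 1L)
    }
  }
  if (!is.null(cfg$control_drug) &&
      !cfg$control_drug %in% c("phenytoin", "nifedipine", "ampakine")) {
    problems <- note("unknown control drug '%s'", cfg$control_drug)
  }
  if (!is.null(cfg$master_seed) && !is.numeric(cfg$master_seed)) {
    problems <- note("master_seed must be an integer")
  }
  problems
}

#' Run a configured experiment end to end
#'
#' Builds the network(s), executes the named experiment and writes CSV
#' results plus a JSON provenance sidecar to the output directory.
#'
#' @param config a YAML path, a config list, or an `hg_config`.
#' @param out_dir output directory (default from the config, else
#'   `tempdir()`).
#' @return invisibly, a list with the in-memory results and the written
#'   file paths.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "hg_config")) config else load_config(config)
  out_dir <- out_dir %||% cfg$output_dir %||% tempdir()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- default_params(cfg$params)
  seed <- cfg$master_seed
  pop <- do.call(population_spec, as.list(params$populations))
  drive_args <- cfg$drive %||% list()

  net <- build_network(pop, params = params,
                       morphology = cfg$network$morphology,
                       seed = cfg$network$seed %||% seed)
  baseline <- compute_baseline(net, master_seed = seed,
                               drive_args = drive_args)
  results <- list(baseline = baseline)
  paths <- character(0)
  save_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  exp <- cfg$experiment
  if (exp %in% c("baseline", "smoke")) {
    pw <- run_drive_trials(net, c(20, 30, 40), seed, 0, drive_args)
    tab <- do.call(rbind, lapply(names(pw), function(f) {
      data.frame(drive = as.numeric(f), p20 = pw[[f]][["20"]],
                 p30 = pw[[f]][["30"]], p40 = pw[[f]][["40"]])
    }))
    save_csv(tab, "baseline_band_powers")
    results$band_powers <- tab
    if (exp == "smoke" && !is.null(cfg$lesion)) {
      les <- lesion_spec(cfg$lesion$nmda_reduction %||% 0,
                         cfg$lesion$spine_reduction %||% 0,
                         cfg$lesion$gaba_pair %||% 0L, params = params)
      sw <- run_sweep(net, data.frame(nmda = les$nmda_reduction,
                                      spine = les$spine_reduction,
                                      gaba_pair = les$gaba_pair),
                      baseline, "illness", master_seed = seed,
                      drive_args = drive_args)
      save_csv(as.data.frame(sw), "smoke_lesion_point")
      results$lesion_point <- sw
    }
  } else if (exp == "lesion_sweep") {
    grid <- do.call(lesion_grid, c(cfg$grid %||% list(),
                                   list(params = params)))
    sw <- run_sweep(net, grid, baseline, "illness", master_seed = seed,
                    drive_args = drive_args)
    save_csv(as.data.frame(sw), "lesion_sweep")
    cl <- find_clusters(sw, threshold = cfg$cluster_threshold %||% 0.65)
    results$sweep <- sw
    results$clusters <- cl
  } else if (exp == "gaba_decomposition") {
    grid <- do.call(gaba_decomposition_grid,
                    c(cfg$grid %||% list(), list(params = params)))
    sw <- run_sweep(net, grid, baseline, "illness", master_seed = seed,
                    drive_args = drive_args)
    save_csv(as.data.frame(sw), "gaba_decomposition")
    results$sweep <- sw
  } else if (exp %in% c("drug_trial", "control_scan")) {
    les <- cfg$lesion %||% list(nmda_reduction = 0.30,
                                spine_reduction = 0.30, gaba_pair = 0L)
    schiz <- apply_lesion(net, lesion_spec(les$nmda_reduction,
                                           les$spine_reduction,
                                           les$gaba_pair %||% 0L,
                                           params = params),
                          seed = seed_hash(seed, 99))
    if (exp == "drug_trial") {
      grid <- do.call(drug_grid, c(cfg$grid %||% list(),
                                   list(params = params)))
      sw <- run_sweep(schiz, grid, baseline, "wellness",
                      master_seed = seed, drive_args = drive_args)
      save_csv(as.data.frame(sw), "drug_trial")
      results$sweep <- sw
      scored <- unique(as.data.frame(
        sw)[, c("ampa_gmax", "alpha2", "nmda", "ampa_tau2", "cr_weight",
                "score")])
      if (any(scored$score > 0, na.rm = TRUE)) {
        results$anova <- factorial_anova(scored)
        save_csv(results$anova, "drug_trial_anova")
      }
    } else {
      sc <- scan_control_drug(schiz, cfg$control_drug %||% "phenytoin",
                              master_seed = seed, drive_args = drive_args,
                              params = params)
      save_csv(sc, paste0("scan_", cfg$control_drug %||% "phenytoin"))
      results$scan <- sc
    }
  } else if (exp == "cohort") {
    n <- cfg$cohort$n %||% 20
    ctrl <- generate_cohort(n, "control", NULL, master_seed = seed,
                            params = params, pop = pop,
                            morphology = cfg$network$morphology,
                            drive_args = drive_args)
    les <- cfg$lesion %||% list(nmda_reduction = 0.30,
                                spine_reduction = 0.30, gaba_pair = 0L)
    sz <- generate_cohort(n, "schizophrenic",
                          lesion_spec(les$nmda_reduction,
                                      les$spine_reduction,
                                      les$gaba_pair %||% 0L,
                                      params = params),
                          master_seed = seed + 1L, params = params,
                          pop = pop, morphology = cfg$network$morphology,
                          drive_args = drive_args)
    records <- rbind(ctrl, sz)
    save_csv(records, "cohort_records")
    results$records <- records
    ok <- records[records$ok, ]
    if (length(unique(ok$group)) == 2 && all(table(ok$group) >= 2)) {
      results$anova <- mixed_anova(ok)
      save_csv(results$anova, "cohort_anova")
      results$regressions <- rbind(
        cbind(outcome = "p40",
              hierarchical_regression(
                transform(ok, grp = as.integer(group == "schizophrenic")),
                "p40", c("p20", "p30"), "grp")),
        cbind(outcome = "p30",
              hierarchical_regression(
                transform(ok, grp = as.integer(group == "schizophrenic")),
                "p30", "p40", "grp")),
        cbind(outcome = "p20",
              hierarchical_regression(
                transform(ok, grp = as.integer(group == "schizophrenic")),
                "p20", "p40", "grp")))
      save_csv(results$regressions, "cohort_regressions")
    }
  }

  sidecar <- list(experiment = exp, master_seed = seed,
                  package_version = as.character(utils::packageVersion("hippogamma")),
                  baseline = as.list(baseline), config = unclass(cfg))
  sp <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[[length(paths) + 1L]] <- sp
  invisible(list(results = results, paths = unlist(paths)))
}
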