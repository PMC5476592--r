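# End-to-end orchestration: dataset -> partition -> linear fit ->
# (optional) residual filter + refit -> rate seeding -> non-linear fit ->
# fingerprint -> exports, with a run manifest and resolved configuration
# written next to the outputs.

#' Assemble a pipeline configuration
#'
#' @param sequence Protein sequence string or FASTA path.
#' @param uptake Uptake table path, or an `hdx_dataset`.
#' @param out_dir Output directory.
#' @param labeling,quench [exchange_conditions()].
#' @param t_lag LC lag time (s); required for the back-exchange model.
#' @param filter_threshold Residual filter threshold in deuterons, or `NULL`
#'   to disable the filter stage.
#' @param n_term_excl Fragment N-terminal exclusions (default 0).
#' @param back_exchange `"model"` or `"reference"` (see [fit_amide_rates()]).
#' @param bounds_policy `"labeling"` (upper bound = intrinsic rate at
#'   labeling conditions, default) or `"quench"` (strict mode: quench-rate
#'   bounds).
#' @param lower_bound Lower rate bound (s^-1).
#' @param n_starts,perturb_sd Multi-start settings for the non-linear stage.
#' @param seed Seed for multi-start perturbations.
#' @param structure Optional PDB path for the structure colouring export.
#' @param temperature_dG Temperature for the free-energy conversion (K).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sequence, uptake, out_dir,
                            labeling = exchange_conditions(7.0, 298.15, "labeling"),
                            quench = exchange_conditions(2.5, 273.15, "quench"),
                            t_lag = 0, filter_threshold = 2,
                            n_term_excl = 0L,
                            back_exchange = "model",
                            bounds_policy = "labeling",
                            lower_bound = 1e-8,
                            n_starts = 1L, perturb_sd = 0.5, seed = 1L,
                            structure = NULL, temperature_dG = NULL) {
  cfg <- list(sequence = sequence, uptake = uptake, out_dir = out_dir,
              labeling = labeling, quench = quench, t_lag = t_lag,
              filter_threshold = filter_threshold,
              n_term_excl = as.integer(n_term_excl),
              back_exchange = back_exchange, bounds_policy = bounds_policy,
              lower_bound = lower_bound, n_starts = as.integer(n_starts),
              perturb_sd = perturb_sd, seed = as.integer(seed),
              structure = structure, temperature_dG = temperature_dG)
  class(cfg) <- "pipeline_config"
  cfg
}

.cfg_yaml <- function(config) {
  ser <- config
  ser$labeling <- unclass(ser$labeling)
  ser$quench <- unclass(ser$quench)
  if (inherits(ser$uptake, "hdx_dataset")) ser$uptake <- "<in-memory dataset>"
  ser$class <- NULL
  yaml::as.yaml(lapply(unclass(ser), function(z) if (is.null(z)) NA else z))
}

#' Run the full fingerprinting pipeline
#'
#' Stages: ingest -> subfragment partition -> constrained linear fit ->
#' optional residual filter and refit -> rate seeding -> bounded global
#' non-linear fit -> stability fingerprint -> delimited exports. Every run
#' writes its resolved configuration (with an md5 hash recorded in the
#' manifest) so reruns are byte-reproducible.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage objects (`dataset`, `partition`,
#'   `dlevels`, `filtered`, `seeds`, `profile`, `fingerprint`) plus `status`
#'   (`"ok"` or `"flagged"`) and the output `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon), add = TRUE)
  say <- function(fmt, ...) {
    writeLines(sprintf(fmt, ...), logcon)
  }
  say("hdxfp %s", as.character(packageVersion("hdxfp")))

  cfg_path <- file.path(config$out_dir, "config.yaml")
  writeLines(.cfg_yaml(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  stage <- "ingest"
  result <- tryCatch({
    dataset <- if (inherits(config$uptake, "hdx_dataset")) config$uptake
      else read_uptake_table(config$uptake, config$sequence,
                             conditions_labeling = config$labeling,
                             conditions_quench = config$quench,
                             t_lag = config$t_lag,
                             n_term_excl = config$n_term_excl)
    say("ingest: %d fragments, %d records", nrow(dataset$fragments),
        nrow(dataset$records))

    stage <- "subfragmentation"
    partition <- compute_partition(dataset$fragments, dataset$sequence,
                                   config$n_term_excl)
    say("subfragmentation: %d subfragments", nrow(partition$subfragments))

    stage <- "linear fit"
    dlevels <- fit_subfragment_d(dataset, partition)
    say("linear fit: GE_lin = %.6g D^2", dlevels$GE_lin)

    removed <- character()
    if (!is.null(config$filter_threshold)) {
      stage <- "residual filter"
      flt <- suppressMessages(
        filter_outliers_iteratively(dataset, config$filter_threshold,
                                    config$n_term_excl))
      removed <- attr(flt, "removed_keys")
      say("filter: removed %d fragments at threshold %g D in %d rounds (%s)",
          length(removed), config$filter_threshold, attr(flt, "rounds"),
          if (length(removed)) paste(removed, collapse = ",") else "none")
      if (length(removed)) {
        dataset <- flt
        partition <- compute_partition(dataset$fragments, dataset$sequence,
                                       config$n_term_excl)
        dlevels <- attr(flt, "final_dlevels")
        say("refit: %d subfragments, GE_lin = %.6g D^2",
            nrow(partition$subfragments), dlevels$GE_lin)
      }
    }

    stage <- "rate seeding"
    seeds <- seed_rates(dlevels)

    stage <- "non-linear fit"
    k_int <- compute_intrinsic_rates(dataset$sequence, config$labeling)
    k_bk <- compute_back_exchange_rates(dataset$sequence, config$quench)
    upper <- if (config$bounds_policy == "quench") k_bk else k_int
    set.seed(config$seed)
    profile <- fit_amide_rates(dataset, partition, seeds, k_bk,
                               t_lag = config$t_lag,
                               bounds = list(lower = config$lower_bound,
                                             upper = upper),
                               d_max_mode = config$back_exchange,
                               n_starts = config$n_starts,
                               perturb_sd = config$perturb_sd)
    say("non-linear fit: GE_nonlin = %.6g D^2 (seed GE %.6g), %d iterations, %s",
        profile$GE_nonlin, profile$GE_seed, profile$iterations,
        if (profile$converged) "converged" else "not converged")

    stage <- "fingerprint"
    fingerprint <- compute_fingerprint(profile, k_int,
                                       temperature = config$temperature_dG)

    stage <- "export"
    files <- c(config = cfg_path, log = logf,
               coverage = file.path(config$out_dir, "coverage.tsv"),
               partition = file.path(config$out_dir, "partition.tsv"),
               dlevels = file.path(config$out_dir, "subfragment_d.tsv"),
               residuals = file.path(config$out_dir, "fragment_errors.tsv"),
               rates = file.path(config$out_dir, "amide_rates.tsv"),
               fingerprint = file.path(config$out_dir, "fingerprint.tsv"))
    write.table(coverage_stats(dataset), files[["coverage"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_partition(partition, files[["partition"]])
    write_dlevels(dlevels, files[["dlevels"]])
    write.table(dlevels$fragment_error, files[["residuals"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_rate_profile(profile, files[["rates"]])
    export_profile(fingerprint, files[["fingerprint"]])
    if (!is.null(config$structure)) {
      files[["structure"]] <- file.path(config$out_dir, "fingerprint.pdb")
      files[["pymol"]] <- file.path(config$out_dir, "fingerprint.pml")
      export_structure_coloring(fingerprint, config$structure,
                                files[["structure"]], files[["pymol"]])
    }

    status <- if (profile$converged &&
                  !any(grepl("censored|at lower bound",
                             fingerprint$flag))) "ok" else "flagged"
    manifest <- list(tool = "hdxfp",
                     version = as.character(packageVersion("hdxfp")),
                     config_md5 = cfg_hash, status = status,
                     removed_fragments = as.list(removed),
                     GE_lin = dlevels$GE_lin,
                     GE_nonlin = profile$GE_nonlin,
                     iterations = profile$iterations,
                     files = as.list(files))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    say("status: %s", status)
    list(dataset = dataset, partition = partition, dlevels = dlevels,
         seeds = seeds, profile = profile, fingerprint = fingerprint,
         removed = removed, status = status, files = files)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)), logcon)
    writeLines("incomplete", file.path(config$out_dir, "INCOMPLETE"))
    .stop_pos("pipeline failed at stage '%s': %s", stage,
              conditionMessage(e))
  })
  invisible(result)
}

#' Simulate a scenario and write its dataset bundle
#'
#' Wraps the synthetic module: writes the uptake table, FASTA, ground-truth
#' rate profile and scenario manifest into a directory.
#'
#' @param scenario An [hdx_scenario()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `dataset` and output `files`.
#' @export
run_simulate <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "hdx_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- simulate_uptake(scenario)
  files <- c(manifest = write_scenario_bundle(scenario, out_dir),
             uptake = file.path(out_dir, "uptake.tsv"))
  write_uptake_table(dataset, files[["uptake"]])
  invisible(list(dataset = dataset, files = files))
}
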