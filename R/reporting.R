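#' @title Reporting and command-line entry points
#' @description
#' CSV writers for the cost-effectiveness table, acceptability curve and
#' tornado diagram data, a JSON run manifest capturing everything needed to
#' reproduce a run bit for bit, and the `lynchcea` command-line driver.
#' @name reporting
NULL

#' Write a cost-effectiveness table as CSV
#'
#' Columns mirror the published layout: strategy, incremental QALYs and
#' costs versus the comparator, ICER versus the comparator, frontier label
#' and fully incremental ICER, plus 3-significant-figure companions.
#'
#' @param table a `lynch_cea` from [frontier()] (an empty data.frame writes
#'   a header-only file)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cea_table <- function(table, path) {
  cols <- c("strategy", "cost", "qaly",
            "inc_qaly_vs_comparator", "inc_cost_vs_comparator",
            "icer_vs_comparator", "frontier_label",
            "fully_incremental_icer",
            "icer_vs_comparator_3sf", "fully_incremental_icer_3sf")
  if (nrow(table) == 0) {
    empty <- as.data.frame(stats::setNames(
      replicate(length(cols), numeric(0), simplify = FALSE), cols))
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write CEAC data as long-format CSV
#'
#' @param ceac_df output of [ceac()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ceac <- function(ceac_df, path) {
  utils::write.csv(ceac_df, path, row.names = FALSE)
  invisible(path)
}

#' Write tornado (one-way sensitivity) data as CSV
#'
#' Rows are sorted by descending INMB range and already respect the 1%-of-
#' maximum filter applied by [owsa()].
#'
#' @param entries output of [owsa()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tornado <- function(entries, path) {
  utils::write.csv(as.data.frame(entries), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' @param command character description of the run
#' @param params_path path of the parameter file used
#' @param scenario scenario name or "base_case"
#' @param seed integer seed
#' @param n_iter iteration count (PSA) or NA
#' @param path output file
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(command, params_path, scenario, seed, n_iter,
                           path) {
  manifest <- list(
    command = command,
    parameters_file = normalizePath(params_path, mustWork = FALSE),
    parameters_sha = unname(tools::md5sum(params_path)),
    scenario = scenario %||% "base_case",
    seed = seed,
    n_iterations = n_iter,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("lynchcea"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Command-line driver
#'
#' Implements the `lynchcea` subcommands (`run`, `tree`, `meta`, `synth`);
#' see `inst/cli/lynchcea` for the executable wrapper. `run` modes:
#' `base` (deterministic CEA table), `psa` (PSA + CEAC), `owsa` (tornado),
#' `ages` (age heterogeneity), `threshold` (age-threshold policy). Outputs
#' land under `--out` with fixed filenames plus a `manifest.json`.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
lynchcea_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat("usage: lynchcea <run|tree|meta|synth> [options]\n",
        "  run   --mode base|psa|owsa|ages|threshold --seed N",
        " --iterations N --out DIR [--params PATH] [--scenario NAME]\n",
        "  tree  --strategy NAME --status NAME [--params PATH]\n",
        "  meta  --studies CSV\n",
        "  synth --what accuracy|life_table|ec_ages --seed N --out FILE\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  switch(cmd,
    run = cli_run(opts),
    tree = cli_tree(opts),
    meta = cli_meta(opts),
    synth = cli_synth(opts),
    stop("unknown command: ", cmd))
  invisible(0L)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args)) {
      stop("malformed option: ", args[i])
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

cli_load <- function(opts) {
  load_parameters(
    config_path = opts$params %||% lynch_extdata("base_case.yaml"),
    scenario = opts$scenario)
}

cli_run <- function(opts) {
  mode <- opts$mode %||% "base"
  out_dir <- opts$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(opts$seed %||% 1L)
  n_iter <- as.integer(opts$iterations %||% 1000L)
  params <- cli_load(opts)
  params_path <- opts$params %||% lynch_extdata("base_case.yaml")

  if (mode == "base") {
    res <- evaluate_strategies(params, relative_ages = "weighted")
    write_cea_table(frontier(res), file.path(out_dir, "cea_table.csv"))
  } else if (mode == "psa") {
    psa <- run_psa(params, n_iter = n_iter, seed = seed)
    grid <- seq(0, 50000, by = 2500)
    write_ceac(ceac(psa$cost, psa$qaly, grid),
               file.path(out_dir, "ceac.csv"))
    utils::write.csv(
      data.frame(iteration = seq_len(psa$n_iter), psa$cost,
                 check.names = FALSE),
      file.path(out_dir, "psa_costs.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(iteration = seq_len(psa$n_iter), psa$qaly,
                 check.names = FALSE),
      file.path(out_dir, "psa_qalys.csv"), row.names = FALSE)
  } else if (mode == "owsa") {
    write_tornado(owsa(params), file.path(out_dir, "tornado.csv"))
  } else if (mode == "ages") {
    utils::write.csv(age_heterogeneity(params),
                     file.path(out_dir, "age_heterogeneity.csv"),
                     row.names = FALSE)
  } else if (mode == "threshold") {
    thr <- age_threshold_policy(params)
    utils::write.csv(thr$table, file.path(out_dir, "age_threshold.csv"),
                     row.names = FALSE)
  } else {
    stop("unknown mode: ", mode)
  }
  write_manifest(paste("run --mode", mode), params_path,
                 opts$scenario, seed, n_iter,
                 file.path(out_dir, "manifest.json"))
}

cli_tree <- function(opts) {
  params <- cli_load(opts)
  path <- proband_pathway(opts$strategy %||% "IHC_METH",
                          opts$status %||% "MSH2", params)
  cat(jsonlite::toJSON(list(
    strategy = path$strategy, status = path$status,
    p_diag = as.list(path$p_diag),
    expected_cost_gbp = path$expected_cost,
    counts = as.list(path$counts)), auto_unbox = TRUE, pretty = TRUE,
    digits = NA), "\n")
}

cli_meta <- function(opts) {
  if (is.null(opts$studies)) stop("meta requires --studies CSV")
  studies <- utils::read.csv(opts$studies)
  print(fit_bivariate(studies))
}

cli_synth <- function(opts) {
  what <- opts$what %||% "accuracy"
  spec <- synth_spec(seed = as.integer(opts$seed %||% 1L))
  tab <- switch(what,
    accuracy = gen_accuracy_studies(spec),
    life_table = gen_life_table(spec),
    ec_ages = gen_ec_age_distribution(spec),
    stop("unknown synth target: ", what))
  out <- opts$out %||% stdout()
  utils::write.csv(tab, out, row.names = FALSE)
}
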