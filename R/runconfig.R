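#' Run configuration for the analysis driver
#'
#' Collects the default analysis settings — the standard timeframes 20-100
#' years, DF grid 0.1-1 in steps of 0.1, 10-year transition period — along
#' with input locations and the top-level seed that every random component is
#' derived from.
#'
#' @param timeframes Timeframes in years.
#' @param dfs Displacement factors.
#' @param params A [model_params()].
#' @param catalog_path Catalog directory (`NULL`: the bundled catalog).
#' @param profile_path Profile file (`NULL`: the bundled profile).
#' @param seed Top-level integer seed.
#' @param n_runs Monte Carlo run count.
#' @param scenario_name `"HIGH"` or `"LOW"` for scenario runs.
#' @param out_dir Output directory for [run_analysis()].
#' @return A `cb_run_config` list.
#' @export
default_run_config <- function(timeframes = c(20, 30, 40, 50, 70, 100),
                               dfs = seq(0.1, 1, by = 0.1),
                               params = model_params(),
                               catalog_path = NULL, profile_path = NULL,
                               seed = 1, n_runs = 10000,
                               scenario_name = "HIGH",
                               out_dir = tempfile("cbenefit_run_")) {
  structure(list(timeframes = timeframes, dfs = dfs, params = params,
                 catalog_path = catalog_path, profile_path = profile_path,
                 seed = as.integer(seed), n_runs = n_runs,
                 scenario_name = scenario_name, out_dir = out_dir),
            class = "cb_run_config")
}

#' @export
print.cb_run_config <- function(x, ...) {
  cat("<cb_run_config>\n")
  cat("  timeframes:", paste(x$timeframes, collapse = ", "), "\n")
  cat("  dfs:       ", paste(x$dfs, collapse = ", "), "\n")
  cat(sprintf("  tp: %d, growth: %s, rotation: %g, losses: on-site %g / supply %g\n",
              x$params$tp, x$params$growth_kind, x$params$rotation,
              x$params$l_onsite, x$params$l_supply))
  cat(sprintf("  seed: %d, n_runs: %d, scenario: %s\n",
              x$seed, x$n_runs, x$scenario_name))
  cat("  out_dir:", x$out_dir, "\n")
  invisible(x)
}

run_inputs <- function(config) {
  cat <- if (is.null(config$catalog_path)) bundled_catalog()
         else load_catalog(config$catalog_path)
  profile <- if (is.null(config$profile_path)) bundled_profile()
             else read_region_profile(config$profile_path)
  list(cat = cat, profile = profile)
}

#' Run one of the standard analyses and write its outputs
#'
#' Dispatches the commands a full study is composed of, each writing
#' delimited tables plus a machine-readable JSON manifest (command, seed,
#' configuration hash, package version, output files) into the configured
#' output directory:
#'
#' * `"gen-data"` — synthetic catalog, profile and cell table.
#' * `"df"` — the route x fossil fuel x upstream case DF table.
#' * `"trajectory"` — aggregated annual pool trajectories of both options.
#' * `"compare"` — the tf x DF cumulative-benefit table.
#' * `"montecarlo"` — box-plot summary of the yield sensitivity analysis.
#' * `"scenario"` — annual cumulative benefit curves under the named
#'   dynamic-DF scenario.
#'
#' Outputs are deterministic given the configuration (including its seed).
#'
#' @param command One of the commands above.
#' @param config A [default_run_config()].
#' @return The result object of the underlying computation, invisibly;
#'   as a side effect, files under `config$out_dir`.
#' @export
run_analysis <- function(command = c("compare", "montecarlo", "scenario",
                                     "trajectory", "df", "gen-data"),
                         config = default_run_config()) {
  command <- match.arg(command)
  stopifnot(inherits(config, "cb_run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  result <- switch(command,
    "gen-data" = {
      cfg <- generator_config(seed = config$seed)
      catalog <- gen_catalog(cfg)
      reg <- gen_region(cfg, catalog)
      save_catalog(catalog, out("catalog"))
      write_region_profile(reg$profile, out("profile.csv"))
      readr::write_csv(reg$cells, out("cells.csv"), progress = FALSE)
      files <- c("catalog/", "profile.csv", "cells.csv")
      reg
    },
    "df" = {
      inp <- run_inputs(config)
      tab <- df_table(inp$cat)
      readr::write_csv(tab, out("df_table.csv"), progress = FALSE)
      files <- "df_table.csv"
      tab
    },
    "trajectory" = {
      inp <- run_inputs(config)
      cmp <- compare_options(inp$profile, inp$cat, config$timeframes,
                             config$dfs, config$params)
      write_trajectory(cmp$trajectories$nsucc, out("trajectory_nsucc.csv"))
      write_trajectory(cmp$trajectories$src, out("trajectory_src.csv"))
      files <- c("trajectory_nsucc.csv", "trajectory_src.csv")
      cmp$trajectories
    },
    "compare" = {
      inp <- run_inputs(config)
      cmp <- compare_options(inp$profile, inp$cat, config$timeframes,
                             config$dfs, config$params)
      readr::write_csv(cmp$table, out("benefits.csv"), progress = FALSE)
      files <- "benefits.csv"
      cmp
    },
    "montecarlo" = {
      inp <- run_inputs(config)
      mc_dfs <- intersect(config$dfs, c(0.2, 0.5, 0.8))
      if (length(mc_dfs) == 0) mc_dfs <- c(0.2, 0.5, 0.8)
      mc <- run_monte_carlo(inp$profile, inp$cat, config$timeframes,
                            dfs = mc_dfs,
                            n_runs = config$n_runs,
                            seed = derive_seed(config$seed, "montecarlo"),
                            params = config$params)
      readr::write_csv(mc$summary, out("montecarlo.csv"), progress = FALSE)
      files <- "montecarlo.csv"
      mc
    },
    "scenario" = {
      inp <- run_inputs(config)
      spec <- switch(toupper(config$scenario_name),
                     HIGH = scenario_high(config$params$growth_kind),
                     LOW = scenario_low(config$params$growth_kind),
                     abort(sprintf("Unknown scenario '%s' (use HIGH or LOW).",
                                   config$scenario_name),
                           class = "cbenefit_validation_error"))
      sc <- run_scenario(spec, inp$profile, inp$cat, config$params)
      readr::write_csv(sc$table, out("scenario.csv"), progress = FALSE)
      files <- "scenario.csv"
      sc
    })

  manifest <- list(
    command = command,
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("cbenefit")),
    files = files)
  jsonlite::write_json(manifest, out(paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE)
  inform(sprintf("[%s] wrote %s to %s (config %s, seed %d)",
                 command, paste(files, collapse = ", "), config$out_dir,
                 manifest$config_hash, config$seed))
  invisible(result)
}
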