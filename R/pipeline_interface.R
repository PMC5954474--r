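#' @title Pipeline orchestration and tabular IO
#'
#' @description
#' CSV readers/writers with schema validation for the three tabular inputs
#' (monitoring series, benthic samples, iceberg registry), and
#' [run_pipeline()], which executes a named stage end to end, writes its
#' outputs, and records a run manifest (config snapshot, seeds, file list,
#' package version) sufficient to reproduce the run. All per-stage
#' randomness is split deterministically from the single user seed.
#'
#' @name pipeline_interface
NULL

.schemas <- list(
  monitoring = list(
    cols = c("year", "fastice_duration", "scoured_proportion"),
    check = function(df) {
      bad <- which(df$scoured_proportion < 0 | df$scoured_proportion > 1)
      if (length(bad)) {
        stop("monitoring row ", bad[1] + 1L,
             ": scoured_proportion outside [0, 1] (",
             df$scoured_proportion[bad[1]], ")", call. = FALSE)
      }
    }
  ),
  benthic = list(
    cols = c("depth", "seaice_duration", "blue_carbon"),
    check = function(df) {
      bad <- which(df$depth < 0 | df$blue_carbon < 0 |
                     df$seaice_duration < 0 | df$seaice_duration > 366)
      if (length(bad)) {
        stop("benthic row ", bad[1] + 1L,
             ": negative depth/carbon or sea-ice duration outside [0, 366]",
             call. = FALSE)
      }
    }
  ),
  registry = list(
    cols = c("id", "area_km2", "status"),
    check = function(df) {
      bad <- which(df$area_km2 <= 30)
      if (length(bad)) {
        stop("registry row ", bad[1] + 1L,
             ": area must exceed the 30 km2 giant-iceberg threshold",
             call. = FALSE)
      }
      ok <- c("fasted", "grounded", "roaming-shelf", "roaming-deep")
      bad <- which(!df$status %in% ok)
      if (length(bad)) {
        stop("registry row ", bad[1] + 1L, ": unknown status '",
             df$status[bad[1]], "'", call. = FALSE)
      }
    }
  )
)

# strip S3 class decoration so jsonlite serializes as a plain data frame
.plain_df <- function(x) {
  class(x) <- "data.frame"
  attr(x, "metadata") <- NULL
  x
}

.read_schema_csv <- function(path, schema) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(schema$cols, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df)) schema$check(df)
  df
}

#' Read a validated monitoring-series CSV
#'
#' Required columns: `year`, `fastice_duration`, `scoured_proportion`.
#' Rows with `scoured_proportion` outside `[0, 1]` raise an error naming
#' the offending line.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_monitoring_csv <- function(path) .read_schema_csv(path, .schemas$monitoring)

#' Read a validated benthic-sample CSV
#'
#' Required columns: `depth`, `seaice_duration`, `blue_carbon`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_benthic_csv <- function(path) .read_schema_csv(path, .schemas$benthic)

#' Read a validated iceberg-registry CSV
#'
#' Required columns: `id`, `area_km2`, `status`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_registry_csv <- function(path) .read_schema_csv(path, .schemas$registry)

#' Write a table as CSV (round-trip safe)
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# deterministic per-stage sub-seeds from one master seed (kept < 2^31)
.stage_seed <- function(seed, stage) {
  offs <- c(budget = 11L, scale = 23L, mc = 37L, simulate = 53L,
            analyze = 71L, generate = 89L, report = 97L)
  (as.integer(seed) * 101L + offs[[stage]]) %% .Machine$integer.max
}

#' Run one pipeline stage end to end
#'
#' Stages: `budget` (net iceberg budget with step ledger), `scale`
#' (circumpolar ladder), `mc` (Monte-Carlo envelopes for both models),
#' `simulate` (scour-recovery simulation; writes cell and event ledgers),
#' `generate` (synthetic inputs: `what` = monitoring / benthos / registry),
#' `analyze` (`mode` = zones / scour on an input CSV), `report` (budget +
#' ladder + census summary in one JSON). Every stage writes its outputs
#' under `out_dir` plus a `manifest.json` capturing the config snapshot,
#' seed, package version and output list.
#'
#' @param stage Stage name.
#' @param config `NULL`, named list, or YAML/JSON path of parameter
#'   overrides (see [load_params()]).
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param out_dir Output directory (created if needed).
#' @param input Input CSV path (for `analyze`).
#' @param mode Analysis mode: `"zones"` or `"scour"` (for `analyze`).
#' @param what Generator choice: `"monitoring"`, `"benthos"` or
#'   `"registry"` (for `generate`).
#' @param ... Stage-specific overrides passed to the underlying functions
#'   (e.g. `years`, `n` for draws).
#' @return List: `outputs` (named file paths), `result` (the in-memory
#'   stage result), `manifest` (path to manifest.json).
#' @export
run_pipeline <- function(stage = c("budget", "scale", "mc", "simulate",
                                   "generate", "analyze", "report"),
                         config = NULL, seed = 1L, out_dir = tempfile("run-"),
                         input = NULL, mode = c("zones", "scour"),
                         what = c("monitoring", "benthos", "registry"), ...) {
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- load_params(config)
  sseed <- .stage_seed(seed, stage)
  outputs <- list()
  dots <- list(...)

  result <- switch(stage,
    budget = {
      sc <- iceberg_scenario(n_icebergs = dots$n_icebergs %||% 2,
                             area_km2 = dots$area_km2 %||% 5000)
      b <- net_budget(sc, params)
      f <- file.path(out_dir, "budget.json")
      jsonlite::write_json(list(
        generation_raw = b$generation_raw,
        generation_reported = b$generation_reported,
        cost_raw = b$cost_raw, cost_reported = b$cost_reported,
        net_raw = b$net_raw, net_reported = b$net_reported,
        steps = b$steps), f, auto_unbox = TRUE, digits = NA)
      outputs$budget <- f
      b
    },
    scale = {
      est <- circumpolar_estimate(params)
      f <- file.path(out_dir, "ladder.json")
      jsonlite::write_json(list(
        areal_rate = est$rate, with_shallows = est$rate_with_shallows,
        shelf_mt = est$shelf_mt,
        rungs = .plain_df(est$ladder),
        final_total = attr(est$ladder, "final_total")),
        f, auto_unbox = TRUE, digits = NA)
      ft <- file.path(out_dir, "ladder.txt")
      writeLines(c("Circumpolar zoobenthic production ladder (Mt C yr-1)",
                   utils::capture.output(print(as.data.frame(est$ladder),
                                               row.names = FALSE))), ft)
      outputs$ladder <- f; outputs$table <- ft
      est
    },
    mc = {
      n <- dots$n %||% 5000
      env_b <- mc_envelope(params, "budget", n = n, seed = sseed)
      env_l <- mc_envelope(params, "ladder", n = n, seed = sseed)
      f <- file.path(out_dir, "envelopes.json")
      jsonlite::write_json(list(budget = .plain_df(env_b),
                                ladder = .plain_df(env_l)), f,
                           auto_unbox = TRUE, digits = NA)
      outputs$envelopes <- f
      list(budget = env_b, ladder = env_l)
    },
    simulate = {
      n_cells <- dots$n_cells %||% 400
      years <- dots$years %||% 50
      grid <- seabed_grid(n_cells, depth_m = dots$depth_m %||% 300,
                          climax = param_point(params, "rho"))
      am <- arrival_model(param_point(params, "groundings_per_year"),
                          placement = dots$placement %||% "uniform",
                          hotspot_cells = dots$hotspot_cells,
                          scour_fraction = param_point(params, "q_scour"))
      sim <- run_simulation(grid, am, years, seed = sseed,
                            t_rec = param_point(params, "t_rec"))
      f1 <- file.path(out_dir, "cells.csv")
      f2 <- file.path(out_dir, "events.csv")
      f3 <- file.path(out_dir, "annual.csv")
      write_table_csv(data.frame(cell_id = sim$grid$cell_id,
                                 depth_m = sim$grid$depth_m,
                                 area_km2 = sim$grid$area_km2,
                                 stock_tC_per_km2 = sim$grid$stock), f1)
      write_table_csv(sim$events, f2)
      write_table_csv(sim$annual, f3)
      outputs$cells <- f1; outputs$events <- f2; outputs$annual <- f3
      sim
    },
    generate = {
      what <- match.arg(what)
      df <- switch(what,
        monitoring = gen_monitoring_series(dots$n_years %||% 14, seed = sseed),
        benthos = gen_benthic_samples(dots$n_per_zone %||% 50, seed = sseed),
        registry = gen_iceberg_registry(
          total = param_point(params, "census_total"),
          n_large = param_point(params, "census_large"),
          n_grounded = param_point(params, "census_grounded"),
          seed = sseed))
      f <- file.path(out_dir, paste0(what, ".csv"))
      write_table_csv(df, f)
      outputs[[what]] <- f
      df
    },
    analyze = {
      mode <- match.arg(mode)
      if (is.null(input)) stop("analyze requires an input CSV", call. = FALSE)
      res <- if (mode == "zones") {
        zone_correlations(read_benthic_csv(input))
      } else {
        fastice_scour_fit(read_monitoring_csv(input))
      }
      f <- file.path(out_dir, paste0("analysis-", mode, ".json"))
      jsonlite::write_json(if (is.data.frame(res)) .plain_df(res) else res, f,
                           auto_unbox = TRUE, digits = NA, na = "null")
      outputs$analysis <- f
      res
    },
    report = {
      b <- net_budget(iceberg_scenario(), params)
      est <- circumpolar_estimate(params)
      f <- file.path(out_dir, "report.json")
      jsonlite::write_json(list(
        net_budget_tC = b$net_reported,
        generation_tC = b$generation_reported,
        scour_cost_tC = b$cost_reported,
        circumpolar_final_Mt = attr(est$ladder, "final_total"),
        grounded_pct = grounded_fraction(
          param_point(params, "census_grounded"),
          param_point(params, "census_total"))), f,
        auto_unbox = TRUE, digits = NA)
      outputs$report <- f
      f
    }
  )

  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    subcommand = stage,
    seed = seed, stage_seed = sseed,
    config = .plain_df(params[params$provenance != "default",
                              c("name", "point", "low", "high")]),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("bergcarbon")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    manifest, auto_unbox = TRUE, digits = NA)
  list(outputs = outputs, result = result, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
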