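#' Run one stage of the culture-analysis pipeline
#'
#' A single programmatic entry point tying the package's stages together.
#' Each command reads its delimited/YAML inputs, runs the corresponding
#' package functions, writes its artifacts into `out_dir`, and records a
#' machine-readable `run_log.json` (command, inputs, parameters, seed,
#' package and R versions, solver tolerances) sufficient to reproduce the
#' run.
#'
#' Commands:
#' \describe{
#'   \item{`simulate`}{needs `config_file`; writes `simulation.csv`.}
#'   \item{`fit`}{needs `data_file` (+ optional `config_file`, `free`,
#'     `bounds`, `weights`); writes `fitted_parameters.yaml` and
#'     `fit_report.json`.}
#'   \item{`rsm`}{needs `design_file` (+ `alpha`); writes, per response,
#'     the pruned model and ANOVA (`rsm_<response>.json`,
#'     `anova_<response>.csv`).}
#'   \item{`optimize`}{needs `design_file` (+ `grid_step`); prunes both
#'     responses, runs [desirability_optimize()]; writes `optimum.json`.}
#'   \item{`synth`}{`mode = "timeseries"` or `"factorial"`; writes the
#'     synthetic table plus a `*_truth.json` sidecar with the generating
#'     parameters.}
#' }
#'
#' @param command One of `"simulate"`, `"fit"`, `"rsm"`, `"optimize"`,
#'   `"synth"`.
#' @param out_dir Output directory (created if absent).
#' @param config_file,data_file,design_file Input paths, per command.
#' @param free,bounds,weights Passed to [fit_culture()].
#' @param alpha Significance level for [prune_terms()].
#' @param grid_step Passed to [desirability_optimize()].
#' @param mode Synthetic-data mode for `synth`.
#' @param noise_sd Noise scale(s) for `synth` (fraction for time series;
#'   named `c(biomass=, lipid=)` vector for factorial).
#' @param seed Integer seed for stochastic stages.
#' @return Exit status 0, invisibly, on success; errors abort with a
#'   diagnostic naming the failing stage or path.
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile()
#' run_pipeline("synth", out_dir = dir, mode = "factorial", seed = 1)
#' run_pipeline("rsm", out_dir = dir,
#'              design_file = file.path(dir, "synthetic_factorial.csv"))
#' }
run_pipeline <- function(command = c("simulate", "fit", "rsm", "optimize", "synth"),
                         out_dir,
                         config_file = NULL, data_file = NULL, design_file = NULL,
                         free = character(), bounds = NULL, weights = "raw",
                         alpha = 0.05,
                         grid_step = c(A = 0.05, B = 0.1),
                         mode = c("timeseries", "factorial"),
                         noise_sd = NULL,
                         seed = 1) {
  command <- match.arg(command)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (p in c(config_file, data_file, design_file)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("input file not found: ", p))
    }
  }
  log <- list(
    command = command, seed = seed,
    inputs = list(
      config_file = config_file, data_file = data_file,
      design_file = design_file
    ),
    package_version = as.character(utils::packageVersion("phycoculture")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (command == "simulate") {
    if (is.null(config_file)) abort("`simulate` needs `config_file`")
    cc <- read_culture_config(config_file)
    sim <- simulate_culture(cc$params, cc$config)
    write_timeseries(sim, file.path(out_dir, "simulation.csv"))
    log$parameters <- unclass(cc$params)
    log$solver <- list(rtol = cc$config$rtol, atol = cc$config$atol)
  } else if (command == "fit") {
    if (is.null(data_file)) abort("`fit` needs `data_file`")
    data <- read_timeseries(data_file)
    if (!is.null(config_file)) {
      cc <- read_culture_config(config_file)
      fit <- fit_culture(data,
        free = free, bounds = bounds, params = cc$params,
        config = cc$config, weights = weights, seed = seed
      )
    } else {
      fit <- fit_culture(data,
        free = free, bounds = bounds,
        weights = weights, seed = seed
      )
    }
    yaml::write_yaml(
      unclass(fit$params),
      file.path(out_dir, "fitted_parameters.yaml")
    )
    jsonlite::write_json(
      list(
        sse = fit$sse, converged = fit$converged,
        n_evaluations = fit$n_evaluations, free = fit$free,
        r_squared = setNames(
          as.list(fit$r_squared$r_squared),
          fit$r_squared$variable
        )
      ),
      file.path(out_dir, "fit_report.json"),
      auto_unbox = TRUE, digits = NA
    )
    log$sse <- fit$sse
  } else if (command == "rsm") {
    if (is.null(design_file)) abort("`rsm` needs `design_file`")
    design <- read_design(design_file)
    for (resp in c("biomass", "lipid")) {
      full <- fit_quadratic(design, resp)
      tab <- anova(full)
      pruned <- prune_terms(design, resp, alpha = alpha)
      readr::write_csv(tab, file.path(out_dir, paste0("anova_", resp, ".csv")))
      jsonlite::write_json(
        list(
          response = pruned$response,
          coefficients = as.list(pruned$coefficients),
          included_terms = pruned$included_terms,
          dropped_terms = attr(pruned, "pruned"),
          r_squared = pruned$r_squared, alpha = alpha
        ),
        file.path(out_dir, paste0("rsm_", resp, ".json")),
        auto_unbox = TRUE, digits = NA
      )
    }
    log$alpha <- alpha
  } else if (command == "optimize") {
    if (is.null(design_file)) abort("`optimize` needs `design_file`")
    design <- read_design(design_file)
    models <- list(
      biomass = prune_terms(design, "biomass", alpha = alpha),
      lipid = prune_terms(design, "lipid", alpha = alpha)
    )
    opt <- desirability_optimize(models, grid_step = grid_step)
    jsonlite::write_json(
      list(
        co2_pct = opt$A, light_umol_m2_s = opt$B, desirability = opt$D,
        predictions = setNames(
          as.list(opt$predictions$predicted),
          opt$predictions$response
        )
      ),
      file.path(out_dir, "optimum.json"),
      auto_unbox = TRUE, digits = NA
    )
    log$alpha <- alpha
  } else { # synth
    mode <- match.arg(mode)
    if (mode == "timeseries") {
      params <- chlorella_kinetics()
      config <- reactor_config(t_end = 14, output_grid = 0:14)
      sd <- if (is.null(noise_sd)) 0.02 else noise_sd
      ts <- generate_timeseries(params, config,
        sample_times = 0:14,
        noise = noise_model(sd = sd, seed = seed)
      )
      write_timeseries(ts, file.path(out_dir, "synthetic_timeseries.csv"))
      jsonlite::write_json(
        list(
          origin = attr(ts, "meta")$origin, seed = seed, noise_sd = sd,
          params = unclass(params)
        ),
        file.path(out_dir, "synthetic_timeseries_truth.json"),
        auto_unbox = TRUE, digits = NA
      )
    } else {
      truth_b <- reference_model("biomass")
      truth_l <- reference_model("lipid")
      sd <- if (is.null(noise_sd)) c(biomass = 0.3, lipid = 4) else noise_sd
      d <- generate_factorial(truth_b, truth_l, noise_sd = sd, seed = seed)
      write_design(d, file.path(out_dir, "synthetic_factorial.csv"))
      jsonlite::write_json(
        list(
          origin = attr(d, "meta")$origin, seed = seed,
          noise_sd = as.list(sd),
          truth_biomass = as.list(truth_b$coefficients),
          truth_lipid = as.list(truth_l$coefficients)
        ),
        file.path(out_dir, "synthetic_factorial_truth.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    log$mode <- mode
  }

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(0L)
}
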