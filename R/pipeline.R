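#' Run a declarative analysis pipeline
#'
#' Executes a sequence of pipeline stages described by a configuration (an R
#' list, or the path of a JSON file with the same shape), writing all outputs
#' plus exactly one [run_manifest()] into `out_dir`, and returning a
#' machine-readable summary (also written as `summary.json`). Deterministic:
#' identical config (including seeds) reproduces byte-identical summary
#' output. Any stage failure aborts with the stage name and context.
#'
#' Recognised stage types (each a list with `stage` plus parameters):
#' * `simulate_pull`: `preset`, optional `seed`; writes `pull_trace.csv` and
#'   `pull_truth.json`; summary reports terminal tension.
#' * `summarize_pull`: `trace` (path; defaults to the stage-1 output),
#'   optional `friction_offset`; drift-corrects, summarises hourly, writes
#'   `pull_summary.csv`.
#' * `simulate_relaxation`: `S_inf`, `S_sp`, `tau`, optional `strain`,
#'   `area_mm2`, `noise_sd_rel`, `n_samples`, `seed`; writes
#'   `relaxation_trace.csv`.
#' * `fit_relaxation`: `trace` (path; defaults to simulated); writes
#'   `sls_fit.json`; summary reports the estimates.
#' * `cell_force_table`: optional `rows` (path to CSV with `time_hr`,
#'   `force_uN`, `effective_ssa_mm2`; defaults to the bundled reference
#'   measurements) and `cell_area_um2`; writes `cell_force_table.csv`.
#'
#' An empty stage list writes the manifest only.
#'
#' @param config List or path to a JSON config: `list(seed = ..., stages =
#'   list(...))`.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L

  summary <- list(n_stages = length(stages), stages = list())
  state <- new.env(parent = emptyenv())

  for (i in seq_along(stages)) {
    st <- stages[[i]]
    name <- st$stage
    if (is.null(name)) stop("stage ", i, " has no `stage` field")
    res <- tryCatch(
      run_stage(st, seed, out_dir, state),
      error = function(e) stop("pipeline stage ", i, " ('", name, "') failed: ",
                               conditionMessage(e), call. = FALSE))
    summary$stages[[name]] <- res
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  man <- run_manifest("run", config = config,
                      inputs = unlist(lapply(stages, `[[`, "trace")),
                      seed = seed)
  write_manifest(man, file.path(out_dir, "manifest.json"))
  invisible(summary)
}

get_par <- function(st, key, default) if (!is.null(st[[key]])) st[[key]] else default

run_stage <- function(st, seed, out_dir, state) {
  switch(st$stage,
    simulate_pull = {
      cfg <- pull_config_preset(get_par(st, "preset", "standard"),
                                seed = get_par(st, "seed", seed))
      sim <- simulate_tractor_pull(cfg)
      p <- file.path(out_dir, "pull_trace.csv")
      write_trace(sim$trace, p)
      jsonlite::write_json(sim$truth, file.path(out_dir, "pull_truth.json"),
                           digits = NA)
      state$pull_trace <- p
      list(trace = basename(p),  # summary stays path-independent
           terminal_tension_uN = sim$truth$tension_uN[nrow(sim$truth)])
    },
    summarize_pull = {
      path <- get_par(st, "trace", state$pull_trace)
      if (is.null(path)) stop("no trace available: give `trace` or run simulate_pull first")
      tr <- correct_drift(read_trace(path))
      off <- get_par(st, "friction_offset", 0)
      if (off > 0) tr <- subtract_friction(tr, off)
      hs <- hourly_summary(tr)
      utils::write.csv(as.data.frame(hs), file.path(out_dir, "pull_summary.csv"),
                       row.names = FALSE)
      list(n_hours = nrow(hs), peak_mean_uN = max(hs$mean_uN),
           friction_offset_uN = off)
    },
    simulate_relaxation = {
      pars <- sls_parameters(st$S_inf, st$S_sp, st$tau)
      tr <- simulate_relaxation(
        pars,
        strain = get_par(st, "strain", 0.12),
        area_mm2 = get_par(st, "area_mm2", 0.5),
        noise_sd_rel = get_par(st, "noise_sd_rel", 0.02),
        n_samples = get_par(st, "n_samples", 200),
        duration_s = get_par(st, "duration_s", 300),
        seed = get_par(st, "seed", seed))
      p <- file.path(out_dir, "relaxation_trace.csv")
      write_trace(tr, p)
      state$relaxation_trace <- p
      list(trace = basename(p),
           truth = list(S_inf = pars$S_inf, S_sp = pars$S_sp, tau = pars$tau))
    },
    fit_relaxation = {
      path <- get_par(st, "trace", state$relaxation_trace)
      if (is.null(path)) stop("no trace available: give `trace` or run simulate_relaxation first")
      fit <- fit_sls(read_trace(path))
      out <- list(S_inf = fit$parameters$S_inf, S_sp = fit$parameters$S_sp,
                  tau = fit$parameters$tau, eta = fit$parameters$eta,
                  converged = fit$converged,
                  rms_residual_pa = fit$rms_residual_pa, method = fit$method)
      jsonlite::write_json(out, file.path(out_dir, "sls_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    },
    cell_force_table = {
      rows <- if (!is.null(st$rows)) utils::read.csv(st$rows) else
        giant_pull_force_ssa()
      tab <- build_cell_force_table(rows, get_par(st, "cell_area_um2", 625))
      utils::write.csv(tab, file.path(out_dir, "cell_force_table.csv"),
                       row.names = FALSE)
      list(n_rows = nrow(tab),
           stress_pa_2sf = tab$stress_pa_2sf,
           force_per_cell_nN_2sf = tab$force_per_cell_nN_2sf)
    },
    stop("unknown stage type '", st$stage, "'")
  )
}
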