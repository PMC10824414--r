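#' Run the full analysis pipeline on files
#'
#' File-in/file-out orchestration of [hsc_fit()]: reads the two CSV inputs,
#' runs every stage, and writes all artifacts into `outdir`:
#' `shapes.csv` (per-age beta shape estimates), `trajectory.json`
#' (biexponential parameters), `ssr_grid.csv` (the 36-row threshold audit
#' table), `fit_summary.csv` (parameter table), `posterior.csv` (MCMC draws),
#' `fractions.csv` (weekly division-mode fractions), and `manifest.json`
#' (configuration hash, seed and package version). If a stage fails, a
#' `FAILED` marker naming the stage is left in `outdir` and the partial
#' artifacts are retained.
#'
#' @param wells_path,census_path Input CSV paths.
#' @param outdir Output directory (created if needed).
#' @param cfg A [fit_config()].
#' @param seed Integer; overrides `cfg$mcmc$seed`.
#' @return The [hsc_fit()] object, invisibly.
#' @export
run_pipeline <- function(wells_path, census_path, outdir,
                         cfg = fit_config(), seed = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!is.null(seed)) cfg$mcmc$seed <- as.integer(seed)
  stage <- "read inputs"
  fit <- tryCatch({
    wells <- read_well_proportions(wells_path)
    census <- read_census(census_path)
    stage <- "beta estimation"
    shapes <- fit_all_ages(wells)
    write_table(shapes, file.path(outdir, "shapes.csv"))
    stage <- "trajectory fit"
    traj <- fit_trajectory(shapes, t0 = cfg$t0)
    jsonlite::write_json(
      list(t0 = traj$t0,
           b1_alpha = traj$alpha[["b1"]], a1_alpha = traj$alpha[["a1"]],
           b2_alpha = traj$alpha[["b2"]], a2_alpha = traj$alpha[["a2"]],
           b1_beta = traj$beta[["b1"]], a1_beta = traj$beta[["a1"]],
           b2_beta = traj$beta[["b2"]], a2_beta = traj$beta[["a2"]]),
      file.path(outdir, "trajectory.json"), auto_unbox = TRUE, digits = NA)
    stage <- "threshold grid search"
    gs <- grid_search_thresholds(traj, census, cfg)
    write_table(gs$ssr_grid, file.path(outdir, "ssr_grid.csv"))
    stage <- "MCMC"
    post <- run_mcmc(gs$thresholds, traj, census, cfg,
                     point = list(params = gs$params, ssr = gs$ssr))
    write_table(post$samples, file.path(outdir, "posterior.csv"))
    stage <- "sensitivity"
    sens <- NULL
    if (length(cfg$d_values) > 1L) {
      sens <- sensitivity_d(traj, census, cfg, thresholds = gs$thresholds)
      write_table(sens, file.path(outdir, "sensitivity.csv"))
    }
    stage <- "summaries"
    fit <- structure(list(shapes = shapes, trajectory = traj,
                          thresholds = gs$thresholds, params = gs$params,
                          ssr = gs$ssr, ssr_grid = gs$ssr_grid,
                          posterior = post, sensitivity = sens, cfg = cfg,
                          wells = wells, census = census),
                     class = "hsc_fit")
    write_table(summary(fit)$parameters,
                file.path(outdir, "fit_summary.csv"))
    write_table(predict(fit, what = "fractions"),
                file.path(outdir, "fractions.csv"))
    write_manifest(outdir, cfg)
    fit
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(fit)
}

## manifest with a content hash of the configuration
write_manifest <- function(outdir, cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg), collapse = ""), tmp)
  jsonlite::write_json(
    list(config = unclass(cfg),
         config_md5 = unname(tools::md5sum(tmp)),
         seed = cfg$mcmc$seed,
         package_version = as.character(utils::packageVersion("hscdiv")),
         r_version = as.character(getRversion())),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
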