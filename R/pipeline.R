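#' Run the analysis pipeline and write all outputs
#'
#' Executes the requested stages in dependency order and writes CSV tables,
#' plots and a JSON run manifest to `out_dir`. Stages:
#' \describe{
#'   \item{labour}{Itemised labour costing ([labour_cost_table()]) ->
#'     `labour_costs.csv`. Needs a `labour` block in the config.}
#'   \item{simulate}{Synthetic cohorts ([generate_cohort()]) ->
#'     `cohort_reference.csv`, `cohort_intervention.csv`. Needs a `cohort`
#'     block.}
#'   \item{bootstrap}{Bootstrap estimation over the simulated cohorts
#'     ([estimate_inputs_from_cohort()]) -> `bootstrap_estimates.csv`.
#'     Requires the `simulate` stage.}
#'   \item{base_case}{Decision-tree base case ([cua()]) -> `base_case.csv`.}
#'   \item{dsa}{One-way sensitivity analysis ([one_way_dsa()]) -> `dsa.csv`
#'     and `tornado.png`.}
#'   \item{psa}{Probabilistic sensitivity analysis ([run_psa()]) ->
#'     `psa_draws.csv` and `ce_plane.png`.}
#'   \item{ceac}{Acceptability curve ([ceac()]) -> `ceac.csv` and
#'     `ceac.png`. Requires the `psa` stage.}
#' }
#'
#' Tables are UTF-8 CSV with `.` decimal separator and no thousands
#' separators; two runs with identical configuration and seed produce
#' byte-identical CSVs. Progress and stage timings are logged to stderr;
#' results are never written to stdout. On failure, files written by the
#' failed run are removed.
#'
#' @param config A [model_config] or path to a configuration file.
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("labour", "simulate", "bootstrap", "base_case", "dsa", "psa",
#'   "ceac")`. An empty set writes the manifest only.
#' @param seed Integer master seed for the stochastic stages (per-stage
#'   seeds are derived as small offsets); defaults to the configured PSA
#'   seed.
#' @param iterations PSA iteration override.
#' @param mode PSA hyperparameter mode, `"reproduction"` or `"derivation"`.
#' @return The run manifest, invisibly: list with `tool_version`,
#'   `config_hash`, `seed`, `mode`, `stages`, `outputs`.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "cua-run")
#' run_pipeline(base_case_config(), out, stages = c("base_case", "dsa"))
#' }
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("labour", "simulate", "bootstrap",
                                    "base_case", "dsa", "psa", "ceac"),
                         seed = NULL, iterations = NULL,
                         mode = c("reproduction", "derivation")) {
  mode <- match.arg(mode)
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- load_config(config)
  }
  stopifnot(inherits(config, "cua_config"))
  all_stages <- c("labour", "simulate", "bootstrap", "base_case", "dsa",
                  "psa", "ceac")
  stages <- unique(stages)
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop(sprintf("run_pipeline: unknown stage(s) %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  if ("bootstrap" %in% stages && !"simulate" %in% stages)
    stop("run_pipeline: the 'bootstrap' stage requires the 'simulate' stage",
         call. = FALSE)
  if ("ceac" %in% stages && !"psa" %in% stages)
    stop("run_pipeline: the 'ceac' stage requires the 'psa' stage",
         call. = FALSE)
  stages <- all_stages[all_stages %in% stages]   # dependency order

  if (is.null(seed)) seed <- config$psa$seed
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # config hash: md5 of the canonical YAML serialisation
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  write_config(config, tmp)
  config_hash <- unname(tools::md5sum(tmp))

  outputs <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    outputs <<- c(outputs, path)
    path
  }
  emit_plot <- function(name, expr) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = 800, height = 600)
    ok <- try(expr, silent = TRUE)
    grDevices::dev.off()
    if (inherits(ok, "try-error")) stop(ok)
    outputs <<- c(outputs, path)
    path
  }
  log_stage <- function(stage, t0)
    message(sprintf("[cuatree] stage %-9s done in %.2fs", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))

  cohorts <- NULL
  run_one <- function(stage) {
    t0 <- Sys.time()
    switch(stage,
      labour = {
        if (is.null(config$labour))
          stop("run_pipeline: 'labour' stage needs a labour block in the config",
               call. = FALSE)
        tab <- labour_cost_table(config$labour)
        emit_csv(cbind(item = rownames(tab), tab), "labour_costs.csv")
      },
      simulate = {
        if (is.null(config$cohort))
          stop("run_pipeline: 'simulate' stage needs a cohort block in the config",
               call. = FALSE)
        cohorts <<- list(
          reference = generate_cohort(config$cohort$reference,
                                      seed = if (is.null(seed)) NULL
                                             else seed + 1L),
          intervention = generate_cohort(config$cohort$intervention,
                                         seed = if (is.null(seed)) NULL
                                                else seed + 2L))
        emit_csv(cohorts$reference, "cohort_reference.csv")
        emit_csv(cohorts$intervention, "cohort_intervention.csv")
      },
      bootstrap = {
        rates <- if (!is.null(config$labour))
          c(reference = cost_per_minute(config$labour$reference$salary,
                                        config$labour$calendar),
            intervention = cost_per_minute(config$labour$intervention$salary,
                                           config$labour$calendar))
        else c(reference = NA_real_, intervention = NA_real_)
        rows <- lapply(names(cohorts), function(a) {
          est <- estimate_inputs_from_cohort(
            cohorts[[a]],
            rate_per_minute = if (is.finite(rates[[a]])) rates[[a]] else NULL,
            seed = if (is.null(seed)) NULL else seed + 3L)
          data.frame(
            arm = a,
            p_error = est$p_error$mean,
            n = est$p_error$n,
            error_cost = if (is.null(est$error_cost)) NA_real_
                         else est$error_cost$mean,
            error_cost_sd = if (is.null(est$error_cost)) NA_real_
                            else est$error_cost$sd,
            labour_cost = if (is.null(est$labour_cost)) NA_real_
                          else est$labour_cost$mean,
            utility_decrement = if (is.null(est$utility_decrement)) NA_real_
                                else est$utility_decrement$mean,
            mean_minutes = est$mean_minutes)
        })
        emit_csv(do.call(rbind, rows), "bootstrap_estimates.csv")
      },
      base_case = {
        emit_csv(base_case_table(cua(config)), "base_case.csv")
      },
      dsa = {
        res <- one_way_dsa(config)
        emit_csv(as.data.frame(res), "dsa.csv")
        base_icer <- cua(config)$incremental$icer
        emit_plot("tornado.png", plot(res, base_icer = base_icer))
      },
      psa = {
        draws <- run_psa(config, n_iter = iterations,
                         seed = if (is.null(seed)) NULL else seed + 4L,
                         mode = mode)
        emit_csv(as.data.frame(draws), "psa_draws.csv")
        emit_plot("ce_plane.png", plot(draws))
        assign("psa_draws", draws, envir = state)
      },
      ceac = {
        curve <- ceac(get("psa_draws", envir = state), config$wtp)
        emit_csv(as.data.frame(curve), "ceac.csv")
        emit_plot("ceac.png", plot(curve))
      })
    log_stage(stage, t0)
  }

  state <- new.env(parent = emptyenv())
  ok <- FALSE
  tryCatch({
    for (st in stages) run_one(st)
    ok <- TRUE
  }, finally = {
    if (!ok && length(outputs)) unlink(outputs)
  })

  manifest <- list(
    tool_version = as.character(utils::packageVersion("cuatree")),
    config_hash = config_hash,
    config_path = config_path,
    seed = seed,
    mode = mode,
    iterations = if (is.null(iterations)) config$psa$iterations
                 else as.integer(iterations),
    stages = as.list(stages),
    outputs = as.list(basename(outputs)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
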