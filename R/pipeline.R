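# Consolidated analysis pipeline: pedigree in (file or simulation),
# validated; pair enumeration; vertical pair table and percentages;
# prevalence per group; observed-vs-expected co-/contravariation;
# birth-order tests; anticipation. All outputs are a pure function of
# (input digest, configuration, seed); a manifest records enough to re-run
# bit-for-bit.

default_pipeline_params <- function() {
  list(alpha = 0.05, chi_df = 2L, max_generations = 5L, max_healthy = 5L,
       vertical_gap = 2L, exact_prevalence = FALSE,
       boe_restrict = NULL)
}

#' Run the full familial-MBD analysis pipeline
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{input}{either `pedigree` (path) with optional `format`
#'       (`csv`/`ped`), `sidecar`, `kindred_mode`; or `simulate`, a list of
#'       [simulation_config()] arguments.}
#'     \item{params}{optional overrides of `alpha`, `chi_df`,
#'       `max_generations`, `max_healthy`, `vertical_gap`,
#'       `exact_prevalence`, `boe_restrict` (list with `sex`/`diagnosis`/
#'       `lineage`).}
#'     \item{reference}{optional path to a reference prevalence count CSV
#'       (columns label,total,male,female) for the anticipation
#'       comparison.}
#'     \item{seed}{integer seed for simulation input.}
#'   }
#' @param output_dir optional directory; when given, writes `pairs.csv`,
#'   `pair_table.csv`, `prevalence_<group>.csv`, `obs_exp.csv`,
#'   `report.txt` and `manifest.json` there.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `pedigree`, `pairs`, `pair_table`,
#'   `percentages`, `lineage_shares`, `prevalence`, `obs_exp`, `boe`,
#'   `wilcoxon`, `anticipation`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort_mbd(paste0("config file not found: ", config),
                class = "mbd_usage_error")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$input))
    abort_mbd("config must have an 'input' section (pedigree path or simulate)",
              class = "mbd_usage_error")
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  input_digest <- NULL
  if (!is.null(config$input$pedigree)) {
    path <- config$input$pedigree
    say("reading pedigree from %s", path)
    ped <- clock("read", read_pedigree(
      path, format = config$input$format %||% "csv",
      sidecar = config$input$sidecar,
      kindred_mode = config$input$kindred_mode %||% "nuclear"))
    input_digest <- unname(tools::md5sum(path))
  } else if (!is.null(config$input$simulate)) {
    sim_args <- config$input$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    if (is.null(sim_args$seed))
      abort_mbd("simulation input requires a seed", class = "mbd_usage_error")
    say("simulating pedigree (mode %s, seed %s)",
        sim_args$mode %||% "nuclear", sim_args$seed)
    cfg <- do.call(simulation_config, sim_args)
    sim <- clock("simulate", generate_pedigree(cfg))
    ped <- sim$pedigree
    input_digest <- paste0("simulate:seed=", sim_args$seed)
  } else {
    abort_mbd("input must provide 'pedigree' or 'simulate'",
              class = "mbd_usage_error")
  }
  if (!any(ped$members$affected))
    abort_mbd("pedigree contains no affected members: nothing to analyse",
              class = "mbd_usage_error")
  clock("validate", validate_pedigree(ped))
  say("pedigree: %d members, %d affected", nrow(ped$members),
      sum(ped$members$affected))

  pairs <- clock("pairs", enumerate_pc_ar(
    ped, max_generations = params$max_generations,
    max_healthy_intermediates = params$max_healthy))
  say("enumerated %d Pc-AR pair(s)", nrow(pairs))
  pair_table <- clock("vertical", extract_vertical_pairs(
    pairs, max_gap = params$vertical_gap))
  say("vertical pairs retained (gap <= %d): %d of %d; dropped %d",
      params$vertical_gap, nrow(pair_table$pairs), nrow(pairs),
      nrow(pairs) - nrow(pair_table$pairs))
  percentages <- if (nrow(pair_table$pairs)) pair_percentages(pair_table)
  shares <- if (nrow(pair_table$pairs)) lineage_shares(pair_table)

  prevalence <- list()
  for (grp in c("LPD", "MPD")) {
    prevalence[[grp]] <- tryCatch(compute_prevalence(ped, grp),
                                  mbd_usage_error = function(e) NULL)
    if (is.null(prevalence[[grp]])) say("no affected members in group %s", grp)
  }
  prevalence <- Filter(Negate(is.null), prevalence)

  obs_exp <- clock("obsexp", cocontravariation_table(
    pairs, prevalence, df = params$chi_df, alpha = params$alpha,
    exact_prevalence = params$exact_prevalence))

  boe <- clock("boe", tryCatch(
    haldane_smith_test(ped, restrict = params$boe_restrict, pairs = pairs),
    mbd_usage_error = function(e) {
      say("birth-order test skipped: %s", conditionMessage(e))
      NULL
    }))
  wil <- tryCatch(
    wilcoxon_boe_control(ped, restrict = params$boe_restrict, pairs = pairs),
    mbd_usage_error = function(e) NULL)

  reference <- if (!is.null(config$reference))
    utils::read.csv(config$reference, stringsAsFactors = FALSE)
  anticipation <- clock("anticipation", tryCatch(
    assess_anticipation(ped, reference = reference, alpha = params$alpha),
    mbd_usage_error = function(e) {
      say("anticipation skipped: %s", conditionMessage(e))
      NULL
    }))

  manifest <- list(
    package = "famMBD",
    version = as.character(utils::packageVersion("famMBD")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input_digest = input_digest,
    seed = config$seed %||% config$input$simulate$seed,
    params = params,
    n_members = nrow(ped$members),
    n_affected = sum(ped$members$affected),
    n_pairs = nrow(pairs),
    n_vertical = nrow(pair_table$pairs),
    stage_seconds = as.list(timings))

  bundle <- list(pedigree = ped, pairs = pairs, pair_table = pair_table,
                 percentages = percentages, lineage_shares = shares,
                 prevalence = prevalence, obs_exp = obs_exp, boe = boe,
                 wilcoxon = wil, anticipation = anticipation,
                 manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_pairs(pairs, file.path(output_dir, "pairs.csv"))
    if (!is.null(percentages))
      utils::write.csv(percentages, file.path(output_dir, "pair_table.csv"),
                       row.names = FALSE)
    for (grp in names(prevalence))
      utils::write.csv(as.data.frame(prevalence[[grp]]),
                       file.path(output_dir,
                                 paste0("prevalence_", grp, ".csv")),
                       row.names = FALSE)
    if (nrow(obs_exp))
      utils::write.csv(obs_exp, file.path(output_dir, "obs_exp.csv"),
                       row.names = FALSE)
    writeLines(render_report(bundle), file.path(output_dir, "report.txt"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("outputs written to %s", output_dir)
  }
  invisible(bundle)
}

# plain-text consolidated report mirroring the four summary tables
render_report <- function(bundle) {
  grab <- function(x) utils::capture.output(print(x))
  out <- c("familial MBD analysis report", strrep("=", 60), grab(bundle$pedigree))
  for (grp in names(bundle$prevalence)) {
    out <- c(out, "", sprintf("-- prevalence (%s) --", grp),
             grab(bundle$prevalence[[grp]]))
  }
  out <- c(out, "", "-- vertical pairs --", grab(bundle$pair_table))
  if (!is.null(bundle$percentages))
    out <- c(out, grab(bundle$percentages))
  if (!is.null(bundle$obs_exp) && nrow(bundle$obs_exp))
    out <- c(out, "", "-- observed vs expected (co-/contravariation) --",
             grab(bundle$obs_exp))
  if (!is.null(bundle$boe))
    out <- c(out, "", "-- birth-order effect --", grab(bundle$boe))
  if (!is.null(bundle$wilcoxon)) out <- c(out, grab(bundle$wilcoxon))
  if (!is.null(bundle$anticipation))
    out <- c(out, "", "-- anticipation --", grab(bundle$anticipation))
  out
}
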