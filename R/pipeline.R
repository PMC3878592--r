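#' Model specification matching a simulation specification
#'
#' Builds the [onpls_spec()] whose component counts mirror the parts of a
#' [sim_spec()] (same global, local and unique counts).
#'
#' @param sim A [sim_spec()].
#' @param ... Overrides forwarded to [onpls_spec()].
#' @return An [onpls_spec()].
#' @export
model_spec_for <- function(sim, ...) {
  n_local <- list()
  for (lp in sim$local_parts) {
    key <- subset_key(lp$blocks)
    n_local[[key]] <- (if (is.null(n_local[[key]])) 0L else
      n_local[[key]]) + as.integer(lp$n)
  }
  args <- list(n_global = sim$n_global, n_local = n_local,
               n_unique = sim$n_unique)
  do.call(onpls_spec, utils::modifyList(args, list(...)))
}

#' Run the full synthetic analysis pipeline and write all outputs
#'
#' Simulates a multi-block dataset, reference-scales it, fits the OnPLS
#' decomposition, selects significant variables by VIP and jackknife,
#' attaches direction arrows and writes the complete set of tab-delimited
#' outputs (blocks, design, scores, loadings, weights, variance report,
#' significance tables, arrow table, MapMan and Paintomics exports, run log).
#' All randomness derives from the simulation seed, and all files are written
#' with fixed formatting, so two runs with the same seed are byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Seed forwarded to the simulation.
#' @param sim A [sim_spec()]; its `seed` is overridden by `seed`.
#' @param spec An [onpls_spec()]; defaults to [model_spec_for()] of `sim`.
#' @param params [preprocess_params()].
#' @param vip_threshold VIP significance threshold.
#' @return Invisibly, a list with the simulation, model, significance tables
#'   and written paths.
#' @export
run_synthetic_pipeline <- function(outdir, seed = 1L, sim = NULL,
                                   spec = NULL,
                                   params = preprocess_params(),
                                   vip_threshold = 0.5) {
  if (is.null(sim)) sim <- sim_spec(seed = as.integer(seed))
  else sim$seed <- as.integer(seed)
  if (is.null(spec)) spec <- model_spec_for(sim)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sr <- simulate_multiomics(sim)
  if (is.null(sr$dataset_scaled)) {
    stop("reference scaling impossible for this simulation (zero reference ",
         "spread); use noise_sd > 0 and within_genotype_sd > 0")
  }
  ds_scaled <- sr$dataset_scaled
  model <- fit_onpls(ds_scaled, spec)
  jk <- jackknife(ds_scaled, spec, params = params,
                  resample_preprocess = "none", model = model)
  nms <- sort(names(ds_scaled$blocks))
  tables <- stats::setNames(lapply(nms, function(b) {
    tab <- call_significance(compute_vip(model, b), jk,
                             threshold = vip_threshold)
    direction_arrows(ds_scaled$blocks[[b]], sr$design, tab)
  }), nms)

  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)
  add(write_design_tsv(sr$design, file.path(outdir, "design.tsv")))
  for (b in nms) {
    add(write_block_tsv(sr$dataset$blocks[[b]],
                        file.path(outdir, sprintf("%s.centered.tsv", b))))
    add(write_block_tsv(ds_scaled$blocks[[b]],
                        file.path(outdir, sprintf("%s.wt_scaled.tsv", b))))
  }
  add(write_global_scores(model, file.path(outdir, "scores_global.tsv")))
  add(write_block_loadings(model, outdir))
  add(write_r2_report(model, file.path(outdir, "r2_report.tsv")))
  add(write_significance_tables(tables, outdir))
  for (b in nms) {
    add(export_mapman(tables[[b]], outdir, value = "direction", prefix = b))
  }
  add(export_paintomics(tables, outdir))
  if (all(c("proteins", "transcripts") %in% nms)) {
    mapping <- stats::setNames(
      sub("^proteins", "transcripts",
          tables$proteins$variable_id),
      tables$proteins$variable_id)
    mapping <- mapping[mapping %in% tables$transcripts$variable_id]
    arrows <- merged_arrow_table(list(tables$proteins,
                                      tables$transcripts),
                                 mapping = mapping)
    add(write_tsv_formatted(arrows, file.path(outdir, "arrow_table.tsv")))
  }
  log_lines <- c(
    sprintf("seed\t%d", sim$seed),
    sprintf("n_global\t%d", spec$n_global),
    sprintf("vip_threshold\t%g", vip_threshold),
    vapply(names(model$convergence), function(k) {
      cv <- model$convergence[[k]]
      sprintf("component\t%s\titerations\t%d\tconverged\t%s", k,
              cv$iterations, ifelse(cv$converged, "yes", "no"))
    }, character(1)))
  log_path <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, log_path, useBytes = TRUE)
  add(log_path)

  invisible(list(sim = sr, model = model, tables = tables, paths = paths))
}
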