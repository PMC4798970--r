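# End-to-end pipeline: synthetic cohort -> trace analysis -> gene-panel
# fitting -> clustering -> JSON report, with a run manifest for
# reproducibility.

#' Run the full analysis pipeline on synthetic data
#'
#' Chains the package's stages under one seed: (1) generate a single-cell
#' cohort under the configured forcing and analyze its synchrony and
#' periods; (2) generate an expression panel, call deregulation, cluster
#' the standardized deregulated profiles; (3) optionally fit gene
#' parameters per cluster-core archetype and compare fitted degradation
#' rates. Writes a JSON report and a run manifest next to it.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param forcing a [forcing_signal()] for the cohort (default square
#'   T1 = T2 = 45 min at S_high = 2, with a 60 min pre-stimulus baseline).
#' @param params baseline [kinetic_params()].
#' @param n_cells cohort size (default 60).
#' @param genes_per_archetype panel size per archetype (default 8).
#' @param fit_genes fit a small gene panel (slowest stage; default TRUE).
#' @param n_fit_genes genes fitted per extreme archetype when
#'   \code{fit_genes} (default 3).
#' @return (invisibly) the report list; side effects: \code{report.json},
#'   \code{traces.csv}, \code{expression.tsv}, \code{manifest.json} in
#'   \code{out_dir}.
#' @export
run_pipeline <- function(out_dir, seed, forcing = forcing_signal(
                           "square", S_high = 2, S_low = 0, T1 = 45,
                           T2 = 45, t_start = 60),
                         params = kinetic_params(), n_cells = 60,
                         genes_per_archetype = 8, fit_genes = TRUE,
                         n_fit_genes = 3) {
  if (missing(seed)) stop("run_pipeline requires an explicit seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_begin <- Sys.time()

  # stage 1: cohort + synchrony
  cs <- cohort_spec(n_cells, forcing, base = params, seed = seed)
  cohort <- generate_cohort(cs)
  write_traces(cohort$traces, file.path(out_dir, "traces.csv"))
  an <- analyze_traces(cohort$traces, forcing)
  periods <- an$periods
  period_hist <- if (length(periods))
    table(cut(periods, breaks = seq(0, max(periods) + 30, by = 30)))
  else NULL

  # stage 2: panel + clustering
  ps <- panel_spec(genes_per_archetype = genes_per_archetype,
                   seed = seed + 1)
  panel <- generate_expression_panel(ps, params)
  write_expression(panel$em, file.path(out_dir, "expression.tsv"))
  dereg <- call_deregulated(panel$em)
  keep <- dereg$direction != "none"
  clus <- NULL; cores <- NULL
  if (sum(keep) >= 6) {
    std <- standardize_profiles(
      expression_matrix(panel$em$values[keep, , drop = FALSE],
                        panel$em$timepoints))
    clus <- fuzzy_cmeans(std$z, c = 6, m = 1.5, seed = seed + 2)
    cores <- extract_cores(clus$memberships)
  }

  # stage 3: gene fits on extreme archetypes
  fit_summary <- NULL
  if (fit_genes) {
    pick <- function(prefix) utils::head(grep(prefix, rownames(panel$em$values),
                                              value = TRUE), n_fit_genes)
    sel <- c(pick("^oscillating"), pick("^slow_up"))
    pf <- fit_gene_panel(panel$em$values[sel, , drop = FALSE],
                         panel$em$timepoints, params,
                         forcing_signal("square", S_high = 2, S_low = 0,
                                        T1 = 30, T2 = 150),
                         seed = seed + 3)
    tb <- pf$table
    fit_summary <- list(
      table = tb,
      median_d_R_G_oscillating = stats::median(
        tb$d_R_G[grepl("^oscillating", tb$gene) & tb$ok]),
      median_d_R_G_accumulating = stats::median(
        tb$d_R_G[grepl("^slow_up", tb$gene) & tb$ok]))
  }

  report <- list(
    n_cells = n_cells,
    n_cells_used = an$n_cells_used,
    eta = if (!is.null(an$synchrony)) an$synchrony$eta else NA,
    n_delta_phi = length(an$delta_phi),
    period_mode_min = if (length(periods))
      as.numeric(names(sort(table(round(periods / 30) * 30),
                            decreasing = TRUE))[1]) else NA,
    n_deregulated = sum(keep),
    cluster_core_sizes = if (!is.null(cores)) lengths(cores) else NULL,
    fit = if (!is.null(fit_summary))
      fit_summary[c("median_d_R_G_oscillating", "median_d_R_G_accumulating")]
    else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("nfkbsync")),
    seed = seed,
    stage_seeds = list(cohort = seed, panel = seed + 1, cluster = seed + 2,
                       fits = seed + 3),
    inputs = list(forcing = unclass(forcing)[c("kind", "S_high", "S_low",
                                               "T1", "T2", "t_start")],
                  n_cells = n_cells,
                  genes_per_archetype = genes_per_archetype),
    outputs = c("traces.csv", "expression.tsv", "report.json"),
    started = format(t_begin, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(report)
}
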