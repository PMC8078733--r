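#' Run the EMT-spectrum pipeline from a configuration
#'
#' Orchestrates the full analysis from a single configuration (a YAML file
#' path or an equivalent nested list): obtain counts (simulate, or load an
#' MTX directory written by [write_emt_counts]), QC-filter, normalize,
#' select cancer cells, diffusion-smooth the signature expression, cluster,
#' score and classify, then write the outputs and a run report. Reruns with
#' the same configuration and seed are bit-identical.
#'
#' Configuration keys (all optional unless noted):
#' \describe{
#'   \item{seed}{global integer seed (default 1).}
#'   \item{simulate}{list of [simulate_emt_population] arguments; used when
#'     no `counts_dir` is given.}
#'   \item{counts_dir}{directory with `matrix.mtx` + sidecars.}
#'   \item{signature_path}{signature TSV (required with `counts_dir`;
#'     simulated runs use the generator's own signature).}
#'   \item{ortholog_table}{optional TSV to map the signature before use.}
#'   \item{qc}{list with `min_genes`, `max_genes`, `max_mito_fraction`.}
#'   \item{select}{`"signature"` or `"none"`.}
#'   \item{diffusion}{list with `k`, `decay`, `t`.}
#'   \item{clustering}{list with `resolutions`, `k`, `quality_floor`.}
#'   \item{cutoffs}{list with `epithelial_min`, `mesenchymal_max`,
#'     `pseudocount`.}
#'   \item{sample_rule}{`"pooled"` or `"plurality"`.}
#'   \item{out_dir}{output directory (required); receives `clusters.csv`,
#'     `em_scores.csv`, `proportions.json`, `samples.csv`, `report.json`.}
#' }
#'
#' @param config YAML path or nested list as above.
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_emt_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config must name out_dir", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$counts_dir)) {
    if (!dir.exists(config$counts_dir))
      stop("counts_dir not found: ", config$counts_dir, call. = FALSE)
    if (is.null(config$signature_path))
      stop("signature_path is required with counts_dir", call. = FALSE)
    if (!file.exists(config$signature_path))
      stop("signature file not found: ", config$signature_path,
           call. = FALSE)
    counts <- read_emt_counts(config$counts_dir)
    signature <- read_emt_signature(config$signature_path)
    input_mode <- "loaded"
  } else {
    sim_args <- if (is.null(config$simulate)) list() else config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    pop <- do.call(simulate_emt_population, sim_args)
    counts <- pop$counts
    signature <- pop$signature
    input_mode <- "simulated"
  }
  if (!is.null(config$ortholog_table)) {
    if (!file.exists(config$ortholog_table))
      stop("ortholog table not found: ", config$ortholog_table,
           call. = FALSE)
    signature <- map_orthologs(signature,
                               table = config$ortholog_table)$signature
  }

  # --- parameters ---------------------------------------------------------
  qc <- do.call(qc_thresholds, as.list(config$qc))
  dif <- utils::modifyList(list(k = 15, decay = 2, t = 3),
                           as.list(config$diffusion))
  clu <- utils::modifyList(list(resolutions = c(0.25, 0.5, 1, 2), k = 20,
                                quality_floor = 0.9),
                           as.list(config$clustering))
  cut <- do.call(phenotype_cutoffs, as.list(config$cutoffs))
  select <- if (is.null(config$select)) "none" else config$select
  sample_rule <- if (is.null(config$sample_rule)) "pooled"
                 else config$sample_rule

  fit <- emt_spectrum(counts, signature,
                      qc = qc, select = select,
                      k_diffusion = dif$k, decay = dif$decay, t = dif$t,
                      resolutions = unlist(clu$resolutions),
                      k_cluster = clu$k, quality_floor = clu$quality_floor,
                      cutoffs = cut, sample_rule = sample_rule, seed = seed)

  # --- outputs ------------------------------------------------------------
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(
    data.frame(cell_id = names(fit$assignment$cluster),
               cluster = fit$assignment$cluster,
               em_class = as.character(fit$cell_class),
               sample = fit$sample_labels),
    file.path(out_dir, "clusters.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(fit$clusters),
                   file.path(out_dir, "em_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(overall = as.list(fit$proportions["overall", ]),
         per_sample = apply(
           fit$proportions[setdiff(rownames(fit$proportions), "overall"), ,
                           drop = FALSE], 1L, as.list),
         seed = seed),
    file.path(out_dir, "proportions.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$samples, file.path(out_dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)

  n_input <- if (is.null(fit$qc_report)) fit$selection$n_input
             else fit$qc_report$n_input
  report <- list(
    seed = seed,
    input_mode = input_mode,
    stages = list(
      input = list(n_cells = n_input),
      qc = fit$qc_report,
      selection = fit$selection,
      diffusion = dif,
      clustering = list(resolution = fit$resolution,
                        rule = fit$resolution_rule,
                        n_clusters = nrow(fit$clusters),
                        log = fit$resolution_log)
    ),
    cutoffs = unclass(fit$cutoffs),
    discovered_signature_genes = fit$discovered_count,
    proportions = as.list(fit$proportions["overall", ]),
    package_version = as.character(utils::packageVersion("emtspectrum"))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
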