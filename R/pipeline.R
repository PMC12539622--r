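# End-to-end orchestration: simulate (or ingest) -> track -> diffusion ->
# condensates, and simulate-decay (or ingest) -> normalize ->
# destabilization -> classification. Every run writes its stage outputs
# plus a JSON manifest capturing config, seed and summary statistics.

#' Assemble a run configuration
#'
#' A single flat configuration with per-stage blocks, so every analysis
#' parameter (0.6/0.9 um linking rules, 0.08 um^2/s immobile threshold,
#' 75/100 nm eps, 50/100 localization and 0.0015 nm^-2 density filters) is
#' auditable in one place. Any block may be omitted to use defaults.
#'
#' @param seed integer master seed; all stochastic stages derive from it.
#' @param population,acquisition argument lists for [population_config()] /
#'   [acquisition_config()].
#' @param tracking arguments for [tracking_params()].
#' @param diffusion list with `frame_interval`, `min_steps`, `threshold`,
#'   `inclusive`, `estimator`.
#' @param condensates arguments for [cluster_params()] (e.g.
#'   `preset = "hfq"`), plus optional `summary_mode`.
#' @param decay arguments for [decay_sim_config()] plus `reference_gene`
#'   and [de_thresholds()] fields.
#' @param localizations_csv,counts_tsv,design_tsv optional paths to ingest
#'   real data instead of simulating.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       population = list(), acquisition = list(),
                       tracking = list(), diffusion = list(),
                       condensates = list(preset = "hfq"),
                       decay = list(),
                       localizations_csv = NULL, counts_tsv = NULL,
                       design_tsv = NULL) {
  check_count(seed, "seed")
  structure(list(seed = as.integer(seed), population = population,
                 acquisition = acquisition, tracking = tracking,
                 diffusion = diffusion, condensates = condensates,
                 decay = decay, localizations_csv = localizations_csv,
                 counts_tsv = counts_tsv, design_tsv = design_tsv),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of [run_config()].
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

default_arg <- function(block, name, default) {
  if (!is.null(block[[name]])) block[[name]] else default
}

write_manifest <- function(outdir, manifest) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' Run the PALM analysis pipeline
#'
#' simulate (or ingest a localization CSV) -> link trajectories ->
#' per-trajectory D* and %H_IM -> condensate detection and per-cell
#' summaries. All stage outputs are written under `outdir` together with a
#' `manifest.json` recording the configuration, seed and summary
#' statistics. A stage failure leaves a `FAILED` marker naming the stage.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory (created).
#' @return the manifest, invisibly a list.
#' @export
run_palm_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "run_config"))
  # validate all parameter blocks before any stage runs
  pop <- do.call(population_config,
                 c(cfg$population,
                   if (is.null(cfg$population$seed)) list(seed = cfg$seed)))
  acq <- do.call(acquisition_config, cfg$acquisition)
  tp <- do.call(tracking_params, cfg$tracking)
  cl <- do.call(cluster_params,
                cfg$condensates[setdiff(names(cfg$condensates),
                                        "summary_mode")])
  frame_interval <- default_arg(cfg$diffusion, "frame_interval",
                                acq$frame_interval)
  min_steps <- default_arg(cfg$diffusion, "min_steps", 4)
  threshold <- default_arg(cfg$diffusion, "threshold", 0.08)
  inclusive <- default_arg(cfg$diffusion, "inclusive", TRUE)
  estimator <- default_arg(cfg$diffusion, "estimator", "lag1")
  summary_mode <- default_arg(cfg$condensates, "summary_mode", "per_cell")

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  manifest <- list(pipeline = "palm", seed = cfg$seed,
                   config = unclass(cfg))
  tryCatch({
    if (is.null(cfg$localizations_csv)) {
      cells <- simulate_cells(pop, acq)
      sim <- simulate_movie(cells, pop, acq)
      locs <- sim$localizations
      write_localizations(locs, file.path(outdir, "localizations.csv"))
      write_ground_truth(sim$ground_truth,
                         file.path(outdir, "ground_truth"))
    } else {
      locs <- read_localizations(cfg$localizations_csv)
      cells <- NULL
    }

    stage <- "track"
    trajs <- link_localizations(locs, tp)
    write_trajectories(trajs, file.path(outdir, "trajectories.csv"))

    stage <- "diffusion"
    recs <- compute_diffusion(trajs, frame_interval, min_steps, estimator)
    utils::write.csv(recs, file.path(outdir, "diffusion.csv"),
                     row.names = FALSE)
    h_im <- if (nrow(recs)) {
      immobile_fraction(recs, threshold, inclusive)
    } else NA_real_

    stage <- "condensates"
    cond <- detect_condensates(locs, cl)
    if (!is.null(cells)) cond <- assign_to_cells(cond, cells)
    utils::write.csv(cond, file.path(outdir, "condensates.csv"),
                     row.names = FALSE)
    frac <- if (!is.null(cells)) {
      fraction_cells_with_condensates(cond, cells, summary_mode)
    } else NA_real_
    occ <- if (nrow(locs)) {
      localization_condensate_occupancy(cond, nrow(locs))
    } else NA_real_

    manifest$summary <- list(
      n_localizations = nrow(locs),
      n_trajectories = nrow(recs),
      H_IM_percent = h_im,
      n_condensates = sum(cond$passes_filter),
      fraction_cells_with_condensates = frac,
      localization_occupancy = occ)
    write_manifest(outdir, manifest)
    invisible(manifest)
  }, error = function(e) {
    writeLines(c(stage, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the transcription-shutoff decay pipeline
#'
#' simulate (or ingest counts + design TSVs) -> reference normalization ->
#' per-gene log2 destabilization -> optional stability classification of
#' externally supplied (log2fc, padj) pairs.
#'
#' @param cfg a [run_config()]; the `decay` block supplies the simulator
#'   and analysis parameters (`reference_gene`, `padj_cutoff`,
#'   `min_abs_log2fc`, `aggregate`, `log_order`).
#' @param outdir output directory (created).
#' @param de_stats optional data.frame `gene_id`, `log2fc`, `padj` for
#'   stability classification.
#' @return the manifest, invisibly a list.
#' @export
run_decay_pipeline <- function(cfg, outdir, de_stats = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dblock <- cfg$decay
  analysis_keys <- c("reference_gene", "padj_cutoff", "min_abs_log2fc",
                     "aggregate", "log_order")
  sim_args <- dblock[setdiff(names(dblock), analysis_keys)]
  reference <- default_arg(dblock, "reference_gene",
                           default_arg(sim_args, "reference_gene_id",
                                       "ssrS"))
  th <- de_thresholds(default_arg(dblock, "padj_cutoff", 0.05),
                      default_arg(dblock, "min_abs_log2fc", 1))
  aggregate <- default_arg(dblock, "aggregate", "mean")
  log_order <- default_arg(dblock, "log_order", "mean_then_log")

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate_decay"
  manifest <- list(pipeline = "decay", seed = cfg$seed,
                   config = unclass(cfg))
  tryCatch({
    if (is.null(cfg$counts_tsv)) {
      dcfg <- do.call(decay_sim_config,
                      c(sim_args,
                        if (is.null(sim_args$seed)) list(seed = cfg$seed)))
      sim <- simulate_decay_counts(dcfg)
      counts <- sim$counts; design <- sim$design
      write_counts_tsv(counts, file.path(outdir, "counts.tsv"))
      write_design_tsv(design, file.path(outdir, "design.tsv"))
    } else {
      counts <- read_counts_tsv(cfg$counts_tsv)
      design <- read_design_tsv(cfg$design_tsv)
    }

    stage <- "normalize"
    normalized <- normalize_to_reference(counts, reference)

    stage <- "destabilization"
    destab <- log2_destabilization(normalized, design, aggregate,
                                   log_order)
    utils::write.table(destab, file.path(outdir, "destabilization.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    if (!is.null(de_stats)) {
      stage <- "classify"
      cls <- cbind(gene_id = de_stats$gene_id,
                   classify_stability(de_stats$log2fc, de_stats$padj, th))
      utils::write.table(cls, file.path(outdir, "classification.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      manifest$summary$class_counts <- as.list(table(cls$class))
    }

    final <- destab[destab$time_min == max(destab$time_min) &
                      destab$gene_id != reference, , drop = FALSE]
    manifest$summary$n_genes <- nrow(counts)
    manifest$summary$n_samples <- ncol(counts)
    manifest$summary$median_log2_destabilization_final <-
      stats::median(final$log2_destabilization, na.rm = TRUE)
    write_manifest(outdir, manifest)
    invisible(manifest)
  }, error = function(e) {
    writeLines(c(stage, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
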