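# Synthetic rifampicin-chase (transcription shutoff) count matrices:
# per-gene exponential decay, a stable reference gene, Poisson sampling,
# sample-specific library sizes.

#' Configuration for a synthetic transcription-shutoff count matrix
#'
#' The forward model: count(g, sample at t, rep) ~ Poisson(
#' size_factor(sample) * baseline(g) * 2^(-t / half_life(g))). The reference
#' gene (6S RNA / ssrS by default) has infinite half-life, i.e. stays at its
#' baseline, matching its role as a rifampicin-stable normalizer.
#'
#' @param n_genes number of decaying genes (the reference gene is added on
#'   top of these).
#' @param reference_gene_id label of the stable reference (default "ssrS").
#' @param baseline_counts expected count at t = 0; scalar or length
#'   `n_genes` vector (the reference baseline may be given separately).
#' @param reference_baseline expected reference-gene count at every time.
#' @param half_lives per-gene half-life in minutes; scalar or length
#'   `n_genes`; `Inf` allowed (stable gene).
#' @param timepoints sampling times in minutes after rifampicin addition.
#' @param library_size_factors per-sample multiplier; scalar or one value
#'   per sample (samples ordered time-major, replicate-minor).
#' @param n_replicates replicates per timepoint.
#' @param genotype condition label stored in the design (default "WT").
#' @param seed integer seed.
#' @return a `decay_sim_config` list.
#' @export
decay_sim_config <- function(n_genes = 20,
                             reference_gene_id = "ssrS",
                             baseline_counts = 5000,
                             reference_baseline = 50000,
                             half_lives = 30,
                             timepoints = c(0, 15, 60),
                             library_size_factors = 1,
                             n_replicates = 3,
                             genotype = "WT",
                             seed = 1L) {
  check_count(n_genes, "n_genes", lower = 1)
  stop_if(!is.character(reference_gene_id) || length(reference_gene_id) != 1,
          "'reference_gene_id' must be a single label")
  stop_if(any(!is.finite(baseline_counts)) || any(baseline_counts <= 0),
          "'baseline_counts' must be positive and finite")
  check_number(reference_baseline, "reference_baseline",
               lower = .Machine$double.xmin)
  stop_if(any(is.na(half_lives)) || any(half_lives <= 0),
          "'half_lives' must be > 0 (Inf allowed)")
  stop_if(any(timepoints < 0), "'timepoints' must be >= 0")
  stop_if(any(library_size_factors <= 0),
          "'library_size_factors' must be > 0")
  check_count(n_replicates, "n_replicates", lower = 1)
  check_count(seed, "seed")
  n_samples <- length(timepoints) * n_replicates
  stop_if(!length(library_size_factors) %in% c(1L, n_samples),
          "'library_size_factors' must be scalar or one per sample (%d)",
          n_samples)
  structure(list(n_genes = as.integer(n_genes),
                 reference_gene_id = reference_gene_id,
                 baseline_counts = rep_len(baseline_counts, n_genes),
                 reference_baseline = reference_baseline,
                 half_lives = rep_len(half_lives, n_genes),
                 timepoints = timepoints,
                 library_size_factors = rep_len(library_size_factors,
                                                n_samples),
                 n_replicates = as.integer(n_replicates),
                 genotype = genotype,
                 seed = as.integer(seed)),
            class = "decay_sim_config")
}

#' Simulate a transcription-shutoff count matrix
#'
#' @param cfg a [decay_sim_config()].
#' @return list with `counts` (integer matrix, genes x samples; the
#'   reference gene is the first row), `design` (data.frame `sample_id`,
#'   `genotype`, `time_min`, `replicate`), `truth` (data.frame `gene_id`,
#'   `baseline`, `half_life_min`), and `config`.
#' @export
simulate_decay_counts <- function(cfg) {
  stopifnot(inherits(cfg, "decay_sim_config"))
  genes <- c(cfg$reference_gene_id,
             sprintf("gene_%03d", seq_len(cfg$n_genes)))
  baseline <- c(cfg$reference_baseline, cfg$baseline_counts)
  hl <- c(Inf, cfg$half_lives)
  design <- data.frame(
    sample_id = sprintf("%s_t%03d_r%d",
                        cfg$genotype,
                        rep(cfg$timepoints, each = cfg$n_replicates),
                        rep(seq_len(cfg$n_replicates),
                            times = length(cfg$timepoints))),
    genotype = cfg$genotype,
    time_min = rep(cfg$timepoints, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates),
                    times = length(cfg$timepoints)))
  withr::with_seed(cfg$seed, {
    # expected count: size_factor * baseline * 2^(-t / half_life)
    decay <- 2^(-outer(1 / hl, design$time_min))     # genes x samples
    mu <- baseline * decay *
      rep(cfg$library_size_factors, each = length(genes))
    counts <- matrix(stats::rpois(length(mu), mu), nrow = length(genes),
                     dimnames = list(genes, design$sample_id))
  })
  list(counts = counts, design = design,
       truth = data.frame(gene_id = genes, baseline = baseline,
                          half_life_min = hl),
       config = cfg)
}

#' Read / write counts and design tables
#'
#' Counts TSV: first column `gene_id`, remaining columns sample IDs.
#' Design TSV: `sample_id`, `genotype`, `time_min`, `replicate`.
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param design design data.frame.
#' @param path file path.
#' @return readers return the matrix / data.frame.
#' @export
write_counts_tsv <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_counts_tsv
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path)
  stop_if(!all(c("sample_id", "time_min", "replicate") %in% names(d)),
          "design TSV must have columns sample_id, time_min, replicate")
  d
}
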