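# Transcription-shutoff (rifampicin-chase) stability analysis:
# reference-gene normalization, per-gene log2 destabilization, and
# fold-change / adjusted-p stability classification.

#' Normalize counts to a stable reference gene
#'
#' Each sample's counts are divided by that sample's count for the
#' reference gene (6S RNA / ssrS by default), so the reference row is 1 in
#' every sample and normalized values are invariant to per-sample library
#' size.
#'
#' @param counts matrix (genes x samples) with gene rownames.
#' @param reference_gene reference gene id (default "ssrS").
#' @return numeric matrix of normalized abundances.
#' @export
normalize_to_reference <- function(counts, reference_gene = "ssrS") {
  stop_if(!reference_gene %in% rownames(counts),
          "reference gene '%s' not found in the count matrix",
          reference_gene)
  ref <- counts[reference_gene, ]
  zero <- which(ref <= 0)
  stop_if(length(zero) > 0,
          "reference gene '%s' has zero counts in sample(s): %s",
          reference_gene,
          paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, ref, "/")
}

#' Per-gene log2 destabilization after transcription shutoff
#'
#' For each gene, genotype and timepoint, the reference-normalized
#' abundance is averaged over replicates and expressed as
#' log2(abundance at t / abundance at t = 0). Zero abundance at a later
#' timepoint yields -Inf, flagged rather than dropped.
#'
#' @param normalized matrix from [normalize_to_reference()].
#' @param design data.frame with `sample_id`, `genotype`, `time_min`,
#'   `replicate` (sample_id must match the matrix columns).
#' @param aggregate replicate aggregation before the log ratio:
#'   `"mean"` (default) or `"geometric"` mean.
#' @param log_order `"mean_then_log"` (default) aggregates replicates then
#'   takes one log ratio; `"log_then_mean"` averages per-replicate log
#'   ratios (replicates paired by number).
#' @return long data.frame: `gene_id`, `genotype`, `time_min`,
#'   `normalized_mean`, `log2_destabilization`, `flag` ("" or
#'   "zero_abundance").
#' @export
log2_destabilization <- function(normalized, design,
                                 aggregate = c("mean", "geometric"),
                                 log_order = c("mean_then_log",
                                               "log_then_mean")) {
  aggregate <- match.arg(aggregate)
  log_order <- match.arg(log_order)
  stop_if(!all(design$sample_id %in% colnames(normalized)),
          "design sample_id(s) missing from the normalized matrix")
  stop_if(!0 %in% design$time_min,
          "design must include the t = 0 baseline samples")
  agg_fun <- if (aggregate == "mean") mean else
    function(v) exp(mean(log(v)))
  out <- list()
  for (gt in unique(design$genotype)) {
    dgt <- design[design$genotype == gt, , drop = FALSE]
    times <- sort(unique(dgt$time_min))
    base_cols <- dgt$sample_id[dgt$time_min == 0]
    stop_if(length(base_cols) == 0,
            "genotype '%s' has no t = 0 samples", gt)
    for (g in rownames(normalized)) {
      base_vals <- normalized[g, base_cols]
      base_mean <- agg_fun(base_vals)
      for (t in times) {
        cols <- dgt$sample_id[dgt$time_min == t]
        vals <- normalized[g, cols]
        m <- agg_fun(vals)
        if (base_mean <= 0) {
          l2 <- NA_real_; flag <- "zero_baseline"
        } else if (log_order == "mean_then_log") {
          l2 <- log2(m / base_mean)
          flag <- if (m <= 0) "zero_abundance" else ""
        } else {
          reps <- dgt$replicate[match(cols, dgt$sample_id)]
          base_reps <- dgt$replicate[match(base_cols, dgt$sample_id)]
          ratio <- vals / base_vals[match(reps, base_reps)]
          l2 <- mean(log2(ratio))
          flag <- if (any(ratio <= 0)) "zero_abundance" else ""
        }
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, genotype = gt, time_min = t,
          normalized_mean = m, log2_destabilization = l2, flag = flag)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Validated wrapper over the standard step-up procedure.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  stop_if(any(!is.na(p) & (p < 0 | p > 1)), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Stability thresholds for differential-abundance classification
#' @param padj_cutoff adjusted-p significance gate (default 0.05).
#' @param min_abs_log2fc magnitude defining full vs partial change in log2
#'   units (default 1, i.e. two-fold).
#' @return a `de_thresholds` list.
#' @export
de_thresholds <- function(padj_cutoff = 0.05, min_abs_log2fc = 1) {
  check_number(padj_cutoff, "padj_cutoff", lower = 1e-300, upper = 1)
  stop_if(padj_cutoff >= 1, "'padj_cutoff' must be < 1")
  check_number(min_abs_log2fc, "min_abs_log2fc", lower = 0)
  structure(list(padj_cutoff = padj_cutoff,
                 min_abs_log2fc = min_abs_log2fc),
            class = "de_thresholds")
}

#' Classify genes by fold change and adjusted p-value
#'
#' Labels: `"down"` (padj < cutoff and log2fc <= -min_abs_log2fc),
#' `"partial_down"` (padj < cutoff and -min_abs_log2fc < log2fc < 0),
#' `"up"` / `"partial_up"` symmetric, otherwise `"ns"`. Missing padj gives
#' `"ns"` with a flag.
#'
#' @param log2fc per-gene log2 fold changes.
#' @param padj per-gene BH-adjusted p-values.
#' @param th a [de_thresholds()].
#' @return data.frame `log2fc`, `padj`, `class`, `flag`.
#' @export
classify_stability <- function(log2fc, padj, th = de_thresholds()) {
  stopifnot(inherits(th, "de_thresholds"), length(log2fc) == length(padj))
  cls <- rep("ns", length(log2fc))
  flag <- ifelse(is.na(padj), "missing_padj", "")
  sig <- !is.na(padj) & padj < th$padj_cutoff & !is.na(log2fc)
  cls[sig & log2fc <= -th$min_abs_log2fc] <- "down"
  cls[sig & log2fc > -th$min_abs_log2fc & log2fc < 0] <- "partial_down"
  cls[sig & log2fc >= th$min_abs_log2fc] <- "up"
  cls[sig & log2fc < th$min_abs_log2fc & log2fc > 0] <- "partial_up"
  data.frame(log2fc = log2fc, padj = padj, class = cls, flag = flag)
}
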