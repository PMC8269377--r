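#' Remove unexpressed and uninformative genes
#'
#' The pre-processing phase of the pipeline: genes whose mean linear-scale
#' expression falls below the given percentile of all gene means are dropped,
#' as are genes with zero variance across samples (which carry no correlation
#' signal and would break downstream Pearson computations).
#'
#' @param mat An [expression_matrix()].
#' @param percentile Percentile in `[0, 100)` of gene mean expression below
#'   which genes are removed.
#' @return The filtered `expression_matrix`.
#' @export
remove_low_expression <- function(mat, percentile = 10) {
  stopifnot(percentile >= 0, percentile < 100)
  lin <- values_linear(mat)
  means <- rowMeans(lin)
  thr <- quantile(means, percentile / 100, names = FALSE)
  vars <- apply(mat$values, 1, stats::var)
  keep <- means >= thr & vars > 0
  if (sum(keep) < 10) {
    stop("insufficient expressed genes after low-expression filtering (",
         sum(keep), " remain)", call. = FALSE)
  }
  expression_matrix(mat$values[keep, , drop = FALSE], mat$scale)
}

.welch_p <- function(a, b) {
  # Welch two-sample t-test on log2 values; degenerate (essentially constant)
  # data falls back to p = 1 when means agree, p = 0 when they differ.
  tryCatch(t.test(a, b)$p.value,
           error = function(e) {
             if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
           })
}

.signed_fc <- function(ratio) ifelse(ratio >= 1, ratio, -1 / ratio)

#' Case/control differential expression
#'
#' Per-gene Welch two-sample t-tests on log2-scale values with
#' Benjamini-Hochberg adjustment across all tested genes. Group means and fold
#' changes are reported on the linear scale; `signed_fc` uses the signed-ratio
#' convention (the ratio when >= 1, otherwise the negated reciprocal).
#'
#' @param mat An [expression_matrix()].
#' @param pheno Phenotype data.frame (see [phenotype_table()]).
#' @param group_a,group_b Group labels compared (`group_a` over `group_b`);
#'   both must have >= 2 samples present in `mat`.
#' @return A data.frame of class `deg_table` with columns `gene`, `mean_case`,
#'   `mean_control`, `log2_fc`, `signed_fc`, `p_value`, `q_value`, `selected`
#'   (all `FALSE` until [select_fc_cutoff()] is applied).
#' @export
differential_expression <- function(mat, pheno, group_a = "case",
                                    group_b = "control") {
  pheno <- pheno[pheno$sample_id %in% sample_ids(mat), , drop = FALSE]
  ids_a <- pheno$sample_id[pheno$group == group_a]
  ids_b <- pheno$sample_id[pheno$group == group_b]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop(sprintf("differential expression needs >= 2 samples per group (%s: %d, %s: %d)",
                 group_a, length(ids_a), group_b, length(ids_b)), call. = FALSE)
  }
  lg <- values_log2(mat)
  lin <- values_linear(mat)
  mean_a <- rowMeans(lin[, ids_a, drop = FALSE])
  mean_b <- rowMeans(lin[, ids_b, drop = FALSE])
  ratio <- ifelse(mean_a == 0 & mean_b == 0, 1, mean_a / mean_b)
  p <- vapply(seq_len(nrow(lg)), function(i) {
    .welch_p(lg[i, ids_a], lg[i, ids_b])
  }, numeric(1))
  out <- data.frame(
    gene = gene_ids(mat),
    mean_case = mean_a,
    mean_control = mean_b,
    log2_fc = log2(ratio),
    signed_fc = .signed_fc(ratio),
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    selected = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Select the fold-change cutoff yielding the target gene count
#'
#' The filtering phase scans linear fold-change cutoffs over
#' `[fc_min, fc_max]` in steps of 0.1. At each cutoff a gene is selected iff
#' `|signed_fc| >= cutoff` and `q_value < fdr_alpha`. The smallest cutoff whose
#' selected count falls inside `[target_gene_min, target_gene_max]` wins; if no
#' cutoff lands in the band, the cutoff with the count closest to the band is
#' used (ties broken toward the smaller cutoff) with a warning. When
#' `cfg$fc_fixed` is set (per-stratum overrides), the scan is bypassed and the
#' fixed cutoff applied directly.
#'
#' @param deg A `deg_table` from [differential_expression()].
#' @param cfg A [swim_config()].
#' @return A list with `cutoff` (linear fold change), `genes` (selected ids)
#'   and `deg` (the table with its `selected` column filled in).
#' @export
select_fc_cutoff <- function(deg, cfg = swim_config()) {
  stopifnot(nrow(deg) > 0)
  passes <- function(theta) abs(deg$signed_fc) >= theta & deg$q_value < cfg$fdr_alpha
  if (!is.null(cfg$fc_fixed)) {
    sel <- passes(cfg$fc_fixed)
    deg$selected <- sel
    return(list(cutoff = cfg$fc_fixed, genes = deg$gene[sel], deg = deg))
  }
  thetas <- seq(cfg$fc_min, cfg$fc_max, by = 0.1)
  counts <- vapply(thetas, function(th) sum(passes(th)), integer(1))
  if (all(counts == 0)) {
    stop("filtering produced empty network: no gene passes any fold-change cutoff in [",
         cfg$fc_min, ", ", cfg$fc_max, "] at q < ", cfg$fdr_alpha, call. = FALSE)
  }
  in_band <- counts >= cfg$target_gene_min & counts <= cfg$target_gene_max
  if (any(in_band)) {
    idx <- which(in_band)[1]
  } else {
    dist_to_band <- pmax(cfg$target_gene_min - counts,
                         counts - cfg$target_gene_max, 0)
    idx <- which.min(dist_to_band)  # which.min takes the first (smallest theta)
    warning(sprintf(
      "no cutoff reaches %d-%d genes; using cutoff %.1f with %d genes",
      cfg$target_gene_min, cfg$target_gene_max, thetas[idx], counts[idx]),
      call. = FALSE)
  }
  sel <- passes(thetas[idx])
  deg$selected <- sel
  list(cutoff = thetas[idx], genes = deg$gene[sel], deg = deg)
}

#' Fold-change histogram counts
#'
#' Bin counts of log2 fold changes, flagged by selection status, for rendering
#' the filtering-phase histogram.
#'
#' @param deg A `deg_table`.
#' @param binwidth Bin width on the log2 scale.
#' @return A data.frame with columns `bin_low`, `bin_high`, `count`,
#'   `count_selected`.
#' @export
fc_histogram <- function(deg, binwidth = 0.25) {
  lfc <- deg$log2_fc
  lo <- floor(min(lfc) / binwidth) * binwidth
  hi <- ceiling(max(lfc) / binwidth) * binwidth
  breaks <- seq(lo, hi + binwidth, by = binwidth)
  bin <- cut(lfc, breaks, include.lowest = TRUE, right = FALSE)
  data.frame(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1],
    count = as.integer(table(bin)),
    count_selected = as.integer(table(factor(bin[deg$selected],
                                             levels = levels(bin)))),
    stringsAsFactors = FALSE
  )
}
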