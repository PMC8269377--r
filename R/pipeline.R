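.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full switch-gene pipeline
#'
#' Executes the stages in order — low-expression pre-filtering, case/control
#' differential expression, fold-change cutoff selection, co-expression network
#' construction, k-means community detection, heat cartography, node
#' classification, switch-gene extraction and (optionally) robustness curves —
#' failing fast with stage-named errors.
#'
#' @param mat An [expression_matrix()].
#' @param pheno Phenotype data.frame with >= 2 case and >= 2 control samples
#'   present in `mat`.
#' @param cfg A [swim_config()].
#' @param robustness Compute robustness curves (the slowest stage)?
#' @return An object of class `pipeline_result`: list with `config`, `deg`
#'   (the `deg_table`), `fc_cutoff`, `network`, `network_stats`, `partition`,
#'   `cartography`, `switch_genes`, `robustness` (or `NULL`) and `provenance`
#'   (seed, input/config hashes, timestamp).
#' @export
run_pipeline <- function(mat, pheno, cfg = swim_config(), robustness = TRUE) {
  .stage("prefilter", {
    pheno_in <- pheno[pheno$sample_id %in% sample_ids(mat), , drop = FALSE]
    n_case <- sum(pheno_in$group == "case")
    n_control <- sum(pheno_in$group == "control")
    if (n_case < 2 || n_control < 2) {
      stop(sprintf("need >= 2 case and >= 2 control samples (got %d case, %d control)",
                   n_case, n_control))
    }
  })
  filtered <- .stage("prefilter", remove_low_expression(mat, cfg$low_expr_percentile))
  deg <- .stage("prefilter", differential_expression(filtered, pheno))
  cut <- .stage("prefilter", select_fc_cutoff(deg, cfg))
  net <- .stage("network", build_network(filtered, cut$genes, cfg$corr_threshold))
  part <- .stage("swim", cluster_expression(filtered, net$nodes, cfg))
  cart <- .stage("swim", {
    classify_nodes(compute_cartography(net, part), cfg)
  })
  switch_genes <- .stage("swim", extract_switch_genes(cart))
  rob <- if (robustness) {
    .stage("robustness",
           robustness_analysis(net, cart, step = cfg$robustness_step,
                               reps = cfg$robustness_reps, seed = cfg$seed))
  } else NULL
  structure(
    list(
      config = cfg,
      deg = cut$deg,
      fc_cutoff = cut$cutoff,
      network = net,
      network_stats = network_stats(net),
      partition = part,
      cartography = cart,
      switch_genes = switch_genes,
      robustness = rob,
      provenance = list(
        seed = cfg$seed,
        input_hash = rlang::hash(list(mat$values, mat$scale, pheno)),
        config_hash = rlang::hash(unclass(cfg)),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result: %d genes selected at fold change %.1f, %d modules (k-means),\n  %d switch genes: %s\n",
    sum(x$deg$selected), x$fc_cutoff, x$partition$k, length(x$switch_genes),
    paste(utils::head(x$switch_genes, 8), collapse = ", ")))
  invisible(x)
}

#' Deterministic JSON-ready summary of a pipeline run
#'
#' Everything needed to audit a run: configuration, stage sizes, chosen
#' cutoff and community count, switch genes and provenance hashes. Excludes
#' wall-clock timestamps so that identical input + seed yields byte-identical
#' JSON.
#'
#' @param result A `pipeline_result`.
#' @return A nested list suitable for [jsonlite::write_json()].
#' @export
pipeline_summary <- function(result) {
  list(
    seed = result$provenance$seed,
    input_hash = result$provenance$input_hash,
    config_hash = result$provenance$config_hash,
    n_genes_tested = nrow(result$deg),
    fc_cutoff = result$fc_cutoff,
    n_genes_selected = sum(result$deg$selected),
    network = result$network_stats,
    k_modules = result$partition$k,
    sse_trace = as.list(result$partition$sse_trace),
    n_switch_genes = length(result$switch_genes),
    switch_genes = as.list(result$switch_genes)
  )
}

#' Write the JSON run summary
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_summary <- function(result, path) {
  jsonlite::write_json(pipeline_summary(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Sex-stratified pipeline runs
#'
#' Runs the full pipeline independently on the male and the female samples.
#' Per-stratum fold-change cutoffs can be fixed with `fc_override`, bypassing
#' the adaptive cutoff scan (the published per-sex analyses report fixed
#' cutoffs, e.g. 1.5 for males and 2.5 for females, or 1.2 for both).
#'
#' @param mat An [expression_matrix()].
#' @param pheno Phenotype data.frame; each stratum must retain >= 2 case and
#'   >= 2 control samples.
#' @param cfg A [swim_config()] shared by both strata.
#' @param fc_override Named numeric vector of fixed linear fold-change
#'   cutoffs: names among `"M"`, `"F"` (per stratum) or `"all"` (both).
#'   `NULL` keeps the adaptive scan.
#' @param robustness Passed through to [run_pipeline()].
#' @return A named list (`M`, `F`) of `pipeline_result` objects.
#' @export
stratify_and_run <- function(mat, pheno, cfg = swim_config(),
                             fc_override = NULL, robustness = FALSE) {
  res <- list()
  for (sex in c("M", "F")) {
    ids <- pheno$sample_id[pheno$sex == sex & pheno$sample_id %in% sample_ids(mat)]
    sub_pheno <- pheno[pheno$sample_id %in% ids, , drop = FALSE]
    n_case <- sum(sub_pheno$group == "case")
    n_control <- sum(sub_pheno$group == "control")
    if (n_case < 2 || n_control < 2) {
      stop(sprintf("stratum %s: need >= 2 case and >= 2 control samples (got %d case, %d control)",
                   sex, n_case, n_control), call. = FALSE)
    }
    cfg_s <- cfg
    if (!is.null(fc_override)) {
      ov <- if (sex %in% names(fc_override)) fc_override[[sex]]
            else if ("all" %in% names(fc_override)) fc_override[["all"]]
            else NULL
      cfg_s$fc_fixed <- ov
    }
    res[[sex]] <- run_pipeline(subset_expression(mat, samples = ids),
                               sub_pheno, cfg_s, robustness = robustness)
  }
  res
}
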