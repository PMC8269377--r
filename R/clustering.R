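#' Community detection by replicated k-means with scree selection
#'
#' Clusters z-scored gene expression profiles with k-means for every `k` in
#' `[cfg$k_min, cfg$k_max]`. Each `k` is run with `cfg$kmeans_replicates`
#' seeded random restarts plus one deterministic warm start derived from the
#' best `k - 1` solution (its centroids plus the profile farthest from its
#' assigned centroid), which guarantees the minimal-SSE trace is non-increasing
#' in `k`. The restart with the lowest sum of squared errors (SSE) wins. The
#' number of communities is chosen by the scree elbow rule: the smallest `k`
#' whose relative SSE drop to `k + 1` falls below 10%; if no drop falls below
#' the tolerance, `k_max` is used.
#'
#' @param mat An [expression_matrix()].
#' @param genes Node ids to cluster (profiles taken from `mat`, log2 scale,
#'   z-scored per gene). Must number at least `cfg$k_max`.
#' @param cfg A [swim_config()].
#' @return An object of class `community_partition`: list with `assignment`
#'   (named integer vector gene -> module), `k`, `sse_trace` (named numeric,
#'   minimal SSE per `k`), `replicates`, `seed`.
#' @export
cluster_expression <- function(mat, genes, cfg = swim_config()) {
  if (cfg$k_min < 2) stop("k_min must be >= 2", call. = FALSE)
  if (length(genes) < cfg$k_max) {
    stop(sprintf("need at least k_max = %d genes to cluster (got %d)",
                 cfg$k_max, length(genes)), call. = FALSE)
  }
  lg <- values_log2(mat)[genes, , drop = FALSE]
  x <- t(apply(lg, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  rownames(x) <- genes

  ks <- cfg$k_min:cfg$k_max
  fits <- vector("list", length(ks))
  sse <- setNames(rep(NA_real_, length(ks)), ks)
  withr::with_seed(cfg$seed, {
    prev_fit <- NULL
    for (i in seq_along(ks)) {
      k <- ks[i]
      best <- NULL
      for (rep in seq_len(cfg$kmeans_replicates)) {
        fit <- tryCatch(
          suppressWarnings(kmeans(x, centers = k, iter.max = 100L, nstart = 1L)),
          error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
          best <- fit
        }
      }
      if (!is.null(prev_fit)) {
        # warm start: previous centroids + the worst-fit profile as a new one
        d2 <- rowSums((x - prev_fit$centers[prev_fit$cluster, , drop = FALSE])^2)
        centers <- rbind(prev_fit$centers, x[which.max(d2), ])
        fit <- tryCatch(
          suppressWarnings(kmeans(x, centers = centers, iter.max = 100L)),
          error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
          best <- fit
        }
      }
      if (is.null(best)) {
        stop(sprintf("k-means failed for every restart at k = %d", k),
             call. = FALSE)
      }
      fits[[i]] <- best
      sse[i] <- best$tot.withinss
      prev_fit <- best
    }
  })

  # scree elbow: smallest k whose relative drop to k + 1 is below 10%
  chosen <- cfg$k_max
  for (i in seq_len(length(ks) - 1)) {
    drop <- if (sse[i] <= 0) 0 else (sse[i] - sse[i + 1]) / sse[i]
    if (drop < 0.10) {
      chosen <- ks[i]
      break
    }
  }
  fit <- fits[[match(chosen, ks)]]
  assignment <- setNames(as.integer(fit$cluster), genes)
  structure(
    list(assignment = assignment, k = as.integer(chosen), sse_trace = sse,
         replicates = cfg$kmeans_replicates, seed = cfg$seed),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d genes in %d modules (k-means, %d replicates)\n",
              length(x$assignment), x$k, x$replicates))
  invisible(x)
}
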