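#' Average shortest path of a network
#'
#' Unweighted mean of shortest-path lengths over all connected, unordered node
#' pairs within the largest connected component.
#'
#' @param net A `coexpression_network` or an igraph graph.
#' @return A numeric scalar; 0 (with a warning) when the largest component has
#'   a single node.
#' @export
average_shortest_path <- function(net) {
  g <- if (inherits(net, "coexpression_network")) as_igraph(net) else net
  if (igraph::vcount(g) < 2) {
    stop("average shortest path needs >= 2 nodes", call. = FALSE)
  }
  comp <- igraph::components(g)
  if (max(comp$csize) < 2) {
    warning("largest connected component has a single node; returning 0",
            call. = FALSE)
    return(0)
  }
  biggest <- which.max(comp$csize)
  lcc <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  igraph::mean_distance(lcc, directed = FALSE, weights = NA)
}

.removal_order_class <- function(cart, members) {
  # class members by descending degree (ties by id), then the rest randomly
  m <- cart[cart$gene %in% members, , drop = FALSE]
  first <- m$gene[order(-m$degree, m$gene)]
  rest <- sample(setdiff(cart$gene, members))
  c(first, rest)
}

#' Network robustness under targeted node removal
#'
#' Tracks the average shortest path of the network as nodes are removed, for
#' five removal strategies: `date`, `party`, `fight_club` (members of that hub
#' class first, in descending degree), `switch` (switch genes first, descending
#' degree), and `random` (uniform shuffles averaged over `reps` replicates).
#' After a class is exhausted, removal continues over the remaining nodes in
#' seeded random order. Removal proceeds in steps of `step` (a fraction of the
#' node count) until half the nodes are gone, or until fewer than 2 nodes
#' remain.
#'
#' @param net A `coexpression_network`.
#' @param cart A classified `node_cartography` for `net`.
#' @param step Removal step as a fraction of nodes, in (0, 0.1].
#' @param reps Number of random-removal replicates.
#' @param seed Integer seed for removal order randomness.
#' @return A data.frame of class `robustness_curves` with columns `strategy`,
#'   `fraction_removed`, `avg_shortest_path`. Curves at fraction 0 are
#'   identical across strategies.
#' @export
robustness_analysis <- function(net, cart, step = 0.05, reps = 10, seed = 1) {
  stopifnot(step > 0, step <= 0.1)
  if (!"is_switch" %in% colnames(cart)) {
    stop("cartography has not been classified; run classify_nodes() first",
         call. = FALSE)
  }
  g0 <- as_igraph(net)
  n <- length(net$nodes)
  fractions <- seq(0, 0.5, by = step)

  asp_after_removal <- function(order, frac) {
    n_remove <- floor(frac * n)
    if (n - n_remove < 2) return(NA_real_)
    g <- igraph::delete_vertices(g0, order[seq_len(n_remove)])
    suppressWarnings(average_shortest_path(g))
  }
  curve_for_order <- function(order, strategy) {
    asp <- vapply(fractions, function(f) asp_after_removal(order, f), numeric(1))
    keep <- !is.na(asp)
    data.frame(strategy = strategy, fraction_removed = fractions[keep],
               avg_shortest_path = asp[keep], stringsAsFactors = FALSE)
  }

  withr::with_seed(seed, {
    class_members <- list(
      date = cart$gene[cart$hub_class == "date"],
      party = cart$gene[cart$hub_class == "party"],
      fight_club = cart$gene[cart$hub_class == "fight_club"],
      switch = cart$gene[cart$is_switch]
    )
    out <- lapply(names(class_members), function(strat) {
      curve_for_order(.removal_order_class(cart, class_members[[strat]]), strat)
    })
    rand <- lapply(seq_len(reps), function(r) {
      curve_for_order(sample(net$nodes), "random")$avg_shortest_path
    })
    # replicates share the fraction grid because removal counts are equal
    n_pts <- length(rand[[1]])
    rand_mean <- rowMeans(do.call(cbind, lapply(rand, function(v) v[seq_len(n_pts)])))
    out <- c(out, list(data.frame(strategy = "random",
                                  fraction_removed = fractions[seq_len(n_pts)],
                                  avg_shortest_path = rand_mean,
                                  stringsAsFactors = FALSE)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("robustness_curves", "data.frame")
  res
}

#' Biclustering leaf orders for the switch-gene heat map
#'
#' Hierarchical clustering (average linkage, Euclidean distance) of z-scored
#' rows (genes) and z-scored columns (samples), returning the dendrogram leaf
#' orders used to render the switch-gene expression heat map.
#'
#' @param mat An [expression_matrix()], typically restricted to switch genes
#'   via [subset_expression()].
#' @return A list with integer vectors `row_order` and `col_order`.
#' @export
bicluster_order <- function(mat) {
  x <- values_log2(mat)
  zscore <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  row_order <- if (nrow(x) < 2) seq_len(nrow(x)) else {
    zr <- t(apply(x, 1, zscore))
    hclust(dist(zr), method = "average")$order
  }
  col_order <- if (ncol(x) < 2) seq_len(ncol(x)) else {
    zc <- apply(x, 2, zscore)
    if (is.null(dim(zc))) zc <- matrix(zc, nrow = nrow(x))
    hclust(dist(t(zc)), method = "average")$order
  }
  list(row_order = row_order, col_order = col_order)
}
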