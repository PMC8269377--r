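#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `x` query genes inside a set of size `K`
#' when `n` genes are drawn from a universe of size `N`:
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`. Always in (0, 1].
#'
#' @param x Observed overlap.
#' @param K Set size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
ora_pvalue <- function(x, K, n, N) {
  stopifnot(N >= 1, K >= 0, K <= N, n >= 0, n <= N, x >= 0, x <= min(K, n))
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene list against every set of a collection by the upper-tail
#' hypergeometric test, with Benjamini-Hochberg adjustment across all tested
#' sets. Sets are intersected with the universe before testing; sets with no
#' member in the universe are dropped. The natural universe for switch-gene
#' queries is the set of genes surviving low-expression filtering — the
#' measured background.
#'
#' @param query Character vector of query gene ids; must be a subset of
#'   `universe`.
#' @param sets A `gene_set_collection` (see [read_gmt()]).
#' @param universe Character vector of background gene ids.
#' @return A data.frame of class `enrichment_table`, sorted by q then p, with
#'   columns `set`, `description`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `q_value`.
#' @export
ora_enrichment <- function(query, sets, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(query) == 0) stop("empty query", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  members <- lapply(sets, function(s) intersect(s, universe))
  keep <- lengths(members) > 0
  members <- members[keep]
  if (length(members) == 0) {
    stop("no gene set overlaps the universe", call. = FALSE)
  }
  K <- lengths(members)
  x <- vapply(members, function(s) length(intersect(s, query)), integer(1))
  p <- vapply(seq_along(members), function(i) ora_pvalue(x[i], K[i], n, N),
              numeric(1))
  descs <- attr(sets, "descriptions")
  out <- data.frame(
    set = names(members),
    description = if (is.null(descs)) "" else unname(descs[names(members)]),
    overlap = x,
    set_size = unname(K),
    query_size = n,
    universe_size = N,
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q_value, out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

.interactions_igraph <- function(interactions) {
  igraph::graph_from_data_frame(
    interactions[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = unique(c(interactions$source,
                                          interactions$target))))
}

#' Minimum connected subnetwork around seed genes
#'
#' Builds the undirected interaction graph, takes the subgraph induced on the
#' seeds plus their first-neighbor interactors, and returns its largest
#' connected component. Seeds absent from the interaction table are reported
#' separately.
#'
#' @param seeds Character vector of seed gene ids (>= 1 must appear in the
#'   table).
#' @param interactions An `interaction_table`.
#' @return A list of class `subnetwork` with `nodes`, `edges` (data.frame
#'   `source`, `target`, `kind`), `seeds` (seeds retained in the component)
#'   and `missing_seeds`.
#' @export
minimum_connected_subnetwork <- function(seeds, interactions) {
  seeds <- unique(as.character(seeds))
  g <- .interactions_igraph(interactions)
  present <- intersect(seeds, igraph::V(g)$name)
  missing <- setdiff(seeds, present)
  if (length(present) == 0) {
    stop("no seed appears in the interaction table", call. = FALSE)
  }
  nbrs <- unique(c(present, igraph::V(g)$name[unlist(
    igraph::adjacent_vertices(g, present))]))
  sub <- igraph::induced_subgraph(g, nbrs)
  comp <- igraph::components(sub)
  lcc_nodes <- igraph::V(sub)$name[comp$membership == which.max(comp$csize)]
  keep_edges <- interactions$source %in% lcc_nodes &
    interactions$target %in% lcc_nodes
  edges <- as.data.frame(interactions)[keep_edges, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = sort(lcc_nodes), edges = edges,
         seeds = intersect(seeds, lcc_nodes), missing_seeds = missing),
    class = "subnetwork"
  )
}

#' Exact betweenness centrality
#'
#' Unweighted shortest-path betweenness with endpoints excluded, for a
#' `subnetwork`, a `coexpression_network` or an igraph graph.
#'
#' @param graph The graph.
#' @return Named numeric vector of betweenness values (>= 0).
#' @export
betweenness_centrality <- function(graph) {
  g <- if (inherits(graph, "subnetwork")) {
    igraph::graph_from_data_frame(graph$edges[, c("source", "target")],
                                  directed = FALSE,
                                  vertices = data.frame(name = graph$nodes))
  } else if (inherits(graph, "coexpression_network")) {
    as_igraph(graph)
  } else {
    graph
  }
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  setNames(as.numeric(b), igraph::V(g)$name)
}

#' Rank regulators of switch genes by degree and betweenness
#'
#' Restricts the interaction table to the requested kind, extracts the minimum
#' connected subnetwork around the seed (switch) genes, and ranks each
#' regulator by its number of seed targets (degree, descending), breaking ties
#' by betweenness centrality (descending) and then name.
#'
#' @param seeds Character vector of switch gene ids.
#' @param interactions An `interaction_table`.
#' @param kind `"tf"` or `"chemical"`.
#' @return A data.frame of class `ranked_table` with columns `source`,
#'   `degree`, `betweenness`, `rank` (a permutation of 1..m).
#' @export
rank_regulators <- function(seeds, interactions, kind = c("tf", "chemical")) {
  kind <- match.arg(kind)
  sub_int <- interactions[interactions$kind == kind, , drop = FALSE]
  if (nrow(sub_int) == 0) {
    stop("no interactions of kind '", kind, "'", call. = FALSE)
  }
  mcs <- minimum_connected_subnetwork(seeds, sub_int)
  sources <- sort(intersect(unique(sub_int$source), mcs$nodes))
  if (length(sources) == 0) {
    stop("no regulator present in the minimum connected subnetwork",
         call. = FALSE)
  }
  seed_set <- intersect(seeds, mcs$nodes)
  degree <- vapply(sources, function(s) {
    length(intersect(mcs$edges$target[mcs$edges$source == s], seed_set))
  }, integer(1))
  btw <- betweenness_centrality(mcs)
  out <- data.frame(
    source = sources,
    degree = degree,
    betweenness = unname(btw[sources]),
    stringsAsFactors = FALSE
  )
  ord <- order(-out$degree, -out$betweenness, out$source)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranked_table", "data.frame")
  out
}
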