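# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and igraph) so that agreement is a real cross-check.

# adjacency matrix (0/1) and weight matrix from an edge data.frame
oracle_adjacency <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[a, b] <- adj[b, a] <- 1
    w[a, b] <- w[b, a] <- edges$r[i]
  }
  list(adj = adj, w = w)
}

# cartography by explicit loops
oracle_cartography <- function(nodes, edges, assignment) {
  am <- oracle_adjacency(nodes, edges)
  n <- length(nodes)
  deg <- kappa <- numeric(n)
  apcc <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(am$adj[i, ] == 1)
    deg[i] <- length(nbrs)
    kappa[i] <- sum(assignment[nodes[nbrs]] == assignment[nodes[i]])
    apcc[i] <- if (deg[i] == 0) 0 else mean(am$w[i, nbrs])
  }
  zg <- numeric(n)
  for (m in unique(assignment[nodes])) {
    members <- which(assignment[nodes] == m)
    mu <- mean(kappa[members])
    s <- if (length(members) >= 2) sd(kappa[members]) else 0
    zg[members] <- if (is.na(s) || s == 0) 0 else (kappa[members] - mu) / s
  }
  kpi <- ifelse(deg == 0, 0, 1 - (kappa / deg)^2)
  data.frame(gene = nodes, degree = deg, internal_degree = kappa,
             zg = zg, kpi = kpi, apcc = apcc, stringsAsFactors = FALSE)
}

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
oracle_distances <- function(nodes, edges) {
  am <- oracle_adjacency(nodes, edges)$adj
  n <- length(nodes)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[am == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  dimnames(d) <- list(nodes, nodes)
  d
}

# average shortest path over connected pairs inside the largest component
oracle_asp <- function(nodes, edges) {
  d <- oracle_distances(nodes, edges)
  # components from reachability
  comp <- rep(NA_integer_, length(nodes))
  cid <- 0
  for (i in seq_along(nodes)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(d[i, ])] <- cid
    }
  }
  sizes <- table(comp)
  big <- as.integer(names(sizes)[which.max(sizes)])
  idx <- which(comp == big)
  if (length(idx) < 2) return(0)
  vals <- d[idx, idx][upper.tri(d[idx, idx])]
  mean(vals)
}

# betweenness by enumerating all shortest paths (small graphs only)
oracle_betweenness <- function(nodes, edges) {
  d <- oracle_distances(nodes, edges)
  am <- oracle_adjacency(nodes, edges)$adj
  n <- length(nodes)
  # count shortest paths and interior visits via recursive enumeration
  paths_through <- setNames(numeric(n), nodes)
  enumerate <- function(s, t) {
    # returns list of all shortest s->t paths (vectors of node indices)
    if (s == t) return(list(s))
    out <- list()
    for (m in which(am[, t] == 1)) {
      if (is.finite(d[s, m]) && d[s, m] + 1 == d[s, t]) {
        for (p in enumerate(s, m)) out[[length(out) + 1]] <- c(p, t)
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      paths <- enumerate(s, t)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        if (length(interior) > 0) {
          paths_through[interior] <- paths_through[interior] + 1 / length(paths)
        }
      }
    }
  }
  paths_through
}

# exact upper-tail hypergeometric by summation of binomial coefficients
oracle_hyper_p <- function(x, K, n, N) {
  xs <- x:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# a random simple undirected graph with correlation-like edge weights
random_edge_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                        r = runif(sum(keep), -1, 1), stringsAsFactors = FALSE)
    list(nodes = nodes, edges = edges)
  })
}

# small expression fixture: k well-separated profile blobs
blob_expression <- function(n_per_blob = 10, n_blobs = 2, n_samples = 12,
                            sep = 10, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(n_blobs * n_samples, sd = sep), nrow = n_blobs)
    vals <- do.call(rbind, lapply(seq_len(n_blobs), function(b) {
      matrix(rep(centers[b, ], each = n_per_blob), nrow = n_per_blob) +
        rnorm(n_per_blob * n_samples, sd = 1)
    }))
    rownames(vals) <- sprintf("b%d_g%02d", rep(seq_len(n_blobs), each = n_per_blob),
                              rep(seq_len(n_per_blob), n_blobs))
    colnames(vals) <- sprintf("s%02d", seq_len(n_samples))
    expression_matrix(vals, "log2")
  })
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
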