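#' Heat cartography of network nodes
#'
#' Computes, for every node of the co-expression network, the quantities that
#' place it on the heat cartography plane:
#'
#' * `degree` — number of incident edges;
#' * `internal_degree` — edges to nodes of the same community;
#' * `zg` — within-module degree z-score: the internal degree standardized
#'   against the internal degrees of the node's module
#'   (`(kappa - mean) / sd`; 0 when the module spread is zero);
#' * `kpi` — clusterphobic coefficient `1 - (internal_degree / degree)^2`
#'   (0 for isolated nodes); near 1 when most links leave the module;
#' * `apcc` — average Pearson correlation coefficient between the node and its
#'   network neighbors (mean of incident edge correlations; 0 when isolated).
#'
#' @param net A `coexpression_network`.
#' @param part A `community_partition` covering all network nodes.
#' @return A data.frame of class `node_cartography` with one row per node:
#'   `gene`, `module`, `degree`, `internal_degree`, `zg`, `kpi`, `apcc`.
#'   Classification columns are added by [classify_nodes()].
#' @export
compute_cartography <- function(net, part) {
  nodes <- net$nodes
  missing <- setdiff(nodes, names(part$assignment))
  if (length(missing) > 0) {
    stop("nodes missing from partition: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  module <- part$assignment[nodes]
  n <- length(nodes)
  deg <- setNames(integer(n), nodes)
  kappa <- setNames(integer(n), nodes)
  apcc_sum <- setNames(numeric(n), nodes)
  ea <- net$edges$gene_a
  eb <- net$edges$gene_b
  er <- net$edges$r
  for (i in seq_along(ea)) {
    a <- ea[i]; b <- eb[i]
    deg[a] <- deg[a] + 1L
    deg[b] <- deg[b] + 1L
    apcc_sum[a] <- apcc_sum[a] + er[i]
    apcc_sum[b] <- apcc_sum[b] + er[i]
    if (module[a] == module[b]) {
      kappa[a] <- kappa[a] + 1L
      kappa[b] <- kappa[b] + 1L
    }
  }
  zg <- numeric(n)
  for (m in unique(module)) {
    members <- which(module == m)
    mu <- mean(kappa[members])
    s <- if (length(members) >= 2) sd(kappa[members]) else 0
    zg[members] <- if (is.na(s) || s == 0) 0 else (kappa[members] - mu) / s
  }
  kpi <- ifelse(deg == 0, 0, 1 - (kappa / deg)^2)
  apcc <- ifelse(deg == 0, 0, apcc_sum / pmax(deg, 1))
  out <- data.frame(
    gene = nodes,
    module = as.integer(module),
    degree = as.integer(deg),
    internal_degree = as.integer(kappa),
    zg = zg,
    kpi = kpi,
    apcc = apcc,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("node_cartography", "data.frame")
  out
}

.region_of <- function(zg, kpi, switch_zg) {
  # Guimera-Amaral role regions; only R4's role (switch genes) is method-pinned.
  if (zg < switch_zg) {
    if (kpi <= 0.05) "R1"
    else if (kpi <= 0.62) "R2"
    else if (kpi <= 0.80) "R3"
    else "R4"
  } else {
    if (kpi <= 0.30) "R5"
    else if (kpi <= 0.75) "R6"
    else "R7"
  }
}

#' Classify nodes into hub taxonomy, cartography regions and switch genes
#'
#' Applies the printed decision rules to a cartography table:
#'
#' * hub: `zg > cfg$hub_zg` (default 5);
#' * hub class (all non-isolated nodes): `fight_club` if `apcc < 0`, `party`
#'   if `apcc >= cfg$apcc_party`, `date` if `0 <= apcc < cfg$apcc_party`,
#'   `none` for isolated nodes;
#' * region: R1-R4 for `zg < cfg$switch_zg` at Kpi boundaries
#'   0.05 / 0.62 / 0.80, R5-R7 otherwise at boundaries 0.30 / 0.75;
#' * switch gene: `zg < cfg$switch_zg` and `kpi > cfg$switch_kpi` and
#'   `apcc < 0` (defaults 2.5 / 0.8 / 0). Every switch gene is a fight-club
#'   node and falls in region R4.
#'
#' @param cart A `node_cartography` data.frame.
#' @param cfg A [swim_config()].
#' @return The cartography table with columns `hub`, `hub_class`, `region`,
#'   `is_switch` added.
#' @export
classify_nodes <- function(cart, cfg = swim_config()) {
  stopifnot(all(c("zg", "kpi", "apcc", "degree") %in% colnames(cart)))
  cart$hub <- cart$zg > cfg$hub_zg
  cart$hub_class <- ifelse(cart$degree == 0, "none",
                    ifelse(cart$apcc < 0, "fight_club",
                    ifelse(cart$apcc >= cfg$apcc_party, "party", "date")))
  cart$region <- vapply(seq_len(nrow(cart)), function(i) {
    .region_of(cart$zg[i], cart$kpi[i], cfg$switch_zg)
  }, character(1))
  cart$is_switch <- cart$zg < cfg$switch_zg &
    cart$kpi > cfg$switch_kpi &
    cart$apcc < 0
  cart
}

#' Extract the switch-gene list
#'
#' @param cart A classified `node_cartography` (after [classify_nodes()]).
#' @return Character vector of switch-gene ids, ordered by ascending APCC and
#'   then id. May be empty.
#' @export
extract_switch_genes <- function(cart) {
  if (!"is_switch" %in% colnames(cart)) {
    stop("cartography has not been classified; run classify_nodes() first",
         call. = FALSE)
  }
  sw <- cart[cart$is_switch, , drop = FALSE]
  sw$gene[order(sw$apcc, sw$gene)]
}

#' Write a cartography table to TSV
#'
#' @param cart A `node_cartography`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cartography <- function(cart, path) {
  write.table(as.data.frame(cart), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
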