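#' Sex-specific contrast table
#'
#' Welch t-tests (log2 scale) with Benjamini-Hochberg adjustment for the three
#' sex-specific contrasts over a supplied gene list: male cases vs all
#' controls, female cases vs all controls, and male cases vs female cases.
#' Fold changes use the signed-ratio convention (ratio when >= 1, negated
#' reciprocal otherwise), so a gene higher in the second group appears as a
#' fold change below -1.
#'
#' @param mat An [expression_matrix()].
#' @param pheno Phenotype data.frame with `group` and `sex` columns.
#' @param genes Gene ids to test (must be present in `mat`).
#' @param alpha BH q-value threshold for the significance flag.
#' @return A data.frame of class `contrast_table` with columns `gene`,
#'   `contrast` (one of `case_M_vs_control`, `case_F_vs_control`,
#'   `case_M_vs_case_F`), `mean_a`, `mean_b`, `log2_fc`, `signed_fc`,
#'   `p_value`, `q_value`, `significant`.
#' @export
sex_contrasts <- function(mat, pheno, genes, alpha = 0.05) {
  missing <- setdiff(genes, gene_ids(mat))
  if (length(missing) > 0) {
    stop("genes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  pheno <- pheno[pheno$sample_id %in% sample_ids(mat), , drop = FALSE]
  groups <- list(
    case_M = pheno$sample_id[pheno$group == "case" & pheno$sex == "M"],
    case_F = pheno$sample_id[pheno$group == "case" & pheno$sex == "F"],
    control = pheno$sample_id[pheno$group == "control"]
  )
  too_small <- names(groups)[lengths(groups) < 2]
  if (length(too_small) > 0) {
    stop("contrast group(s) with < 2 samples: ",
         paste(too_small, collapse = ", "), call. = FALSE)
  }
  contrasts <- list(
    case_M_vs_control = c("case_M", "control"),
    case_F_vs_control = c("case_F", "control"),
    case_M_vs_case_F = c("case_M", "case_F")
  )
  lg <- values_log2(mat)[genes, , drop = FALSE]
  lin <- values_linear(mat)[genes, , drop = FALSE]
  out <- lapply(names(contrasts), function(cn) {
    a <- groups[[contrasts[[cn]][1]]]
    b <- groups[[contrasts[[cn]][2]]]
    mean_a <- rowMeans(lin[, a, drop = FALSE])
    mean_b <- rowMeans(lin[, b, drop = FALSE])
    ratio <- ifelse(mean_a == 0 & mean_b == 0, 1, mean_a / mean_b)
    p <- vapply(seq_along(genes), function(i) {
      .welch_p(lg[i, a], lg[i, b])
    }, numeric(1))
    q <- p.adjust(p, method = "BH")
    data.frame(gene = genes, contrast = cn,
               mean_a = mean_a, mean_b = mean_b,
               log2_fc = log2(ratio), signed_fc = .signed_fc(ratio),
               p_value = p, q_value = q, significant = q < alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contrast_table", "data.frame")
  res
}

#' Exact overlap decomposition of 2-4 named sets
#'
#' Venn-style decomposition: every element of the union is assigned to exactly
#' one region keyed by the sets containing it (e.g. `"A&B"`), so region counts
#' sum to the union size. The intersection of all sets is reported separately.
#'
#' @param named_sets Named list of 2-4 character vectors.
#' @return A list of class `overlap_result` with `sets` (deduplicated inputs),
#'   `membership` (data.frame `element`, `region`), `region_counts` (named
#'   integer) and `intersection` (character).
#' @export
overlap_sets <- function(named_sets) {
  if (length(named_sets) < 2 || length(named_sets) > 4) {
    stop("overlap_sets takes 2-4 sets", call. = FALSE)
  }
  if (is.null(names(named_sets)) || any(!nzchar(names(named_sets))) ||
      anyDuplicated(names(named_sets))) {
    stop("sets must have unique non-empty names", call. = FALSE)
  }
  named_sets <- lapply(named_sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(named_sets)))
  member <- vapply(named_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(named_sets)))
  region <- apply(member, 1, function(row) {
    paste(names(named_sets)[row], collapse = "&")
  })
  counts <- table(region)
  structure(
    list(
      sets = named_sets,
      membership = data.frame(element = universe, region = region,
                              stringsAsFactors = FALSE),
      region_counts = setNames(as.integer(counts), names(counts)),
      intersection = universe[rowSums(member) == length(named_sets)]
    ),
    class = "overlap_result"
  )
}
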