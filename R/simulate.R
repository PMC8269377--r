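#' Simulator configuration
#'
#' Parameters of the synthetic expression generator. The generator emulates
#' the structure the switch-gene method assumes: modular co-expression blocks
#' driven by per-module latent factors, case/control fold changes inside a
#' 1.5-4x linear band, planted switch genes that anti-correlate with their own
#' module, and sex-specific effects including one XIST-like gene with extreme
#' female-biased expression.
#'
#' The `i`-th regular gene of module `m` is, on the log2 scale,
#' `baseline + alpha * f_m + beta * c_{m,i} + noise_sd * eps (+ shifts)`,
#' where `f_m` is the module's global latent factor and `c_{m,i}` is a smooth
#' expression gradient along the module (an AR(1) chain over gene positions
#' with autocorrelation `gradient_rho`), with
#' `alpha^2 + beta^2 = within_module_corr` split by `gradient_share`.
#' Adjacent genes therefore correlate at `within_module_corr` while distant
#' same-module genes share only the global factor, giving the co-expression
#' blocks the banded, partly sparse topology of real modules rather than a
#' clique. Planted switch genes load *negatively* and strongly (squared
#' loading `max(0.95, within_module_corr)`) on their own module's global
#' factor, so in the built network their neighbors anti-correlate (APCC < 0),
#' their links leave their k-means community (high Kpi), their internal degree
#' is low (low Zg) — and they are block-wide topological shortcuts, which the
#' robustness analysis probes. Differential genes receive a case-only additive
#' log2 shift drawn from `case_fc_range` with random sign; switch genes are
#' always differential, with shifts from `switch_fc_range` (a narrower
#' mid-band), so they reliably satisfy the method's premise of surviving the
#' fold-change filter.
#'
#' @param n_modules Number of co-expression modules.
#' @param genes_per_module Genes per module (switch genes included).
#' @param n_switch Number of planted switch genes (spread round-robin over
#'   modules).
#' @param n_case,n_control Sample sizes; sexes alternate M/F within each group.
#' @param within_module_corr Correlation between adjacent same-module genes
#'   (the total shared variance `alpha^2 + beta^2` when noise keeps gene
#'   variance at 1).
#' @param gradient_share Fraction of the shared variance carried by the
#'   within-module gradient rather than the global factor.
#' @param gradient_rho Autocorrelation of the gradient across adjacent gene
#'   positions.
#' @param noise_sd Standard deviation of i.i.d. gene-level noise (log2 scale).
#' @param case_fc_range Linear fold-change band for planted differential genes.
#' @param switch_fc_range Linear fold-change band for planted switch genes.
#' @param response_sd Relative inter-patient variability of disease effect
#'   sizes: the log2 shift of gene `g` in case sample `j` is
#'   `d_g * (1 + response_sd * z_gj)`. Real cohorts are heterogeneous in
#'   response; this also keeps the case/control shift from acting as a global
#'   latent factor that would correlate unrelated differential genes.
#' @param diff_fraction Fraction of each module's regular genes that receive a
#'   case/control effect.
#' @param sex_effect_genes Number of genes with a sex main effect (chosen from
#'   non-differential genes); the first is the XIST-like gene.
#' @param sex_fc Linear fold change of ordinary sex-effect genes.
#' @param xist_fc Linear female/male fold change of the XIST-like gene.
#' @param baseline_range Uniform range of per-gene baseline expression (log2).
#' @param seed Integer seed; identical configuration + seed gives
#'   byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_modules = 4L,
                       genes_per_module = 60L,
                       n_switch = 8L,
                       n_case = 30L,
                       n_control = 30L,
                       within_module_corr = 0.8,
                       gradient_share = 0.25,
                       gradient_rho = 0.9,
                       noise_sd = 0.45,
                       case_fc_range = c(1.5, 4),
                       switch_fc_range = c(2.2, 2.8),
                       response_sd = 0.5,
                       diff_fraction = 0.6,
                       sex_effect_genes = 6L,
                       sex_fc = 3,
                       xist_fc = 30,
                       baseline_range = c(6, 10),
                       seed = 1L) {
  stopifnot(
    n_modules >= 1, genes_per_module >= 1, n_switch >= 0,
    n_case >= 2, n_control >= 2,
    within_module_corr > 0, within_module_corr <= 1,
    gradient_share >= 0, gradient_share < 1,
    gradient_rho >= 0, gradient_rho < 1, noise_sd >= 0,
    length(case_fc_range) == 2, case_fc_range[1] >= 1,
    case_fc_range[1] <= case_fc_range[2],
    response_sd >= 0,
    diff_fraction >= 0, diff_fraction <= 1,
    sex_effect_genes >= 0, sex_fc >= 1, xist_fc >= 1
  )
  structure(
    list(n_modules = as.integer(n_modules),
         genes_per_module = as.integer(genes_per_module),
         n_switch = as.integer(n_switch),
         n_case = as.integer(n_case), n_control = as.integer(n_control),
         within_module_corr = within_module_corr,
         gradient_share = gradient_share,
         gradient_rho = gradient_rho,
         noise_sd = noise_sd,
         case_fc_range = case_fc_range,
         switch_fc_range = switch_fc_range,
         response_sd = response_sd,
         diff_fraction = diff_fraction,
         sex_effect_genes = as.integer(sex_effect_genes),
         sex_fc = sex_fc, xist_fc = xist_fc,
         baseline_range = baseline_range,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic case/control expression dataset
#'
#' See [sim_config()] for the generative model. Returns the expression matrix
#' (log2 scale), the phenotype table and a ground-truth table recording every
#' planted label, so that each pipeline stage can be scored against what was
#' planted.
#'
#' @param sim A [sim_config()].
#' @return A list with `expr` ([expression_matrix()], log2 scale), `pheno`
#'   (phenotype data.frame) and `truth` (data.frame of class `ground_truth`
#'   with columns `gene`, `module`, `is_switch`, `is_differential`,
#'   `true_log2_fc`, `sex_effect`, `sex_log2_fc`, `is_xist_like`).
#' @export
generate_dataset <- function(sim = sim_config()) {
  G <- sim$n_modules * sim$genes_per_module
  if (sim$n_switch > G) {
    stop("infeasible configuration: more switch genes than genes", call. = FALSE)
  }
  sw_per_mod <- tabulate(((seq_len(sim$n_switch) - 1) %% sim$n_modules) + 1,
                         nbins = sim$n_modules)
  if (any(sw_per_mod >= sim$genes_per_module)) {
    stop("infeasible configuration: a module would consist only of switch genes",
         call. = FALSE)
  }
  withr::with_seed(sim$seed, {
    genes <- sprintf("gene_%04d", seq_len(G))
    module <- rep(seq_len(sim$n_modules), each = sim$genes_per_module)
    # switch genes occupy the first slots of each module, round-robin
    is_switch <- logical(G)
    for (m in seq_len(sim$n_modules)) {
      if (sw_per_mod[m] > 0) {
        idx <- which(module == m)[seq_len(sw_per_mod[m])]
        is_switch[idx] <- TRUE
      }
    }

    n_samp <- sim$n_case + sim$n_control
    sample_id <- c(sprintf("case_%02d", seq_len(sim$n_case)),
                   sprintf("ctrl_%02d", seq_len(sim$n_control)))
    group <- rep(c("case", "control"), c(sim$n_case, sim$n_control))
    sex <- c(rep_len(c("M", "F"), sim$n_case),
             rep_len(c("M", "F"), sim$n_control))
    pheno <- phenotype_table(sample_id, group, sex)

    # shared-variance split: global factor vs within-module gradient
    alpha <- sqrt(sim$within_module_corr * (1 - sim$gradient_share))
    beta <- sqrt(sim$within_module_corr * sim$gradient_share)
    switch_loading <- -sqrt(max(0.95, sim$within_module_corr))
    switch_noise_sd <- sqrt(1 - switch_loading^2)

    # case/control effects: module-coherent direction (co-expressed genes are
    # co-regulated), switch genes shifted against their module
    mod_sign <- rep_len(c(1, -1), sim$n_modules)
    is_differential <- is_switch
    for (m in seq_len(sim$n_modules)) {
      regular <- which(module == m & !is_switch)
      n_diff <- floor(sim$diff_fraction * length(regular))
      if (n_diff > 0) {
        is_differential[sample(regular, n_diff)] <- TRUE
      }
    }
    true_log2_fc <- numeric(G)
    reg_diff <- which(is_differential & !is_switch)
    true_log2_fc[reg_diff] <- mod_sign[module[reg_diff]] *
      runif(length(reg_diff), log2(sim$case_fc_range[1]),
            log2(sim$case_fc_range[2]))
    sw <- which(is_switch)
    true_log2_fc[sw] <- -mod_sign[module[sw]] *
      runif(length(sw), log2(sim$switch_fc_range[1]),
            log2(sim$switch_fc_range[2]))

    # sex effects on non-differential genes; first one is XIST-like (F >> M)
    sex_log2_fc <- numeric(G)
    is_xist_like <- logical(G)
    if (sim$sex_effect_genes > 0) {
      candidates <- which(!is_differential)
      if (length(candidates) < sim$sex_effect_genes) {
        stop("infeasible configuration: not enough non-differential genes for sex effects",
             call. = FALSE)
      }
      sex_idx <- sample(candidates, sim$sex_effect_genes)
      is_xist_like[sex_idx[1]] <- TRUE
      sex_log2_fc[sex_idx[1]] <- log2(sim$xist_fc)
      if (sim$sex_effect_genes > 1) {
        rest <- sex_idx[-1]
        sex_log2_fc[rest] <- sample(c(-1, 1), length(rest), replace = TRUE) *
          log2(sim$sex_fc)
      }
    }

    baseline <- runif(G, sim$baseline_range[1], sim$baseline_range[2])
    factors <- matrix(rnorm(sim$n_modules * n_samp), nrow = sim$n_modules)
    is_case <- as.numeric(group == "case")
    is_f <- as.numeric(sex == "F")
    vals <- matrix(0, nrow = G, ncol = n_samp,
                   dimnames = list(genes, sample_id))
    for (m in seq_len(sim$n_modules)) {
      regular <- which(module == m & !is_switch)
      # AR(1) gradient over gene positions within the module
      if (length(regular) > 0) {
        chain <- matrix(0, nrow = length(regular), ncol = n_samp)
        chain[1, ] <- rnorm(n_samp)
        if (length(regular) > 1) {
          innov_sd <- sqrt(1 - sim$gradient_rho^2)
          for (i in 2:length(regular)) {
            chain[i, ] <- sim$gradient_rho * chain[i - 1, ] +
              rnorm(n_samp, sd = innov_sd)
          }
        }
        vals[regular, ] <- alpha * matrix(factors[m, ], nrow = length(regular),
                                          ncol = n_samp, byrow = TRUE) +
          beta * chain +
          matrix(rnorm(length(regular) * n_samp, sd = sim$noise_sd),
                 nrow = length(regular))
      }
      swm <- which(module == m & is_switch)
      if (length(swm) > 0) {
        vals[swm, ] <- switch_loading *
          matrix(factors[m, ], nrow = length(swm), ncol = n_samp, byrow = TRUE) +
          matrix(rnorm(length(swm) * n_samp, sd = switch_noise_sd),
                 nrow = length(swm))
      }
    }
    shift <- outer(true_log2_fc, is_case)
    if (sim$response_sd > 0) {
      shift <- shift * (1 + sim$response_sd *
                          matrix(rnorm(G * n_samp), nrow = G))
    }
    vals <- vals + baseline + shift + outer(sex_log2_fc, is_f)

    truth <- data.frame(
      gene = genes, module = as.integer(module),
      is_switch = is_switch, is_differential = is_differential,
      true_log2_fc = true_log2_fc,
      sex_effect = sex_log2_fc != 0, sex_log2_fc = sex_log2_fc,
      is_xist_like = is_xist_like,
      stringsAsFactors = FALSE
    )
    class(truth) <- c("ground_truth", "data.frame")
    list(expr = expression_matrix(vals, "log2"), pheno = pheno, truth = truth)
  })
}

#' Generate gene sets with one switch-enriched set
#'
#' Emits one set (`switch_enriched`) containing a fraction of the planted
#' switch genes plus random padding, and `n_sets - 1` decoy sets sampled
#' uniformly from all genes.
#'
#' @param truth A `ground_truth` table.
#' @param n_sets Total number of sets.
#' @param enriched_fraction Fraction of the planted switch genes included in
#'   the enriched set.
#' @param set_size Members per set.
#' @param seed Integer seed.
#' @return A `gene_set_collection`.
#' @export
generate_gene_sets <- function(truth, n_sets = 20, enriched_fraction = 0.8,
                               set_size = 10, seed = 1) {
  sw <- truth$gene[truth$is_switch]
  other <- truth$gene[!truth$is_switch]
  withr::with_seed(seed, {
    n_sw <- ceiling(enriched_fraction * length(sw))
    members <- if (n_sw > 0) sample(sw, n_sw) else character()
    pad <- max(0, set_size - length(members))
    enriched <- c(members, sample(other, min(pad, length(other))))
    sets <- list(switch_enriched = enriched)
    for (i in seq_len(n_sets - 1)) {
      sets[[sprintf("decoy_%02d", i)]] <- sample(truth$gene, set_size)
    }
    gene_set_collection(sets)
  })
}

#' Generate a regulator-target interaction table with a planted hub
#'
#' Plants one high-degree regulator (`REG_hub`) targeting `hub_degree` of the
#' switch genes, plus `n_regulators - 1` background regulators whose total
#' degree is at most `hub_degree / 2` (each targets one random switch gene so
#' that it competes inside the minimum connected subnetwork, plus random
#' non-switch genes).
#'
#' @param truth A `ground_truth` table with at least one switch gene.
#' @param n_regulators Total number of regulators.
#' @param hub_degree Targets of the planted hub (default: all switch genes).
#' @param seed Integer seed.
#' @param kind Interaction kind (`"tf"` or `"chemical"`).
#' @return An `interaction_table` with a `planted_regulator` attribute.
#' @export
generate_interaction_table <- function(truth, n_regulators = 10,
                                       hub_degree = NULL, seed = 1,
                                       kind = "tf") {
  sw <- truth$gene[truth$is_switch]
  if (length(sw) == 0) stop("no switch genes in ground truth", call. = FALSE)
  if (is.null(hub_degree)) hub_degree <- length(sw)
  stopifnot(hub_degree >= 1, hub_degree <= length(sw), n_regulators >= 1)
  other <- truth$gene[!truth$is_switch]
  withr::with_seed(seed, {
    tgt <- sample(sw, hub_degree)
    src <- rep("REG_hub", length(tgt))
    max_bg <- max(1L, floor(hub_degree / 2))
    for (i in seq_len(n_regulators - 1)) {
      deg <- sample.int(max_bg, 1)
      targets <- c(sample(sw, 1),
                   if (deg > 1) sample(other, deg - 1) else character())
      src <- c(src, rep(sprintf("REG_bg%02d", i), length(targets)))
      tgt <- c(tgt, targets)
    }
    out <- interaction_table(src, tgt, rep(kind, length(src)))
    attr(out, "planted_regulator") <- "REG_hub"
    out
  })
}

#' Write a simulated dataset to a directory
#'
#' Writes expression TSV, phenotype TSV, ground-truth JSON, a GMT collection
#' and an interaction TSV — everything the pipeline consumes.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param seed Seed forwarded to [generate_gene_sets()] and
#'   [generate_interaction_table()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(dataset$expr, file.path(dir, "expression.tsv"))
  write_phenotypes(dataset$pheno, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       digits = NA)
  write_gmt(generate_gene_sets(dataset$truth, seed = seed),
            file.path(dir, "gene_sets.gmt"))
  write_interaction_table(
    generate_interaction_table(dataset$truth, seed = seed),
    file.path(dir, "interactions.tsv"))
  invisible(dir)
}
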