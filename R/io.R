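.group_synonyms <- list(
  case = c("case", "als", "patient", "patients", "disease", "diseased",
           "affected", "sals"),
  control = c("control", "controls", "ctrl", "healthy", "normal", "hc")
)

#' Read a phenotype table
#'
#' Expects a TSV with columns `sample_id`, `group` and `sex`. Group labels are
#' normalized case-insensitively to `case`/`control` (synonyms such as "ALS",
#' "patient", "healthy" are accepted); sex labels to `M`/`F`, anything else
#' becoming `"unknown"`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with columns `sample_id`, `group`, `sex`.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  need <- c("sample_id", "group", "sex")
  if (!all(need %in% colnames(df))) {
    stop("phenotype TSV must have columns sample_id, group, sex",
         call. = FALSE)
  }
  phenotype_table(df$sample_id, df$group, df$sex)
}

#' Construct a phenotype table
#'
#' @param sample_id Character vector of unique sample ids.
#' @param group Group labels; normalized to `case`/`control`.
#' @param sex Sex labels; normalized to `M`/`F`/`unknown`.
#' @return A data.frame with columns `sample_id`, `group`, `sex`.
#' @export
phenotype_table <- function(sample_id, group, sex = rep("unknown", length(sample_id))) {
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  g <- tolower(trimws(group))
  grp <- ifelse(g %in% .group_synonyms$case, "case",
                ifelse(g %in% .group_synonyms$control, "control", NA))
  if (anyNA(grp)) {
    bad <- unique(group[is.na(grp)])
    stop("unrecognized group label(s): ", paste(bad, collapse = ", "),
         " (expected case/control or a synonym)", call. = FALSE)
  }
  s <- tolower(trimws(sex))
  sx <- ifelse(s %in% c("m", "male"), "M",
               ifelse(s %in% c("f", "female"), "F", "unknown"))
  data.frame(sample_id = as.character(sample_id), group = grp, sex = sx,
             stringsAsFactors = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene ids. Members are deduplicated with
#' order preserved.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character member vectors
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file", call. = FALSE)
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(fields)), call. = FALSE)
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop(sprintf("duplicate gene-set name '%s' at GMT line %d", name, i),
           call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("GMT line %d ('%s') has no non-empty members", i, name),
           call. = FALSE)
    }
    sets[[name]] <- members
    descs[name] <- fields[2]
  }
  gene_set_collection(sets, descs)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique set names, non-empty
#'   members).
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) stop("sets must be non-empty", call. = FALSE)
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions[names(sets)],
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, if (nzchar(descs[[nm]])) descs[[nm]] else "NA", sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulator/chemical interaction table
#'
#' Expects TSV columns `source`, `target`, `kind` with kind in
#' `tf`/`chemical`/`gene`. Duplicate edges are collapsed; self-loops are
#' dropped with a warning.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame of class `interaction_table` with columns `source`,
#'   `target`, `kind`.
#' @export
read_interaction_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  need <- c("source", "target", "kind")
  if (!all(need %in% colnames(df))) {
    stop("interaction TSV must have columns source, target, kind",
         call. = FALSE)
  }
  interaction_table(df$source, df$target, df$kind)
}

#' Construct an interaction table
#'
#' @param source,target Character vectors: regulator/chemical ids and target
#'   gene ids.
#' @param kind Interaction kind per edge: `tf`, `chemical` or `gene`.
#' @return An `interaction_table` data.frame.
#' @export
interaction_table <- function(source, target, kind) {
  kind <- tolower(trimws(kind))
  bad <- setdiff(unique(kind), c("tf", "chemical", "gene"))
  if (length(bad) > 0) {
    stop("unrecognized interaction kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   kind = kind, stringsAsFactors = FALSE)
  loops <- df$source == df$target
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s)", call. = FALSE)
    df <- df[!loops, , drop = FALSE]
  }
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Write an interaction table to TSV
#'
#' @param x An `interaction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a phenotype table to TSV
#'
#' @param x A phenotype data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
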