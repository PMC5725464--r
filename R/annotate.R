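#' Construct a biotype/gene-family catalog
#'
#' @param gene_id character vector of gene ids (unique).
#' @param biotype one annotation class per gene (protein_coding,
#'   pseudogene, lincRNA, antisense, ...).
#' @param families list of character vectors (possibly empty) of family
#'   labels per gene (oncogene, tumor suppressor, protein kinase, ...),
#'   or a character vector of semicolon-joined labels.
#' @param is_parental logical: is the gene a parental gene of some
#'   pseudogene.
#' @return a `biotype_catalog` list.
#' @export
biotype_catalog <- function(gene_id, biotype, families = NULL,
                            is_parental = FALSE) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) abort_data("catalog gene ids must be unique")
  if (length(biotype) != length(gene_id)) abort_data("one biotype per gene required")
  if (is.null(families)) families <- rep(list(character(0)), length(gene_id))
  if (is.character(families)) {
    families <- lapply(strsplit(families, ";", fixed = TRUE),
                       function(f) f[nzchar(f)])
  }
  structure(list(gene_id = gene_id,
                 biotype = stats::setNames(as.character(biotype), gene_id),
                 families = stats::setNames(families, gene_id),
                 is_parental = stats::setNames(
                   rep_len(as.logical(is_parental), length(gene_id)), gene_id)),
            class = "biotype_catalog")
}

#' Read a catalog TSV (gene_id, biotype, families, is_parental)
#'
#' `families` is semicolon-separated and may be empty; `is_parental` is
#' optional (defaults to FALSE).
#'
#' @param path TSV path with a header row.
#' @return a [biotype_catalog()].
#' @export
read_biotype_catalog <- function(path) {
  if (!file.exists(path)) abort_config("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = character(0))
  for (col in c("gene_id", "biotype")) {
    if (!col %in% names(df)) abort_config("catalog lacks column '", col, "'")
  }
  biotype_catalog(df$gene_id, df$biotype,
                  families = if ("families" %in% names(df)) df$families else NULL,
                  is_parental = if ("is_parental" %in% names(df)) {
                    df$is_parental %in% c("TRUE", "true", "1")
                  } else FALSE)
}

#' Decompose a gene selection by biotype
#'
#' Every selected gene is counted exactly once under its biotype (or
#' `unclassified` when absent from the catalog), so counts sum to the
#' selection size.  Parental genes are additionally reported as an
#' overlapping roll-up (they remain counted under their own biotype),
#' mirroring the convention of listing parental genes alongside biotype
#' classes.
#'
#' @param selection character vector of gene ids.
#' @param catalog a [biotype_catalog()].
#' @return data frame with columns `class`, `count`, `exclusive`;
#'   `exclusive` rows partition the selection, the `parental_genes` row
#'   (exclusive = FALSE) overlaps them.
#' @export
biotype_decompose <- function(selection, catalog) {
  selection <- unique(as.character(selection))
  bt <- catalog$biotype[selection]
  bt[is.na(bt)] <- "unclassified"
  tab <- table(bt)
  out <- data.frame(class = names(tab), count = as.integer(tab),
                    exclusive = TRUE, stringsAsFactors = FALSE)
  n_parental <- sum(catalog$is_parental[selection], na.rm = TRUE)
  out <- rbind(out, data.frame(class = "parental_genes",
                               count = as.integer(n_parental),
                               exclusive = FALSE, stringsAsFactors = FALSE))
  out
}

#' Decompose a gene selection by gene family
#'
#' Family labels overlap: a gene carrying k labels contributes to k rows,
#' so family counts may sum to more than the selection size.
#'
#' @param selection character vector of gene ids.
#' @param catalog a [biotype_catalog()].
#' @return data frame with columns `family`, `count`.
#' @export
family_decompose <- function(selection, catalog) {
  selection <- unique(as.character(selection))
  labels <- unlist(catalog$families[intersect(selection, catalog$gene_id)],
                   use.names = FALSE)
  if (!length(labels)) {
    return(data.frame(family = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(labels)
  data.frame(family = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Compare two annotation versions' gene sets
#'
#' Reports how much of set A survives in set B: the shared count, the
#' percentage of A shared, and the percentage of A absent from B.
#' Percentages are rounded half-up to two decimals and always sum to
#' 100 within rounding.
#'
#' @param set_a,set_b character vectors of gene ids (duplicates ignored);
#'   `set_a` must be non-empty.
#' @return list with `n_a`, `n_b`, `shared`, `pct_shared`, `pct_absent`.
#' @export
compare_annotation_versions <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  if (!length(a)) abort_data("set_a is empty; percentages undefined")
  shared <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), shared = shared,
       pct_shared = round_half_up(100 * shared / length(a), 2),
       pct_absent = round_half_up(100 * (length(a) - shared) / length(a), 2))
}
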