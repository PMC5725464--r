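#' Significance rule for per-method DE calls
#'
#' A gene is significant when its FDR-adjusted q-value is at most `q_max`
#' (inclusive) and, when `lfc_min > 0`, its absolute log2 fold change
#' strictly exceeds `lfc_min`.  Genes lacking a q-value are never called.
#'
#' @param q_max FDR threshold in (0, 1], inclusive comparison (default 0.05).
#' @param lfc_min minimum |log2FC|, strict comparison when positive
#'   (default 0 = no fold-change condition).
#' @return a `significance_rule` list.
#' @export
significance_rule <- function(q_max = 0.05, lfc_min = 0) {
  if (q_max <= 0 || q_max > 1) abort_config("q_max must be in (0, 1]")
  if (lfc_min < 0) abort_config("lfc_min must be >= 0")
  structure(list(q_max = q_max, lfc_min = lfc_min), class = "significance_rule")
}

#' Significant gene set of one method
#'
#' @param table a [method_call_table()].
#' @param rule a [significance_rule()].
#' @return character vector of significant gene ids.
#' @export
significant_set <- function(table, rule = significance_rule()) {
  keep <- !is.na(table$qvalue) & table$qvalue <= rule$q_max
  if (rule$lfc_min > 0) keep <- keep & abs(table$log2fc) > rule$lfc_min
  table$gene_id[keep]
}

#' Venn-region decomposition of per-method gene sets
#'
#' Assigns each gene in the union of all sets the signature of methods
#' that called it (labels joined by `+` in the declared method order) and
#' tallies each non-empty region.  Region counts always sum to the union
#' size, and the core is the all-methods region.
#'
#' @param sets named list (method -> character vector of gene ids); at
#'   least two sets.
#' @return a `consensus_result` list with `membership` (named character:
#'   gene -> signature), `region_counts` (named integer), `core`
#'   (character vector), `union_size`, and `methods`.
#' @export
venn_decompose <- function(sets) {
  if (length(sets) < 2L) abort_usage("need at least 2 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort_usage("sets must be uniquely named by method")
  }
  methods <- names(sets)
  genes <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1)
  signature <- apply(member, 1L, function(row) paste(methods[row], collapse = "+"))
  names(signature) <- genes
  region_counts <- table(signature)
  region_counts <- stats::setNames(as.integer(region_counts), names(region_counts))
  all_sig <- paste(methods, collapse = "+")
  structure(list(membership = signature,
                 region_counts = region_counts,
                 core = genes[signature == all_sig],
                 union_size = length(genes),
                 methods = methods),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus over %d methods: union %d genes, core %d\n",
              length(x$methods), x$union_size, length(x$core)))
  invisible(x)
}

#' Average log2 fold change over detecting methods
#'
#' Arithmetic mean of a gene's observed cells only; methods that did not
#' report the gene do not contribute.
#'
#' @param matrix a `profile_matrix`.
#' @param gene one or more gene ids present in the matrix.
#' @return named numeric vector of per-gene means.
#' @export
mean_lfc <- function(matrix, gene) {
  missing_genes <- setdiff(gene, rownames(matrix))
  if (length(missing_genes)) {
    abort_data("gene(s) not in matrix: ", paste(missing_genes, collapse = ", "))
  }
  rows <- matrix[gene, , drop = FALSE]
  out <- rowMeans(rows, na.rm = TRUE)
  stats::setNames(as.numeric(out), gene)
}

#' Sign concordance across detecting methods
#'
#' A gene is concordant when all methods that reported it agree on a
#' strict direction.  A reported log2FC of exactly 0 carries no direction
#' and renders the gene discordant.  Genes with fewer than two observed
#' calls are not applicable (`NA`).
#'
#' @param matrix a `profile_matrix`.
#' @param gene one or more gene ids present in the matrix.
#' @return named character vector: `"concordant"`, `"discordant"`, or
#'   `NA` (fewer than two calls).
#' @export
sign_concordance <- function(matrix, gene) {
  missing_genes <- setdiff(gene, rownames(matrix))
  if (length(missing_genes)) {
    abort_data("gene(s) not in matrix: ", paste(missing_genes, collapse = ", "))
  }
  out <- vapply(gene, function(g) {
    v <- matrix[g, ]
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_character_)
    if (any(v == 0)) return("discordant")
    if (all(v > 0) || all(v < 0)) "concordant" else "discordant"
  }, character(1))
  stats::setNames(out, gene)
}

#' Per-gene consensus summary table
#'
#' Combines the Venn signature, number of detecting methods, averaged
#' log2 fold change, and sign concordance into one table ready to write
#' as TSV.
#'
#' @param matrix a `profile_matrix`.
#' @param sets named list of per-method significant sets (defaults to
#'   "observed in the method's table", i.e. all matrix cells).
#' @return data frame with columns `gene_id`, `signature`, `n_methods`,
#'   `mean_lfc`, `concordant`.
#' @export
consensus_summary <- function(matrix, sets = NULL) {
  if (is.null(sets)) {
    sets <- lapply(seq_len(ncol(matrix)), function(j) rownames(matrix)[!is.na(matrix[, j])])
    names(sets) <- colnames(matrix)
  }
  cons <- venn_decompose(sets)
  genes <- intersect(names(cons$membership), rownames(matrix))
  data.frame(gene_id = genes,
             signature = unname(cons$membership[genes]),
             n_methods = vapply(strsplit(unname(cons$membership[genes]), "+", fixed = TRUE),
                                length, integer(1)),
             mean_lfc = unname(mean_lfc(matrix, genes)),
             concordant = unname(sign_concordance(matrix, genes)),
             stringsAsFactors = FALSE)
}
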