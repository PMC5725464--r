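#' Construct a per-method differential-expression call table
#'
#' One RNA-Seq analysis method's results: one row per gene with its log2
#' fold change and (optionally) p- and FDR-adjusted q-values.  Gene ids
#' must be unique and log2 fold changes finite; p/q values, where present,
#' must lie in \[0, 1\].  Genes lacking a q-value are kept but are
#' ineligible for significance calls downstream.
#'
#' @param gene_id character vector of gene identifiers (opaque strings).
#' @param log2fc finite numeric log2 fold changes.
#' @param pvalue,qvalue numeric vectors in \[0, 1\]; NA allowed.
#' @param method_name label of the producing method.
#' @return a `method_call_table`, a data frame with columns `gene_id`,
#'   `log2fc`, `pvalue`, `qvalue` and attribute `method_name`.
#' @export
method_call_table <- function(gene_id, log2fc, pvalue = NA_real_,
                              qvalue = NA_real_, method_name) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    dups <- unique(gene_id[duplicated(gene_id)])
    abort_data("duplicate gene_id in table '", method_name, "': ",
               paste(dups, collapse = ", "))
  }
  if (!is.numeric(log2fc) || any(!is.finite(log2fc))) {
    abort_data("log2fc must be finite numeric in table '", method_name, "'")
  }
  check_prob <- function(x, nm) {
    if (!is.numeric(x)) abort_data(nm, " must be numeric in table '", method_name, "'")
    if (any(x < 0 | x > 1, na.rm = TRUE)) {
      abort_data(nm, " outside [0, 1] in table '", method_name, "'")
    }
  }
  check_prob(pvalue, "pvalue")
  check_prob(qvalue, "qvalue")
  out <- data.frame(gene_id = gene_id, log2fc = as.numeric(log2fc),
                    pvalue = rep_len(as.numeric(pvalue), length(gene_id)),
                    qvalue = rep_len(as.numeric(qvalue), length(gene_id)),
                    stringsAsFactors = FALSE)
  attr(out, "method_name") <- as.character(method_name)
  class(out) <- c("method_call_table", "data.frame")
  out
}

#' Read one method's DE table from delimited text
#'
#' Column names in the file are adapted through `column_map`, so native
#' export layouts of different DE callers can be ingested without editing
#' the files.  Values `NA`/empty in the p/q columns are retained as
#' missing and counted in the parse report (attribute `parse_report`).
#'
#' @param path path to a delimited text file with one header row.
#' @param method_name label for the method that produced the table.
#' @param column_map named character vector mapping the canonical names
#'   `gene_id`, `log2fc`, `pvalue`, `qvalue` to the file's column names.
#'   `pvalue`/`qvalue` entries may be omitted.
#' @param sep field separator (tab by default).
#' @return a [method_call_table()] with a `parse_report` attribute listing
#'   row and missing-value counts.
#' @export
read_method_table <- function(path, method_name,
                              column_map = c(gene_id = "gene_id",
                                             log2fc = "log2fc",
                                             pvalue = "pvalue",
                                             qvalue = "qvalue"),
                              sep = "\t") {
  if (!file.exists(path)) abort_config("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  needed <- c("gene_id", "log2fc")
  for (canon in needed) {
    if (is.na(column_map[canon])) abort_config("column_map lacks an entry for '", canon, "'")
  }
  for (canon in intersect(names(column_map), c("gene_id", "log2fc", "pvalue", "qvalue"))) {
    col <- column_map[[canon]]
    if (!col %in% names(raw)) {
      abort_config("mapped column '", col, "' (for ", canon, ") not found in ", path)
    }
  }
  num <- function(canon) {
    if (!canon %in% names(column_map)) return(rep(NA_real_, nrow(raw)))
    x <- raw[[column_map[[canon]]]]
    miss <- is.na(x) | x == "" | toupper(x) == "NA"
    v <- suppressWarnings(as.numeric(x))
    bad <- !miss & is.na(v)
    if (any(bad)) {
      abort_data("non-numeric ", canon, " value(s) in ", path, ": ",
                 paste(unique(x[bad])[1:min(3, sum(bad))], collapse = ", "))
    }
    v
  }
  lfc <- num("log2fc")
  p <- num("pvalue")
  q <- num("qvalue")
  if (any(is.na(lfc))) abort_data("missing log2fc value(s) in ", path)
  out <- method_call_table(raw[[column_map[["gene_id"]]]], lfc, p, q,
                           method_name = method_name)
  attr(out, "parse_report") <- list(n_rows = nrow(out),
                                    n_missing_pvalue = sum(is.na(p)),
                                    n_missing_qvalue = sum(is.na(q)))
  out
}

#' Write a method call table to delimited text
#'
#' Inverse of [read_method_table()]; missing p/q values are written as
#' `NA` so a read/write/read cycle reproduces the table exactly.
#'
#' @param table a [method_call_table()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_method_table <- function(table, path, sep = "\t") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the gene-by-method log2 fold-change matrix
#'
#' Merges two or more per-method call tables into a numeric matrix whose
#' rows are the union of all gene ids (sorted) and whose columns follow
#' the declared table order.  A cell is observed iff the gene appears in
#' that method's table; unobserved cells are `NA`.  Every row has at
#' least one observed cell by construction.
#'
#' @param tables list of [method_call_table()] objects with distinct
#'   method names.
#' @return a `profile_matrix`: a numeric matrix with `NA` marking
#'   missing cells.
#' @export
build_profile_matrix <- function(tables) {
  if (length(tables) < 2L) abort_usage("need at least 2 method tables")
  methods <- unname(vapply(tables, function(t) attr(t, "method_name"), character(1)))
  if (anyDuplicated(methods)) abort_usage("method names must be distinct")
  genes <- sort(unique(unlist(lapply(tables, function(t) t$gene_id),
                              use.names = FALSE)))
  values <- matrix(NA_real_, length(genes), length(tables),
                   dimnames = list(genes, methods))
  for (i in seq_along(tables)) {
    values[tables[[i]]$gene_id, i] <- tables[[i]]$log2fc
  }
  profile_matrix(values)
}

#' Construct a profile matrix from a numeric matrix
#'
#' @param values numeric matrix, genes as (named) rows, methods as named
#'   columns; `NA` cells are treated as missing.
#' @return a `profile_matrix`.
#' @export
profile_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) abort_usage("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_usage("values must have gene row names and method column names")
  }
  if (anyDuplicated(rownames(values))) abort_data("gene ids must be unique")
  if (any(rowSums(!is.na(values)) == 0L)) {
    abort_data("every gene row must have at least one observed cell")
  }
  structure(values, class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d genes x %d methods, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a profile matrix from TSV (genes x methods, empty cells missing)
#'
#' @param path TSV path: first column gene ids, remaining columns one per
#'   method; empty cells are missing.
#' @return a `profile_matrix`.
#' @export
read_profile_matrix <- function(path) {
  if (!file.exists(path)) abort_config("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  profile_matrix(m)
}

#' Write a profile matrix to TSV
#' @param matrix a `profile_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct an expression matrix (FPKM or read counts)
#'
#' @param values non-negative numeric matrix, genes x samples; integer
#'   values required when `unit = "read_count"`.
#' @param unit `"fpkm"` or `"read_count"`.
#' @param group per-sample condition label (e.g. tumor/control).
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, unit = c("fpkm", "read_count"), group) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) abort_usage("values must be a numeric matrix")
  if (any(values < 0, na.rm = TRUE)) abort_data("expression values must be >= 0")
  if (unit == "read_count" && any(values != round(values), na.rm = TRUE)) {
    abort_data("read_count values must be integers")
  }
  if (length(group) != ncol(values)) abort_data("one group label per sample required")
  structure(values, unit = unit, group = as.character(group),
            class = c("expression_matrix", "matrix", "array"))
}

#' Expression-filter configuration
#'
#' Inclusion rule for downstream analysis: a gene is retained when its
#' FPKM exceeds `fpkm_min` (strictly) and its read count exceeds
#' `count_min` (strictly) in at least `ceiling(sample_frac * n)` samples.
#' With `per_group = TRUE` (default) the rule must hold within every
#' condition group separately; otherwise it is evaluated over the pooled
#' samples.
#'
#' @param fpkm_min exclusive FPKM threshold (default 1).
#' @param count_min exclusive read-count threshold (default 10).
#' @param sample_frac minimum fraction of samples, inclusive (default 0.10).
#' @param per_group evaluate per condition group (default TRUE).
#' @return a `filter_config` list.
#' @export
filter_config <- function(fpkm_min = 1, count_min = 10, sample_frac = 0.10,
                          per_group = TRUE) {
  if (fpkm_min < 0 || count_min < 0) abort_config("thresholds must be >= 0")
  if (sample_frac <= 0 || sample_frac > 1) abort_config("sample_frac must be in (0, 1]")
  structure(list(fpkm_min = fpkm_min, count_min = count_min,
                 sample_frac = sample_frac, per_group = isTRUE(per_group)),
            class = "filter_config")
}

#' Apply the expression inclusion filter
#'
#' @param fpkm an [expression_matrix()] in FPKM units.
#' @param counts an [expression_matrix()] in read-count units sharing the
#'   same gene and sample sets.
#' @param cfg a [filter_config()].
#' @return list with `retained` (character vector of gene ids) and
#'   `report` (data frame of per-gene passing-sample counts per group and
#'   the retention flag).
#' @export
expression_filter <- function(fpkm, counts, cfg = filter_config()) {
  if (!identical(rownames(fpkm), rownames(counts)) ||
      !identical(colnames(fpkm), colnames(counts))) {
    abort_data("fpkm and counts matrices must share gene and sample sets")
  }
  if (!identical(attr(fpkm, "group"), attr(counts, "group"))) {
    abort_data("fpkm and counts matrices must share sample groups")
  }
  groups <- if (cfg$per_group) attr(fpkm, "group") else rep("all", ncol(fpkm))
  levels <- unique(groups)
  report <- data.frame(gene_id = rownames(fpkm), stringsAsFactors = FALSE)
  pass <- rep(TRUE, nrow(fpkm))
  for (g in levels) {
    idx <- groups == g
    quota <- ceiling(cfg$sample_frac * sum(idx))
    n_fpkm <- rowSums(fpkm[, idx, drop = FALSE] > cfg$fpkm_min)
    n_count <- rowSums(counts[, idx, drop = FALSE] > cfg$count_min)
    report[[paste0("fpkm_pass_", g)]] <- n_fpkm
    report[[paste0("count_pass_", g)]] <- n_count
    pass <- pass & n_fpkm >= quota & n_count >= quota
  }
  report$retained <- pass
  list(retained = report$gene_id[pass], report = report)
}

#' Read a sample manifest (sample_id, group, qc_flag TSV)
#'
#' @param path TSV with columns `sample_id`, `group`, `qc_flag`
#'   (pass/fail) and optionally `flag_reason`.
#' @return a data frame; sample ids are checked for uniqueness.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) abort_config("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  for (col in c("sample_id", "group", "qc_flag")) {
    if (!col %in% names(df)) abort_config("manifest lacks column '", col, "'")
  }
  if (anyDuplicated(df$sample_id)) abort_data("duplicate sample_id in manifest")
  df
}

#' Count retained records
#'
#' Cohort/filter accounting: how many records carry a pass flag, overall
#' or per group.  An empty input counts 0.
#'
#' @param records a data frame with a `qc_flag` column (`"pass"`/`"fail"`
#'   or logical), or a logical vector of retention flags.
#' @param by_group when `records` is a data frame with a `group` column,
#'   also return per-group counts.
#' @return integer count, or a named integer vector when `by_group`.
#' @export
count_retained <- function(records, by_group = FALSE) {
  flags <- if (is.data.frame(records)) {
    f <- records$qc_flag
    if (is.null(f)) abort_usage("records must carry a qc_flag column")
    if (is.character(f)) f == "pass" else as.logical(f)
  } else {
    as.logical(records)
  }
  if (by_group) {
    if (!is.data.frame(records) || is.null(records$group)) {
      abort_usage("by_group requires a data frame with a group column")
    }
    counts <- tapply(flags, records$group, sum)
    return(vapply(counts, as.integer, integer(1)))
  }
  as.integer(sum(flags, na.rm = TRUE))
}

#' Strip Ensembl-style version suffixes from gene ids
#'
#' Optional normalizer turning `ENSG00000141510.11` into
#' `ENSG00000141510`.  Off by default everywhere; apply explicitly.
#'
#' @param ids character vector of gene ids.
#' @return ids without a trailing `.N` version suffix.
#' @export
strip_gene_versions <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}
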