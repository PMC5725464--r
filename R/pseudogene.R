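hit_columns <- c("query_id", "subject_id", "identity_pct", "align_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' Parse a 12-column tabular alignment-hit file
#'
#' Reads the standard blast-tabular dialect (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore).  Fields are split on tabs when present, otherwise on
#' whitespace.  Any row without exactly 12 fields aborts with the first
#' offending line number.
#'
#' @param path path to the alignment file (no header).
#' @return an `alignment_hits` data frame with typed columns.
#' @export
parse_hits <- function(path) {
  if (!file.exists(path)) abort_config("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), hit_columns))
    class(out) <- c("alignment_hits", "data.frame")
    return(out)
  }
  split_one <- function(line) {
    if (grepl("\t", line, fixed = TRUE)) strsplit(line, "\t", fixed = TRUE)[[1]]
    else strsplit(trimws(line), "[[:space:]]+")[[1]]
  }
  fields <- lapply(lines, split_one)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    abort_data("expected 12 columns but found ", nf[bad], " on line ", bad,
               " of ", path)
  }
  m <- do.call(rbind, fields)
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    identity_pct = as.numeric(m[, 3]),
                    align_len = as.integer(m[, 4]),
                    mismatches = as.integer(m[, 5]),
                    gap_opens = as.integer(m[, 6]),
                    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
                    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]),
                    bitscore = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  bad_num <- which(!stats::complete.cases(out[, 3:12]))
  if (length(bad_num)) {
    abort_data("non-numeric field(s) on line ", bad_num[1L], " of ", path)
  }
  if (any(out$identity_pct < 0 | out$identity_pct > 100)) {
    abort_data("identity_pct outside [0, 100] in ", path)
  }
  if (any(out$evalue < 0)) abort_data("negative e-value in ", path)
  class(out) <- c("alignment_hits", "data.frame")
  out
}

#' Write alignment hits as a 12-column tabular file
#' @param hits an `alignment_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(as.data.frame(hits)[, hit_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assign each pseudogene its parental gene by best alignment hit
#'
#' Per query (pseudogene), the winning hit has the minimum e-value; ties
#' are broken by the maximum bitscore, then by the lexicographically
#' smallest subject id, so the result is invariant under input row
#' order.  When a transcript-to-gene map is supplied, subjects are
#' collapsed to genes first (best hit per gene kept by the same rules).
#' The winning hit's percent identity sets the `high_similarity` flag
#' against the 90% criterion: associations below it carry weaker
#' sequence evidence.
#'
#' @param hits an `alignment_hits` data frame.
#' @param tx2gene optional two-column data frame (`transcript_id`,
#'   `gene_id`) collapsing subject transcripts to genes.
#' @return a `parent_association` data frame: `pseudogene_id`,
#'   `parent_gene_id`, `evalue`, `bitscore`, `identity_pct`,
#'   `high_similarity`; one row per pseudogene, ordered by id.
#' @export
best_hit <- function(hits, tx2gene = NULL) {
  df <- as.data.frame(hits)
  if (!is.null(tx2gene)) {
    map <- stats::setNames(as.character(tx2gene[[2]]), as.character(tx2gene[[1]]))
    mapped <- map[df$subject_id]
    df$subject_id <- ifelse(is.na(mapped), df$subject_id, mapped)
  }
  if (!nrow(df)) {
    out <- data.frame(pseudogene_id = character(0), parent_gene_id = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      identity_pct = numeric(0), high_similarity = logical(0))
    class(out) <- c("parent_association", "data.frame")
    return(out)
  }
  ord <- order(df$query_id, df$evalue, -df$bitscore, df$subject_id)
  df <- df[ord, ]
  win <- df[!duplicated(df$query_id), ]
  out <- data.frame(pseudogene_id = win$query_id,
                    parent_gene_id = win$subject_id,
                    evalue = win$evalue,
                    bitscore = win$bitscore,
                    identity_pct = win$identity_pct,
                    high_similarity = win$identity_pct >= 90,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("parent_association", "data.frame")
  out
}

#' Deduplicate parental genes and report multiplicities
#'
#' @param associations a `parent_association` data frame.
#' @return list with `parents` (distinct parent gene ids, sorted),
#'   `n_unique`, and `multiplicity` (named integer: pseudogenes per
#'   parent).
#' @export
unique_parents <- function(associations) {
  if (!nrow(associations)) {
    return(list(parents = character(0), n_unique = 0L,
                multiplicity = stats::setNames(integer(0), character(0))))
  }
  tab <- table(associations$parent_gene_id)
  parents <- sort(names(tab))
  list(parents = parents,
       n_unique = length(parents),
       multiplicity = stats::setNames(as.integer(tab[parents]), parents))
}

#' Pseudogene-parent fold-change correlation, optionally by stratum
#'
#' For each stratum (all pairs, an explicit factor, or quantile bins of
#' an expression-level column) computes the correlation between
#' pseudogene and parent log2 fold changes and the least-squares slope of
#' pseudogene on parent.  Strata with fewer than 3 pairs or a constant
#' member are flagged degenerate instead of computed.
#'
#' @param pairs data frame with columns `pseudo_lfc`, `parent_lfc`, and
#'   optionally `expression_level`.
#' @param method `"pearson"` or `"spearman"`.
#' @param strata `NULL` (single stratum), an integer number of
#'   quantile bins of `expression_level`, or a factor/character vector of
#'   length `nrow(pairs)`.
#' @return data frame with one row per stratum: `stratum`, `n`, `r`,
#'   `slope`, `degenerate`.
#' @export
pair_correlation <- function(pairs, method = c("pearson", "spearman"),
                             strata = NULL) {
  method <- match.arg(method)
  for (col in c("pseudo_lfc", "parent_lfc")) {
    if (!col %in% names(pairs)) abort_usage("pairs must carry column '", col, "'")
  }
  groups <- if (is.null(strata)) {
    factor(rep("all", nrow(pairs)))
  } else if (length(strata) == 1L && is.numeric(strata)) {
    if (!"expression_level" %in% names(pairs)) {
      abort_usage("quantile strata need an expression_level column")
    }
    br <- unique(stats::quantile(pairs$expression_level,
                                 probs = seq(0, 1, length.out = strata + 1),
                                 type = 7))
    cut(pairs$expression_level, breaks = br, include.lowest = TRUE)
  } else {
    factor(strata)
  }
  res <- lapply(levels(groups), function(g) {
    idx <- groups == g
    x <- pairs$parent_lfc[idx]
    y <- pairs$pseudo_lfc[idx]
    n <- sum(idx)
    if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(stratum = g, n = n, r = NA_real_, slope = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    r <- stats::cor(x, y, method = method)
    slope <- stats::cov(x, y) / stats::var(x)
    data.frame(stratum = g, n = n, r = r, slope = slope, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Sign concordance among DE pseudogene-parent pairs
#'
#' Restricting to pairs where both members are differentially expressed
#' (both fold changes nonzero here; apply a significance rule upstream),
#' reports the fraction whose fold changes agree in sign.
#'
#' @param pairs data frame with `pseudo_lfc` and `parent_lfc`.
#' @return list with `n_pairs`, `n_concordant`, `fraction`.
#' @export
pair_concordance <- function(pairs) {
  ok <- pairs$pseudo_lfc != 0 & pairs$parent_lfc != 0
  conc <- sign(pairs$pseudo_lfc[ok]) == sign(pairs$parent_lfc[ok])
  list(n_pairs = sum(ok), n_concordant = sum(conc),
       fraction = if (sum(ok)) sum(conc) / sum(ok) else NA_real_)
}
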