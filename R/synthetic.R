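#' Simulation configuration for ground-truth profile matrices
#'
#' The generator emulates the statistical structure the ensemble model
#' assumes: a shared per-gene signal theta observed by each method
#' through its own channel `y = a_m + b_m * theta + noise(sd_m)`, with
#' per-method dropout, plus one optional "outlier method" whose profile
#' is independent noise (emulating a caller whose calls occupy gene-space
#' regions the other methods never confirm).
#'
#' @param n_genes number of genes (default 5000).
#' @param n_methods number of methods (default 5).
#' @param pi_de fraction of truly DE genes (default 0.10).
#' @param effect_range range of |theta| for DE genes, drawn uniformly
#'   with random sign (default c(2, 4), log2FC units).
#' @param bias per-method additive bias a_m (recycled; default 0).
#' @param gain per-method multiplicative gain b_m (recycled; default 1).
#' @param noise_sd per-method noise standard deviation; `NULL` (default)
#'   draws each method's sd uniformly from `noise_sd_range`.
#' @param noise_sd_range range for drawn noise sds (default c(0.3, 0.8)).
#' @param dropout per-method probability that a cell is missing
#'   (recycled; default 0.15).
#' @param outlier_method index of the independent-noise method, or `NA`
#'   for none (default: the last method).
#' @param outlier_sd standard deviation of the outlier method's profile
#'   (default 2.0).
#' @param method_names method labels (default `method_1 ...`).
#' @param seed RNG seed; every generator output is a pure function of
#'   the config including this seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000, n_methods = 5, pi_de = 0.10,
                       effect_range = c(2, 4), bias = 0, gain = 1,
                       noise_sd = NULL, noise_sd_range = c(0.3, 0.8),
                       dropout = 0.15, outlier_method = n_methods,
                       outlier_sd = 2.0,
                       method_names = paste0("method_", seq_len(n_methods)),
                       seed = 1L) {
  if (pi_de < 0 || pi_de > 1) abort_config("pi_de must be in [0, 1]")
  if (any(dropout < 0 | dropout >= 1)) abort_config("dropout must be in [0, 1)")
  if (!is.null(noise_sd) && any(noise_sd <= 0)) abort_config("noise_sd must be > 0")
  if (outlier_sd <= 0) abort_config("outlier_sd must be > 0")
  if (length(method_names) != n_methods) abort_config("one name per method required")
  structure(list(n_genes = as.integer(n_genes), n_methods = as.integer(n_methods),
                 pi_de = pi_de, effect_range = effect_range,
                 bias = rep_len(bias, n_methods), gain = rep_len(gain, n_methods),
                 noise_sd = noise_sd, noise_sd_range = noise_sd_range,
                 dropout = rep_len(dropout, n_methods),
                 outlier_method = outlier_method, outlier_sd = outlier_sd,
                 method_names = method_names, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a gene-by-method log2FC matrix with known truth
#'
#' Non-outlier method m emits `a_m + b_m * theta_g + N(0, sd_m^2)`; the
#' outlier method emits independent `N(0, outlier_sd^2)`.  Each cell is
#' masked missing independently with the method's dropout probability.
#' Genes that lose every cell are dropped from the matrix (they remain in
#' the truth record), keeping the row invariant that every gene has at
#' least one observation.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a `profile_matrix`) and `truth`: `theta`,
#'   `de_labels` (named by gene over all simulated genes),
#'   `dropout_mask` (full logical matrix, TRUE = missing), `noise_sd`,
#'   `bias`, `gain`, `outlier_method`, `dropped_genes`.
#' @export
gen_profile_matrix <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  m <- cfg$n_methods
  genes <- sprintf("g%05d", seq_len(n))
  de <- stats::runif(n) < cfg$pi_de
  theta <- numeric(n)
  theta[de] <- sample(c(-1, 1), sum(de), replace = TRUE) *
    stats::runif(sum(de), cfg$effect_range[1], cfg$effect_range[2])
  sds <- if (is.null(cfg$noise_sd)) {
    stats::runif(m, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
  } else {
    rep_len(cfg$noise_sd, m)
  }
  values <- matrix(NA_real_, n, m, dimnames = list(genes, cfg$method_names))
  for (j in seq_len(m)) {
    values[, j] <- if (!is.na(cfg$outlier_method) && j == cfg$outlier_method) {
      stats::rnorm(n, 0, cfg$outlier_sd)
    } else {
      cfg$bias[j] + cfg$gain[j] * theta + stats::rnorm(n, 0, sds[j])
    }
  }
  mask <- matrix(stats::runif(n * m) < rep(cfg$dropout, each = n), n, m,
                 dimnames = dimnames(values))
  values[mask] <- NA_real_
  keep <- rowSums(!mask) > 0L
  truth <- list(theta = stats::setNames(theta, genes),
                de_labels = stats::setNames(de, genes),
                dropout_mask = mask,
                noise_sd = stats::setNames(sds, cfg$method_names),
                bias = stats::setNames(cfg$bias, cfg$method_names),
                gain = stats::setNames(cfg$gain, cfg$method_names),
                outlier_method = if (is.na(cfg$outlier_method)) NA_character_
                                 else cfg$method_names[cfg$outlier_method],
                dropped_genes = genes[!keep])
  list(matrix = profile_matrix(values[keep, , drop = FALSE]), truth = truth)
}

#' Generate per-method DE call tables with p- and q-values
#'
#' Builds on [gen_profile_matrix()]: each method's table contains its
#' observed genes, a z-statistic `y / sd_m` (the outlier method uses its
#' own sd), two-sided normal p-values, and Benjamini-Hochberg q-values
#' computed within the table.
#'
#' @param cfg a [sim_config()].
#' @return list with `tables` (named list of [method_call_table()]),
#'   `matrix`, and `truth` as in [gen_profile_matrix()].
#' @export
gen_method_tables <- function(cfg) {
  sim <- gen_profile_matrix(cfg)
  mat <- unclass(sim$matrix)
  tables <- lapply(seq_len(ncol(mat)), function(j) {
    obs <- !is.na(mat[, j])
    y <- mat[obs, j]
    sd_j <- if (!is.na(cfg$outlier_method) &&
                colnames(mat)[j] == sim$truth$outlier_method) {
      cfg$outlier_sd
    } else {
      sim$truth$noise_sd[j]
    }
    z <- (y - sim$truth$bias[j]) / sd_j
    p <- 2 * stats::pnorm(-abs(z))
    method_call_table(rownames(mat)[obs], y, pvalue = p, qvalue = bh_adjust(p),
                      method_name = colnames(mat)[j])
  })
  names(tables) <- colnames(mat)
  list(tables = tables, matrix = sim$matrix, truth = sim$truth)
}

#' Generate an alignment-hit fixture with known parent associations
#'
#' Each pseudogene receives one true-parent hit whose e-value is drawn
#' strictly below every decoy e-value (construction guarantees the
#' best-hit rule recovers the truth), plus `decoys` hits against other
#' genes.  Percent identities straddle the 90% similarity criterion.
#'
#' @param n_pseudogenes number of pseudogenes (>= 1).
#' @param n_parents size of the candidate parent-gene pool (>= 2 when
#'   decoys are requested).
#' @param decoys decoy hits per pseudogene (default 5).
#' @param seed RNG seed.
#' @return list with `hits` (an `alignment_hits` data frame, rows
#'   shuffled) and `truth` (data frame `pseudogene_id`,
#'   `parent_gene_id`, `identity_pct`).
#' @export
gen_hit_table <- function(n_pseudogenes, n_parents, decoys = 5, seed = 1L) {
  if (n_pseudogenes < 1 || n_parents < 1) abort_config("counts must be >= 1")
  if (decoys > 0 && n_parents < 2) abort_config("decoys need >= 2 parent genes")
  set.seed(seed)
  psg <- sprintf("PSG%04d", seq_len(n_pseudogenes))
  pool <- sprintf("GENE%04d", seq_len(n_parents))
  true_parent <- sample(pool, n_pseudogenes, replace = TRUE)
  rows <- vector("list", n_pseudogenes)
  for (i in seq_len(n_pseudogenes)) {
    true_e <- 10^(-stats::runif(1, 120, 180))
    decoy_e <- 10^(-stats::runif(decoys, 5, 80))
    subj <- c(true_parent[i],
              sample(setdiff(pool, true_parent[i]), decoys,
                     replace = decoys > n_parents - 1))
    ev <- c(true_e, decoy_e)
    len <- sample(200:2000, decoys + 1, replace = TRUE)
    ident <- round(c(stats::runif(1, 80, 100), stats::runif(decoys, 60, 95)), 2)
    rows[[i]] <- data.frame(
      query_id = psg[i], subject_id = subj, identity_pct = ident,
      align_len = len,
      mismatches = as.integer(round(len * (100 - ident) / 100)),
      gap_opens = sample(0:5, decoys + 1, replace = TRUE),
      q_start = 1L, q_end = len,
      s_start = 1L, s_end = len,
      evalue = ev,
      bitscore = round(2 * -log10(ev) + stats::runif(decoys + 1, 0, 5), 1),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  hits <- hits[sample(nrow(hits)), ]
  rownames(hits) <- NULL
  class(hits) <- c("alignment_hits", "data.frame")
  list(hits = hits,
       truth = data.frame(pseudogene_id = psg, parent_gene_id = true_parent,
                          identity_pct = vapply(rows, function(r) r$identity_pct[1],
                                                numeric(1)),
                          stringsAsFactors = FALSE))
}
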