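#' Run the full reconciliation pipeline
#'
#' Wires the stages in workflow order: per-method significant sets and
#' Venn decomposition of the DE-space, Alternating Regression Model
#' rotation and rotation-averaged ensemble profile, IQR selection of the
#' coreset, the PCA-based alternative selection, their overlap, and
#' (when a catalog is supplied) biotype/family decomposition of the
#' ensemble selection.  When `out_dir` is given, every stage's table is
#' written as TSV together with a machine-readable JSON summary of all
#' stage counts and the configuration actually used.
#'
#' @param tables named list of [method_call_table()] objects (>= 3 for
#'   the regression stage).
#' @param catalog optional [biotype_catalog()].
#' @param rule a [significance_rule()] for the consensus stage.
#' @param cfg an [arm_config()].
#' @param pca_k fence multiplier for the PCA selection (default 1.5).
#' @param out_dir optional output directory; created if absent.
#' @return (invisibly) a list with `matrix`, `consensus`, `rotation`,
#'   `ensemble`, `arm_selection`, `pca`, `overlap`, `biotypes`,
#'   `families`, and `summary` (the stage counts).
#' @export
run_pipeline <- function(tables, catalog = NULL, rule = significance_rule(),
                         cfg = arm_config(), pca_k = 1.5, out_dir = NULL) {
  matrix <- build_profile_matrix(tables)

  sets <- lapply(tables, significant_set, rule = rule)
  names(sets) <- vapply(tables, function(t) attr(t, "method_name"), character(1))
  consensus <- venn_decompose(sets)
  cons_table <- consensus_summary(matrix, sets)

  rotation <- arm_rotate(matrix, cfg)
  ensemble <- ensemble_average(rotation, cfg)
  arm_selection <- ensemble_select(ensemble, cfg)

  pca <- pc1_select(matrix, k = pca_k)
  overlap <- intersect(arm_selection$selected, pca$selection$selected)

  biotypes <- families <- NULL
  if (!is.null(catalog)) {
    biotypes <- biotype_decompose(arm_selection$selected, catalog)
    families <- family_decompose(arm_selection$selected, catalog)
  }

  summary <- list(
    n_genes = nrow(matrix),
    n_methods = ncol(matrix),
    per_method_significant = vapply(sets, length, integer(1)),
    consensus_union = consensus$union_size,
    consensus_core = length(consensus$core),
    excluded_responses = names(attr(ensemble, "excluded_responses")),
    ensemble_genes = nrow(ensemble),
    arm_selected = length(arm_selection$selected),
    pca_selected = length(pca$selection$selected),
    arm_pca_overlap = length(overlap),
    config = list(q_max = rule$q_max, lfc_min = rule$lfc_min,
                  alpha = cfg$alpha, missing_policy = cfg$missing_policy,
                  elimination = cfg$elimination,
                  summary_stat = cfg$summary_stat, iqr_k = cfg$iqr_k,
                  pca_k = pca_k))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_matrix(matrix, file.path(out_dir, "profile_matrix.tsv"))
    utils::write.table(cons_table, file.path(out_dir, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(signature = names(consensus$region_counts),
                 count = as.integer(consensus$region_counts)),
      file.path(out_dir, "venn_regions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rotation_report(rotation),
                       file.path(out_dir, "arm_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(ensemble),
                       file.path(out_dir, "ensemble_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selection_table(arm_selection, ensemble, cfg),
                       file.path(out_dir, "arm_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = names(pca$pc1_scores),
                 pc1_score = unname(pca$pc1_scores),
                 selected = names(pca$pc1_scores) %in% pca$selection$selected,
                 stringsAsFactors = FALSE),
      file.path(out_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(biotypes)) {
      utils::write.table(biotypes, file.path(out_dir, "biotypes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(families, file.path(out_dir, "families.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(matrix = matrix, consensus = consensus,
                 consensus_table = cons_table, rotation = rotation,
                 ensemble = ensemble, arm_selection = arm_selection,
                 pca = pca, overlap = overlap, biotypes = biotypes,
                 families = families, summary = summary))
}

#' Per-rotation fit report
#'
#' One row per (response, regressor) pair plus the intercept, with the
#' coefficient, its p-value, whether it was retained, and the fit's r2.
#'
#' @param rotation an `arm_rotation`.
#' @return a data frame ready to write as TSV.
#' @export
rotation_report <- function(rotation) {
  rows <- lapply(rotation, function(f) {
    terms <- names(f$coefficients)
    data.frame(response = f$response, term = terms,
               coefficient = unname(f$coefficients),
               pvalue = unname(f$coef_pvalues[terms]),
               retained = terms %in% c("(Intercept)", f$regressors_retained),
               r2 = f$r2, predictable = f$predictable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

selection_table <- function(selection, ensemble, cfg) {
  vals <- stats::setNames(ensemble[[cfg$summary_stat]], ensemble$gene_id)
  data.frame(gene_id = selection$selected,
             value = unname(vals[selection$selected]),
             direction = unname(selection$direction[selection$selected]),
             stringsAsFactors = FALSE)
}

#' One-command demo on simulated data
#'
#' Generates method tables from the default simulation scenario at the
#' given seed and runs the full pipeline, returning the pipeline result
#' augmented with the simulation truth and recovery metrics (recall and
#' precision of the ensemble selection against the true DE labels).
#'
#' @param seed simulation seed.
#' @param cfg_sim a [sim_config()]; its `seed` field is overridden by
#'   `seed`.
#' @param ... passed to [run_pipeline()].
#' @return the [run_pipeline()] result list, plus `truth` and `recovery`.
#' @export
run_demo <- function(seed = 7L, cfg_sim = sim_config(), ...) {
  cfg_sim$seed <- as.integer(seed)
  sim <- gen_method_tables(cfg_sim)
  res <- run_pipeline(sim$tables, ...)
  truth_de <- names(sim$truth$de_labels)[sim$truth$de_labels]
  sel <- res$arm_selection$selected
  res$truth <- sim$truth
  res$recovery <- list(
    recall = length(intersect(sel, truth_de)) / length(truth_de),
    precision = if (length(sel)) length(intersect(sel, truth_de)) / length(sel)
                else NA_real_)
  res$summary$recall <- res$recovery$recall
  res$summary$precision <- res$recovery$precision
  invisible(res)
}
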