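#' Alternating Regression Model configuration
#'
#' @param alpha coefficient-significance level in (0, 1); a regressor is
#'   retained while its two-sided t-test p-value is below `alpha`
#'   (default 0.05).
#' @param missing_policy `"complete_case"` (default): each fit uses only
#'   genes where the response and all current regressors are observed;
#'   `"mean_fill"`: missing regressor cells are imputed with the
#'   regressor's mean over the response-observed rows.
#' @param include_intercept include an intercept term (default TRUE).
#'   The intercept is never subject to elimination.
#' @param elimination `"backward"` (default): repeatedly drop the
#'   regressor with the largest p-value >= alpha and refit until all
#'   retained regressors are significant; `"single_pass"`: fit once and
#'   flag significance without refitting.
#' @param summary_stat which rotation summary feeds the selection step:
#'   `"mean"` (default) or `"median"`.  Both are always computed.
#' @param iqr_k fence multiplier for the selection step (default 3).
#' @return an `arm_config` list.
#' @export
arm_config <- function(alpha = 0.05,
                       missing_policy = c("complete_case", "mean_fill"),
                       include_intercept = TRUE,
                       elimination = c("backward", "single_pass"),
                       summary_stat = c("mean", "median"),
                       iqr_k = 3) {
  if (alpha <= 0 || alpha >= 1) abort_config("alpha must be in (0, 1)")
  if (iqr_k <= 0) abort_config("iqr_k must be > 0")
  structure(list(alpha = alpha,
                 missing_policy = match.arg(missing_policy),
                 include_intercept = isTRUE(include_intercept),
                 elimination = match.arg(elimination),
                 summary_stat = match.arg(summary_stat),
                 iqr_k = iqr_k),
            class = "arm_config")
}

# One OLS fit of y on X (columns already chosen).  Returns coefficients,
# two-sided t-test p-values, r2 and the qr object.  Errors on rank
# deficiency, naming the dependent columns.
ols_fit <- function(X, y, response) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    abort_numeric("rank-deficient regressors for response '", response,
                  "': ", paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rdf <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / rdf
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), rdf)
  has_int <- "(Intercept)" %in% colnames(X)
  sst <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
  list(coefficients = stats::setNames(beta, colnames(X)),
       pvalues = stats::setNames(pval, colnames(X)),
       r2 = r2, n = length(y))
}

# Design matrix for the given regressor columns under the missing policy.
# Returns the row index used for fitting and the (possibly imputed) full
# regressor matrix for prediction.
arm_design <- function(matrix, response, regressors, policy) {
  Z <- unclass(matrix)[, regressors, drop = FALSE]
  y_obs <- !is.na(unclass(matrix)[, response])
  if (policy == "complete_case") {
    rows <- y_obs & stats::complete.cases(Z)
  } else {
    rows <- y_obs
    for (j in seq_len(ncol(Z))) {
      mu <- mean(Z[rows, j], na.rm = TRUE)
      Z[is.na(Z[, j]), j] <- mu
    }
  }
  list(rows = rows, Z = Z)
}

#' Fit one rotation of the Alternating Regression Model
#'
#' Ordinary least squares of one method's log2FC profile on the remaining
#' methods' profiles, with significance-driven regressor retention.
#' Under backward elimination, the regressor with the largest p-value
#' >= `alpha` is dropped and the model refit (the usable gene rows are
#' recomputed for the current regressor set under `complete_case`) until
#' every retained regressor is significant.  When no regressor survives,
#' the response is flagged not predictable and contributes no fitted
#' values to the ensemble.
#'
#' Fitted values of a predictable rotation are computed for every gene
#' whose retained regressors are all observed, so the rotation also
#' predicts the response where the response method itself reported
#' nothing; this is what lets the ensemble fill per-method gaps.
#'
#' @param matrix a `profile_matrix`.
#' @param response the method label serving as response.
#' @param cfg an [arm_config()].
#' @return an `arm_fit` list: `response`, `regressors_initial`,
#'   `regressors_retained`, `coefficients`, `coef_pvalues`, `fitted`
#'   (named numeric over the prediction domain; `NULL` when not
#'   predictable), `r2`, `n_obs`, `predictable`.
#' @export
fit_response <- function(matrix, response, cfg = arm_config()) {
  if (!response %in% colnames(matrix)) {
    abort_usage("response '", response, "' not among matrix methods")
  }
  regs_init <- setdiff(colnames(matrix), response)
  regs <- regs_init
  y_all <- unclass(matrix)[, response]
  fit <- NULL
  repeat {
    d <- arm_design(matrix, response, regs, cfg$missing_policy)
    n_rows <- sum(d$rows)
    if (n_rows < length(regs) + 2L) {
      abort_data("too few usable genes (", n_rows, ") to fit response '",
                 response, "'")
    }
    X <- d$Z[d$rows, , drop = FALSE]
    if (cfg$include_intercept) X <- cbind(`(Intercept)` = 1, X)
    fit <- ols_fit(X, y_all[d$rows], response)
    p_reg <- fit$pvalues[regs]
    if (cfg$elimination == "single_pass") {
      regs <- regs[p_reg < cfg$alpha]
      break
    }
    if (length(regs) == 0L || all(p_reg < cfg$alpha)) break
    worst <- names(which.max(p_reg))
    regs <- setdiff(regs, worst)
    if (length(regs) == 0L) break
  }

  retained <- regs
  predictable <- length(retained) > 0L

  if (!predictable) {
    mu <- if (cfg$include_intercept) mean(y_all, na.rm = TRUE) else 0
    return(structure(list(response = response,
                          regressors_initial = regs_init,
                          regressors_retained = character(0),
                          coefficients = c(`(Intercept)` = mu),
                          coef_pvalues = c(`(Intercept)` = NA_real_),
                          fitted = NULL, r2 = NA_real_,
                          n_obs = sum(!is.na(y_all)),
                          predictable = FALSE),
                     class = "arm_fit"))
  }

  if (cfg$elimination == "backward") {
    # `fit` already reflects exactly the retained regressors
    final <- fit
    pred_regs <- retained
  } else {
    final <- fit
    pred_regs <- regs_init   # single-pass predicts from the full fit
  }

  d <- arm_design(matrix, response, pred_regs, cfg$missing_policy)
  pred_rows <- if (cfg$missing_policy == "complete_case") {
    stats::complete.cases(d$Z)
  } else {
    rep(TRUE, nrow(d$Z))
  }
  Xp <- d$Z[pred_rows, , drop = FALSE]
  if (cfg$include_intercept) Xp <- cbind(`(Intercept)` = 1, Xp)
  fitted <- drop(Xp %*% final$coefficients[colnames(Xp)])
  names(fitted) <- rownames(matrix)[pred_rows]

  structure(list(response = response,
                 regressors_initial = regs_init,
                 regressors_retained = retained,
                 coefficients = final$coefficients,
                 coef_pvalues = final$pvalues,
                 fitted = fitted,
                 r2 = final$r2,
                 n_obs = final$n,
                 predictable = TRUE),
            class = "arm_fit")
}

#' @export
print.arm_fit <- function(x, ...) {
  cat(sprintf("arm_fit: %s ~ %s\n", x$response,
              if (x$predictable) paste(x$regressors_retained, collapse = " + ")
              else "(no significant regressors)"))
  if (x$predictable) {
    cat(sprintf("  n = %d, r2 = %.4f, fitted over %d genes\n",
                x$n_obs, x$r2, length(x$fitted)))
  }
  invisible(x)
}

#' Rotate the response over all methods
#'
#' Runs [fit_response()] once per method, each time with the remaining
#' methods as regressors.  Deterministic given the matrix and config.
#'
#' @param matrix a `profile_matrix` with at least 3 methods.
#' @param cfg an [arm_config()].
#' @return an `arm_rotation`: a named list of `arm_fit` objects, one per
#'   method in the matrix's column order.
#' @export
arm_rotate <- function(matrix, cfg = arm_config()) {
  if (ncol(matrix) < 3L) abort_usage("rotation needs at least 3 methods")
  fits <- lapply(colnames(matrix), function(m) fit_response(matrix, m, cfg))
  names(fits) <- colnames(matrix)
  structure(fits, class = "arm_rotation")
}

#' Rotation-averaged ensemble profile
#'
#' Per gene, the mean and median of fitted values over the predictable
#' rotations that cover it.  Rotations flagged not predictable are
#' excluded from the average (with the reason recorded) but their
#' profiles remain available as regressors inside the other fits.
#'
#' @param fits an `arm_rotation` or list of `arm_fit` objects.
#' @param cfg an [arm_config()].
#' @return an `ensemble_profile`: data frame with columns `gene_id`,
#'   `mean`, `median`, `n_contributing`, plus attributes
#'   `included_responses` and `excluded_responses`.
#' @export
ensemble_average <- function(fits, cfg = arm_config()) {
  pred <- vapply(fits, function(f) f$predictable, logical(1))
  if (!any(pred)) abort_numeric("no predictable rotation; ensemble undefined")
  included <- fits[pred]
  excluded <- vapply(fits[!pred], function(f) f$response, character(1))
  genes <- sort(unique(unlist(lapply(included, function(f) names(f$fitted)))))
  F <- matrix(NA_real_, length(genes), length(included),
              dimnames = list(genes, vapply(included, function(f) f$response,
                                            character(1))))
  for (j in seq_along(included)) {
    f <- included[[j]]
    F[names(f$fitted), j] <- f$fitted
  }
  n_contrib <- rowSums(!is.na(F))
  out <- data.frame(gene_id = genes,
                    mean = rowMeans(F, na.rm = TRUE),
                    median = apply(F, 1L, stats::median, na.rm = TRUE),
                    n_contributing = as.integer(n_contrib),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "included_responses") <- colnames(F)
  attr(out, "excluded_responses") <-
    if (length(excluded)) stats::setNames(rep("no significant regressors",
                                              length(excluded)), excluded)
    else stats::setNames(character(0), character(0))
  class(out) <- c("ensemble_profile", "data.frame")
  out
}

#' Boxplot/IQR outlier selection
#'
#' Tukey fences around the interquartile range: quartiles are computed by
#' linear interpolation of the sorted values at positions
#' `(n - 1) * {0.25, 0.75}`, the fences are `Q1 - k * IQR` and
#' `Q3 + k * IQR`, and a value is selected only when strictly outside a
#' fence.  Non-finite values are dropped before computing quartiles.
#'
#' @param values named numeric vector (names = gene ids); at least 4
#'   finite values.
#' @param k fence multiplier (1.5 is the boxplot whisker convention; 3 is
#'   the stringent choice for ensemble predictions).
#' @param statistic_name label recorded in the result.
#' @return a `selection_result` list: `q1`, `q3`, `iqr`, `lower_fence`,
#'   `upper_fence`, `k`, `selected` (character), `direction` (named
#'   `"above"`/`"below"`), `n_values`.
#' @export
iqr_select <- function(values, k = 1.5, statistic_name = "value") {
  if (k <= 0) abort_config("k must be > 0")
  v <- values[is.finite(values)]
  if (length(v) < 4L) abort_data("need at least 4 finite values, got ", length(v))
  if (is.null(names(v))) names(v) <- as.character(seq_along(values))[is.finite(values)]
  # quartiles by linear interpolation of the order statistics at
  # positions (n - 1) * q; computed directly at those positions so that
  # values tied exactly with a fence behave reproducibly
  s <- sort(v)
  n <- length(s)
  q <- vapply(c(0.25, 0.75), function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    s[[lo + 1]] + (h - lo) * (s[[min(lo + 2, n)]] - s[[lo + 1]])
  }, numeric(1))
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  below <- v < lower
  above <- v > upper
  selected <- names(v)[below | above]
  direction <- stats::setNames(ifelse(below[below | above], "below", "above"),
                               selected)
  structure(list(statistic_name = statistic_name,
                 q1 = q[1], q3 = q[2], iqr = iqr,
                 lower_fence = lower, upper_fence = upper, k = k,
                 selected = selected, direction = direction,
                 n_values = length(v)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("iqr selection (%s, k = %g): %d of %d outside [%.4g, %.4g]\n",
              x$statistic_name, x$k, length(x$selected), x$n_values,
              x$lower_fence, x$upper_fence))
  invisible(x)
}

#' Select the ensemble coreset
#'
#' Convenience wrapper: applies [iqr_select()] to the configured summary
#' statistic of an [ensemble_average()] profile at `cfg$iqr_k`.
#'
#' @param profile an `ensemble_profile`.
#' @param cfg an [arm_config()].
#' @return a `selection_result`.
#' @export
ensemble_select <- function(profile, cfg = arm_config()) {
  v <- stats::setNames(profile[[cfg$summary_stat]], profile$gene_id)
  iqr_select(v, k = cfg$iqr_k,
             statistic_name = paste0("ensemble_", cfg$summary_stat))
}
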