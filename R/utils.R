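# Classed conditions so callers (and the CLI) can map failures to exit codes:
# config errors -> 2, data errors -> 3, numerical/degeneracy errors -> 4.

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("armonize_config_error", "armonize_error")))
}

abort_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("armonize_data_error", "armonize_error")))
}

abort_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("armonize_numeric_error", "armonize_error")))
}

abort_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("armonize_usage_error", "armonize_error")))
}

#' Round half away from zero
#'
#' Fixed-precision rounding where ties go up (0.005 -> 0.01), unlike base
#' [round()] which rounds half to even.  Used for percentage reporting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts raw p-values into FDR-adjusted q-values by the step-up
#' procedure: sort p ascending, q_(i) = min over j >= i of p_(j) * n / j,
#' capped at 1.  NA p-values yield NA q-values and do not enter n.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort_usage("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort_data("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  n <- sum(ok)
  if (n == 0L) return(q)
  ord <- order(p[ok])
  ranked <- p[ok][ord] * n / seq_len(n)
  q_sorted <- pmin(1, rev(cummin(rev(ranked))))
  qv <- numeric(n)
  qv[ord] <- q_sorted
  q[ok] <- qv
  q
}
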