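# Small builders shared across test files.  Everything is generated in
# code; no fixture files are stored.

toy_table <- function(method, genes, lfc, p = NULL, q = NULL) {
  if (is.null(p)) p <- rep(0.01, length(genes))
  if (is.null(q)) q <- p
  method_call_table(genes, lfc, p, q, method_name = method)
}

# gene x method matrix with names filled in
toy_matrix <- function(values, genes = NULL, methods = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(methods)) {
    methods <- if (!is.null(colnames(values))) colnames(values)
               else paste0("m", seq_len(ncol(values)))
  }
  dimnames(values) <- list(genes, methods)
  profile_matrix(values)
}

# Independent straightforward re-implementation of one ARM rotation used
# as the end-to-end oracle: stats::lm for fitting, summary() p-values,
# backward elimination, prediction wherever retained regressors are
# observed.  Shares no code with the package internals.
oracle_fit <- function(Y, resp, alpha = 0.05) {
  regs <- setdiff(colnames(Y), resp)
  repeat {
    rows <- stats::complete.cases(Y[, c(resp, regs), drop = FALSE])
    df <- as.data.frame(Y[rows, c(resp, regs), drop = FALSE])
    names(df) <- c("y", regs)
    f <- stats::lm(stats::reformulate(regs, "y"), data = df)
    p <- summary(f)$coefficients[-1, 4]
    if (length(regs) == 0L || all(p < alpha)) break
    w <- which.max(p)
    if (p[w] < alpha) break
    regs <- regs[-w]
    if (length(regs) == 0L) return(NULL)
  }
  if (length(regs) == 0L) return(NULL)
  pr <- stats::complete.cases(Y[, regs, drop = FALSE])
  newdata <- as.data.frame(Y[pr, regs, drop = FALSE])
  names(newdata) <- regs
  fitted <- stats::predict(f, newdata = newdata)
  names(fitted) <- rownames(Y)[pr]
  fitted
}

oracle_ensemble_mean <- function(Y, alpha = 0.05) {
  fits <- lapply(colnames(Y), function(m) oracle_fit(Y, m, alpha))
  fits <- Filter(Negate(is.null), fits)
  genes <- sort(unique(unlist(lapply(fits, names))))
  F <- sapply(fits, function(f) f[genes])
  rownames(F) <- genes
  rowMeans(F, na.rm = TRUE)
}

# Brute-force Tukey fences from a sorted array, interpolating order
# statistics at positions (n - 1) * q by hand.
oracle_iqr_select <- function(values, k) {
  v <- sort(values[is.finite(values)])
  n <- length(v)
  interp <- function(q) {
    h <- (n - 1) * q
    lo <- floor(h)
    v[lo + 1] + (h - lo) * (v[min(lo + 2, n)] - v[lo + 1])
  }
  q1 <- interp(0.25)
  q3 <- interp(0.75)
  iqr <- q3 - q1
  keep <- values[is.finite(values)]
  names(keep)[keep < q1 - k * iqr | keep > q3 + k * iqr]
}
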