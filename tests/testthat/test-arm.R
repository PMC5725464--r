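test_that("identity regression recovers slope 1, intercept 0, r2 = 1", {
  set.seed(1)
  x <- rnorm(50)
  m <- toy_matrix(cbind(x, x), methods = c("resp", "reg"))
  fit <- fit_response(m, "resp")
  expect_true(fit$predictable)
  expect_equal(unname(fit$coefficients["reg"]), 1)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0)
  expect_equal(fit$r2, 1)
})

test_that("backward elimination keeps the informative regressor, drops noise", {
  set.seed(42)
  n <- 200
  a <- rnorm(n, sd = 2)
  m <- toy_matrix(cbind(resp = a + rnorm(n, sd = 0.05),
                        a = a,
                        noise1 = rnorm(n),
                        noise2 = rnorm(n)),
                  methods = c("resp", "a", "noise1", "noise2"))
  fit <- fit_response(m, "resp")
  expect_equal(fit$regressors_retained, "a")
  expect_lt(abs(fit$coefficients[["a"]] - 1), 0.05)
  expect_gt(fit$r2, 0.99)
})

test_that("a response independent of all regressors is not predictable", {
  set.seed(7)
  n <- 500
  theta <- ifelse(runif(n) < 0.2, rnorm(n, sd = 3), 0)
  m <- toy_matrix(cbind(r1 = theta + rnorm(n, sd = 0.4),
                        r2 = theta + rnorm(n, sd = 0.5),
                        r3 = theta + rnorm(n, sd = 0.6),
                        indep = rnorm(n, sd = 2)))
  fit <- fit_response(m, "indep")
  expect_false(fit$predictable)
  expect_length(fit$regressors_retained, 0L)
  expect_named(fit$coefficients, "(Intercept)")
  expect_null(fit$fitted)
})

test_that("OLS coefficients match a normal-equations oracle", {
  # full-model (single-pass) coefficients vs solve(X'X, X'y)
  cfg <- arm_config(elimination = "single_pass")
  set.seed(99)
  for (i in 1:20) {
    n <- sample(20:500, 1)
    p <- sample(2:4, 1)
    shared <- rnorm(n, sd = 2)
    V <- sapply(seq_len(p + 1), function(j) shared + rnorm(n))
    colnames(V) <- c("resp", paste0("x", seq_len(p)))
    m <- toy_matrix(V, methods = colnames(V))
    fit <- fit_response(m, "resp", cfg)
    X <- cbind(1, V[, -1, drop = FALSE])
    beta <- solve(crossprod(X), crossprod(X, V[, 1]))
    expect_lt(max(abs(fit$coefficients - drop(beta))) /
                max(abs(beta)), 1e-8)
  }
})

test_that("collinear regressors raise a rank-deficiency error naming them", {
  set.seed(2)
  v <- rnorm(30)
  m <- toy_matrix(cbind(v, v, v), methods = c("a", "b", "c"))
  expect_error(fit_response(m, "a"), "rank-deficient",
               class = "armonize_numeric_error")
  expect_error(arm_rotate(m), class = "armonize_numeric_error")
})

test_that("too few usable rows raise a fit error naming the response", {
  m <- toy_matrix(matrix(rnorm(9), 3, 3), methods = c("a", "b", "c"))
  expect_error(fit_response(m, "a"), "a", class = "armonize_data_error")
})

test_that("rotation yields one fit per method over adapted domains", {
  sim <- gen_profile_matrix(sim_config(n_genes = 600, seed = 3))
  rot <- arm_rotate(sim$matrix)
  expect_length(rot, 5L)
  expect_equal(names(rot), colnames(sim$matrix))
  for (f in rot[vapply(rot, function(f) f$predictable, logical(1))]) {
    # fit rows: response and all retained regressors observed
    cols <- c(f$response, f$regressors_retained)
    expect_equal(f$n_obs,
                 sum(stats::complete.cases(unclass(sim$matrix)[, cols])))
    # prediction domain: all retained regressors observed
    expect_setequal(names(f$fitted),
                    rownames(sim$matrix)[stats::complete.cases(
                      unclass(sim$matrix)[, f$regressors_retained, drop = FALSE])])
  }
})

test_that("mean_fill imputation extends fits to the response domain", {
  sim <- gen_profile_matrix(sim_config(n_genes = 400, seed = 5))
  fit <- fit_response(sim$matrix, colnames(sim$matrix)[1],
                      arm_config(missing_policy = "mean_fill"))
  expect_true(fit$predictable)
  expect_equal(length(fit$fitted), nrow(sim$matrix))
})

test_that("ensemble averaging is a fixed point on identical fitted profiles", {
  v <- c(g1 = -2, g2 = 0.5, g3 = 1, g4 = 3)
  mk <- function(resp) structure(
    list(response = resp, regressors_initial = c("x", "y"),
         regressors_retained = "x",
         coefficients = c(`(Intercept)` = 0, x = 1),
         coef_pvalues = c(`(Intercept)` = 1, x = 0),
         fitted = v, r2 = 1, n_obs = 4, predictable = TRUE),
    class = "arm_fit")
  prof <- ensemble_average(list(mk("a"), mk("b"), mk("c")))
  expect_equal(setNames(prof$mean, prof$gene_id), v[prof$gene_id])
  expect_equal(prof$mean, prof$median)
  expect_equal(prof$n_contributing, rep(3L, 4))
})

test_that("a gene covered by one rotation takes that rotation's value", {
  f1 <- structure(list(response = "a", regressors_initial = "x",
                       regressors_retained = "x",
                       coefficients = c(`(Intercept)` = 0, x = 1),
                       coef_pvalues = c(`(Intercept)` = 1, x = 0),
                       fitted = c(g1 = 1, g2 = 2), r2 = 1, n_obs = 2,
                       predictable = TRUE), class = "arm_fit")
  f2 <- structure(list(response = "b", regressors_initial = "x",
                       regressors_retained = character(0),
                       coefficients = c(`(Intercept)` = 5),
                       coef_pvalues = c(`(Intercept)` = NA_real_),
                       fitted = NULL, r2 = NA_real_, n_obs = 2,
                       predictable = FALSE), class = "arm_fit")
  f3 <- structure(list(response = "c", regressors_initial = "x",
                       regressors_retained = "x",
                       coefficients = c(`(Intercept)` = 0, x = 1),
                       coef_pvalues = c(`(Intercept)` = 1, x = 0),
                       fitted = c(g2 = 4, g3 = 9), r2 = 1, n_obs = 2,
                       predictable = TRUE), class = "arm_fit")
  prof <- ensemble_average(list(f1, f2, f3))
  got <- setNames(prof$mean, prof$gene_id)
  expect_equal(got[["g1"]], 1)     # only rotation a covers g1
  expect_equal(got[["g3"]], 9)     # only rotation c covers g3
  expect_equal(got[["g2"]], 3)     # mean of 2 and 4
  expect_equal(names(attr(prof, "excluded_responses")), "b")
  expect_error(ensemble_average(list(f2)), class = "armonize_numeric_error")
})

test_that("ensemble mean matches an independently coded end-to-end oracle", {
  sim <- gen_profile_matrix(sim_config(n_genes = 800, seed = 17))
  rot <- arm_rotate(sim$matrix)
  prof <- ensemble_average(rot)
  oracle <- oracle_ensemble_mean(unclass(sim$matrix))
  expect_setequal(prof$gene_id, names(oracle))
  expect_equal(setNames(prof$mean, prof$gene_id)[names(oracle)], oracle,
               tolerance = 1e-10)
})

test_that("iqr_select uses type-7 quartiles and strict fences", {
  const <- setNames(rep(2, 10), paste0("g", 1:10))
  sel <- iqr_select(const, k = 1.5)
  expect_equal(sel$iqr, 0)
  expect_length(sel$selected, 0L)

  v <- setNames(c(1:100, -1000, 1000), c(sprintf("g%03d", 1:100), "lo", "hi"))
  sel2 <- iqr_select(v, k = 1.5)
  expect_setequal(sel2$selected, c("lo", "hi"))
  expect_equal(sel2$direction[["lo"]], "below")
  expect_equal(sel2$direction[["hi"]], "above")

  set.seed(31)
  z <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  sel3 <- iqr_select(z, k = 3)
  expect_setequal(sel3$selected, oracle_iqr_select(z, 3))

  expect_error(iqr_select(c(a = 1, b = 2, c = 3), k = 1.5),
               class = "armonize_data_error")
})

test_that("scaling all profiles scales fences but not the selection", {
  sim <- gen_profile_matrix(sim_config(n_genes = 500, seed = 23))
  rot1 <- arm_rotate(sim$matrix)
  sel1 <- ensemble_select(ensemble_average(rot1))
  scaled <- profile_matrix(unclass(sim$matrix) * 2.5)
  rot2 <- arm_rotate(scaled)
  sel2 <- ensemble_select(ensemble_average(rot2))
  expect_equal(sel2$upper_fence, 2.5 * sel1$upper_fence, tolerance = 1e-10)
  expect_equal(sel2$lower_fence, 2.5 * sel1$lower_fence, tolerance = 1e-10)
  expect_setequal(sel2$selected, sel1$selected)
})

test_that("rotation and ensemble are invariant under method order", {
  sim <- gen_profile_matrix(sim_config(n_genes = 500, seed = 29))
  perm <- profile_matrix(unclass(sim$matrix)[, c(4, 1, 5, 2, 3)])
  p1 <- ensemble_average(arm_rotate(sim$matrix))
  p2 <- ensemble_average(arm_rotate(perm))
  expect_equal(setNames(p1$mean, p1$gene_id), setNames(p2$mean, p2$gene_id))
  expect_setequal(names(attr(p1, "excluded_responses")),
                  names(attr(p2, "excluded_responses")))
})
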