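test_that("read_method_table parses well-formed tables and reports missing q", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = sprintf("g%02d", 1:10),
                   lfc = round(seq(-2, 2.5, length.out = 10), 3),
                   p = rep(0.01, 10),
                   q = c("0.02", "NA", "0.03", "NA", "0.05", "0.1", "NA",
                         "0.2", "0.5", "0.9"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_method_table(path, "demo",
                           column_map = c(gene_id = "gene", log2fc = "lfc",
                                          pvalue = "p", qvalue = "q"))
  expect_s3_class(tab, "method_call_table")
  expect_equal(nrow(tab), 10L)
  # rows with q = NA are retained, with q absent, and counted in the report
  expect_equal(sum(is.na(tab$qvalue)), 3L)
  expect_equal(attr(tab, "parse_report")$n_missing_qvalue, 3L)
  expect_equal(tab$log2fc, df$lfc)
})

test_that("read_method_table rejects bad inputs with classed errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("g1", "g2", "g1"), lfc = 1:3),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_method_table(path, "x", column_map = c(gene_id = "gene", log2fc = "lfc")),
    "g1", class = "armonize_data_error")
  expect_error(
    read_method_table(path, "x", column_map = c(gene_id = "gene", log2fc = "nope")),
    "nope", class = "armonize_config_error")

  write.table(data.frame(gene = c("g1", "g2"), lfc = c("1.5", "high")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_method_table(path, "x", column_map = c(gene_id = "gene", log2fc = "lfc")),
    class = "armonize_data_error")
})

test_that("method tables round-trip through write/read exactly", {
  tab <- method_call_table(sprintf("g%02d", 1:6),
                           c(-1.5, 0, 2.25, 0.125, -3, 1e-3),
                           pvalue = c(0.01, NA, 0.5, 1, 0, 0.25),
                           qvalue = c(0.05, NA, NA, 1, 0, 0.5),
                           method_name = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_method_table(tab, path)
  back <- read_method_table(path, "rt")
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
})

test_that("build_profile_matrix takes the union with an observed mask", {
  a <- toy_table("A", c("g1", "g2"), c(1, 2))
  b <- toy_table("B", c("g2", "g3"), c(3, 4))
  m <- build_profile_matrix(list(a, b))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m)), 2L)
  expect_equal(unclass(m)["g2", ], c(A = 2, B = 3))

  same <- lapply(1:2, function(i)
    toy_table(c("A", "B")[i], sprintf("g%d", 1:5), 1:5))
  m5 <- build_profile_matrix(same)
  expect_equal(dim(m5), c(5L, 2L))
  expect_false(anyNA(m5))

  expect_error(build_profile_matrix(list(a)), class = "armonize_usage_error")
})

test_that("build_profile_matrix is invariant under table reordering", {
  sim <- gen_method_tables(sim_config(n_genes = 300, seed = 11))
  m1 <- build_profile_matrix(sim$tables)
  m2 <- build_profile_matrix(rev(sim$tables))
  expect_equal(unclass(m1), unclass(m2)[, colnames(m1)])
})

test_that("matrix missingness equals the generator's realized dropout", {
  cfg <- sim_config(n_genes = 800, seed = 42)
  sim <- gen_method_tables(cfg)
  m <- build_profile_matrix(sim$tables)
  kept <- rownames(m)
  expect_identical(is.na(unclass(m))[kept, ],
                   sim$truth$dropout_mask[kept, ])
  # and the matrix built from tables matches the generator's own matrix
  expect_equal(unclass(m), unclass(sim$matrix)[kept, ])
})

test_that("expression filter applies strict thresholds and the sample quota", {
  genes <- c("zero", "edge_fpkm", "one_sample", "strong")
  samples <- sprintf("s%02d", 1:10)
  fpkm <- matrix(0, 4, 10, dimnames = list(genes, samples))
  counts <- matrix(0L, 4, 10, dimnames = list(genes, samples))
  fpkm["edge_fpkm", ] <- 1        # exactly at threshold: strict > excludes
  counts["edge_fpkm", ] <- 100L
  fpkm["one_sample", 1] <- 2      # one passing sample meets ceil(0.1 * 10) = 1
  counts["one_sample", 1] <- 11L
  fpkm["strong", ] <- 5
  counts["strong", ] <- 50L
  fe <- expression_matrix(fpkm, "fpkm", group = rep("tumor", 10))
  ce <- expression_matrix(counts, "read_count", group = rep("tumor", 10))
  res <- expression_filter(fe, ce, filter_config())
  expect_setequal(res$retained, c("one_sample", "strong"))
  expect_false("zero" %in% res$retained)
  expect_false("edge_fpkm" %in% res$retained)
  expect_equal(res$report$fpkm_pass_tumor[res$report$gene_id == "one_sample"], 1)
})

test_that("per-group evaluation requires the rule in every condition", {
  genes <- c("tumor_only", "both")
  samples <- sprintf("s%02d", 1:10)
  group <- rep(c("tumor", "control"), each = 5)
  fpkm <- matrix(0, 2, 10, dimnames = list(genes, samples))
  counts <- matrix(0L, 2, 10, dimnames = list(genes, samples))
  fpkm["tumor_only", 1:5] <- 10; counts["tumor_only", 1:5] <- 100L
  fpkm["both", ] <- 10; counts["both", ] <- 100L
  fe <- expression_matrix(fpkm, "fpkm", group = group)
  ce <- expression_matrix(counts, "read_count", group = group)
  per_group <- expression_filter(fe, ce, filter_config(per_group = TRUE))
  pooled <- expression_filter(fe, ce, filter_config(per_group = FALSE))
  expect_setequal(per_group$retained, "both")
  expect_setequal(pooled$retained, c("tumor_only", "both"))
})

test_that("raising thresholds never grows the retained set", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:50)
  samples <- sprintf("s%02d", 1:12)
  fpkm <- matrix(rexp(600, 1 / 2), 50, 12, dimnames = list(genes, samples))
  counts <- matrix(rpois(600, 15), 50, 12, dimnames = list(genes, samples))
  fe <- expression_matrix(fpkm, "fpkm", group = rep(c("a", "b"), 6))
  ce <- expression_matrix(counts, "read_count", group = rep(c("a", "b"), 6))
  base <- expression_filter(fe, ce, filter_config(fpkm_min = 1, count_min = 5))
  for (f in c(2, 4)) {
    for (cmin in c(10, 20)) {
      tighter <- expression_filter(fe, ce, filter_config(fpkm_min = f,
                                                         count_min = cmin))
      expect_true(all(tighter$retained %in% base$retained))
    }
  }
})

test_that("count_retained handles flags, groups and empty input", {
  expect_equal(count_retained(logical(0)), 0L)
  manifest <- data.frame(
    sample_id = sprintf("s%02d", 1:8),
    group = rep(c("tumor", "control"), each = 4),
    qc_flag = c("pass", "fail", "pass", "pass", "pass", "pass", "fail", "pass"))
  expect_equal(count_retained(manifest), 6L)
  expect_equal(count_retained(manifest, by_group = TRUE),
               c(control = 3L, tumor = 3L))
})
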