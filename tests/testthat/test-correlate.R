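test_that("r_squared matches hand-computed and boundary examples", {
  x <- c(0, 1, 2, 3)
  expect_equal(r_squared(x, x), 1.0)
  expect_warning(anti <- r_squared(c(1, 2, 3), c(3, 2, 1)), "anticorrelated")
  expect_equal(anti, 1.0)
  expect_equal(r_squared(x, c(0, 1, 1, 2)), 0.9, tolerance = 1e-12)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:2, 1:2), "at least 3")
})

test_that("r_squared matches the brute-force covariance oracle to 1e-12", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(3:200, 1)
    x <- rnorm(n); y <- x * runif(1, -2, 2) + rnorm(n)
    expect_equal(suppressWarnings(r_squared(x, y)), oracle_r2(x, y),
                 tolerance = 1e-12)
  }
})

test_that("r_squared is symmetric and invariant to positive affine maps and log base", {
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(20, 5, 2); y <- x + rnorm(20)
    expect_equal(r_squared(x, y), r_squared(y, x), tolerance = 1e-14)
    a <- runif(1, 0.1, 5); b <- runif(1, -3, 3)
    expect_equal(r_squared(a * x + b, y), r_squared(x, y), tolerance = 1e-12)
    # changing the upstream log base rescales both vectors by log2(10)
    expect_equal(r_squared(x / log2(10), y / log2(10)), r_squared(x, y),
                 tolerance = 1e-12)
  }
})

test_that("identity_line mode penalizes offsets that pearson_sq ignores", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(x, x + 2, mode = "pearson_sq"), 1)
  expect_lt(r_squared(x, x + 2, mode = "identity_line"), 1)
  expect_equal(r_squared(x, x, mode = "identity_line"), 1)
  expect_equal(r_squared(x, x + 2, mode = "identity_line"),
               r_squared(x + 2, x, mode = "identity_line"))
})

test_that("reference_profile takes per-gene medians across lots", {
  m <- matrix(c(1, 1, 5, 2, 9, 8, 0, 9), 2, 4,
              dimnames = list(c("gA", "gB"), paste0("L", 1:4)))
  em <- expression_matrix(m, "logTPM")
  p4 <- reference_profile(em, "four")
  expect_equal(unname(p4$values["gA"]), 3)  # median(1,5,9,0) = 3
  expect_equal(p4$n_lots, 4)
  odd <- reference_profile(
    expression_matrix(m[, 1:3], "logTPM"), "three")
  expect_equal(unname(odd$values["gA"]), 5)  # median(1,5,9)
  one <- reference_profile(expression_matrix(m[, 1, drop = FALSE], "logTPM"),
                           "single")
  expect_equal(one$values, m[, 1])
  # even-count median averages the middle two
  m2 <- matrix(c(1, 2, 8, 9, 0, 0, 0, 0), 2, 4, byrow = TRUE,
               dimnames = list(c("gA", "gB"), paste0("L", 1:4)))
  expect_equal(unname(reference_profile(
    expression_matrix(m2, "logTPM"), "x")$values["gA"]), 5)
  expect_error(reference_profile(make_counts_em(), "x"), "logTPM")
})

test_that("correlation_table records all requested pairs with gene counts", {
  em <- make_logtpm_em(n_genes = 15, samples = c("a", "b", "c"))
  em$values[, "b"] <- em$values[, "a"]  # duplicate sample
  ref <- reference_profile(
    expression_matrix(em$values[, "a", drop = FALSE], "logTPM"), "ref_a")
  tab <- correlation_table(em, panel = NULL, references = ref,
                           sample_pairs = TRUE)
  expect_equal(nrow(tab), 3 + 3)  # 3 vs reference + 3 sample pairs
  expect_true(all(tab$n_genes == 15))
  expect_equal(tab$r_squared[tab$sample_id == "a" &
                               tab$reference_id == "ref_a"], 1.0)
  expect_equal(tab$r_squared[tab$sample_id == "a" &
                               tab$reference_id == "b"], 1.0)
  expect_true(all(tab$r_squared >= 0 & tab$r_squared <= 1))
})

test_that("cv_percent reproduces the printed discrimination values", {
  ref <- reference_r2()
  self <- ref$r2_panel[ref$population == "SyMSC_med"]
  expect_equal(round(cv_percent(self, ref$r2_panel[ref$population == "T_cells"])), 89)
  expect_equal(round(cv_percent(self, ref$r2_panel[ref$population == "PAEC"])), 51)
  expect_equal(cv_percent(0.5, 0.5), 0)
  expect_error(cv_percent(0, 0.5), "positive")
  # monotone decreasing in the compared R^2
  expect_true(all(diff(cv_percent(0.95, seq(0, 0.95, by = 0.05))) < 0))
})

test_that("detection_power reproduces printed ratios and identity cases", {
  expect_equal(round(detection_power(0.949, 0.462, 0.977, 0.803), 2), 2.88)
  expect_equal(round(detection_power(0.949, 0.100, 0.977, 0.541), 2), 2.00)
  expect_equal(detection_power(0.9, 0.5, 0.9, 0.5), 1.0)
  expect_error(detection_power(0.9, 0.5, 0.9, 0.9), "zero")
})

test_that("benchmark_gene_sets favors the curated panel on simulated data", {
  sim <- simulate_dataset(sim_config(seed = 404))
  logtpm <- counts_to_logtpm(sim$counts)
  rand <- sample_random_panel(rownames(sim$counts$values),
                              length(sim$panel), seed = 505)
  bm <- benchmark_gene_sets(logtpm, sim$panel, "SyMSC_L1", "SyMSC",
                            comparators = list(random = rand,
                                               all_genes = NULL))
  expect_true(all(bm$power_vs_random[bm$cell_type != "SyMSC"] > 1))
  expect_true(all(bm$power_vs_all_genes[bm$cell_type != "SyMSC"] > 1))
  expect_true(is.na(bm$power_vs_random[bm$cell_type == "SyMSC"]))
  # comparator = the panel itself gives power 1 everywhere
  self_bm <- benchmark_gene_sets(logtpm, sim$panel, "SyMSC_L1", "SyMSC",
                                 comparators = list(same = sim$panel))
  expect_equal(self_bm$power_vs_same[self_bm$cell_type != "SyMSC"],
               rep(1, 9), tolerance = 1e-12)
})
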