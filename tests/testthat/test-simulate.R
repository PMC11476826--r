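test_that("simulator output is deterministic under the seed", {
  cfg <- sim_config(n_genes = 400, panel_size = 40, seed = 33)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$panel$entries$gene_id, b$panel$entries$gene_id)
  c2 <- simulate_dataset(sim_config(n_genes = 400, panel_size = 40, seed = 34))
  expect_false(identical(a$counts$values, c2$counts$values))
  # simulator calls do not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_dataset(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("archetype divergence concentrates on panel genes and respects relatedness", {
  cfg <- sim_config(seed = 2)
  arch <- simulate_archetypes(cfg)
  target <- arch$archetypes[, "SyMSC"]
  on_panel <- rownames(arch$archetypes) %in% arch$panel_genes
  ratios <- sapply(setdiff(colnames(arch$archetypes), "SyMSC"), function(tp) {
    dif <- abs(arch$archetypes[, tp] - target)
    mean(dif[on_panel]) / mean(dif[!on_panel])
  })
  expect_true(all(ratios > 1))
  # zero effect SDs collapse all archetypes onto the baseline
  flat <- simulate_archetypes(sim_config(n_genes = 300, panel_size = 30,
                                         panel_effect_sd = 0,
                                         offpanel_effect_sd = 0, seed = 5))
  expect_equal(max(abs(flat$archetypes - flat$baseline)), 0)
  # full relatedness duplicates the target archetype
  types <- sim_default_types()
  types$relatedness[types$type == "BMSC"] <- 1
  twin <- simulate_archetypes(sim_config(n_genes = 300, panel_size = 30,
                                         types = types, seed = 5))
  expect_equal(twin$archetypes[, "BMSC"], twin$archetypes[, "SyMSC"])
})

test_that("noise-free lots of one type converge to identical profiles", {
  cfg <- sim_config(n_genes = 300, panel_size = 30, lot_noise_sd = 0,
                    zero_rate = 0, library_size = 5e6, seed = 9)
  sim <- simulate_dataset(cfg)
  logtpm <- counts_to_logtpm(sim$counts)
  tcols <- sim$labels$sample_id[sim$labels$role == "target"]
  for (p in utils::combn(tcols, 2, simplify = FALSE))
    expect_gt(r_squared(logtpm$values[, p[1]], logtpm$values[, p[2]]), 0.99)
})

test_that("counts are non-negative integers with labels covering all samples", {
  sim <- simulate_dataset(sim_config(n_genes = 500, panel_size = 50, seed = 44))
  expect_true(all(sim$counts$values >= 0))
  expect_true(all(sim$counts$values == round(sim$counts$values)))
  expect_setequal(sim$labels$sample_id, colnames(sim$counts$values))
  expect_equal(sum(sim$config$types$lots), ncol(sim$counts$values))
  expect_equal(length(sim$panel), sim$config$panel_size)
  expect_true(all(panel_included(sim$panel) %in% rownames(sim$counts$values)))
})

test_that("simulated R^2 separates same-type, other-MSC and non-MSC comparisons", {
  sim <- simulate_dataset(sim_config(seed = 77))
  qc <- run_panel_qc(sim$counts, sim$panel)
  r2 <- qc$type_r2
  same_min <- min(qc$decisions$r_squared[qc$decisions$role == "target"])
  other <- r2$r_squared[r2$role == "other_msc"]
  non <- r2$r_squared[r2$role == "non_msc"]
  expect_gt(same_min, max(other))
  expect_gt(min(other), max(non))
})

test_that("widening lot noise lowers same-type correlation", {
  med_same <- sapply(c(0.1, 0.6, 1.2), function(noise) {
    sim <- simulate_dataset(sim_config(n_genes = 800, panel_size = 80,
                                       lot_noise_sd = noise, seed = 55))
    logtpm <- counts_to_logtpm(sim$counts)
    sub <- subset_matrix(logtpm, sim$panel)
    tcols <- sim$labels$sample_id[sim$labels$role == "target"]
    stats::median(utils::combn(tcols, 2, function(p)
      r_squared(sub$values[, p[1]], sub$values[, p[2]])))
  })
  expect_true(all(diff(med_same) < 0))
})

test_that("removing the panel effect removes the panel's detection advantage", {
  run_powers <- function(panel_sd, seeds) {
    unlist(lapply(seeds, function(s) {
      sim <- simulate_dataset(sim_config(panel_effect_sd = panel_sd, seed = s))
      logtpm <- counts_to_logtpm(sim$counts)
      rand <- sample_random_panel(rownames(sim$counts$values),
                                  length(sim$panel), seed = s + 1)
      bm <- benchmark_gene_sets(logtpm, sim$panel, "SyMSC_L1", "SyMSC",
                                comparators = list(random = rand))
      bm$power_vs_random[bm$cell_type != "SyMSC"]
    }))
  }
  seeds <- c(66, 166, 266)
  null_pw <- run_powers(0.35, seeds)   # panel SD equal to off-panel SD
  expect_gt(stats::median(null_pw), 0.5)
  expect_lt(stats::median(null_pw), 2)
  default_pw <- run_powers(sim_config()$panel_effect_sd, seeds)
  expect_gt(stats::median(default_pw), stats::median(null_pw))
  expect_gt(stats::median(default_pw), 2)
})

test_that("calibrate_to_paper restores the packaged calibration", {
  tweaked <- sim_config(panel_effect_sd = 9, zero_rate = 0.4, seed = 123)
  cal <- calibrate_to_paper(tweaked)
  expect_equal(cal$panel_effect_sd, sim_config()$panel_effect_sd)
  expect_equal(cal$zero_rate, sim_config()$zero_rate)
  expect_equal(cal$seed, 123L)  # sizes and seed preserved
})

test_that("write_sim_result emits readable plain-text files", {
  sim <- simulate_dataset(sim_config(n_genes = 200, panel_size = 20, seed = 3))
  dir <- withr::local_tempdir()
  write_sim_result(sim, dir)
  counts <- read_expression(file.path(dir, "counts.tsv"), "counts")
  expect_equal(dim(counts$values), dim(sim$counts$values))
  lengths <- read_gene_lengths(file.path(dir, "lengths.tsv"))
  expect_equal(lengths, sim$gene_lengths)
  panel <- load_panel(file.path(dir, "panel.tsv"))
  expect_equal(panel_included(panel), panel_included(sim$panel))
})
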