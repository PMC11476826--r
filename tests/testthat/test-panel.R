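test_that("load_panel parses the TSV dialect, collapses duplicates, counts exclusions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line",
               "symbol\tgene_id\tcategories\texcluded_high_expression\texcluded_no_primer",
               "IDO1\t3620\timmunoregulation\t0\t0",
               "VEGFA\t7422\tangiogenesis\t0\t0",
               "VEGFA\t7422\tneurogenesis\t0\t0",
               "ACTB\t60\thousekeeping\t1\t0",
               "OR2T1\t26696\tolfactory\t0\t1"), path)
  p <- load_panel(path)
  expect_s3_class(p, "gene_panel")
  expect_equal(nrow(p$entries), 4)  # VEGFA collapsed
  vegfa <- p$entries$categories[[which(p$entries$symbol == "VEGFA")]]
  expect_setequal(vegfa, c("angiogenesis", "neurogenesis"))
  # 4 candidates, 2 flagged -> 2 included
  expect_length(panel_included(p), 2)
  expect_equal(panel_included(p), c("3620", "7422"))
})

test_that("load_panel rejects empty files and missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("symbol\tgene_id\tcategories\texcluded_high_expression\texcluded_no_primer",
             path)
  expect_error(load_panel(path), "empty")
  writeLines(c("symbol\tgene_id", "A\t1"), path)
  expect_error(load_panel(path), "required column")
})

test_that("build_panel removes flagged entries and keeps the count identity", {
  mk <- function(n, high, noprimer) {
    gene_panel(data.frame(
      symbol = sprintf("G%03d", 1:n), gene_id = sprintf("id%03d", 1:n),
      excluded_high_expression = seq_len(n) %in% high,
      excluded_no_primer = seq_len(n) %in% noprimer))
  }
  p <- build_panel(mk(10, high = 1:2, noprimer = 3:5))
  expect_equal(nrow(p$entries), 5)
  # identity holds across random disjoint flag configurations
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    flagged <- sample(n, sample(0:n, 1))
    high <- flagged[seq_len(length(flagged) %/% 2)]
    nop <- setdiff(flagged, high)
    built <- suppressWarnings(build_panel(mk(n, high, nop)))
    expect_equal(nrow(built$entries), n - length(flagged))
  }
})

test_that("build_panel warns on doubly flagged genes and empty results", {
  p <- gene_panel(data.frame(symbol = c("A", "B"), gene_id = c("1", "2"),
                             excluded_high_expression = c(TRUE, FALSE),
                             excluded_no_primer = c(TRUE, FALSE)))
  expect_warning(out <- build_panel(p), "both")
  expect_equal(nrow(out$entries), 1)
  all_flagged <- gene_panel(data.frame(symbol = LETTERS[1:5],
                                       gene_id = as.character(1:5),
                                       excluded_high_expression = TRUE))
  expect_warning(empty <- build_panel(all_flagged), "empty")
  expect_equal(nrow(empty$entries), 0)
})

test_that("sample_random_panel is seeded, duplicate-free and order-independent", {
  universe <- sprintf("g%05d", 1:5000)
  a <- sample_random_panel(universe, 143, seed = 7)
  b <- sample_random_panel(sample(universe), 143, seed = 7)  # shuffled input
  expect_equal(a$entries$gene_id, b$entries$gene_id)
  expect_equal(length(a), 143)
  expect_false(anyDuplicated(a$entries$gene_id) > 0)
  expect_true(all(a$entries$gene_id %in% universe))
  expect_equal(a$universe_size, 5000)
  # different seed, different draw
  expect_false(identical(
    a$entries$gene_id, sample_random_panel(universe, 143, seed = 8)$entries$gene_id))
  # exhaustive sample returns the whole universe
  full <- sample_random_panel(universe[1:20], 20, seed = 1)
  expect_setequal(full$entries$gene_id, universe[1:20])
  expect_error(sample_random_panel(universe[1:5], 6, seed = 1), "universe")
})

test_that("subset_matrix follows panel order, reports absences, is idempotent", {
  em <- make_logtpm_em(n_genes = 10)
  ids <- rownames(em$values)
  panel <- gene_panel(data.frame(symbol = c(ids[7], ids[2], ids[5], "notthere"),
                                 gene_id = c(ids[7], ids[2], ids[5], "nope")))
  sub <- subset_matrix(em, panel)
  expect_equal(rownames(sub$values), ids[c(7, 2, 5)])  # panel order
  expect_equal(attr(sub, "n_absent"), 1)
  again <- subset_matrix(sub, panel)
  expect_equal(again$values, sub$values)
  # symbol fallback is case-insensitive
  sym_panel <- gene_panel(data.frame(symbol = toupper(ids[1:3]),
                                     gene_id = paste0("ext", 1:3)))
  expect_equal(rownames(subset_matrix(em, sym_panel)$values), ids[1:3])
  # zero overlap errors
  off <- gene_panel(data.frame(symbol = c("x1", "x2", "x3"),
                               gene_id = c("x1", "x2", "x3")))
  expect_error(subset_matrix(em, off), "mismatch")
})
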