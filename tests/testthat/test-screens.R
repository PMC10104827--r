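# Screen integration: normalization, fold changes, rank tests, the
# common/context-specific partition, and screen correlation.

test_that("CPM scaling and the 0.5-pseudocount fold change follow the stated arithmetic", {
  ct <- data.frame(sgrna_id = "s1", gene_id = "g1",
                   a = 10, b = 10, stringsAsFactors = FALSE)
  tot <- data.frame(sgrna_id = "pad", gene_id = "pad",
                    a = 1e6 - 10, b = 2e6 - 10)
  norm <- normalize_counts(rbind(ct, tot))
  expect_equal(norm$a[1], 10)
  expect_equal(norm$b[1], 5)
  expect_error(normalize_counts(data.frame(sgrna_id = "s", gene_id = "g",
                                           a = 0)), "all-zero")

  cpm <- data.frame(sgrna_id = c("s1", "s2", "s3"),
                    gene_id = c("g1", "g2", "g3"),
                    t0 = c(40, 7, 0), t14 = c(10, 7, 0))
  lfc <- sgrna_lfc(cpm, timepoints = c(t0 = "t0", t14 = "t14"),
                   from = "t0", to = "t14")
  expect_equal(lfc$lfc[1], log2(10.5) - log2(40.5), tolerance = 1e-12)
  expect_equal(lfc$lfc[2], 0)
  expect_equal(lfc$lfc[3], 0)  # 0 -> 0: pseudocount symmetry
  expect_error(sgrna_lfc(cpm, timepoints = c(t0 = "t0", t14 = "t14"),
                         from = "t7", to = "t14"), "t7")
})

test_that("signed-rank p-values match full sign-pattern enumeration", {
  lfc <- data.frame(sgrna_id = paste0("s", 1:3),
                    gene_id = paste0("g", 1:3), lfc = c(1, 2, 3))
  res <- compare_gene_sets(lfc, paste0("g", 1:3), paired = TRUE,
                           alternative = "greater")
  expect_equal(res$p.value, 0.125)  # 1 of 2^3 sign patterns
  for (n in c(5, 8, 10)) {
    withr::with_seed(n, {
      vals <- round(rnorm(n), 3)
      lfc <- data.frame(sgrna_id = paste0("s", 1:n),
                        gene_id = paste0("g", 1:n), lfc = vals)
      res <- compare_gene_sets(lfc, paste0("g", 1:n), paired = TRUE)
      expect_equal(res$p.value, oracle_signed_rank(vals), tolerance = 1e-12)
    })
  }
  lfc0 <- data.frame(sgrna_id = paste0("s", 1:4),
                     gene_id = paste0("g", 1:4), lfc = rep(0, 4))
  expect_warning(res0 <- compare_gene_sets(lfc0, paste0("g", 1:4),
                                           paired = TRUE), "zero")
  expect_equal(res0$p.value, 1)
})

test_that("rank-sum comparison is symmetric and separates planted essentials", {
  lfc <- data.frame(sgrna_id = paste0("s", 1:8),
                    gene_id = rep(c("gA", "gB"), each = 4),
                    lfc = rep(c(1, 2, 3, 4), 2))
  res <- compare_gene_sets(lfc, "gA", "gB")
  expect_equal(res$p.value, 1)

  scr <- gen_screens(small_cfg(seed = 21))
  ct <- normalize_counts(scr$counts[[1]])
  lfc <- sgrna_lfc(ct)
  ess <- scr$truth$essential[[1]]
  non <- setdiff(unique(lfc$gene_id), ess)[1:50]
  res <- compare_gene_sets(lfc, ess, non)
  expect_lt(res$p.value, 0.01)
})

test_that("expressed-gene filtering uses a strict 0.5 boundary", {
  expr <- matrix(c(0.5, 0.5, 0.51, 0.51, 4, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gAt", "gAbove", "gHigh"), c("s1", "s2")))
  res <- filter_expressed(c("gAt", "gAbove", "gHigh"), expr)
  expect_identical(res$expressed, c("gAbove", "gHigh"))
  expect_identical(res$low_non_expressed, "gAt")
  expect_warning(res2 <- filter_expressed(c("gHigh", "missing"), expr),
                 "absent")
  expect_identical(res2$low_non_expressed, "missing")
  expect_identical(filter_expressed(character(0), expr),
                   list(expressed = character(0),
                        low_non_expressed = character(0)))
})

test_that("the common/context partition matches set algebra and is exhaustive", {
  mk <- function(sig, all = c("A", "B", "C", "D")) {
    data.frame(gene_id = all, p_neg = ifelse(all %in% sig, 0.01, 0.5))
  }
  part <- integrate_screens(list(mk(c("A", "B")), mk(c("A", "C")), mk("A")))
  expect_identical(part$common, "A")
  expect_setequal(part$context_specific, c("B", "C"))

  part2 <- integrate_screens(list(mk(c("A", "B")), mk(c("A", "B"))))
  expect_length(part2$context_specific, 0)
  expect_error(integrate_screens(list(mk("A"))), ">= 2")

  # fuzz: partition disjoint and exhaustive, common = intersection
  withr::with_seed(42, {
    for (i in 1:50) {
      genes <- paste0("g", 1:30)
      tabs <- lapply(1:4, function(s) {
        data.frame(gene_id = genes, p_neg = runif(30))
      })
      p <- integrate_screens(tabs, alpha = 0.3)
      expect_length(intersect(p$common, p$context_specific), 0)
      expect_setequal(c(p$common, p$context_specific),
                      Reduce(union, p$per_screen_significant))
      expect_setequal(p$common, Reduce(intersect, p$per_screen_significant))
    }
  })
})

test_that("planted all-screen essentials are recovered in the common set", {
  scr <- gen_screens(small_cfg(seed = 30))
  part <- integrate_screens(scr$gene_tables)
  recall <- length(intersect(part$common, scr$truth$common)) /
    length(scr$truth$common)
  expect_gte(recall, 0.9)
})

test_that("screen correlations behave at the identity, negation and noise limits", {
  t1 <- data.frame(gene_id = paste0("g", 1:100),
                   lfc = withr::with_seed(1, rnorm(100)))
  t2 <- t1; t2$lfc <- -t1$lfc
  r <- screen_correlation(list(a = t1, b = t2, c = t1))
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "b"], -1)
  expect_equal(r["a", "c"], 1)
  expect_true(isSymmetric(r))
  expect_true(all(r >= -1 & r <= 1))
  # PSD on fully shared genes
  expect_true(all(eigen(r, only.values = TRUE)$values > -1e-8))
  # duplicate + shrinking noise: correlation increases towards 1
  cors <- vapply(c(1, 0.5, 0.1), function(s) {
    t2 <- t1
    t2$lfc <- t1$lfc + withr::with_seed(99, rnorm(100, 0, s))
    screen_correlation(list(t1, t2))[1, 2]
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.95)
  # pairs sharing < 3 genes are NA with a warning, not 0
  t3 <- data.frame(gene_id = c("g1", "g2"), lfc = c(1, 2))
  expect_warning(r2 <- screen_correlation(list(a = t1, b = t3)), "< 3 genes")
  expect_true(is.na(r2["a", "b"]))
})

test_that("MAGeCK-style gene summaries are read through the column map", {
  dir <- withr::local_tempdir()
  df <- data.frame(id = c("g1", "g2"), `neg|p-value` = c(0.01, 0.6),
                   `pos|p-value` = c(0.9, 0.2), `neg|lfc` = c(-2, 0.1),
                   check.names = FALSE)
  path <- file.path(dir, "screen1_gene_summary.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_gene_summary(path)
  expect_identical(tab$gene_id, c("g1", "g2"))
  expect_equal(tab$p_neg, c(0.01, 0.6))
  expect_equal(tab$lfc, c(-2, 0.1))
})
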