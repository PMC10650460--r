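# BH adjustment, fold-change/FDR gene sets, Venn partitions, ddCt, and the
# naive count test.

test_that("bh_adjust matches the step-up formula on worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0, 5)), rep(0, 5))
  expect_identical(bh_adjust(numeric()), numeric())
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("bh_adjust agrees with an independent step-up implementation", {
  set.seed(71)
  for (i in 1:200) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("de_sets applies the fold-change and adjusted-p rule", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    log2fc = c(1.0, 0.4, -2, -1.2),
    padj = c(0.01, 0.001, 0.2, 0.04),
    stringsAsFactors = FALSE)
  sets <- de_sets(tab)
  expect_identical(sets$up, "g1")       # 2-fold, significant
  expect_identical(sets$down, "g4")
  expect_false("g2" %in% c(sets$up, sets$down))  # 2^0.4 ~ 1.32 < 1.5
  expect_true(2^0.4 < 1.5)
  expect_false("g3" %in% sets$down)     # fails alpha
  expect_length(intersect(sets$up, sets$down), 0)
})

test_that("de_sets computes padj from pvalue when absent and validates input", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(2, 2, 0, 0),
                    pvalue = c(0.001, 0.04, 0.5, 0.9),
                    stringsAsFactors = FALSE)
  sets <- de_sets(tab)
  expect_identical(sets$up, intersect(tab$gene_id[bh_adjust(tab$pvalue) < 0.05],
                                      c("a", "b")))
  expect_error(de_sets(data.frame(gene_id = "a", log2fc = 1)), "pvalue or padj")
  expect_error(de_sets(data.frame(gene_id = c("a", "a"), log2fc = 1,
                                  padj = 0.1)), "unique")
})

test_that("boundary semantics: inclusive fold change, strict adjusted p", {
  boundary <- data.frame(
    gene_id = c("fc_edge", "p_edge", "both_edge", "inside"),
    log2fc = c(log2(1.5), 1, log2(1.5), 1),
    padj = c(0.01, 0.05, 0.05, 0.049),
    stringsAsFactors = FALSE)
  sets <- de_sets(boundary)
  expect_true("fc_edge" %in% sets$up)       # fold change == 1.5 is included
  expect_false("p_edge" %in% sets$up)       # padj == 0.05 is excluded
  expect_false("both_edge" %in% sets$up)
  expect_true("inside" %in% sets$up)
  # inclusive-alpha variant admits the padj == 0.05 rows
  sets_inc <- de_sets(boundary, padj_inclusive = TRUE)
  expect_true(all(c("p_edge", "both_edge") %in% sets_inc$up))
  # down-regulation boundary mirrors: 2^log2fc == 1/1.5
  down_edge <- data.frame(gene_id = "d", log2fc = -log2(1.5), padj = 0.01,
                          stringsAsFactors = FALSE)
  expect_identical(de_sets(down_edge)$down, "d")
})

test_that("diff_vs_reference partitions the union exactly", {
  d <- diff_vs_reference(c("a", "b"), c("b", "c"))
  expect_identical(d$shared, "b")
  expect_identical(d$iso_only, "c")
  expect_identical(d$ref_only, "a")

  d2 <- diff_vs_reference(c("a", "b", "c"), c("b", "c"))
  expect_length(d2$iso_only, 0)

  d3 <- diff_vs_reference(c("a"), c("b"))
  expect_length(d3$shared, 0)
  expect_setequal(unlist(d3), c("a", "b"))
})

test_that("venn_partition produces all regions with the stated semantics", {
  p2 <- venn_partition(list(A = c("1", "2"), B = c("2", "3")))
  expect_identical(p2$sets[["A only"]], "1")
  expect_identical(p2$sets[["B only"]], "3")
  expect_identical(p2$sets[["A∩B"]], "2")

  same <- venn_partition(list(A = c("x", "y"), B = c("x", "y"),
                              C = c("x", "y")))
  expect_identical(sort(same$sets[["A∩B∩C"]]), c("x", "y"))
  expect_true(all(lengths(same$sets[names(same$sets) !=
                                      "A∩B∩C"]) == 0))

  disj <- venn_partition(list(A = "1", B = "2", C = "3"))
  only <- grepl("only", names(disj$sets))
  expect_identical(sum(lengths(disj$sets[only])), 3L)
  expect_identical(sum(lengths(disj$sets[!only])), 0L)

  expect_error(venn_partition(list(A = "1")), "2 or 3")
  expect_error(venn_partition(list("1", "2")), "named")
})

test_that("venn regions are disjoint and exhaustive on random set triples", {
  set.seed(101)
  universe <- sprintf("g%03d", 1:60)
  for (i in 1:100) {
    sets <- list(A = sample(universe, sample(0:40, 1)),
                 B = sample(universe, sample(0:40, 1)),
                 C = sample(universe, sample(0:40, 1)))
    part <- venn_partition(sets)
    all_genes <- unlist(part$sets, use.names = FALSE)
    expect_identical(anyDuplicated(all_genes), 0L)
    expect_setequal(all_genes, unique(unlist(sets)))
    # region membership tallies against direct membership tests
    expect_setequal(part$sets[["A∩B∩C"]],
                    intersect(intersect(sets$A, sets$B), sets$C))
  }
})

test_that("ddct_fold_change computes 2^-ddCt with exact identities", {
  treated <- data.frame(sample = c("t1", "t2"), group = "treated",
                        target_ct = c(20, 20), ref_ct = c(15, 15))
  control <- data.frame(sample = c("c1", "c2"), group = "control",
                        target_ct = c(22, 22), ref_ct = c(15, 15))
  expect_equal(ddct_fold_change(rbind(treated, control)), 4)

  # identical groups give exactly 1
  same <- rbind(treated, transform(treated, group = "control",
                                   sample = c("c1", "c2")))
  expect_equal(ddct_fold_change(same), 1)

  # treated dCt one cycle above control halves the target
  up1 <- control
  up1$group <- "treated"
  up1$target_ct <- up1$target_ct + 1
  expect_equal(ddct_fold_change(rbind(up1, control)), 0.5)

  expect_error(ddct_fold_change(treated), "at least one control")
  bad <- rbind(treated, control)
  bad$target_ct[1] <- -1
  expect_error(ddct_fold_change(bad), "positive")
})

test_that("ddct of any table against itself is exactly 1", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    ct <- data.frame(sample = sprintf("s%d", 1:(2 * n)),
                     group = rep(c("control", "treated"), each = n),
                     target_ct = runif(2 * n, 15, 35),
                     ref_ct = runif(2 * n, 10, 25))
    ct$target_ct[ct$group == "treated"] <- ct$target_ct[ct$group == "control"]
    ct$ref_ct[ct$group == "treated"] <- ct$ref_ct[ct$group == "control"]
    expect_equal(ddct_fold_change(ct), 1)
  }
})

test_that("naive_count_test recovers exact fold changes on clean data", {
  m <- matrix(rep(c(100, 200, 50, 400), each = 3), nrow = 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3", "g4"), NULL))
  res <- naive_count_test(m, m)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$pvalue == 1))

  m2 <- m
  m2["g2", ] <- m2["g2", ] * 8
  res2 <- naive_count_test(m, m2)
  # library-size normalization shifts all genes by the same factor; the
  # scaled gene is 8x against that common background
  expect_equal(res2[res2$gene_id == "g2", "log2fc"] -
                 res2[res2$gene_id == "g1", "log2fc"], 3)
  expect_error(naive_count_test(m, m2[c(2, 1, 3, 4), ]), "rownames")
  expect_error(naive_count_test(m[, 1, drop = FALSE], m), "replicates")
})

test_that("naive_count_test p-values are near-uniform under the null", {
  set.seed(202)
  n <- 1000
  mu <- 100
  a <- matrix(rnbinom(n * 3, mu = mu, size = 20), nrow = n,
              dimnames = list(sprintf("g%04d", 1:n), NULL))
  b <- matrix(rnbinom(n * 3, mu = mu, size = 20), nrow = n,
              dimnames = list(sprintf("g%04d", 1:n), NULL))
  res <- naive_count_test(a, b)
  expect_gt(mean(res$pvalue), 0.40)
  expect_lt(mean(res$pvalue), 0.60)
  expect_lt(mean(res$pvalue < 0.05), 0.10)
})

test_that("DE tables round-trip through TSV with padj provenance intact", {
  tab <- data.frame(gene_id = c("a", "b"), log2fc = c(1.2, -0.3),
                    pvalue = c(0.01, 0.6), padj = c(0.02, 0.7),
                    stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_de_tsv(tsv)
  expect_s3_class(back, "de_result")
  expect_equal(back$padj, tab$padj)
  sets <- de_sets(back)
  expect_identical(sets$up, "a")
})
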