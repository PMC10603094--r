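test_that("proteinGroups parsing handles intensities, zeros and flags", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_protein_groups(path)
  m <- load_protein_groups(path, toy_conditions)
  expect_equal(nrow(m$exprs), 3)
  expect_equal(m$protein_id, c("P1", "P2", "P3"))
  expect_true(is.na(m$exprs["P2", "c_1"]))        # zero intensity -> missing
  expect_equal(m$exprs["P1", "c_1"], 20)          # log2 transform
  expect_equal(m$reverse, c(FALSE, FALSE, TRUE))
  expect_error(load_protein_groups(path, toy_conditions[-1]), "condition")
})

test_that("write/read round trip preserves the abundance matrix", {
  m <- generate_lfq_table(simulation_spec(seed = 21, n_proteins = 50))
  path <- withr::local_tempfile(fileext = ".txt")
  write_protein_groups(m, path)
  cond <- stats::setNames(as.character(m$condition), colnames(m$exprs))
  m2 <- load_protein_groups(path, cond)
  expect_equal(m2$exprs, m$exprs, tolerance = 1e-12)
  expect_identical(m2$reverse, m$reverse)
  expect_identical(m2$contaminant, m$contaminant)
})

test_that("valid-value filtering implements the one-condition-absence rule", {
  x <- rbind(
    full      = c(20, 21, 20, 23, 24, 23),
    pa        = c(20, 21, 20, NA, NA, NA),   # 3/3 vs 0/3 -> retained + flag
    partial   = c(20, NA, 20, 23, 24, 23),   # 2/3 vs 3/3 -> removed
    contam    = c(20, 21, 20, 23, 24, 23))
  m <- abundance_matrix(x, rep(c("control", "lesioned"), each = 3),
                        contaminant = c(FALSE, FALSE, FALSE, TRUE))
  f <- filter_and_impute(m, "presence_absence", seed = 1)
  expect_setequal(f$protein_id, c("full", "pa"))
  expect_identical(f$presence_absence[f$protein_id == "pa"], TRUE)
  expect_false(anyNA(f$exprs))                    # imputed
  fs <- filter_and_impute(m, "strict")
  expect_identical(fs$protein_id, "full")
  expect_error(filter_and_impute(m, "bogus"))
})

test_that("s0-moderated statistic matches its definition and t limit", {
  expect_equal(sam_statistic(c(1, 2, 3), c(1, 2, 3), s0 = 0.1), 0)
  expect_equal(sam_statistic(c(10, 11, 12), c(13, 14, 15), s0 = 0.1),
               3 / (sqrt(2 / 3) + 0.1), tolerance = 1e-12)
  # s0 = 0 identity with the classical pooled t on random draws
  set.seed(42)
  for (i in 1:200) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), sd = runif(1, .5, 2))
    expect_equal(sam_statistic(a, b, s0 = 0), pooled_t_enum(a, b),
                 tolerance = 1e-12)
  }
  expect_error(sam_statistic(1, c(1, 2)), "n >= 2")
})

test_that("permutation FDR enumerates splits and flags a strong spike", {
  m <- generate_lfq_table(simulation_spec(seed = 31, n_proteins = 100,
                                          frac_regulated = 0))
  mf <- filter_and_impute(m, seed = 31)
  res <- permutation_fdr(mf, s0 = 0.1, n_perm = 1000, seed = 1)
  expect_identical(attr(res, "n_splits_total"), 20L)  # C(6,3) balanced splits
  expect_identical(attr(res, "n_permutations"), 18L)  # observed + mirror out
  expect_true(attr(res, "exhaustive"))

  # single protein spiked at log2FC = 5 is called significant
  set.seed(101)
  x <- matrix(rnorm(100 * 6, 25, 0.3), 100)
  x[1, 4:6] <- x[1, 4:6] + 5
  res2 <- permutation_fdr(x, rep(c("a", "b"), each = 3), seed = 1)
  expect_true(res2$significant[1])
  expect_equal(which.max(abs(res2$t_s0)), 1L)
  expect_error(permutation_fdr(x, rep(c("a", "b"), each = 3), n_perm = 0),
               "n_perm")
})

test_that("exhaustive permutation FDR is invariant to sample order within condition", {
  x <- matrix(rnorm(60 * 6, 25, 0.5), 60)
  lab <- rep(c("a", "b"), each = 3)
  r1 <- permutation_fdr(x, lab, seed = 1)
  perm_cols <- c(2, 3, 1, 6, 4, 5)                # shuffle within each condition
  r2 <- permutation_fdr(x[, perm_cols], lab[perm_cols], seed = 1)
  expect_equal(r1$qvalue, r2$qvalue, tolerance = 1e-12)
  expect_equal(r1$t_s0, r2$t_s0, tolerance = 1e-12)
})

test_that("regulation classes follow the log2-scale fold-change threshold", {
  expect_equal(as.character(classify_regulation(1, TRUE)), "up")
  expect_equal(as.character(classify_regulation(0.2, TRUE)), "ns")  # < log2(1.3)
  expect_equal(as.character(classify_regulation(-1, FALSE)), "ns")
  expect_equal(as.character(classify_regulation(-1, TRUE)), "down")
  expect_error(classify_regulation(1, TRUE, fc_threshold = 1), "> 1")
  # monotone in log2fc at fixed significance
  lfc <- seq(-3, 3, length.out = 61)
  cls <- classify_regulation(lfc, rep(TRUE, 61))
  ranks <- c(down = 1, ns = 2, up = 3)[as.character(cls)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("row Z-scores standardize exactly", {
  expect_equal(zscore_rows(matrix(c(1, 2, 3), 1)),
               matrix(c(-1, 0, 1), 1))
  z0 <- matrix(c(-1, 0, 1), 1)
  expect_equal(zscore_rows(z0), z0)
  set.seed(1)
  z <- zscore_rows(matrix(rnorm(200, 10, 4), 20))
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  expect_error(zscore_rows(matrix(c(1, 1, 1, 2, 3, 4), 2, byrow = TRUE)),
               "constant")
})

test_that("matrisome annotation joins and flags unknowns", {
  ann <- data.frame(gene = c("lum", "fn1a", "ctsla"),
                    division = c("core matrisome", "core matrisome",
                                 "matrisome-associated"),
                    category = c("proteoglycan", "glycoprotein",
                                 "ECM regulator"),
                    mammalian_ortholog = c("LUM", "FN1", "CTSL"))
  out <- annotate_matrisome(c("lum", "xyz", "FN1A"), ann,
                            normalizer = "case_insensitive")
  expect_equal(out$matrisome, c(TRUE, FALSE, TRUE))
  expect_equal(out$division[1], "core matrisome")
  expect_true(is.na(out$division[2]))
  expect_equal(out$mammalian_ortholog[3], "FN1")
  # exact matching treats case variants as unknown
  out2 <- annotate_matrisome(c("FN1A"), ann, normalizer = "exact")
  expect_false(out2$matrisome)
  expect_error(annotate_matrisome("lum", ann[c(1, 1), ]), "duplicate")
})

test_that("cross-species screen buckets partition a constructed table", {
  mk <- function(ids, cls) data.frame(gene_symbol = ids, t_s0 = seq_along(ids),
                                      class = factor(cls, c("up", "down", "ns")))
  a_cls <- c("up", "up", "up", "down", "ns", "ns", "down", "up", "down", "ns")
  b_cls <- c("ns", "down", "up", "up",  "up", "ns", "down", "up", "ns",  "down")
  ids <- paste0("g", 1:10)
  screen <- cross_species_screen(mk(ids, a_cls), mk(ids, b_cls),
                                 data.frame(a = ids, b = ids))
  counts <- attr(screen, "counts")
  # by construction: A-up & B-down/ns: g1, g2 -> 2; A-down/ns & B-up: g4, g5 -> 2
  # concordant: g3, g6, g7, g8 -> 4; other: g9, g10 -> 2
  expect_equal(as.integer(counts[c("A_up_B_down_or_ns", "A_down_or_ns_B_up",
                                   "concordant", "other")]), c(2L, 2L, 4L, 2L))
  expect_equal(as.integer(sum(counts)), 10L)
  expect_equal(as.character(screen$bucket[1]), "A_up_B_down_or_ns")
  expect_equal(as.character(screen$bucket[3]), "concordant")
})

test_that("hypergeometric over-representation matches brute-force tail sums", {
  bg <- paste0("g", 1:100)
  sets <- list(all = bg, none = paste0("x", 1:5),
               hit = c(paste0("g", 1:5), paste0("g", 90:94)))
  fg <- paste0("g", 1:10)
  out <- ora_enrichment(fg, bg, sets)
  expect_equal(out$p[out$set == "all"], 1)
  expect_equal(out$p[out$set == "none"], 1)      # zero overlap in background
  # N=100, K=10, n=10, k=5 against the enumeration oracle
  expect_equal(out$overlap[out$set == "hit"], 5)
  expect_equal(out$p[out$set == "hit"], hyper_tail_enum(5, 100, 10, 10),
               tolerance = 1e-12)
  expect_equal(out$p_bonferroni, pmin(out$p * 3, 1))
  expect_error(ora_enrichment(c("z"), bg, sets), "subset")
  expect_error(ora_enrichment(fg, character(0), sets), "background")
})
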