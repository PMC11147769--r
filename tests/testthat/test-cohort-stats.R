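test_that("Fisher wrapper matches hypergeometric enumeration on small tables", {
  set.seed(9)
  for (i in 1:40) {
    tot <- sample(8:60, 1)
    cells <- as.vector(stats::rmultinom(1, tot, runif(4, 0.1, 1)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_2x2(tab),
                 tolerance = 1e-10)
  }
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  deg <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("baseline contingency tables reproduce the published p-values", {
  # printed two-strata counts are the test inputs; p-values compared after
  # rounding to the printed precision
  expect_equal(round(fisher_exact(matrix(c(38, 12, 24, 29), 2, byrow = TRUE))$p_value, 3),
               0.002)   # number of previous lines
  expect_lt(fisher_exact(matrix(c(46, 4, 29, 24), 2, byrow = TRUE))$p_value,
            0.001)      # prior PARPi treatment
  expect_equal(round(fisher_exact(matrix(c(48, 2, 45, 8), 2, byrow = TRUE))$p_value, 2),
               0.09)    # history of cancer
  expect_equal(round(fisher_exact(matrix(c(44, 6, 39, 14), 2, byrow = TRUE))$p_value, 2),
               0.08)    # ECOG performance status
  expect_equal(round(fisher_exact(matrix(c(16, 18, 17, 18, 17, 17), nrow = 3,
                                         byrow = TRUE))$p_value, 2),
               1.00)    # treatment arm (3 x 2 exact test)
})

test_that("Wilcoxon wrapper handles paired, separated and tied samples", {
  x <- 1:10
  expect_equal(wilcoxon_rank_sum(x, x, paired = TRUE), 1)
  expect_lt(wilcoxon_rank_sum(x + 100, x), 0.001)
  expect_equal(wilcoxon_rank_sum(x, x), 1, tolerance = 0.01)
  expect_error(wilcoxon_rank_sum(numeric(0), x), "empty")
  # agreement with the exact rank-sum distribution at small n
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)),
               2 * (1 / choose(6, 3)))
})

test_that("co-occurrence matrix finds a planted gene-pair enrichment", {
  set.seed(77)
  n <- 150
  # planted dependence: TP53 much more likely in PPM1D-mutant patients
  ppm1d <- runif(n) < 0.5
  tp53 <- runif(n) < ifelse(ppm1d, 0.6, 0.08)
  other <- runif(n) < 0.4
  rows <- list()
  for (i in seq_len(n)) {
    genes <- c("PPM1D"[ppm1d[i]], "TP53"[tp53[i]], "DNMT3A"[other[i]], "TET2")
    for (g in genes) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%03d", i), gene = g, vaf = runif(1, 0.01, 0.3))
    }
  }
  variants <- do.call(rbind, rows)
  cm <- cooccurrence_matrix(variants, top_k = 4)
  hit <- cm[(cm$gene_1 == "PPM1D" & cm$gene_2 == "TP53") |
            (cm$gene_1 == "TP53" & cm$gene_2 == "PPM1D"), ]
  expect_equal(nrow(hit), 1L)
  expect_gt(hit$odds_ratio, 2)
  expect_lt(hit$p_fdr, 0.05)
  # FDR never decreases a p-value and preserves order
  expect_true(all(cm$p_fdr >= cm$p_raw - 1e-12))
  expect_true(all(diff(cm$p_fdr[order(cm$p_raw)]) >= -1e-12))
  # VAF-ordering fractions of a directed pair are complementary without ties
  ok <- !is.na(cm$frac_gene1_higher_vaf)
  expect_equal(cm$frac_gene1_higher_vaf[ok] + cm$frac_gene2_higher_vaf[ok],
               rep(1, sum(ok)))
})

test_that("perfectly nested gene pairs are flagged with an infinite OR", {
  variants <- do.call(rbind, lapply(1:30, function(i) {
    genes <- c("C", "D", if (i <= 20) "A", if (i <= 10) "B")
    data.frame(patient_id = paste0("P", i), gene = genes,
               vaf = runif(length(genes), 0.01, 0.2))
  }))
  cm <- cooccurrence_matrix(variants, top_k = 4)
  ab <- cm[cm$gene_1 == "A" & cm$gene_2 == "B", ]
  expect_true(ab$or_upper_flagged)
})

test_that("VAF concordance handles exact, inverted and constant input", {
  expect_equal(vaf_concordance(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$r, 1)
  expect_lt(vaf_concordance(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1))$r, 0)
  const <- vaf_concordance(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.3))
  expect_true(is.na(const$r))
  expect_true(const$constant_input)
  expect_error(vaf_concordance(0.1, 0.2), "at least 3")
})

test_that("baseline table dispatches on variable type and row order", {
  set.seed(31)
  pts <- data.frame(
    age = c(rnorm(40, 55, 5), rnorm(40, 68, 5)),
    arm = sample(c("A", "B", "C"), 80, TRUE),
    same = rep("x", 80)
  )
  strata <- rep(c(FALSE, TRUE), each = 40)
  bt <- baseline_table(pts, strata,
                       c(age = "numeric", arm = "categorical", same = "categorical"))
  expect_lt(bt$p_value[bt$variable == "age"], 0.001)
  expect_equal(bt$p_value[bt$variable == "same"], 1)  # invariant variable
  # statistics are invariant to patient row order
  perm <- sample(80)
  bt2 <- baseline_table(pts[perm, ], strata[perm],
                        c(age = "numeric", arm = "categorical", same = "categorical"))
  expect_equal(bt2$p_value, bt$p_value)
})
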