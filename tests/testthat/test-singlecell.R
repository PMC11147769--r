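test_that("sample QC counts cells genotyped at any somatic target", {
  m <- build_matrix(400, list(c(1L, 0L)))
  expect_true(qc_sample(m)$pass)                      # inclusive boundary
  expect_false(qc_sample(m[1:399, ])$pass)
  allmiss <- m; allmiss[] <- NA
  expect_false(qc_sample(allmiss)$pass)
  expect_equal(qc_sample(allmiss)$n_genotyped, 0L)
  expect_false(qc_sample(m[0, , drop = FALSE])$pass)
  # a cell missing one target but called at another still counts
  m2 <- m; m2[1, 1] <- NA
  expect_equal(qc_sample(m2)$n_genotyped, 400L)
})

test_that("clone calling groups exact genotype vectors with a 5-cell floor", {
  m <- build_matrix(c(600, 4), list(c(1L, 0L), c(0L, 1L)), n_wt = 400)
  cl <- call_clones(m)
  expect_equal(cl$clones$label, c("C0", "C1"))
  expect_equal(cl$clones$cell_count, c(400L, 600L))
  # the 4-cell group is unassigned, not a clone
  expect_equal(sum(is.na(cl$assignment)), 4L)
  expect_equal(cl$n_genotyped, 1004L)
  # fractions + unassigned sum to one
  expect_equal(sum(cl$clones$fraction) + cl$unassigned_fraction, 1, tolerance = 1e-12)
  # boundary: exactly 5 cells is reported
  m5 <- build_matrix(c(600, 5), list(c(1L, 0L), c(0L, 1L)), n_wt = 400)
  expect_equal(nrow(call_clones(m5)$clones), 3L)
})

test_that("homozygous-mutant clones are flagged as LOH", {
  m <- build_matrix(c(50, 30), list(c(2L, 0L), c(1L, 1L)), n_wt = 20)
  cl <- call_clones(m)
  expect_equal(cl$clones$loh[cl$clones$label == "C1"], TRUE)
  expect_equal(cl$clones$loh[cl$clones$label == "C2"], FALSE)
  expect_false(cl$clones$loh[cl$clones$label == "C0"])
})

test_that("clone calling is invariant to cell and variant order", {
  set.seed(13)
  m <- build_matrix(c(40, 25, 8), list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L)),
                    n_wt = 30)
  ref <- call_clones(m)$clones
  perm_cells <- m[sample(nrow(m)), ]
  perm_vars <- m[, c(2, 3, 1)]
  expect_equal(call_clones(perm_cells)$clones, ref)
  got <- call_clones(perm_vars, somatic_targets = colnames(perm_vars))$clones
  expect_equal(got$cell_count, ref$cell_count)
  expect_equal(got$fraction, ref$fraction)
})

test_that("cells missing any target genotype stay unassigned", {
  m <- build_matrix(c(20), list(c(1L, 0L)), n_wt = 10)
  m[1, 2] <- NA
  cl <- call_clones(m)
  expect_true(is.na(cl$assignment[1]))
  expect_equal(cl$clones$cell_count[cl$clones$label == "C1"], 19L)
})

test_that("SNP-profile demultiplexing assigns singlets and drops mixtures", {
  profiles <- rbind(A = c(0L, 2L, 1L, 0L, 2L, 1L),
                    B = c(2L, 0L, 0L, 2L, 1L, 2L))
  colnames(profiles) <- paste0("snp", 1:6)
  cells <- rbind(profiles["A", ], profiles["A", ], profiles["B", ],
                 c(1L, 1L, 1L, 1L, 1L, 1L),          # mixed signature
                 c(0L, 2L, 1L, 0L, 2L, 2L))          # 5/6 concordant with A
  colnames(cells) <- colnames(profiles)
  out <- demultiplex(cells, profiles)
  expect_equal(out[1:3], c("A", "A", "B"))
  expect_equal(out[4], "ambiguous")
  expect_equal(out[5], "ambiguous")   # 0.83 < 0.9 concordance floor
  expect_error(demultiplex(cells, profiles[c(1, 1), ]), "non-separable")
  nosnp <- cells; nosnp[1, ] <- NA
  expect_true(is.na(demultiplex(nosnp, profiles)[1]))
})

test_that("pooled-sample simulation demultiplexes >= 95% of singlets", {
  set.seed(55)
  n_snp <- 12
  profiles <- rbind(A = sample(0:2, n_snp, TRUE), B = sample(0:2, n_snp, TRUE))
  while (mean(profiles[1, ] == profiles[2, ]) > 0.5) {
    profiles[2, ] <- sample(0:2, n_snp, TRUE)
  }
  colnames(profiles) <- paste0("snp", seq_len(n_snp))
  n <- 1000
  src <- sample(c("A", "B"), n, TRUE)
  dbl <- runif(n) < 0.05
  g <- profiles[src, , drop = FALSE]
  other <- profiles[ifelse(src == "A", "B", "A"), , drop = FALSE]
  g[dbl, ] <- pmax(g[dbl, ], other[dbl, ])
  g[matrix(runif(length(g)) < 0.05, n)] <- NA   # sparse missingness
  rownames(g) <- NULL
  out <- demultiplex(g, profiles)
  ok <- !dbl & !is.na(out)
  expect_gte(mean(out[ok] == src[ok]), 0.95)
})

test_that("exclusivity testing separates exclusive, nested and doublet signals", {
  # two clones, zero double mutants: exclusive
  m <- build_matrix(c(100, 80), list(c(1L, 0L), c(0L, 1L)), n_wt = 300)
  res <- test_exclusivity(m, "V1", "V2", doublet_rate = 0)
  expect_equal(res$call, "exclusive")
  expect_equal(res$double_mutant_fraction, 0)
  # nested pair: all B-mutant cells also A-mutant
  nest <- build_matrix(c(200, 60), list(c(1L, 0L), c(1L, 1L)), n_wt = 240)
  res2 <- test_exclusivity(nest, "V1", "V2", doublet_rate = 0.08)
  expect_equal(res2$call, "co_occurring")
  # degenerate: one variant never mutated
  vac <- build_matrix(50, list(c(1L, 0L)), n_wt = 50)
  res3 <- test_exclusivity(vac, "V1", "V2", doublet_rate = 0.05)
  expect_equal(res3$call, "exclusive")
  expect_true(res3$vacuous)
})

test_that("serial architecture comparison tracks expansion and disappearance", {
  t1 <- call_clones(build_matrix(c(100, 50), list(c(1L, 0L), c(0L, 1L)), n_wt = 850))
  t2 <- call_clones(build_matrix(c(600), list(c(1L, 0L)), n_wt = 400))
  cmp <- compare_serial_architecture(t1, t2)
  expanded <- cmp[cmp$genotype == "1,0", ]
  expect_equal(expanded$status, "shared")
  expect_gt(expanded$delta, 0.4)
  expect_equal(cmp$status[cmp$genotype == "0,1"], "disappeared")
  # identical samples: all deltas zero
  same <- compare_serial_architecture(t1, t1)
  expect_true(all(same$delta == 0))
  t3 <- call_clones(build_matrix(20, list(c(1L, 1L)),
                                 variant_ids = c("W1", "W2")))
  expect_error(compare_serial_architecture(t1, t3), "disjoint")
})
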