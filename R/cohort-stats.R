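#' Cohort-level statistics
#'
#' Descriptive and inferential statistics over a classified cohort:
#' baseline-table tests (Fisher's exact for categorical variables, Wilcoxon
#' rank-sum for numeric ones), the gene-pair mutation co-occurrence matrix
#' with Benjamini-Hochberg FDR control and VAF-ordering fractions, and
#' WB-cfDNA VAF concordance.
#'
#' @name cohort-stats
NULL

#' Fisher's exact test on a contingency table
#'
#' Thin wrapper around [stats::fisher.test()] returning the two-sided
#' probability-based exact p-value and, for 2x2 tables, the conditional-MLE
#' odds ratio. Tables with a zero margin return p = 1 with the odds ratio
#' flagged undefined.
#'
#' @param table Integer matrix (at least 2x2) of non-negative counts.
#' @return List with `p_value`, `odds_ratio` (NA unless 2x2),
#'   `degenerate` (zero margin).
#' @examples
#' fisher_exact(matrix(c(38, 12, 24, 29), 2, byrow = TRUE))$p_value
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_, degenerate = TRUE))
  }
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value,
       odds_ratio = if (all(dim(table) == 2)) unname(ft$estimate) else NA_real_,
       degenerate = FALSE)
}

#' Wilcoxon rank-sum / signed-rank test
#'
#' Wrapper around [stats::wilcox.test()]: exact distribution for small
#' samples without ties, normal approximation with continuity and tie
#' correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param paired Paired (signed-rank) test; requires equal lengths.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, paired = FALSE) {
  if (length(x) == 0 || length(y) == 0) stop("empty input", call. = FALSE)
  if (paired && length(x) != length(y)) {
    stop("paired test requires equal lengths", call. = FALSE)
  }
  if (paired && all(x == y)) return(1)  # degenerate: no non-zero differences
  suppressWarnings(stats::wilcox.test(x, y, paired = paired)$p.value)
}

#' Gene-pair mutation co-occurrence matrix
#'
#' Among patients carrying multiple mutations, tests each unordered pair of
#' the `top_k` most frequently mutated genes for co-occurrence with
#' Fisher's exact test on the patient-level 2x2 table (has / has-not each
#' gene), adjusts across pairs with Benjamini-Hochberg FDR, and reports for
#' each directed pair the fraction of co-mutated patients in which the
#' first gene's largest clone has the higher VAF.
#'
#' @param variants Classified somatic variant data.frame with `patient_id`,
#'   `gene`, `vaf`.
#' @param top_k Number of most frequently mutated genes to test (default
#'   5).
#' @param min_mutations Restrict to patients with at least this many
#'   somatic mutations (default 2).
#' @param fdr_method Adjustment method for [stats::p.adjust()] (default
#'   `"BH"`).
#' @return data.frame with one row per unordered pair: `gene_1`, `gene_2`,
#'   `n_cooccur`, `odds_ratio`, `p_raw`, `p_fdr`,
#'   `frac_gene1_higher_vaf`, `frac_gene2_higher_vaf`, `or_upper_flagged`
#'   (infinite OR from a zero cell).
#' @export
cooccurrence_matrix <- function(variants, top_k = 5, min_mutations = 2,
                                fdr_method = "BH") {
  stopifnot(top_k >= 2,
            all(c("patient_id", "gene", "vaf") %in% names(variants)))
  som <- if (is.null(variants$category)) variants else
    variants[variants$category == "somatic", ]
  n_mut <- table(som$patient_id)
  keep <- names(n_mut)[n_mut >= min_mutations]
  som <- som[som$patient_id %in% keep, ]
  if (nrow(som) == 0) stop("no patients with multiple mutations", call. = FALSE)

  gene_n <- sort(table(unique(som[, c("patient_id", "gene")])$gene), decreasing = TRUE)
  genes <- names(gene_n)[seq_len(min(top_k, length(gene_n)))]
  pats <- unique(som$patient_id)
  has <- sapply(genes, function(g) pats %in% som$patient_id[som$gene == g])
  has <- matrix(has, nrow = length(pats), dimnames = list(pats, genes))
  max_vaf <- sapply(genes, function(g) {
    vapply(pats, function(p) {
      v <- som$vaf[som$patient_id == p & som$gene == g]
      if (length(v)) max(v) else NA_real_
    }, numeric(1))
  })
  max_vaf <- matrix(max_vaf, nrow = length(pats), dimnames = list(pats, genes))

  pairs <- utils::combn(genes, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    tab <- table(factor(has[, g1], c(TRUE, FALSE)),
                 factor(has[, g2], c(TRUE, FALSE)))
    ft <- fisher_exact(tab)
    both <- has[, g1] & has[, g2]
    nb <- sum(both)
    f1 <- if (nb > 0) mean(max_vaf[both, g1] > max_vaf[both, g2]) else NA_real_
    data.frame(gene_1 = g1, gene_2 = g2, n_cooccur = nb,
               odds_ratio = ft$odds_ratio, p_raw = ft$p_value,
               frac_gene1_higher_vaf = f1,
               frac_gene2_higher_vaf = if (is.na(f1)) NA_real_ else {
                 ties <- mean(max_vaf[both, g1] == max_vaf[both, g2])
                 1 - f1 - ties
               },
               or_upper_flagged = is.infinite(ft$odds_ratio),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- stats::p.adjust(res$p_raw, method = fdr_method)
  res
}

#' WB-cfDNA VAF concordance
#'
#' Pearson correlation of untransformed VAF fractions of variants detected
#' in both DNA sources.
#'
#' @param wb_vaf,cf_vaf Paired VAF fractions.
#' @return List with `r`, `n`, `p_value`; `r` is NA (flagged) for constant
#'   input.
#' @export
vaf_concordance <- function(wb_vaf, cf_vaf) {
  keep <- !is.na(wb_vaf) & !is.na(cf_vaf)
  wb <- wb_vaf[keep]; cf <- cf_vaf[keep]
  if (length(wb) < 3) stop("need at least 3 paired VAFs", call. = FALSE)
  if (stats::sd(wb) == 0 || stats::sd(cf) == 0) {
    return(list(r = NA_real_, n = length(wb), p_value = NA_real_,
                constant_input = TRUE))
  }
  ct <- stats::cor.test(wb, cf)
  list(r = unname(ct$estimate), n = length(wb), p_value = ct$p.value,
       constant_input = FALSE)
}

#' Baseline characteristics table with per-variable tests
#'
#' Compares baseline variables between two strata (typically CH-negative
#' vs CH-positive): categorical variables with Fisher's exact test on the
#' level x stratum contingency table, numeric variables with the unpaired
#' Wilcoxon rank-sum test (medians and IQRs reported).
#'
#' @param patients data.frame of per-patient covariates.
#' @param strata Logical or two-level factor along `patients` rows.
#' @param variables Named character vector mapping column names to
#'   `"categorical"` or `"numeric"`; defaults to a guess from column
#'   classes.
#' @return data.frame with `variable`, `type`, `p_value` and a formatted
#'   `summary` column (counts per level, or median (IQR), per stratum).
#' @export
baseline_table <- function(patients, strata, variables = NULL) {
  strata <- factor(strata)
  stopifnot(nrow(patients) == length(strata), nlevels(strata) == 2)
  if (is.null(variables)) {
    variables <- vapply(patients, function(x)
      if (is.numeric(x)) "numeric" else "categorical", "")
  }
  rows <- lapply(names(variables), function(v) {
    x <- patients[[v]]
    ok <- !is.na(x)
    if (!any(ok)) {
      warning("variable ", v, " is all-missing; skipped", call. = FALSE)
      return(NULL)
    }
    if (variables[[v]] == "categorical") {
      tab <- table(x[ok], strata[ok])
      p <- if (any(dim(tab) < 2)) 1 else fisher_exact(tab)$p_value
      fmt <- paste(apply(tab, 1, paste, collapse = "/"), collapse = "; ")
    } else {
      g <- split(x[ok], strata[ok])
      p <- wilcoxon_rank_sum(g[[1]], g[[2]])
      fmt <- paste(vapply(g, function(z) sprintf("%.2f (%.2f-%.2f)",
        stats::median(z), stats::quantile(z, 0.25), stats::quantile(z, 0.75)),
        ""), collapse = " vs ")
    }
    data.frame(variable = v, type = variables[[v]], p_value = p,
               summary = fmt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
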