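#' Single-cell DNA genotype analysis
#'
#' Clonal-architecture inference from single-cell DNA genotype matrices
#' (cells x variants; values 0 = wild type, 1 = heterozygous,
#' 2 = homozygous, NA = not genotyped). Covers sample QC, SNP-profile
#' demultiplexing of pooled samples, clone calling by exact genotype-vector
#' grouping, loss-of-heterozygosity flagging, doublet-aware
#' mutual-exclusivity testing, and serial comparison of clonal
#' architectures.
#'
#' Clone definition: cells are grouped by their complete genotype vector
#' over the somatic target variants; cells missing a genotype at any target
#' are left unassigned rather than imputed. Groups carrying at least one
#' mutant allele in at least 5 cells are reported as clones C1, C2, ...
#' ordered by descending cell count; the all-wild-type group is C0.
#'
#' @name single-cell
NULL

#' Sample-level QC on genotyped-cell count
#'
#' A cell counts as genotyped if it has a non-missing genotype at one or
#' more somatic target variants; the sample passes if at least `min_cells`
#' (default 400) cells are genotyped.
#'
#' @param matrix Genotype matrix (cells x variants, values 0/1/2/NA).
#' @param somatic_targets Columns holding the somatic targets (default all
#'   columns).
#' @param min_cells Minimum genotyped cells (inclusive; default 400).
#' @return List with `pass` (logical) and `n_genotyped`.
#' @export
qc_sample <- function(matrix, somatic_targets = colnames(matrix),
                      min_cells = 400) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0 || length(somatic_targets) == 0) {
    return(list(pass = FALSE, n_genotyped = 0L))
  }
  n <- sum(rowSums(!is.na(matrix[, somatic_targets, drop = FALSE])) >= 1)
  list(pass = n >= min_cells, n_genotyped = as.integer(n))
}

#' Demultiplex pooled cells by germline SNP profile
#'
#' When samples are pooled, each patient's germline SNP genotype profile
#' serves as a sample marker. Each cell is assigned to the profile with the
#' highest genotype concordance over its non-missing SNP calls. Cells whose
#' best concordance is below `min_concordance`, or whose top two
#' concordances differ by less than `min_margin` (the signature of an
#' inter-sample doublet or a noisy cell), are labelled `"ambiguous"`.
#'
#' @param matrix Genotype matrix restricted to (or containing) the SNP
#'   marker columns.
#' @param profiles Matrix or data.frame of per-sample SNP genotype vectors
#'   (samples x SNPs, rownames = sample ids, values 0/1/2).
#' @param min_concordance Minimum best concordance (default 0.9).
#' @param min_margin Minimum top-two concordance gap (default 0.1).
#' @return Character vector of sample assignments per cell (`"ambiguous"`
#'   where undecidable, NA where no SNP was genotyped).
#' @export
demultiplex <- function(matrix, profiles, min_concordance = 0.9,
                        min_margin = 0.1) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 SNP profiles", call. = FALSE)
  if (anyDuplicated(apply(profiles, 1, paste, collapse = ","))) {
    stop("identical SNP profiles are non-separable", call. = FALSE)
  }
  snps <- colnames(profiles)
  stopifnot(all(snps %in% colnames(matrix)))
  g <- as.matrix(matrix[, snps, drop = FALSE])
  samples <- rownames(profiles)

  conc <- sapply(seq_len(nrow(profiles)), function(k) {
    ref <- matrix(profiles[k, ], nrow = nrow(g), ncol = length(snps), byrow = TRUE)
    ok <- !is.na(g)
    hits <- rowSums(ok & g == ref)
    hits / pmax(rowSums(ok), 1)
  })
  conc <- matrix(conc, nrow = nrow(g))
  n_called <- rowSums(!is.na(g))
  best <- max.col(conc, ties.method = "first")
  best_val <- conc[cbind(seq_len(nrow(g)), best)]
  second_val <- apply(conc, 1, function(x) sort(x, decreasing = TRUE)[2])

  out <- samples[best]
  out[best_val < min_concordance | (best_val - second_val) < min_margin] <- "ambiguous"
  out[n_called == 0] <- NA_character_
  out
}

#' Call clones by exact genotype-vector grouping
#'
#' @param matrix Genotype matrix (cells x variants, 0/1/2/NA).
#' @param somatic_targets Columns holding the somatic targets (default all).
#' @param min_clone_cells Minimum cells for a mutant clone to be reported
#'   (inclusive; default 5).
#' @return List of class `chdyn_clones` with elements
#'   * `clones`: data.frame with `label` (C0, C1, ...), `genotype`
#'     (comma-separated vector over the targets), `cell_count`, `fraction`
#'     (of genotyped cells), `loh` (any homozygous-mutant genotype —
#'     loss of heterozygosity);
#'   * `assignment`: per-cell clone label (NA for unassigned cells:
#'     missing a target genotype, or member of an unreported small group);
#'   * `n_genotyped`, `unassigned_fraction`, `targets`.
#' @export
call_clones <- function(matrix, somatic_targets = colnames(matrix),
                        min_clone_cells = 5) {
  g <- as.matrix(matrix[, somatic_targets, drop = FALSE])
  genotyped <- rowSums(!is.na(g)) >= 1
  complete <- rowSums(is.na(g)) == 0
  n_genotyped <- sum(genotyped)

  key <- apply(g, 1, paste, collapse = ",")
  key[!complete] <- NA
  groups <- table(key[complete & genotyped])

  wt_key <- paste(rep(0L, ncol(g)), collapse = ",")
  mut_keys <- setdiff(names(groups), wt_key)
  reported <- mut_keys[groups[mut_keys] >= min_clone_cells]
  reported <- reported[order(-groups[reported], reported)]

  labels <- c(C0 = wt_key)
  if (length(reported)) {
    labels <- c(labels, stats::setNames(reported, paste0("C", seq_along(reported))))
  }
  counts <- as.integer(ifelse(names(labels) == "C0" & !(wt_key %in% names(groups)),
                              0L, groups[labels]))
  counts[is.na(counts)] <- 0L
  loh <- vapply(labels, function(k) {
    any(as.integer(strsplit(k, ",")[[1]]) == 2L)
  }, logical(1))

  assignment <- rep(NA_character_, nrow(g))
  for (i in seq_along(labels)) {
    assignment[!is.na(key) & key == labels[i] & genotyped] <- names(labels)[i]
  }
  clones <- data.frame(
    label = names(labels),
    genotype = unname(labels),
    cell_count = counts,
    fraction = if (n_genotyped > 0) counts / n_genotyped else rep(0, length(counts)),
    loh = unname(loh),
    row.names = NULL
  )
  structure(list(
    clones = clones,
    assignment = assignment,
    n_genotyped = n_genotyped,
    unassigned_fraction = if (n_genotyped > 0)
      1 - sum(clones$fraction) else 0,
    targets = somatic_targets
  ), class = "chdyn_clones")
}

#' @export
print.chdyn_clones <- function(x, ...) {
  cat(sprintf("Clonal architecture: %d genotyped cells, %d clones (+C0), %.1f%% unassigned\n",
              x$n_genotyped, sum(x$clones$label != "C0"),
              100 * x$unassigned_fraction))
  print(x$clones, ...)
  invisible(x)
}

#' Doublet-aware mutual-exclusivity test for two mutations
#'
#' Tests whether two mutations co-occur in the same cells beyond what cell
#' doublets alone would produce. Among cells genotyped at both variants,
#' the observed double-mutant count is compared against the expected
#' doublet background `2 * doublet_rate * f_a * f_b` (f = mutant-cell
#' fractions) with a one-sided exact binomial test; the pair is called
#' `co_occurring` if the observed count significantly exceeds the
#' background at level `alpha`, `exclusive` otherwise.
#'
#' @param matrix Genotype matrix (0/1/2/NA).
#' @param variant_a,variant_b Column names of the two variants.
#' @param doublet_rate Fraction of cell barcodes containing two cells.
#' @param alpha One-sided significance level (default 0.05).
#' @param min_cells Minimum mutant cells per variant for the test to be
#'   informative (default 5).
#' @return List: `call` (`"exclusive"`/`"co_occurring"`),
#'   `double_mutant_fraction`, `expected_background`, `p_value`, `n_cells`
#'   (genotyped at both), `f_a`, `f_b`, `vacuous` (a marginal fraction is
#'   zero or below `min_cells` mutant cells).
#' @export
test_exclusivity <- function(matrix, variant_a, variant_b, doublet_rate,
                             alpha = 0.05, min_cells = 5) {
  a <- matrix[, variant_a]
  b <- matrix[, variant_b]
  both <- !is.na(a) & !is.na(b)
  n <- sum(both)
  mut_a <- both & a > 0
  mut_b <- both & b > 0
  f_a <- if (n > 0) sum(mut_a) / n else 0
  f_b <- if (n > 0) sum(mut_b) / n else 0
  x <- sum(mut_a & mut_b)
  vacuous <- sum(mut_a) < min_cells || sum(mut_b) < min_cells
  bg <- min(2 * doublet_rate * f_a * f_b, 1)
  p <- if (n == 0) 1
       else if (bg == 0) as.numeric(x == 0)   # any double mutant exceeds a zero background
       else stats::binom.test(x, n, p = bg, alternative = "greater")$p.value
  call <- if (!vacuous && p < alpha) "co_occurring" else "exclusive"
  list(call = call,
       double_mutant_fraction = if (n > 0) x / n else 0,
       expected_background = bg,
       p_value = p,
       n_cells = n, f_a = f_a, f_b = f_b,
       vacuous = vacuous)
}

#' Compare clonal architectures between serial samples
#'
#' Matches clones by genotype vector across two samples sharing a variant
#' panel and reports per-clone fraction changes and appearance /
#' disappearance flags.
#'
#' @param clones_t1,clones_t2 Outputs of [call_clones()] on the two
#'   samples; the target panels must overlap.
#' @return data.frame with `genotype`, `label_t1`, `label_t2`,
#'   `fraction_t1`, `fraction_t2`, `delta`, `status`
#'   (`"shared"`, `"appeared"`, `"disappeared"`).
#' @export
compare_serial_architecture <- function(clones_t1, clones_t2) {
  stopifnot(inherits(clones_t1, "chdyn_clones"), inherits(clones_t2, "chdyn_clones"))
  if (!identical(clones_t1$targets, clones_t2$targets)) {
    if (length(intersect(clones_t1$targets, clones_t2$targets)) == 0) {
      stop("clone tables have disjoint variant panels", call. = FALSE)
    }
    stop("clone tables must be called on the same variant panel", call. = FALSE)
  }
  a <- clones_t1$clones; b <- clones_t2$clones
  genos <- union(a$genotype, b$genotype)
  ia <- match(genos, a$genotype); ib <- match(genos, b$genotype)
  f1 <- ifelse(is.na(ia), 0, a$fraction[ia])
  f2 <- ifelse(is.na(ib), 0, b$fraction[ib])
  data.frame(
    genotype = genos,
    label_t1 = ifelse(is.na(ia), NA_character_, a$label[ia]),
    label_t2 = ifelse(is.na(ib), NA_character_, b$label[ib]),
    fraction_t1 = f1,
    fraction_t2 = f2,
    delta = f2 - f1,
    status = ifelse(is.na(ia), "appeared",
             ifelse(is.na(ib), "disappeared", "shared"))
  )
}
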