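#' Synthetic CH cohort generation
#'
#' Generates ground-truth cohorts with the statistical structure the
#' downstream analysis assumes: patients with CH clones whose fitness
#' depends on gene class and treatment phase, three serial timepoints
#' spanning a carboplatin phase and a PARP-inhibitor maintenance phase,
#' binomial sequencing noise on error-corrected consensus reads at
#' configurable depth, germline variants near 50% VAF, tumor-shed
#' cfDNA-only variants, and ground-truth labels for every emitted row.
#'
#' @name synthetic-cohort
NULL

#' Simulation configuration
#'
#' All rates are fractions in `[0, 1]`; VAF thresholds quoted in percent
#' elsewhere are fractions here (1% = 0.01). Defaults mirror the study
#' design the generator emulates: ~100 patients sampled at treatment
#' start, maintenance start and end of treatment (0 / 0.5 / 1.0 years,
#' approximating median phase durations of roughly half a year each), with
#' DDR-gene clones (TP53, PPM1D) given high fitness under carboplatin,
#' PPM1D fitness dropping during PARPi maintenance, and DTA-gene clones
#' (DNMT3A, TET2) near-neutral throughout.
#'
#' @param n_patients Number of patients (default 103).
#' @param timepoints_years Strictly increasing sample times in years
#'   (default `c(0, 0.5, 1)`).
#' @param wb_depth,cf_depth Mean consensus-read depth per locus for whole
#'   blood and cfDNA; per-locus depths are Poisson around the mean
#'   (defaults 2000 and 1000).
#' @param gene_fitness_priors data.frame with columns `gene`, `weight`
#'   (sampling weight for clone genes), `s_carbo`, `s_maint` (mean fitness
#'   per phase, /year) and `s_sd` (between-clone SD).
#' @param tumor_shed_fraction Probability a patient has tumor-derived
#'   cfDNA-only variants (default 0.5).
#' @param ado_rate Allele dropout probability for single-cell genotypes
#'   (default 0.1).
#' @param doublet_rate Fraction of cell barcodes containing two cells
#'   (default 0.08).
#' @param mean_clones Mean number of CH clones per patient (Poisson;
#'   default 1.3).
#' @param seed Integer RNG seed.
#' @return Validated list of class `chdyn_config`.
#' @export
simulation_config <- function(n_patients = 103,
                              timepoints_years = c(0, 0.5, 1),
                              wb_depth = 2000,
                              cf_depth = 1000,
                              gene_fitness_priors = default_fitness_priors(),
                              tumor_shed_fraction = 0.5,
                              ado_rate = 0.1,
                              doublet_rate = 0.08,
                              mean_clones = 1.3,
                              seed = 1L) {
  stopifnot(
    n_patients >= 0,
    length(timepoints_years) >= 2, all(diff(timepoints_years) > 0),
    wb_depth > 0, cf_depth > 0,
    tumor_shed_fraction >= 0, tumor_shed_fraction <= 1,
    ado_rate >= 0, ado_rate <= 1,
    doublet_rate >= 0, doublet_rate <= 1,
    all(c("gene", "weight", "s_carbo", "s_maint", "s_sd") %in%
          names(gene_fitness_priors))
  )
  structure(list(
    n_patients = as.integer(n_patients),
    timepoints_years = timepoints_years,
    wb_depth = wb_depth, cf_depth = cf_depth,
    gene_fitness_priors = gene_fitness_priors,
    tumor_shed_fraction = tumor_shed_fraction,
    ado_rate = ado_rate, doublet_rate = doublet_rate,
    mean_clones = mean_clones,
    seed = as.integer(seed)
  ), class = "chdyn_config")
}

#' Default per-gene fitness priors
#'
#' Gene weights follow the mutation prevalence ordering typical of
#' therapy-exposed CH cohorts (PPM1D most frequent, then DNMT3A, TET2,
#' CHEK2, TP53, ...); phase fitness means encode strong positive selection
#' of TP53/PPM1D clones under carboplatin, attenuation of PPM1D (but not
#' TP53) fitness under PARPi maintenance, and near-neutral DTA clones.
#'
#' @return data.frame with columns `gene`, `weight`, `s_carbo`, `s_maint`,
#'   `s_sd`.
#' @export
default_fitness_priors <- function() {
  data.frame(
    gene    = c("PPM1D", "DNMT3A", "TET2", "CHEK2", "TP53", "ATM", "ASXL1", "SRSF2"),
    weight  = c(0.35, 0.20, 0.12, 0.09, 0.08, 0.05, 0.06, 0.05),
    s_carbo = c(1.93, 0.10, 0.05, 0.80, 1.90, 0.60, 0.10, 0.20),
    s_maint = c(0.36, 0.10, 0.05, 0.50, 1.90, 0.40, 0.10, 0.20),
    s_sd    = c(0.60, 0.30, 0.30, 0.40, 0.60, 0.40, 0.30, 0.30)
  )
}

#' Draw binomial read counts for a locus
#'
#' Noise model for error-corrected consensus reads: the alternate-read
#' count is Binomial(depth, true VAF).
#'
#' @param true_vaf True VAF fraction in `[0, 1]` (vector).
#' @param depth Consensus-read depth (vector, > 0).
#' @return data.frame with `alt_reads`, `depth`, `vaf` (observed).
#' @export
sample_read_counts <- function(true_vaf, depth) {
  stopifnot(all(true_vaf >= 0 & true_vaf <= 1), all(depth > 0))
  n <- max(length(true_vaf), length(depth))
  true_vaf <- rep_len(true_vaf, n); depth <- rep_len(as.integer(depth), n)
  alt <- stats::rbinom(n, depth, true_vaf)
  data.frame(alt_reads = alt, depth = depth, vaf = alt / depth)
}

# gene symbols used for non-CH germline SNP filler loci
.snp_filler_genes <- c("GPR98", "TTN", "OBSCN", "MUC16")

#' Simulate a ground-truth cohort with noisy observations
#'
#' Produces (a) per-patient clinical covariates; (b) a complete pileup of
#' per-variant, per-sample, per-timepoint read counts for WB and cfDNA
#' (binomial noise, Poisson depth); (c) a detected-calls table applying
#' the 0.1% calling floor; (d) a ground-truth table for every variant.
#' Hematopoietic clones share their true VAF trajectory between WB and
#' cfDNA (independent noise per source); tumor-shed variants (drawn in
#' TP53 and HR genes) have true WB VAF 0; germline variants sit at true
#' VAF 0.5 in both sources.
#'
#' @param config A [simulation_config()].
#' @return List of class `chdyn_cohort`:
#'   * `patients`: `patient_id`, `age`, `arm`, `prior_lines`,
#'     `prior_parpi`, `prior_parpi_months`, `germline_hrd`;
#'   * `truth`: per-variant ground truth (`variant_id`, gene, identity,
#'     `category` in somatic/germline/germline_snp/tumor/artifact,
#'     `origin`, `v0`, `s_carbo`, `s_maint`, plus true VAF per timepoint
#'     columns `true_vaf_t<k>`);
#'   * `pileup`: every variant x source x timepoint with `alt_reads`,
#'     `depth`, `vaf` (including zero-read rows);
#'   * `calls`: the detected subset (VAF >= 0.1% and >= 1 alt read) in
#'     the annotated-call schema consumed by [classify_variants()].
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "chdyn_config"))
  set.seed(config$seed)
  tps <- config$timepoints_years
  pri <- config$gene_fitness_priors

  empty_truth <- data.frame(
    patient_id = character(0), variant_id = character(0), gene = character(0),
    chrom = character(0), pos = integer(0), ref = character(0), alt = character(0),
    protein_change = character(0), effect = character(0), category = character(0),
    origin = character(0), v0 = numeric(0), s_carbo = numeric(0),
    s_maint = numeric(0), dbsnp = logical(0), gnomad_af = numeric(0),
    clinvar = character(0), stringsAsFactors = FALSE
  )

  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(config$n_patients)),
    age = round(stats::rnorm(config$n_patients, 63, 9)),
    arm = sample(c("A", "B", "C"), config$n_patients, replace = TRUE),
    prior_lines = 1L + stats::rpois(config$n_patients, 0.5),
    stringsAsFactors = FALSE
  )
  patients$prior_parpi <- stats::runif(config$n_patients) < 0.27
  patients$prior_parpi_months <- ifelse(patients$prior_parpi,
                                        round(stats::runif(config$n_patients, 3, 30)), 0)
  patients$germline_hrd <- stats::runif(config$n_patients) < 0.3

  truth_rows <- list()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk_variant <- function(pid, gene, effect, category, origin, v0, s_carbo, s_maint,
                         dbsnp = FALSE, gnomad_af = NA_real_, clinvar = NA_character_) {
    pos <- sample.int(2e8, 1)
    data.frame(
      patient_id = pid,
      variant_id = sprintf("%s_%s_%d", pid, gene, pos),
      gene = gene, chrom = paste0("chr", sample.int(22, 1)), pos = pos,
      ref = sample(c("A", "C", "G", "T"), 1),
      alt = sample(c("A", "C", "G", "T"), 1),
      protein_change = paste0(sample(aa, 1), sample.int(900, 1), sample(aa, 1)),
      effect = effect, category = category, origin = origin,
      v0 = v0, s_carbo = s_carbo, s_maint = s_maint,
      dbsnp = dbsnp, gnomad_af = gnomad_af, clinvar = clinvar,
      stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(config$n_patients)) {
    pid <- patients$patient_id[i]
    # CH clones: gene-weighted, log-uniform starting VAF, per-phase fitness
    n_clones <- stats::rpois(1, config$mean_clones)
    for (k in seq_len(n_clones)) {
      g <- sample(pri$gene, 1, prob = pri$weight)
      row <- pri[pri$gene == g, ]
      v0 <- exp(stats::runif(1, log(0.002), log(0.15)))
      truth_rows[[length(truth_rows) + 1]] <- mk_variant(
        pid, g, "nonsynonymous", "somatic", "hematopoietic", v0,
        stats::rnorm(1, row$s_carbo, row$s_sd),
        stats::rnorm(1, row$s_maint, row$s_sd)
      )
    }
    # common germline SNPs (true VAF 0.5, dbSNP-flagged, common in gnomAD)
    for (k in seq_len(2)) {
      truth_rows[[length(truth_rows) + 1]] <- mk_variant(
        pid, sample(.snp_filler_genes, 1), "nonsynonymous", "germline_snp",
        "hematopoietic", 0.5, 0, 0,
        dbsnp = TRUE, gnomad_af = stats::runif(1, 0.05, 0.4)
      )
    }
    # pathogenic germline HR variant for HRD-positive patients
    if (patients$germline_hrd[i]) {
      g <- sample(c("BRCA1", "BRCA2", "RAD51C", "PALB2"), 1)
      truth_rows[[length(truth_rows) + 1]] <- mk_variant(
        pid, g, sample(c("stopgain", "truncating_indel", "splice"), 1),
        "germline", "hematopoietic", 0.5, 0, 0,
        gnomad_af = stats::runif(1, 0, 5e-4),
        clinvar = sample(c("pathogenic", NA_character_), 1)
      )
    }
    # tumor-shed cfDNA-only variants (true WB VAF 0)
    if (stats::runif(1) < config$tumor_shed_fraction) {
      for (k in seq_len(1 + stats::rpois(1, 0.8))) {
        g <- sample(c("TP53", "TP53", "BRCA1", "BRCA2", "RAD51D", "BRIP1"), 1)
        v0 <- exp(stats::runif(1, log(0.01), log(0.25)))
        truth_rows[[length(truth_rows) + 1]] <- mk_variant(
          pid, g, "nonsynonymous", "tumor", "non_hematopoietic", v0,
          stats::rnorm(1, -1.5, 2.5), stats::rnorm(1, 0, 1.5)
        )
      }
    }
    # artifact calls that the retention filter must remove
    if (stats::runif(1) < 0.3) {
      truth_rows[[length(truth_rows) + 1]] <- mk_variant(
        pid, sample(pri$gene, 1), "synonymous", "artifact", "hematopoietic",
        exp(stats::runif(1, log(0.002), log(0.05))), 0, 0
      )
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else empty_truth

  # true VAF per timepoint: phase durations from the configured timepoints
  dur1 <- tps[2] - tps[1]
  true_vaf <- matrix(0, nrow(truth), length(tps))
  for (j in seq_len(nrow(truth))) {
    if (truth$v0[j] >= 0.5) {
      # germline variants sit at fixed allele fraction, outside the somatic model
      true_vaf[j, ] <- truth$v0[j]
    } else {
      phases <- list(c(dur1, truth$s_carbo[j]), c(Inf, truth$s_maint[j]))
      true_vaf[j, ] <- simulate_trajectory(truth$v0[j], phases, tps - tps[1])
    }
  }
  colnames(true_vaf) <- sprintf("true_vaf_t%d", seq_along(tps))
  truth <- cbind(truth, true_vaf)

  # emit pileup: variant x source x timepoint
  if (nrow(truth) > 0) {
    grid <- expand.grid(row = seq_len(nrow(truth)), source = c("WB", "cfDNA"),
                        tp = seq_along(tps), stringsAsFactors = FALSE)
    tv <- true_vaf[cbind(grid$row, grid$tp)]
    tv[grid$source == "WB" & truth$category[grid$row] == "tumor"] <- 0
    mean_depth <- ifelse(grid$source == "WB", config$wb_depth, config$cf_depth)
    depth <- pmax(stats::rpois(nrow(grid), mean_depth), 1L)
    counts <- sample_read_counts(tv, depth)
    pileup <- data.frame(
      patient_id = truth$patient_id[grid$row],
      sample_id = sprintf("%s_%s_t%d", truth$patient_id[grid$row],
                          grid$source, grid$tp),
      variant_id = truth$variant_id[grid$row],
      source = grid$source,
      timepoint_years = tps[grid$tp],
      chrom = truth$chrom[grid$row], pos = truth$pos[grid$row],
      ref = truth$ref[grid$row], alt = truth$alt[grid$row],
      gene = truth$gene[grid$row],
      protein_change = truth$protein_change[grid$row],
      effect = truth$effect[grid$row],
      vaf = counts$vaf, alt_reads = counts$alt_reads, depth = counts$depth,
      dbsnp = truth$dbsnp[grid$row],
      gnomad_af = truth$gnomad_af[grid$row],
      clinvar = truth$clinvar[grid$row],
      stringsAsFactors = FALSE
    )
    pileup <- pileup[order(pileup$patient_id, pileup$variant_id,
                           pileup$source, pileup$timepoint_years), ]
    rownames(pileup) <- NULL
    calls <- pileup[pileup$vaf >= 0.001 & pileup$alt_reads >= 1, ]
    rownames(calls) <- NULL
  } else {
    pileup <- calls <- data.frame()
  }

  structure(list(patients = patients, truth = truth,
                 pileup = pileup, calls = calls,
                 config = config), class = "chdyn_cohort")
}

#' @export
print.chdyn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CH cohort: %d patients, %d truth variants, %d detected calls\n",
              nrow(x$patients), nrow(x$truth), nrow(x$calls)))
  invisible(x)
}

#' Simulate a single-cell genotype matrix with dropout and doublets
#'
#' Each simulated cell barcode is a singlet drawn from the clone fractions
#' (the remainder being all-wild-type C0 cells) or, with probability
#' `doublet_rate`, a doublet merging two independently drawn cells
#' (per-locus maximum genotype). Each genotyped allele is then
#' independently dropped: heterozygous calls drop to wild type or
#' homozygous (one allele lost) and any call may drop to missing.
#'
#' @param clones List of clones, each `list(genotype = <vector of 0/1/2
#'   over the variants>, fraction = <cell fraction>)`; fractions must sum
#'   to <= 1.
#' @param n_cells Number of cell barcodes to simulate.
#' @param ado_rate Per-allele dropout probability (default 0).
#' @param doublet_rate Doublet barcode fraction (default 0).
#' @param missing_rate Per-genotype missingness probability (default equal
#'   to `ado_rate / 2`).
#' @param variant_ids Column names (default V1, V2, ...).
#' @return List with `matrix` (cells x variants, 0/1/2/NA) and
#'   `truth` data.frame (`clone` index of first drawn cell, 0 = wild type;
#'   `doublet` logical; `clone2` second clone for doublets).
#' @export
simulate_genotype_matrix <- function(clones, n_cells, ado_rate = 0,
                                     doublet_rate = 0,
                                     missing_rate = ado_rate / 2,
                                     variant_ids = NULL) {
  fr <- vapply(clones, function(cl) cl$fraction, numeric(1))
  if (sum(fr) > 1 + 1e-12) stop("clone fractions must sum to <= 1", call. = FALSE)
  geno <- do.call(rbind, lapply(clones, function(cl) cl$genotype))
  n_var <- ncol(geno)
  if (is.null(variant_ids)) variant_ids <- paste0("V", seq_len(n_var))
  probs <- c(1 - sum(fr), fr)   # index 1 = wild-type C0

  draw <- function(n) sample.int(length(probs), n, replace = TRUE, prob = probs) - 1L
  c1 <- draw(n_cells)
  dbl <- stats::runif(n_cells) < doublet_rate
  c2 <- ifelse(dbl, draw(n_cells), NA_integer_)

  cell_geno <- function(idx) {
    out <- matrix(0L, length(idx), n_var)
    hit <- idx > 0
    out[hit, ] <- geno[idx[hit], , drop = FALSE]
    out
  }
  g <- cell_geno(c1)
  g2 <- cell_geno(ifelse(is.na(c2), 0L, c2))
  g[dbl, ] <- pmax(g[dbl, , drop = FALSE], g2[dbl, , drop = FALSE])

  if (ado_rate > 0) {
    # each of the two alleles drops independently; for a het call one
    # dropped allele yields an apparent hom (0 or 2), both dropped -> NA
    drop1 <- matrix(stats::runif(length(g)) < ado_rate, nrow(g))
    drop2 <- matrix(stats::runif(length(g)) < ado_rate, nrow(g))
    het <- g == 1L
    g[het & drop1 & !drop2] <- 2L   # wild-type allele lost
    g[het & !drop1 & drop2] <- 0L   # mutant allele lost
    g[het & drop1 & drop2] <- NA
    g[!het & drop1 & drop2] <- NA
  }
  if (missing_rate > 0) {
    g[matrix(stats::runif(length(g)) < missing_rate, nrow(g))] <- NA
  }
  dimnames(g) <- list(sprintf("cell%05d", seq_len(n_cells)), variant_ids)
  list(matrix = g,
       truth = data.frame(clone = c1, doublet = dbl, clone2 = c2))
}
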