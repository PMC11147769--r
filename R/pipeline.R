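#' Pipeline configuration with study-default thresholds
#'
#' Collects every analysis constant in one place so that stage logic never
#' hard-codes a threshold. Defaults are the study's printed values:
#' germline VAF > 45%, SNP exclusion above VAF 40% at population AF > 1%,
#' CH calling at VAF >= 1%, paired inclusion at 0.8%, detection floor
#' 0.1%, 5-fold cfDNA/WB origin rule, 10-fold tumor-dynamics rule,
#' +/-0.25/year fitness categories, >= 10 alternate consensus reads,
#' >= 400 genotyped cells per single-cell sample and >= 5 cells per clone.
#' Overrides are recorded in the run manifest.
#'
#' @param ... Named overrides of any default threshold, gene list or
#'   simulation setting.
#' @return List of class `chdyn_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    germline_vaf = 0.45,
    snp_vaf = 0.40,
    snp_pop_af = 0.01,
    ch_vaf = 0.01,
    paired_sum_vaf = 0.008,
    detection_floor = 0.001,
    origin_fold = 5,
    tumor_fold = 10,
    fitness_threshold = 0.25,
    min_alt_reads = 10,
    min_cells = 400,
    min_clone_cells = 5,
    ch_genes = default_gene_list("ch"),
    hr_genes = default_gene_list("hr"),
    seed = 1L,
    simulation = NULL   # a simulation_config(), or NULL to use defaults
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  cfg$overrides <- names(overrides)
  class(cfg) <- "chdyn_pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   fields.
#' @return List of class `chdyn_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a synthetic or supplied cohort
#'
#' Orchestrates the stages end to end: simulate (unless a cohort is
#' supplied) -> classify -> CH status -> paired WB/cfDNA attribution ->
#' germline HRD -> clonal fitness (whole-course WB pairs and per-phase
#' cfDNA decomposition) -> cohort statistics. Writes each stage's table as
#' TSV plus a YAML manifest (seed, thresholds, overrides, per-stage record
#' counts) when `out_dir` is given. Deterministic for a fixed config.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional `chdyn_cohort`; simulated from
#'   `config$simulation` when NULL.
#' @param out_dir Optional output directory for TSVs and the manifest.
#' @return Invisibly, a list with elements `cohort`, `classified`,
#'   `ch_status`, `trajectories`, `germline`, `hrd_status`,
#'   `fitness_overall`, `fitness_phase`, `crossings`, `cooccurrence`,
#'   `concordance`, `baseline`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "chdyn_pipeline_config"))
  if (is.null(cohort)) {
    sim_cfg <- if (is.null(config$simulation))
      simulation_config(seed = config$seed) else config$simulation
    cohort <- simulate_cohort(sim_cfg)
  }
  if (nrow(cohort$calls) == 0) stop("cohort has no detected calls", call. = FALSE)

  classified <- classify_variants(
    cohort$calls,
    germline_vaf = config$germline_vaf, snp_vaf = config$snp_vaf,
    snp_pop_af = config$snp_pop_af, min_alt_reads = config$min_alt_reads,
    hr_genes = config$hr_genes, ch_genes = config$ch_genes
  )

  baseline_wb <- classified[classified$source == "WB" &
                              classified$timepoint_years == min(classified$timepoint_years), ]
  ch_status <- call_ch_status(baseline_wb, config$ch_genes, config$ch_vaf,
                              patients = cohort$patients$patient_id)

  somatic_ids <- unique(classified$variant_id[classified$category == "somatic"])
  pile <- cohort$pileup[cohort$pileup$variant_id %in% somatic_ids, ]
  trajectories <- attribute_cfdna(
    pile, sum_vaf = config$paired_sum_vaf, fold = config$origin_fold,
    floor = config$detection_floor
  )

  germ <- classified[classified$category == "germline" & classified$source == "WB", ]
  germ <- germ[!duplicated(germ$variant_id), ]
  germline <- classify_germline(germ, hr_genes = config$hr_genes,
                                pop_af_max = config$snp_pop_af)
  hrd_status <- patient_hrd_status(germline, patients = cohort$patients$patient_id)

  # whole-course fitness from first/last WB observation per retained variant
  tr <- trajectories[trajectories$retained & trajectories$included, ]
  fitness_overall <- .trajectory_fitness(tr, "WB", config)
  fitness_phase <- .phase_fitness_table(tr, "cfDNA", config)
  crossings <- if (nrow(fitness_overall))
    count_threshold_crossings(fitness_overall, config$ch_vaf) else NULL

  somatic_wb <- baseline_wb[baseline_wb$category == "somatic", ]
  cooccurrence <- tryCatch(
    cooccurrence_matrix(somatic_wb),
    error = function(e) { warning(conditionMessage(e), call. = FALSE); NULL }
  )
  wide <- merge(
    classified[classified$source == "WB", c("variant_id", "timepoint_years", "vaf")],
    classified[classified$source == "cfDNA", c("variant_id", "timepoint_years", "vaf")],
    by = c("variant_id", "timepoint_years"), suffixes = c("_wb", "_cf")
  )
  concordance <- if (nrow(wide) >= 3)
    vaf_concordance(wide$vaf_wb, wide$vaf_cf) else NULL
  baseline <- baseline_table(
    cohort$patients[, c("age", "arm", "prior_lines", "prior_parpi")],
    strata = ch_status$ch_positive[match(cohort$patients$patient_id,
                                         ch_status$patient_id)],
    variables = c(age = "numeric", arm = "categorical",
                  prior_lines = "categorical", prior_parpi = "categorical")
  )

  result <- list(
    cohort = cohort, classified = classified, ch_status = ch_status,
    trajectories = trajectories, germline = germline, hrd_status = hrd_status,
    fitness_overall = fitness_overall, fitness_phase = fitness_phase,
    crossings = crossings, cooccurrence = cooccurrence,
    concordance = concordance, baseline = baseline
  )
  result$manifest <- list(
    package_version = as.character(utils::packageVersion("chdyn")),
    seed = config$seed,
    thresholds = config[c("germline_vaf", "snp_vaf", "snp_pop_af", "ch_vaf",
                          "paired_sum_vaf", "detection_floor", "origin_fold",
                          "tumor_fold", "fitness_threshold", "min_alt_reads",
                          "min_cells", "min_clone_cells")],
    overrides = config$overrides,
    stages = lapply(result[c("classified", "ch_status", "trajectories",
                             "germline", "hrd_status", "fitness_overall",
                             "fitness_phase")],
                    function(x) if (is.data.frame(x)) nrow(x) else NA_integer_)
  )
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  invisible(result)
}

.trajectory_fitness <- function(tr, source, config) {
  tr <- tr[tr$source == source, ]
  if (nrow(tr) == 0) {
    return(data.frame(variant_id = character(0), gene = character(0),
                      v_start = numeric(0), v_end = numeric(0), s = numeric(0),
                      A = numeric(0), category = character(0),
                      censored = logical(0)))
  }
  out <- lapply(split(tr, tr$variant_id), function(v) {
    v <- v[order(v$timepoint_years), ]
    n <- nrow(v)
    fit <- fit_fitness(v$vaf[1], v$vaf[n],
                       v$timepoint_years[n] - v$timepoint_years[1],
                       floor = config$detection_floor,
                       threshold = config$fitness_threshold)
    cbind(data.frame(variant_id = v$variant_id[1],
                     gene = if (is.null(v$gene)) NA_character_ else v$gene[1],
                     v_start = v$vaf[1], v_end = v$vaf[n]),
          fit)
  })
  out <- do.call(rbind, out)
  out$censored <- out$censored | vapply(split(tr, tr$variant_id),
                                        function(v) any(v$censored), logical(1))
  rownames(out) <- NULL
  out
}

.phase_fitness_table <- function(tr, source, config) {
  tr <- tr[tr$source == source, ]
  out <- lapply(split(tr, tr$variant_id), function(v) {
    v <- v[order(v$timepoint_years), ]
    if (nrow(v) != 3) return(NULL)
    fit <- phase_fitness(v$timepoint_years, v$vaf,
                         floor = config$detection_floor,
                         threshold = config$fitness_threshold)
    cbind(data.frame(variant_id = v$variant_id[1],
                     gene = if (is.null(v$gene)) NA_character_ else v$gene[1]),
          fit)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(variant_id = character(0), gene = character(0),
                      phase = character(0), s = numeric(0), A = numeric(0),
                      category = character(0), censored = logical(0)))
  }
  rownames(out) <- NULL
  out
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("classified", "ch_status", "trajectories", "germline",
            "hrd_status", "fitness_overall", "fitness_phase", "crossings",
            "cooccurrence", "baseline")
  for (nm in tabs) {
    if (is.data.frame(result[[nm]])) {
      write_tsv(result[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Read / write tab-separated variant tables
#'
#' Plain TSV with a header row, no quoting of numeric fields, `NA` for
#' missing values — the interchange format of every pipeline stage.
#'
#' @param path File path.
#' @param x data.frame to write.
#' @return `read_variant_tsv`: a data.frame.
#' @export
read_variant_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_variant_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
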