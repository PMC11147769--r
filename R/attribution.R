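#' Paired whole-blood / cfDNA analysis and origin attribution
#'
#' Plasma cell-free DNA (cfDNA) is a mixture of hematopoietic and
#' tumor-derived fragments, so a variant seen in cfDNA may reflect either a
#' CH clone (also present in whole blood, WB) or tumor shedding (absent or
#' far smaller in WB). These functions implement the paired-sample
#' inclusion rule, the fold-change origin rule, serial-timepoint retention,
#' the detection-limit rescue of sub-threshold timepoints, and the 10-fold
#' categorisation of tumor-mutation dynamics.
#'
#' @name cfdna-attribution
NULL

#' Paired-sample inclusion rule
#'
#' A variant enters the paired WB/cfDNA analysis if it is detected in
#' either source with VAF >= 0.8%, or detected in both sources with the sum
#' of the two VAFs >= 0.8%. Undetected is encoded as VAF 0.
#'
#' @param wb_vaf,cf_vaf Observed VAF fractions (vectors, recycled).
#' @param sum_vaf Inclusion threshold on the VAF (fraction, default 0.008).
#' @return Logical vector.
#' @export
include_paired <- function(wb_vaf, cf_vaf, sum_vaf = 0.008) {
  n <- max(length(wb_vaf), length(cf_vaf))
  wb <- rep_len(wb_vaf, n); cf <- rep_len(cf_vaf, n)
  wb >= sum_vaf | cf >= sum_vaf | (wb > 0 & cf > 0 & wb + cf >= sum_vaf)
}

#' Hematopoietic versus non-hematopoietic origin of a cfDNA variant
#'
#' A cfDNA variant is attributed a non-hematopoietic (tumor-shed) origin if
#' its cfDNA VAF is at least `fold` times (default 5) the WB VAF. When the
#' variant is undetected in WB, the WB VAF is substituted by the 0.1%
#' detection floor rather than zero, which avoids division by zero and is
#' conservative towards a hematopoietic call.
#'
#' @param wb_vaf,cf_vaf Observed VAF fractions (0 = undetected).
#' @param fold Fold-change threshold (default 5, inclusive).
#' @param floor Detection floor substituted for undetected WB (default
#'   0.001).
#' @return Character vector, `"non_hematopoietic"` or `"hematopoietic"`.
#' @export
classify_origin <- function(wb_vaf, cf_vaf, fold = 5, floor = 0.001) {
  n <- max(length(wb_vaf), length(cf_vaf))
  wb <- rep_len(wb_vaf, n); cf <- rep_len(cf_vaf, n)
  ifelse(cf >= fold * pmax(wb, floor), "non_hematopoietic", "hematopoietic")
}

#' Serial-timepoint retention rule
#'
#' In the serial analysis a variant is retained if it is detected (VAF at
#' or above the 0.1% calling threshold) at two or more timepoints and
#' reaches VAF >= 0.8% at least once.
#'
#' @param vafs Numeric vector of per-timepoint VAFs for one variant in one
#'   DNA source (0 = undetected).
#' @param min_timepoints Minimum number of detected timepoints (default 2).
#' @param max_vaf_min Minimum of the maximum VAF across timepoints
#'   (fraction, default 0.008).
#' @param detection Calling threshold (fraction, default 0.001).
#' @return Logical scalar.
#' @export
retain_serial <- function(vafs, min_timepoints = 2, max_vaf_min = 0.008,
                          detection = 0.001) {
  detected <- vafs >= detection
  sum(detected) >= min_timepoints && max(vafs) >= max_vaf_min
}

#' Rescue sub-threshold timepoints of a retained variant
#'
#' For a variant retained by [retain_serial()] but undetected at some
#' timepoint, the raw pileup is reviewed: if any alternate consensus reads
#' support the variant beneath the calling threshold, the VAF is set to the
#' 0.1% detection threshold. Timepoints with zero supporting reads also get
#' the 0.1% floor (so that fitness math has a finite endpoint) but are
#' flagged `censored`.
#'
#' @param trajectory data.frame with per-timepoint columns `vaf` and
#'   `alt_reads` for one variant; rows are timepoints.
#' @param detection Detection threshold (fraction, default 0.001).
#' @return The data.frame with `vaf` updated and logical columns `rescued`
#'   (evidence present beneath threshold) and `censored` (no evidence; VAF
#'   is a floor, not a measurement).
#' @export
rescue_below_threshold <- function(trajectory, detection = 0.001) {
  stopifnot(all(c("vaf", "alt_reads") %in% names(trajectory)))
  undet <- trajectory$vaf < detection
  trajectory$rescued <- undet & trajectory$alt_reads > 0
  trajectory$censored <- undet & trajectory$alt_reads == 0
  trajectory$vaf[undet] <- detection
  trajectory
}

#' Categorise tumor-mutation VAF dynamics
#'
#' Tumor-derived cfDNA mutations are categorised by the VAF change between
#' two timepoints: `increasing` if the VAF rose by at least a factor of
#' `fold` (default 10), `decreasing` if it fell by at least that factor,
#' `stable` otherwise. Both boundaries are inclusive. Inputs are expected
#' to be floored at the detection limit.
#'
#' @param v_start,v_end VAF fractions at the two timepoints (vectors).
#' @param fold Fold-change threshold (default 10).
#' @return Character vector in `c("increasing", "decreasing", "stable")`.
#' @export
classify_tumor_dynamics <- function(v_start, v_end, fold = 10) {
  n <- max(length(v_start), length(v_end))
  v0 <- rep_len(v_start, n); v1 <- rep_len(v_end, n)
  stopifnot(all(v0 > 0))
  ifelse(v1 >= fold * v0, "increasing",
         ifelse(v1 <= v0 / fold, "decreasing", "stable"))
}

#' Merge paired WB and cfDNA calls into an attributed trajectory table
#'
#' Table-level driver for the paired analysis: merges per-timepoint WB and
#' cfDNA observations of each variant, applies the paired inclusion rule,
#' attributes origin at the earliest timepoint with any detection, applies
#' per-source serial retention (union across sources) and the
#' detection-limit rescue.
#'
#' @param observations Long-format data.frame with columns `patient_id`,
#'   `variant_id`, `gene`, `source` (`"WB"`/`"cfDNA"`), `timepoint_years`,
#'   `vaf`, `alt_reads`. Missing (variant, timepoint, source) combinations
#'   are treated as undetected with zero supporting reads.
#' @param sum_vaf,fold,floor,min_timepoints See the rule functions.
#' @return Long-format data.frame: one row per variant x timepoint x source
#'   with `vaf` (rescued), `origin`, `included`, `retained`, `rescued`,
#'   `censored`.
#' @export
attribute_cfdna <- function(observations, sum_vaf = 0.008, fold = 5,
                            floor = 0.001, min_timepoints = 2) {
  need <- c("patient_id", "variant_id", "source", "timepoint_years", "vaf", "alt_reads")
  stopifnot(all(need %in% names(observations)))
  obs <- observations
  key <- interaction(obs$patient_id, obs$variant_id, drop = TRUE)
  out <- lapply(split(obs, key), function(v) {
    tps <- sort(unique(v$timepoint_years))
    # complete grid: undetected combinations get vaf 0, no reads
    grid <- expand.grid(timepoint_years = tps, source = c("WB", "cfDNA"),
                        stringsAsFactors = FALSE)
    grid$patient_id <- v$patient_id[1]
    grid$variant_id <- v$variant_id[1]
    if (!is.null(v$gene)) grid$gene <- v$gene[1]
    m <- match(paste(grid$timepoint_years, grid$source),
               paste(v$timepoint_years, v$source))
    grid$vaf <- ifelse(is.na(m), 0, v$vaf[m])
    grid$alt_reads <- ifelse(is.na(m), 0L, v$alt_reads[m])

    wb <- grid[grid$source == "WB", ]
    cf <- grid[grid$source == "cfDNA", ]
    grid$included <- any(include_paired(wb$vaf, cf$vaf, sum_vaf))
    first_det <- which(wb$vaf > 0 | cf$vaf > 0)[1]
    grid$origin <- if (is.na(first_det)) NA_character_ else
      classify_origin(wb$vaf[first_det], cf$vaf[first_det], fold, floor)
    grid$retained <- (grid$source == "WB" &
                        retain_serial(wb$vaf, min_timepoints, sum_vaf, floor)) |
                     (grid$source == "cfDNA" &
                        retain_serial(cf$vaf, min_timepoints, sum_vaf, floor))
    # union across sources: a variant surviving in either source keeps both
    grid$retained <- any(grid$retained)
    if (grid$retained[1]) {
      for (src in c("WB", "cfDNA")) {
        sel <- grid$source == src
        grid[sel, c("vaf", "alt_reads", "rescued", "censored")] <-
          rescue_below_threshold(grid[sel, c("vaf", "alt_reads")], floor)
      }
    } else {
      grid$rescued <- FALSE
      grid$censored <- FALSE
    }
    grid
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$patient_id, out$variant_id, out$source, out$timepoint_years), ]
}
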