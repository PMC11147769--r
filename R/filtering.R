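#' Variant retention and classification cascade
#'
#' Post-processing of annotated error-corrected variant calls into
#' somatic-CH, germline, SNP-excluded and filtered categories. The cascade
#' is, per call:
#'
#' 1. retention: only protein-altering coding calls (nonsynonymous,
#'    stopgain, startloss, frameshift / truncating indel) and splice-site
#'    calls with at least 10 alternate consensus reads are retained; all
#'    other calls get `category = "filtered"`;
#' 2. germline: retained calls with VAF > 45% are classified `germline`;
#' 3. SNP exclusion: retained calls with VAF > 40% that are flagged as a
#'    dbSNP polymorphism or have gnomAD population allele frequency > 1%
#'    are classified `snp_excluded`, unless they hit a recurrent CH
#'    hotspot (see [is_hotspot()]);
#' 4. everything else is `somatic`.
#'
#' Thresholds are strict (`> 0.45`, `> 0.40`) where quoted as such and
#' inclusive where quoted as a minimum (`>= 10` reads). Classification
#' depends only on the call's own fields, so it is order-independent.
#'
#' @name variant-classification
NULL

# effects counted as protein-altering for retention; "nonsynonymous coding"
# is read broadly (any coding change of the protein), splice kept separately
.retained_effects <- c("nonsynonymous", "stopgain", "startloss",
                       "truncating_indel", "frameshift", "splice")

.deleterious_effects <- c("splice", "truncating_indel", "frameshift",
                          "stopgain", "startloss")

# recurrent CH hotspots retained even when SNP-flagged; codon-level entries
# (alt_aa NA) match any substitution at the codon
.hotspot_table <- data.frame(
  gene   = c("DNMT3A", "GNB1", "JAK2", "SF3B1", "SF3B1", "SRSF2", "U2AF1", "U2AF1"),
  codon  = c(882L, 57L, 617L, 666L, 700L, 95L, 34L, 157L),
  ref_aa = c(NA, "K", "V", NA, NA, NA, NA, NA),
  alt_aa = c(NA, "E", "F", NA, NA, NA, NA, NA)
)

.parse_protein_change <- function(protein_change) {
  # accepts "R882H", "p.R882H", "K700E", "P95_R102del" (first codon used)
  pc <- sub("^p\\.", "", as.character(protein_change))
  m <- regmatches(pc, regexec("^([A-Za-z\\*])(\\d+)([A-Za-z\\*]*)", pc))
  ref_aa <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, "")
  codon  <- vapply(m, function(x) if (length(x)) x[3] else NA_character_, "")
  alt_aa <- vapply(m, function(x) if (length(x)) x[4] else NA_character_, "")
  list(ref_aa = toupper(ref_aa),
       codon = suppressWarnings(as.integer(codon)),
       alt_aa = toupper(alt_aa))
}

#' Recurrent CH hotspot lookup
#'
#' TRUE for variants at highly recurrent CH driver sites: `DNMT3A` codon
#' R882 (any substitution), `GNB1` K57E, `JAK2` V617F, `SF3B1` codons K666
#' and K700, `SRSF2` codon P95, and `U2AF1` codons S34 and Q157. Codon-level
#' entries match any amino-acid substitution at that codon; `K57E` and
#' `V617F` require the exact change. Protein changes that cannot be parsed
#' are treated as non-hotspot with a warning.
#'
#' @param gene Character vector of gene symbols (legacy aliases accepted).
#' @param protein_change Character vector like `"R882H"` or `"p.V617F"`.
#' @return Logical vector.
#' @examples
#' is_hotspot("DNMT3A", "R882C")  # TRUE (codon rule)
#' is_hotspot("DNMT3A", "R883H")  # FALSE
#' @export
is_hotspot <- function(gene, protein_change) {
  n <- max(length(gene), length(protein_change))
  gene <- canonical_gene(rep_len(as.character(gene), n))
  protein_change <- rep_len(as.character(protein_change), n)
  p <- .parse_protein_change(protein_change)
  unparsed <- is.na(p$codon) & !is.na(protein_change) & nzchar(protein_change) &
    gene %in% .hotspot_table$gene
  if (any(unparsed)) {
    warning("unparseable protein change treated as non-hotspot: ",
            paste(unique(protein_change[unparsed]), collapse = ", "),
            call. = FALSE)
  }
  out <- logical(n)
  for (i in seq_len(nrow(.hotspot_table))) {
    h <- .hotspot_table[i, ]
    hit <- gene == h$gene & !is.na(p$codon) & p$codon == h$codon
    if (!is.na(h$alt_aa)) {
      hit <- hit & p$ref_aa == h$ref_aa & p$alt_aa == h$alt_aa
    }
    out <- out | (hit & !is.na(hit))
  }
  out
}

#' Apply the retention filter to raw variant calls
#'
#' Retains protein-altering coding and splice-site calls with at least
#' `min_alt_reads` alternate consensus reads.
#'
#' @param calls data.frame of variant calls with at least `effect` and
#'   `alt_reads` columns.
#' @param min_alt_reads Minimum alternate consensus-read count (default 10,
#'   inclusive).
#' @return Logical vector, TRUE for retained calls.
#' @export
apply_retention_filters <- function(calls, min_alt_reads = 10) {
  stopifnot(all(c("effect", "alt_reads") %in% names(calls)))
  calls$effect %in% .retained_effects & calls$alt_reads >= min_alt_reads
}

#' Classify annotated variant calls
#'
#' Runs the full retention and classification cascade (see
#' [variant-classification]) and annotates each call with its category,
#' hotspot status, gene class and the rule that fired.
#'
#' @param calls data.frame of annotated variant calls with columns `gene`,
#'   `protein_change`, `effect`, `vaf`, `alt_reads`, `dbsnp`, `gnomad_af`
#'   (NA where the variant is absent from gnomAD).
#' @param germline_vaf VAF above which a call is germline (strict; default
#'   0.45).
#' @param snp_vaf VAF above which dbSNP/gnomAD exclusion applies (strict;
#'   default 0.40).
#' @param snp_pop_af Population allele frequency above which a high-VAF
#'   call is SNP-excluded (strict; default 0.01).
#' @param min_alt_reads Passed to [apply_retention_filters()].
#' @param hr_genes,ch_genes Gene lists for [assign_gene_class()].
#' @return The input data.frame with added columns `category` (one of
#'   `filtered`, `germline`, `snp_excluded`, `somatic`), `hotspot`,
#'   `gene_class` and `filter_rule` (audit trail of the rule that fired).
#' @export
classify_variants <- function(calls,
                              germline_vaf = 0.45,
                              snp_vaf = 0.40,
                              snp_pop_af = 0.01,
                              min_alt_reads = 10,
                              hr_genes = default_gene_list("hr"),
                              ch_genes = default_gene_list("ch")) {
  need <- c("gene", "protein_change", "effect", "vaf", "alt_reads")
  stopifnot(all(need %in% names(calls)))
  if (is.null(calls$dbsnp)) calls$dbsnp <- FALSE
  if (is.null(calls$gnomad_af)) calls$gnomad_af <- NA_real_
  stopifnot(all(calls$vaf >= 0 & calls$vaf <= 1))

  calls$gene <- canonical_gene(calls$gene)
  calls$hotspot <- is_hotspot(calls$gene, calls$protein_change)
  calls$gene_class <- assign_gene_class(calls$gene, hr_genes, ch_genes)

  retained <- apply_retention_filters(calls, min_alt_reads)
  germline <- retained & calls$vaf > germline_vaf
  snp_flag <- (calls$dbsnp %in% TRUE) |
    (!is.na(calls$gnomad_af) & calls$gnomad_af > snp_pop_af)
  snp_excl <- retained & !germline & calls$vaf > snp_vaf & snp_flag & !calls$hotspot
  somatic <- retained & !germline & !snp_excl

  calls$category <- ifelse(!retained, "filtered",
                    ifelse(germline, "germline",
                    ifelse(snp_excl, "snp_excluded", "somatic")))
  calls$filter_rule <- ifelse(
    !retained,
    ifelse(calls$effect %in% .retained_effects,
           sprintf("alt_reads < %d", min_alt_reads), "effect_not_retained"),
    ifelse(germline, sprintf("vaf > %g", germline_vaf),
    ifelse(snp_excl, sprintf("vaf > %g & SNP-annotated", snp_vaf),
    ifelse(calls$hotspot & calls$vaf > snp_vaf & snp_flag,
           "hotspot_retained", "passed"))))
  calls
}

#' Per-patient CH status
#'
#' A patient is CH-positive if they carry at least one somatic mutation in
#' a typical CH gene with VAF at or above the threshold (default 1%,
#' inclusive). Also reports the largest qualifying clone and the number of
#' qualifying mutations per patient.
#'
#' @param variants Classified variant data.frame (see [classify_variants()])
#'   with a `patient_id` column.
#' @param ch_genes CH gene list (non-empty).
#' @param vaf_threshold CH calling threshold as a VAF fraction (default
#'   0.01).
#' @param patients Optional character vector of all patient ids, so that
#'   patients with no qualifying calls appear as CH-negative rows.
#' @return data.frame with columns `patient_id`, `ch_positive`, `max_vaf`,
#'   `n_mutations`.
#' @export
call_ch_status <- function(variants, ch_genes = default_gene_list("ch"),
                           vaf_threshold = 0.01, patients = NULL) {
  if (length(ch_genes) == 0) stop("ch_genes must be non-empty", call. = FALSE)
  stopifnot(all(c("patient_id", "gene", "category", "vaf") %in% names(variants)))
  ch_genes <- canonical_gene(ch_genes)
  qual <- variants$category == "somatic" &
    canonical_gene(variants$gene) %in% ch_genes &
    variants$vaf >= vaf_threshold
  ids <- unique(c(as.character(patients), as.character(variants$patient_id)))
  out <- data.frame(patient_id = ids, ch_positive = FALSE,
                    max_vaf = NA_real_, n_mutations = 0L)
  for (i in seq_along(ids)) {
    v <- qual & variants$patient_id == ids[i]
    out$n_mutations[i] <- sum(v)
    if (any(v)) {
      out$ch_positive[i] <- TRUE
      out$max_vaf[i] <- max(variants$vaf[v])
    }
  }
  out
}
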