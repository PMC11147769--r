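#' Germline homologous-recombination deficiency (HRD) calling
#'
#' Rule-based classification of pathogenic germline variants in BRCA1/2 and
#' the wider HR pathway from WB variant calls at germline-range VAF
#' (> 40%). For BRCA1/2 a call is pathogenic if any curated source
#' (ClinVar, ENIGMA, expert review) classes it pathogenic or likely
#' pathogenic, or if it is deleterious (splice site, truncating indel,
#' stopgain or startloss) with population allele frequency below 1%. For
#' the remaining HR genes only the deleterious-and-rare arm applies.
#' Missing population AF is treated as rare (< 1%) and flagged: absence
#' from gnomAD almost always means very rare. Pathogenicity lookups are
#' pre-annotated columns; no live database queries are made.
#'
#' @name germline-hrd
NULL

.pathogenic_classes <- c("pathogenic", "likely_pathogenic")

#' Classify germline calls in BRCA and HR-pathway genes
#'
#' @param calls data.frame of germline-range variant calls (VAF > 0.40)
#'   with columns `gene`, `effect`, `vaf`, `gnomad_af` and optional
#'   annotation columns `clinvar`, `enigma`, `expert` (values
#'   `"pathogenic"`, `"likely_pathogenic"`, anything else, or NA).
#' @param hr_genes HR-pathway gene list (default packaged list).
#' @param pop_af_max Population allele frequency bound (strict; default
#'   0.01).
#' @return The input with added columns `pathogenic` (logical), `basis`
#'   (first matching of `clinvar`, `enigma`, `expert`, `deleterious_rare`;
#'   NA if not pathogenic) and `af_missing` (AF absent, treated as rare).
#' @examples
#' calls <- data.frame(gene = "BRCA1", effect = "stopgain", vaf = 0.49,
#'                     gnomad_af = 1e-4)
#' classify_germline(calls)$pathogenic
#' @export
classify_germline <- function(calls, hr_genes = default_gene_list("hr"),
                              pop_af_max = 0.01) {
  stopifnot(all(c("gene", "effect", "vaf", "gnomad_af") %in% names(calls)))
  for (col in c("clinvar", "enigma", "expert")) {
    if (is.null(calls[[col]])) calls[[col]] <- rep(NA_character_, nrow(calls))
  }
  gene <- canonical_gene(calls$gene)
  brca <- gene %in% c("BRCA1", "BRCA2")
  in_hr <- gene %in% canonical_gene(hr_genes)

  calls$af_missing <- is.na(calls$gnomad_af)
  rare <- calls$af_missing | calls$gnomad_af < pop_af_max
  deleterious <- calls$effect %in% .deleterious_effects

  anno_basis <- rep(NA_character_, nrow(calls))
  for (col in c("clinvar", "enigma", "expert")) {
    hit <- is.na(anno_basis) & calls[[col]] %in% .pathogenic_classes
    anno_basis[hit] <- col
  }
  # annotation arm applies to BRCA1/2 only; deleterious+rare arm to all HR
  basis <- ifelse(brca & !is.na(anno_basis), anno_basis,
           ifelse((brca | in_hr) & deleterious & rare, "deleterious_rare",
                  NA_character_))
  calls$pathogenic <- !is.na(basis)
  calls$basis <- basis
  calls
}

#' Pathogenic germline BRCA classification (single-gene convenience)
#'
#' Restriction of [classify_germline()] to BRCA1/2 calls; calls in other
#' genes are routed through the HR-pathway rule.
#'
#' @inheritParams classify_germline
#' @return See [classify_germline()].
#' @export
classify_brca_germline <- function(calls, pop_af_max = 0.01) {
  classify_germline(calls, hr_genes = character(0), pop_af_max = pop_af_max)
}

#' Per-patient germline HRD status
#'
#' TRUE for patients with at least one pathogenic germline BRCA or
#' HR-pathway call.
#'
#' @param germline_calls Output of [classify_germline()] with a
#'   `patient_id` column.
#' @param patients Optional character vector of all patient ids, so that
#'   patients without calls appear as HRD-negative rows.
#' @return data.frame with columns `patient_id`, `germline_hrd`.
#' @export
patient_hrd_status <- function(germline_calls, patients = NULL) {
  ids <- unique(c(as.character(patients),
                  as.character(germline_calls$patient_id)))
  if (length(ids) == 0) {
    return(data.frame(patient_id = character(0), germline_hrd = logical(0)))
  }
  pos <- unique(germline_calls$patient_id[germline_calls$pathogenic %in% TRUE])
  data.frame(patient_id = ids, germline_hrd = ids %in% as.character(pos))
}
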