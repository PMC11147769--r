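#' Packaged gene lists
#'
#' Default gene lists used for classification: genes recurrently mutated in
#' clonal hematopoiesis (CH) and genes of the homologous-recombination (HR)
#' repair pathway. Both are plain one-symbol-per-line text files under
#' `inst/extdata/` and are meant to be replaced by panel-specific lists via
#' the `ch_genes` / `hr_genes` arguments of the classification functions.
#'
#' @param which `"ch"` or `"hr"`.
#' @return Character vector of gene symbols.
#' @examples
#' head(default_gene_list("ch"))
#' @export
default_gene_list <- function(which = c("ch", "hr")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_genes.txt"), package = "chdyn")
  out <- readLines(path)
  out[nzchar(out) & !startsWith(out, "#")]
}

# legacy gene symbols canonicalised on input (SFRS2 is the pre-HGNC name of
# the SRSF2 splicing factor)
.gene_aliases <- c(SFRS2 = "SRSF2", MRE11A = "MRE11")

#' Canonicalise gene symbols
#'
#' Maps legacy aliases (e.g. `SFRS2` -> `SRSF2`) to current HGNC symbols so
#' that hotspot and gene-class lookups are alias-proof.
#'
#' @param gene Character vector of gene symbols.
#' @return Character vector of canonical symbols.
#' @export
canonical_gene <- function(gene) {
  hit <- gene %in% names(.gene_aliases)
  gene[hit] <- .gene_aliases[gene[hit]]
  gene
}

#' Assign a gene to its CH gene class
#'
#' Classes follow the standard grouping of CH driver genes:
#' * `DTA` — the epigenetic regulators `DNMT3A`, `TET2`, `ASXL1` that
#'   dominate ageing-related CH;
#' * `DDR` — the DNA-damage-response genes `TP53`, `PPM1D`, `ATM`, `CHEK2`
#'   whose clones are preferentially selected under cytotoxic therapy;
#' * `HR` — homologous-recombination pathway genes (configurable list);
#' * `other_CH` — remaining genes on the CH panel;
#' * `other` — everything else.
#' DDR membership takes precedence over HR for genes on both lists
#' (`ATM`, `CHEK2`).
#'
#' @param gene Character vector of gene symbols.
#' @param hr_genes HR-pathway gene list (default packaged list).
#' @param ch_genes CH gene list (default packaged list).
#' @return Character vector of classes.
#' @export
assign_gene_class <- function(gene,
                              hr_genes = default_gene_list("hr"),
                              ch_genes = default_gene_list("ch")) {
  gene <- canonical_gene(gene)
  dta <- c("DNMT3A", "TET2", "ASXL1")
  ddr <- c("TP53", "PPM1D", "ATM", "CHEK2")
  out <- rep("other", length(gene))
  out[gene %in% canonical_gene(ch_genes)] <- "other_CH"
  out[gene %in% canonical_gene(hr_genes)] <- "HR"
  out[gene %in% ddr] <- "DDR"
  out[gene %in% dta] <- "DTA"
  out
}
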