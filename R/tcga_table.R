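#' Published TCGA expression of neurotrophin-signaling target genes
#'
#' Mean expression levels of neurotrophin-signaling pathway genes targeted by
#' the OSCC miRNA signature, measured in TCGA head-and-neck samples (134 OSCC
#' vs 30 controls), as published: per-gene tumor and non-tumor mean levels,
#' the printed fold change, and the FDR. Rows without published levels
#' ("No Change" calls) are not included. Useful as a worked example for
#' [fold_change()]: recomputing tumor/nontumor from the levels reproduces the
#' printed fold-change column.
#'
#' @return Data frame with columns `gene`, `fold_change_printed`,
#'   `tumor_level`, `nontumor_level`, `fdr`.
#' @export
#' @examples
#' tb <- tcga_neurotrophin_targets()
#' round(fold_change(tb$tumor_level, tb$nontumor_level), 2)
tcga_neurotrophin_targets <- function() {
  path <- system.file("extdata", "tcga_neurotrophin_expression.tsv",
                      package = "oscmir", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
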