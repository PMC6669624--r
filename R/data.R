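#' Published SNP table for the CpGV isolate panel
#'
#' The 67 alignment columns reported as unique to the South African CpGV
#' isolate (CpGV-SA) relative to the CpGV-E2, -I07, -I12, -M and -S genomes,
#' bundled as plain text. Each row gives the column's position in the CpGV-M
#' and CpGV-SA frames and the six isolates' symbols (including the IUPAC
#' ambiguity symbols carried by individual isolates at four columns).
#'
#' @return data.frame with columns `pos_m`, `pos_sa`, `sa`, `e2`, `i07`,
#'   `i12`, `m`, `s`.
#' @export
cpgv_unique_snp_table <- function() {
  utils::read.table(
    system.file("extdata", "cpgv_sa_unique_snps.tsv", package = "isovar"),
    header = TRUE, sep = "\t", colClasses = "character")
}

#' Published intra-isolate SNV table for CpGV-SA
#'
#' The 66 genotypic single-nucleotide variants reported within the CpGV-SA
#' isolate: position in the CpGV-SA genome frame, consensus base, variant
#' base and variant coverage. The tri-allelic site (position 51290) appears
#' as two rows.
#'
#' @return data.frame with columns `pos_sa`, `ref`, `alt`,
#'   `variant_coverage`.
#' @export
cpgv_snv_table <- function() {
  utils::read.table(
    system.file("extdata", "cpgv_sa_snvs.tsv", package = "isovar"),
    header = TRUE, sep = "\t",
    colClasses = c("integer", "character", "character", "integer"))
}
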