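#' Packaged yeast cell-length phenotype table
#'
#' In-vivo cell lengths at septation (micrometres) of eight fission-yeast
#' strains, each carrying one missense mutation in Cdk1 or cyclin B, plus
#' the wild type, measured at the permissive (25 degC) and semi-restrictive
#' (30 degC) temperatures over n = 30 septated cells per condition.
#'
#' @return data.frame with columns `strain_number`, `strain_name`,
#'   `protein`, `residue_change`, `mean_25c`, `stdev_25c`, `mean_30c`,
#'   `stdev_30c`, `n`.
#' @export
table2_cell_lengths <- function() {
  path <- system.file("extdata", "table2_cell_lengths.tsv", package = "sifr")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Packaged G2-M mutation table with ddG, coefficients and scores
#'
#' The eight Cdk1/CycB missense mutations of the yeast panel, with the
#' per-state free-energy changes (kcal/mol), the impact class, the printed
#' control coefficient applicable to each mutation's perturbation route
#' (column `C`) and the printed SIF score (column `sif`).  The `C` and
#' `sif` columns drive the pure-arithmetic table-C scoring path; the
#' model-C path recomputes coefficients from [g2m_model()] instead.
#'
#' @return data.frame with columns `protein`, `residue_change`,
#'   `impact_class`, `ddg_monomer`, `ddg_complex`, `C`, `sif`.
#' @export
table3_mutations <- function() {
  path <- system.file("extdata", "table3_mutations.tsv", package = "sifr")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "-", ""))
}
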