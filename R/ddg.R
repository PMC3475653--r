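#' A missense mutation with per-state free-energy changes
#'
#' Each mutation carries its one-letter residue change (e.g. `"G43E"`), an
#' impact class -- `"F"` for functional (at or near the active site) or
#' `"S"` for structural (elsewhere in the fold) -- and the free-energy
#' change, in kcal/mol, of the monomeric and/or complexed state of its host
#' protein.  An optional ensemble of ddG values over sampled conformations
#' supports Boltzmann-weighted averaging and an uncertainty estimate.
#'
#' @param protein host protein name.
#' @param residue_change string `<wt><position><mutant>`, 1-based.
#' @param impact_class `"F"` or `"S"`.
#' @param ddg_monomer,ddg_complex free-energy change (kcal/mol) of the
#'   uncomplexed / complexed state; at least one must be given.
#' @param ddg_ensemble optional numeric vector of per-conformation values.
#' @return object of class `mutation_record`.
#' @export
mutation_record <- function(protein, residue_change, impact_class,
                            ddg_monomer = NA_real_, ddg_complex = NA_real_,
                            ddg_ensemble = NULL) {
  if (!impact_class %in% c("F", "S")) {
    stop("impact_class must be 'F' (functional) or 'S' (structural)")
  }
  if (is.na(ddg_monomer) && is.na(ddg_complex)) {
    stop("at least one of ddg_monomer/ddg_complex must be present")
  }
  structure(
    list(protein = protein, residue_change = residue_change,
         impact_class = impact_class,
         ddg_monomer = ddg_monomer, ddg_complex = ddg_complex,
         ddg_ensemble = ddg_ensemble),
    class = "mutation_record"
  )
}

#' @export
print.mutation_record <- function(x, ...) {
  cat(sprintf("<mutation_record> %s %s (%s): ddG monomer %s, complex %s kcal/mol%s\n",
              x$protein, x$residue_change, x$impact_class,
              format(x$ddg_monomer), format(x$ddg_complex),
              if (length(x$ddg_ensemble)) sprintf(" (ensemble n = %d)", length(x$ddg_ensemble)) else ""))
  invisible(x)
}

#' Maximum ddG over the protein states of a mutation
#'
#' When both the complexed and uncomplexed states of the host protein are
#' modelled, the score uses the maximum of the two ddG values: averaging or
#' summing states has no clean biophysical meaning and would not be
#' comparable with proteins for which only one state is available.
#'
#' @param record a [mutation_record()].
#' @return scalar kcal/mol.
#' @export
max_ddg <- function(record) {
  stopifnot(inherits(record, "mutation_record"))
  vals <- c(record$ddg_monomer, record$ddg_complex)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("mutation has no ddG value in either state")
  max(vals)
}

## gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.987204259e-3

#' Boltzmann-weighted ensemble average of ddG values
#'
#' Conformations are weighted by `exp(-ddG_i / (R T))` (lower-energy
#' structures weigh more), with R in kcal/(mol K).  The average is therefore
#' never larger than the arithmetic mean and tends to it as T grows.
#'
#' @param ensemble numeric vector of per-conformation ddG values (kcal/mol).
#' @param temperature absolute temperature in kelvin (default 298, the
#'   temperature at which the underlying stability predictions are made).
#' @return scalar kcal/mol.
#' @export
boltzmann_average <- function(ensemble, temperature = 298) {
  if (length(ensemble) == 0L) stop("empty ensemble")
  stopifnot(is.numeric(ensemble), temperature > 0)
  ## shift for numerical stability; weights are shift-invariant
  e <- ensemble - min(ensemble)
  w <- exp(-e / (.R_KCAL * temperature))
  sum(w * ensemble) / sum(w)
}

#' Standard error of an ensemble ddG
#'
#' Reported as the unweighted standard deviation of the ensemble divided by
#' the square root of its size.  (The Boltzmann weights enter the mean, not
#' the dispersion estimate; a weighted variance would understate the
#' conformational spread that the error bar is meant to convey.)
#'
#' @param ensemble numeric vector of per-conformation ddG values.
#' @return scalar kcal/mol; zero with attribute `flag = "degenerate"` when
#'   fewer than two values are supplied.
#' @export
ddg_stderr <- function(ensemble) {
  if (length(ensemble) < 2L) {
    return(structure(0, flag = "degenerate"))
  }
  stats::sd(ensemble) / sqrt(length(ensemble))
}

#' Summarise the ddG information of a mutation
#'
#' @param record a [mutation_record()].
#' @param temperature kelvin, for the ensemble average.
#' @return list with `max_ddg`, `mean_ddg` (Boltzmann ensemble average, or
#'   `max_ddg` when no ensemble is attached) and `stderr`.
#' @export
ddg_summary <- function(record, temperature = 298) {
  m <- max_ddg(record)
  if (length(record$ddg_ensemble)) {
    list(max_ddg = m,
         mean_ddg = boltzmann_average(record$ddg_ensemble, temperature),
         stderr = as.numeric(ddg_stderr(record$ddg_ensemble)))
  } else {
    list(max_ddg = m, mean_ddg = m, stderr = NA_real_)
  }
}

#' Read / write mutation tables
#'
#' Tab-separated with header columns `protein`, `residue_change`,
#' `impact_class`, `ddg_monomer`, `ddg_complex`; empty fields or `-` mean
#' absent.  Additional columns are preserved.
#'
#' @param path TSV file path.
#' @return `read_mutation_table` returns a data.frame;
#'   `as_mutation_records` converts its rows to a list of
#'   [mutation_record()] objects.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "-", ""))
  required <- c("protein", "residue_change", "impact_class")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("mutation table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' @rdname read_mutation_table
#' @param table data.frame as returned by `read_mutation_table`.
#' @export
as_mutation_records <- function(table) {
  lapply(seq_len(nrow(table)), function(i) {
    mutation_record(
      protein = table$protein[i],
      residue_change = table$residue_change[i],
      impact_class = table$impact_class[i],
      ddg_monomer = if ("ddg_monomer" %in% names(table)) table$ddg_monomer[i] else NA_real_,
      ddg_complex = if ("ddg_complex" %in% names(table)) table$ddg_complex[i] else NA_real_
    )
  })
}

#' @rdname read_mutation_table
#' @export
write_mutation_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
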