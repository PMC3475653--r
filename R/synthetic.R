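#' Generate a synthetic MAPK mutation panel
#'
#' Draws a reproducible set of missense mutations spread over the four
#' cascade proteins, with impact classes and log-normal ddG values whose
#' bulk falls in the 0.5-10 kcal/mol range plus an occasional
#' steric-clash-scale outlier (> 20 kcal/mol, the signature of mutating
#' into a larger side chain inside a packed core).  Every protein is
#' represented whenever `n_mutations >= length(proteins)`.  The same seed
#' always yields the identical table.
#'
#' @param n_mutations number of mutations (default 40).
#' @param proteins proteins to spread the mutations over.
#' @param seed integer RNG seed.
#' @param ddg_meanlog,ddg_sdlog log-normal parameters of the bulk ddG draw
#'   (defaults centre the bulk near 3 kcal/mol).
#' @param clash_prob probability that a mutation is a clash-scale outlier.
#' @param prob_functional probability of class `"F"` versus `"S"`.
#' @return data.frame with columns `protein`, `residue_change`,
#'   `impact_class`, `ddg_monomer`, `ddg_complex`.
#' @export
generate_mutation_set <- function(n_mutations = 40L,
                                  proteins = c("H-Ras", "Raf-1", "B-Raf", "Mek"),
                                  seed = 1L,
                                  ddg_meanlog = log(3), ddg_sdlog = 0.8,
                                  clash_prob = 0.05, prob_functional = 0.5) {
  stopifnot(n_mutations >= 1L, length(proteins) >= 1L)
  set.seed(seed)
  n <- as.integer(n_mutations)
  prot <- if (n >= length(proteins)) {
    sample(c(proteins, sample(proteins, n - length(proteins), replace = TRUE)))
  } else {
    sample(proteins, n)
  }
  cls <- ifelse(stats::runif(n) < prob_functional, "F", "S")
  ddg <- stats::rlnorm(n, ddg_meanlog, ddg_sdlog)
  clash <- stats::runif(n) < clash_prob
  ddg[clash] <- stats::runif(sum(clash), 20, 35)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  wt <- sample(aa, n, replace = TRUE)
  mut <- vapply(wt, function(a) sample(setdiff(aa, a), 1L), character(1L))
  pos <- sample(10:450, n, replace = TRUE)
  data.frame(
    protein = prot,
    residue_change = paste0(wt, pos, mut),
    impact_class = cls,
    ddg_monomer = round(ddg, 2),
    ddg_complex = round(ddg * stats::runif(n, 0.8, 1.2), 2),
    stringsAsFactors = FALSE
  )
}

#' Generate a noisy reference time course from a model
#'
#' Integrates the model (optionally with parameter overrides), samples it
#' at the requested times and species, and adds i.i.d. Gaussian noise of
#' standard deviation `noise_sigma`, which is also recorded per point so
#' the chi-squared energy of the calibrator is correctly scaled.
#'
#' @param model an [ode_model()].
#' @param times sample times (within the model horizon).
#' @param species species to record (default: all).
#' @param noise_sigma noise standard deviation (0 gives exact model values;
#'   the recorded `sigma` is then 1 so chi-squared stays defined).
#' @param seed integer RNG seed.
#' @param params optional named parameter overrides (the "true" values the
#'   calibrator is meant to recover).
#' @return data.frame with columns `time`, `species`, `value`, `sigma`.
#' @export
generate_reference_timecourse <- function(model, times, species = NULL,
                                          noise_sigma = 0.05, seed = 1L,
                                          params = NULL) {
  stopifnot(inherits(model, "ode_model"), all(times > 0))
  if (is.null(species)) species <- model$species
  set.seed(seed)
  traj <- integrate_model(model, times = sort(unique(c(0, times))), params = params)
  idx <- match(times, traj$times)
  out <- do.call(rbind, lapply(species, function(sp) {
    clean <- traj$states[idx, sp]
    data.frame(time = times, species = sp,
               value = clean + stats::rnorm(length(clean), 0, noise_sigma),
               sigma = if (noise_sigma > 0) noise_sigma else 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
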