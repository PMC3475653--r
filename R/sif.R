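#' Map a mutation to the perturbation spec of its pathway model
#'
#' For the G2-M model the mapping follows the mutation-class rules of the
#' yeast analysis: functional Cdk1 mutations perturb the MPF--regulator
#' interaction constants (`J_combined`, 0.9/0.1 over the Wee1 and Cdc25
#' Michaelis constants of MPF), structural Cdk1 mutations perturb MPF
#' degradation only (`kd_Cdk1`; total Cdk1 is constant), and structural
#' CycB mutations perturb cyclin degradation 0.3/0.7 over the monomeric and
#' complexed pools (`kd_CycB`).
#'
#' For the MAPK model the mapping is read from a protein/class -> channel
#' table ([default_mapk_mapping()] ships a documented surrogate; supply your
#' own via `mapping` to override it).
#'
#' @param record a [mutation_record()].
#' @param model_key `"g2m"` or `"mapk_reduced"`.
#' @param mapping data.frame with columns `protein`, `impact_class`,
#'   `channels` (semicolon-separated), `weights` (semicolon-separated,
#'   summing to 1); only used for MAPK-type models.
#' @param delta total relative perturbation of the returned spec.
#' @return a [perturbation_spec()].
#' @export
map_mutation <- function(record, model_key = "g2m", mapping = NULL, delta = 0.1) {
  stopifnot(inherits(record, "mutation_record"))
  if (model_key == "g2m") {
    specs <- g2m_mutation_specs(delta = delta)
    key <- paste(record$protein, record$impact_class, sep = "/")
    spec <- switch(key,
      "Cdk1/F" = specs$J_combined,
      "Cdk1/S" = specs$kd_Cdk1,
      "CycB/S" = specs$kd_CycB,
      NULL
    )
    if (is.null(spec)) {
      stop("no G2-M mapping rule for (", key, "); known rules: Cdk1/F, Cdk1/S, CycB/S")
    }
    return(spec)
  }
  if (is.null(mapping)) mapping <- default_mapk_mapping()
  hit <- mapping[mapping$protein == record$protein &
                 mapping$impact_class == record$impact_class, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("mutation (", record$protein, ", ", record$impact_class,
         ") has no entry in the channel mapping table; add a row for it")
  }
  chs <- strsplit(hit$channels[1L], ";", fixed = TRUE)[[1L]]
  w <- as.numeric(strsplit(as.character(hit$weights[1L]), ";", fixed = TRUE)[[1L]])
  perturbation_spec(stats::setNames(w, chs), delta = delta,
                    label = paste0(record$protein, "/", record$impact_class))
}

#' Default protein-to-channel mapping for the MAPK model
#'
#' A synthetic surrogate mapping (the published per-mutation parameter
#' assignments are not redistributable here), built on the principle that a
#' protein's mutations perturb the rate terms of the reactions that protein
#' mediates: H-Ras functional mutations hit the Ras-Raf effector interface
#' (the RasGTP-mediated Raf interconversion terms), H-Ras structural
#' mutations the Ras nucleotide cycle, Raf mutations the Raf* kinase
#' activity towards Mek, and Mek mutations the Mek* kinase activity towards
#' Erk (functional) or their own activatability (structural).  Stored as an
#' editable TSV at `system.file("extdata", "mapk_channel_mapping.tsv",
#' package = "sifr")`.
#'
#' @return data.frame with columns `protein`, `impact_class`, `channels`,
#'   `weights`.
#' @export
default_mapk_mapping <- function() {
  path <- system.file("extdata", "mapk_channel_mapping.tsv", package = "sifr")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Combine ddG and control coefficient(s) into a SIF score
#'
#' The systemic impact factor of a mutation is the product of (a transform
#' of) its maximum ddG and the control coefficient of the pathway readout
#' with respect to the perturbation the mutation induces:
#' * `linear` (default): `SIF = max_ddg * C`;
#' * `lambda`: `SIF = lambda_class * max_ddg * C`, with a separate scale
#'   factor per impact class (both default to 1);
#' * `exponential` (provisional): `SIF = C * exp(max_ddg / (R T))`, with
#'   R T in kcal/mol at `temperature`.
#'
#' `coefficients` may be a single value (scalar G2-M readout) or a
#' `control_vector` (MAPK amplitude/duration/peak-time), in which case one
#' component is produced per metric.  When the record carries a ddG
#' ensemble, the ensemble's Boltzmann average replaces the point ddG and a
#' standard error `|C| * se(ddG)` is attached (linear/lambda transforms).
#'
#' @param record a [mutation_record()].
#' @param coefficients numeric scalar, `control_coefficient`, or
#'   `control_vector`.
#' @param transform `"linear"`, `"lambda"` or `"exponential"`.
#' @param lambda_f,lambda_s class-specific scale factors for the lambda
#'   transform.
#' @param temperature kelvin, for the exponential transform and ensemble
#'   averaging.
#' @return object of class `sif_score`: list with `mutation`, `components`
#'   (named numeric), `stderr` (or NULL), `transform`.
#' @export
sif_score <- function(record, coefficients, transform = c("linear", "lambda", "exponential"),
                      lambda_f = 1, lambda_s = 1, temperature = 298) {
  stopifnot(inherits(record, "mutation_record"))
  transform <- match.arg(transform)
  cvals <- if (inherits(coefficients, "control_vector")) {
    c(amplitude = coefficients$amplitude, duration = coefficients$duration,
      peak_time = coefficients$peak_time)
  } else if (inherits(coefficients, "control_coefficient")) {
    c(readout = coefficients$value)
  } else if (is.numeric(coefficients)) {
    if (is.null(names(coefficients))) names(coefficients) <- rep("readout", length(coefficients))
    coefficients
  } else {
    stop("`coefficients` must be numeric, a control_coefficient or a control_vector")
  }
  if (anyNA(cvals)) stop("missing control-coefficient component for ", record$residue_change)
  has_ens <- length(record$ddg_ensemble) > 0L
  ddg <- if (has_ens) boltzmann_average(record$ddg_ensemble, temperature) else max_ddg(record)
  lam <- if (record$impact_class == "F") lambda_f else lambda_s
  components <- switch(transform,
    linear = ddg * cvals,
    lambda = lam * ddg * cvals,
    exponential = cvals * exp(ddg / (.R_KCAL * temperature))
  )
  se <- NULL
  if (has_ens && transform %in% c("linear", "lambda")) {
    se <- abs(cvals) * as.numeric(ddg_stderr(record$ddg_ensemble)) *
      (if (transform == "lambda") lam else 1)
  }
  structure(
    list(mutation = record, components = components, stderr = se,
         transform = transform),
    class = "sif_score"
  )
}

#' @export
print.sif_score <- function(x, ...) {
  cat(sprintf("<sif_score> %s %s (%s, %s): %s\n",
              x$mutation$protein, x$mutation$residue_change,
              x$mutation$impact_class, x$transform,
              paste(sprintf("%s = %.4g", names(x$components), x$components),
                    collapse = ", ")))
  invisible(x)
}

#' Score a table of mutations against a pathway model
#'
#' Two scoring paths are exposed.  The *table-C* path (`use = "table_c"`)
#' multiplies each mutation's maximum ddG by the control coefficient given
#' in the table's `C` column -- pure arithmetic, independent of any ODE
#' reproduction.  The *model-C* path (`use = "model_c"`) maps each mutation
#' to its perturbation spec, computes the coefficient(s) from the model, and
#' scores against those.  Rows that fail to map are reported in the `error`
#' column and the batch continues.
#'
#' @param table data.frame as from [read_mutation_table()]; for the table-C
#'   path it must carry a numeric `C` column.
#' @param model_key `"g2m"` or `"mapk_reduced"`.
#' @param use `"table_c"` or `"model_c"`.
#' @param model optional pre-built model (for `model_c`).
#' @param mapping MAPK channel mapping table (see [map_mutation()]).
#' @param transform,lambda_f,lambda_s,temperature passed to [sif_score()].
#' @param delta total relative perturbation for model-derived coefficients.
#' @return data.frame, one row per input mutation (input order), with the
#'   spec label, coefficient(s), `max_ddg` and SIF component(s).
#' @export
batch_score <- function(table, model_key = "g2m", use = c("table_c", "model_c"),
                        model = NULL, mapping = NULL,
                        transform = "linear", lambda_f = 1, lambda_s = 1,
                        temperature = 298, delta = 0.1) {
  use <- match.arg(use)
  if (nrow(table) == 0L) {
    return(data.frame(protein = character(), residue_change = character(),
                      impact_class = character(), spec = character(),
                      max_ddg = numeric(), stringsAsFactors = FALSE))
  }
  records <- as_mutation_records(table)
  if (use == "model_c" && is.null(model)) model <- get_model(model_key)
  is_mapk <- model_key != "g2m"
  coef_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    base <- data.frame(protein = rec$protein, residue_change = rec$residue_change,
                       impact_class = rec$impact_class, stringsAsFactors = FALSE)
    res <- tryCatch({
      spec <- map_mutation(rec, model_key, mapping = mapping, delta = delta)
      if (use == "table_c") {
        if (!"C" %in% names(table)) stop("table-C scoring needs a numeric 'C' column")
        cc <- table$C[i]
        if (is.na(cc)) stop("printed C missing for ", rec$residue_change)
        sc <- sif_score(rec, c(readout = cc), transform = transform,
                        lambda_f = lambda_f, lambda_s = lambda_s,
                        temperature = temperature)
        cbind(base, spec = spec$label, C = cc, max_ddg = max_ddg(rec),
              sif = unname(sc$components[1L]), error = NA_character_,
              stringsAsFactors = FALSE)
      } else if (!is_mapk) {
        key <- spec$label
        if (is.null(coef_cache[[key]])) {
          coef_cache[[key]] <- control_coefficient(model, g2m_readout, spec)$value
        }
        cc <- coef_cache[[key]]
        sc <- sif_score(rec, c(readout = cc), transform = transform,
                        lambda_f = lambda_f, lambda_s = lambda_s,
                        temperature = temperature)
        cbind(base, spec = spec$label, C = cc, max_ddg = max_ddg(rec),
              sif = unname(sc$components[1L]), error = NA_character_,
              stringsAsFactors = FALSE)
      } else {
        key <- paste(spec$label, paste(names(spec$components), collapse = ","))
        if (is.null(coef_cache[[key]])) {
          coef_cache[[key]] <- mapk_control_vector(model, spec)
        }
        cv <- coef_cache[[key]]
        sc <- sif_score(rec, cv, transform = transform,
                        lambda_f = lambda_f, lambda_s = lambda_s,
                        temperature = temperature)
        cbind(base, spec = spec$label,
              C_amplitude = cv$amplitude, C_duration = cv$duration,
              C_peak_time = cv$peak_time, max_ddg = max_ddg(rec),
              sif_amplitude = unname(sc$components[["amplitude"]]),
              sif_duration = unname(sc$components[["duration"]]),
              sif_peak_time = unname(sc$components[["peak_time"]]),
              censored = cv$censored, error = NA_character_,
              stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      cbind(base, spec = NA_character_, max_ddg = NA_real_,
            error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}

#' Which curve metric dominates each protein's systemic impact?
#'
#' For three-component (MAPK) score tables, computes for every mutation the
#' share of each component in the total absolute SIF, averages the shares
#' per protein, and reports the component with the largest mean share.
#' Proteins whose mutations reshape the transient in time (duration / peak
#' time) separate from those that mainly rescale its amplitude.
#'
#' @param scores data.frame from [batch_score()] (model-C MAPK path), with
#'   columns `protein`, `sif_amplitude`, `sif_duration`, `sif_peak_time`.
#' @return data.frame, one row per protein: mean shares per component and
#'   `dominant` component name.
#' @export
sif_trajectory_grouping <- function(scores) {
  comp_cols <- c("sif_amplitude", "sif_duration", "sif_peak_time")
  if (!all(comp_cols %in% names(scores))) {
    stop("`scores` must have 3-component columns: ", paste(comp_cols, collapse = ", "))
  }
  scores <- scores[stats::complete.cases(scores[comp_cols]), , drop = FALSE]
  out <- lapply(split(scores, scores$protein), function(df) {
    absmat <- abs(as.matrix(df[comp_cols]))
    tot <- rowSums(absmat)
    tot[tot == 0] <- NA_real_
    shares <- colMeans(absmat / tot, na.rm = TRUE)
    data.frame(
      protein = df$protein[1L], n = nrow(df),
      share_amplitude = shares[["sif_amplitude"]],
      share_duration = shares[["sif_duration"]],
      share_peak_time = shares[["sif_peak_time"]],
      dominant = c("amplitude", "duration", "peak_time")[which.max(shares)],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
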