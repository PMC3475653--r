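#' Normalised control coefficient of a scalar readout
#'
#' The control coefficient of readout S with respect to a composite
#' perturbation spec is the relative response per unit relative
#' perturbation,
#' \deqn{C^S_{p} = \frac{(S' - S)/S}{\delta},}
#' where S is the readout of the unperturbed model and S' that of
#' [apply_perturbation()]`(model, spec)`.  A one-sided forward difference at
#' the spec's `delta` (default 0.1, i.e. a 10\% total relative perturbation)
#' is used; set `sides = 2` for a central difference at `delta/2` on either
#' side.  Positive values mean the readout increases when the perturbed
#' terms are scaled up.
#'
#' @param model an [ode_model()].
#' @param readout_fn function of one argument (a model) returning the scalar
#'   readout, e.g. `g2m_readout`.
#' @param spec a [perturbation_spec()]; its `delta` must be positive.
#' @param sides 1 (forward, default) or 2 (central).
#' @return object of class `control_coefficient`: list with `value`,
#'   `readout_wt`, `spec` and `label`.
#' @section Errors: a readout failure on the perturbed model (for example a
#'   missing threshold crossing) is re-signalled with the spec label
#'   attached.
#' @export
control_coefficient <- function(model, readout_fn, spec, sides = 1L) {
  stopifnot(inherits(model, "ode_model"), is.function(readout_fn),
            inherits(spec, "perturbation_spec"))
  if (spec$delta <= 0) stop("control coefficients require spec delta > 0")
  eval_pert <- function(s) {
    tryCatch(readout_fn(apply_perturbation(model, s)),
             error = function(e) {
               stop("readout failed under perturbation '", spec$label, "': ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  if (sides == 2L) {
    half_up <- spec; half_up$delta <- spec$delta / 2
    half_dn <- spec; half_dn$delta <- spec$delta / 2
    half_dn$components <- -half_dn$components
    class(half_dn) <- class(spec)  # sign flip is internal; weights still sum to 1 in spec
    s_wt <- readout_fn(model)
    value <- ((eval_pert(half_up) - eval_pert(half_dn)) / s_wt) / spec$delta
  } else {
    s_wt <- readout_fn(model)
    value <- ((eval_pert(spec) - s_wt) / s_wt) / spec$delta
  }
  structure(
    list(value = unname(value), readout_wt = unname(s_wt),
         spec = spec, label = spec$label),
    class = "control_coefficient"
  )
}

#' @export
print.control_coefficient <- function(x, ...) {
  cat(sprintf("<control_coefficient> %s: C = %.6g (wild-type readout %.6g)\n",
              x$label, x$value, x$readout_wt))
  invisible(x)
}

#' The composite perturbation specs of the G2-M mutation classes
#'
#' Three named specs, each spending a total relative perturbation
#' `delta` (default 0.1):
#' * `kd_CycB` -- cyclin degradation, split 0.3 on the monomeric-CycB
#'   degradation term and 0.7 on the MPF (complexed-CycB) degradation term;
#' * `kd_Cdk1` -- Cdk1 degradation, routed entirely through the MPF
#'   degradation term (total Cdk1 is constant, only the complex is lost);
#' * `J_combined` -- the MPF--regulator interaction, split 0.9 on the
#'   Michaelis constant of MPF for Wee1 (`J_iwee`) and 0.1 on that of MPF
#'   for Cdc25 (`J_a25`).  The mapping of the two interaction constants onto
#'   the four J's is configurable via `j_wee`/`j_25`.
#'
#' @param delta total relative perturbation.
#' @param j_wee,j_25 channel names of the two interaction Michaelis
#'   constants.
#' @return named list of three [perturbation_spec()] objects.
#' @export
g2m_mutation_specs <- function(delta = 0.1, j_wee = "J_iwee", j_25 = "J_a25") {
  list(
    kd_CycB = perturbation_spec(
      c(cycb_degradation = 0.3, mpf_degradation = 0.7),
      delta = delta, label = "kd_CycB"),
    kd_Cdk1 = perturbation_spec(
      c(mpf_degradation = 1.0),
      delta = delta, label = "kd_Cdk1"),
    J_combined = perturbation_spec(
      stats::setNames(c(0.9, 0.1), c(j_wee, j_25)),
      delta = delta, label = "J_combined")
  )
}

#' Three-component control vector of the MAPK reporter curve
#'
#' One normalised control coefficient per curve metric (amplitude, duration,
#' peak time) of the active-Erk reporter, each defined as the relative
#' change of the metric per unit relative perturbation.  A censored duration
#' on either the wild-type or the perturbed curve flags the duration
#' component instead of reporting a silently misleading number.
#'
#' @param model a MAPK-shaped [ode_model()].
#' @param spec a [perturbation_spec()].
#' @param reporter reporter species.
#' @param n_out output grid density used for the metrics.
#' @return object of class `control_vector`: list with `amplitude`,
#'   `duration`, `peak_time`, `censored`, `label`.
#' @export
mapk_control_vector <- function(model, spec, reporter = "Erk_a", n_out = 4001L) {
  stopifnot(inherits(model, "ode_model"), inherits(spec, "perturbation_spec"))
  if (spec$delta <= 0) stop("control vectors require spec delta > 0")
  m_wt <- curve_metrics(integrate_model(model, n_out = n_out), reporter)
  m_p <- curve_metrics(integrate_model(apply_perturbation(model, spec), n_out = n_out),
                       reporter)
  rel <- function(a, b) ((a - b) / b) / spec$delta
  structure(
    list(
      amplitude = rel(m_p$amplitude, m_wt$amplitude),
      duration = rel(m_p$duration, m_wt$duration),
      peak_time = rel(m_p$peak_time, m_wt$peak_time),
      censored = m_wt$censored || m_p$censored,
      label = spec$label
    ),
    class = "control_vector"
  )
}

#' @export
print.control_vector <- function(x, ...) {
  cat(sprintf("<control_vector> %s: amplitude %.4g, duration %.4g%s, peak time %.4g\n",
              x$label, x$amplitude, x$duration,
              if (x$censored) " (censored)" else "", x$peak_time))
  invisible(x)
}

#' Sweep control coefficients over channels and/or initial conditions
#'
#' Perturbs each target in turn by a relative `delta` and tabulates the
#' resulting coefficients.  For the G2-M model the readout is the scalar
#' CycB-at-mitotic-entry; for MAPK-shaped models the three curve metrics are
#' reported as separate rows.  Failures of individual targets (for example
#' a perturbation that abolishes the threshold crossing) are recorded in the
#' `error` column and the sweep continues.
#'
#' @param model an [ode_model()].
#' @param channels character vector of channel targets (default: all).
#' @param inits character vector of species whose *initial conditions* are
#'   perturbed as additional targets.
#' @param delta total relative perturbation per target.
#' @param readout `"g2m"` (scalar CycB readout) or `"mapk"` (curve metrics);
#'   chosen automatically from the model species when `NULL`.
#' @return data.frame with columns `target`, `type`, `readout`, `value`,
#'   `censored`, `error`; deterministic row order (targets in the order
#'   given, metrics alphabetical within target).
#' @export
sensitivity_sweep <- function(model, channels = names(model_channels(model)),
                              inits = character(), delta = 0.1, readout = NULL) {
  stopifnot(inherits(model, "ode_model"))
  if (is.null(readout)) {
    readout <- if (all(c("CycB", "MPF") %in% model$species)) "g2m" else "mapk"
  }
  rows <- list()
  add_row <- function(target, type, metric, value, censored = FALSE, error = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, type = type, readout = metric, value = value,
      censored = censored, error = error, stringsAsFactors = FALSE
    )
  }
  eval_target <- function(target, type, pert_model) {
    if (readout == "g2m") {
      s_wt <- g2m_readout(model)
      val <- tryCatch(((g2m_readout(pert_model) - s_wt) / s_wt) / delta,
                      error = function(e) e)
      if (inherits(val, "error")) {
        add_row(target, type, "cycb_at_entry", NA_real_, error = conditionMessage(val))
      } else {
        add_row(target, type, "cycb_at_entry", val)
      }
    } else {
      m_wt <- curve_metrics(integrate_model(model, n_out = 4001L))
      res <- tryCatch(curve_metrics(integrate_model(pert_model, n_out = 4001L)),
                      error = function(e) e)
      if (inherits(res, "error")) {
        for (m in c("amplitude", "duration", "peak_time")) {
          add_row(target, type, m, NA_real_, error = conditionMessage(res))
        }
      } else {
        cens <- m_wt$censored || res$censored
        add_row(target, type, "amplitude", ((res$amplitude - m_wt$amplitude) / m_wt$amplitude) / delta)
        add_row(target, type, "duration", ((res$duration - m_wt$duration) / m_wt$duration) / delta, censored = cens)
        add_row(target, type, "peak_time", ((res$peak_time - m_wt$peak_time) / m_wt$peak_time) / delta)
      }
    }
  }
  for (ch in channels) {
    if (!ch %in% names(model$channels)) {
      add_row(ch, "channel", if (readout == "g2m") "cycb_at_entry" else "amplitude",
              NA_real_, error = "unknown channel")
      next
    }
    eval_target(ch, "channel", set_channels(model, stats::setNames(1 + delta, ch)))
  }
  for (sp in inits) {
    if (!sp %in% model$species) {
      add_row(sp, "initial_condition",
              if (readout == "g2m") "cycb_at_entry" else "amplitude",
              NA_real_, error = "unknown species")
      next
    }
    m2 <- model
    m2$init[[sp]] <- m2$init[[sp]] * (1 + delta)
    eval_target(sp, "initial_condition", m2)
  }
  if (length(rows) == 0L) {
    return(data.frame(target = character(), type = character(),
                      readout = character(), value = numeric(),
                      censored = logical(), error = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
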