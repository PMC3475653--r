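#' Define a weighted composite perturbation
#'
#' A perturbation spec distributes a total relative perturbation `delta`
#' over one or more channels.  Applying it scales each channel multiplier by
#' `1 + weight * delta`, so a spec with a single weight-1 component and
#' `delta = 0.1` scales its term by 1.1, and a 0.3/0.7 split scales the two
#' terms by 1.03 and 1.07.  Weights must sum to one: the spec always spends
#' exactly `delta` of total relative perturbation, however it is divided.
#'
#' @param components named numeric vector: channel name -> weight.
#' @param delta total relative perturbation (default 0.1, i.e. 10\%).
#' @param label identifier carried through error messages and result tables.
#' @return an object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(components, delta = 0.1, label = NULL) {
  if (is.null(names(components)) || any(names(components) == "")) {
    stop("`components` must be a named vector (channel -> weight)")
  }
  if (abs(sum(components) - 1) > 1e-12) {
    stop("perturbation weights must sum to 1 (got ", sum(components), ")")
  }
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  if (is.null(label)) label <- paste(names(components), collapse = "+")
  structure(
    list(components = components, delta = delta, label = label),
    class = "perturbation_spec"
  )
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat("<perturbation_spec> ", x$label, " (delta = ", x$delta, ")\n", sep = "")
  for (i in seq_along(x$components)) {
    cat(sprintf("  %-28s weight %.3g\n", names(x$components)[i], x$components[i]))
  }
  invisible(x)
}

#' Apply a composite perturbation to a model
#'
#' Returns a copy of `model` whose channel multipliers are scaled by
#' `1 + weight_k * delta` for every component of the spec.  The input model
#' is never modified.  With `delta = 0` the copy is identical to the input.
#'
#' @param model an [ode_model()].
#' @param spec a [perturbation_spec()].
#' @return a perturbed `ode_model`.
#' @export
apply_perturbation <- function(model, spec) {
  stopifnot(inherits(model, "ode_model"), inherits(spec, "perturbation_spec"))
  unknown <- setdiff(names(spec$components), names(model$channels))
  if (length(unknown)) {
    stop("spec '", spec$label, "' references unknown channel(s): ",
         paste(unknown, collapse = ", "),
         "; valid channels are: ", paste(names(model$channels), collapse = ", "))
  }
  scale <- 1 + spec$components * spec$delta
  model$channels[names(scale)] <- model$channels[names(scale)] * scale
  model
}
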