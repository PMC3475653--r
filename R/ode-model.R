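#' Construct a small named ODE system with perturbation channels
#'
#' An `ode_model` bundles a right-hand-side function with named parameters,
#' initial conditions and a registry of *channels*: named multiplicative
#' factors attached to individual rate terms.  Channels are the perturbation
#' surface of the model -- a mutation or a sensitivity sweep scales one or
#' more channels away from their neutral value of 1, leaving the parameter
#' vector itself untouched.  Scaling at the term level (rather than on shared
#' parameter symbols) matters whenever one rate constant appears in several
#' terms that must be perturbed with different weights.
#'
#' @param name model identifier.
#' @param species character vector of state names, in equation order.
#' @param params named numeric vector of rate constants.
#' @param init named numeric vector of initial conditions; names must equal
#'   `species`.
#' @param horizon default integration end time, in the model's time unit.
#' @param rhs function `(t, state, params, channels)` returning the list of
#'   derivatives in `species` order, as expected by [deSolve::ode()].
#' @param channels character vector naming the model's channels.  All channel
#'   multipliers default to 1.
#' @param units optional list with entries `time` and `concentration`,
#'   recorded for documentation.
#'
#' @return an object of class `ode_model`.
#' @seealso [integrate_model()], [apply_perturbation()], [g2m_model()],
#'   [mapk_model()]
#' @export
ode_model <- function(name, species, params, init, horizon, rhs,
                      channels = character(), units = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.character(species), length(species) >= 1L)
  if (!all(species %in% names(init)) || length(init) != length(species)) {
    stop("`init` must name exactly the model species")
  }
  if (is.null(names(params)) || anyNA(names(params)) || any(names(params) == "")) {
    stop("`params` must be a fully named numeric vector")
  }
  if (anyDuplicated(channels)) {
    stop("channel names must be unique")
  }
  stopifnot(is.function(rhs), is.numeric(horizon), horizon > 0)
  model <- structure(
    list(
      name = name,
      species = species,
      params = params,
      init = init[species],
      horizon = horizon,
      rhs = rhs,
      channels = stats::setNames(rep(1, length(channels)), channels),
      units = units
    ),
    class = "ode_model"
  )
  ## smoke-evaluate the rhs so a mistranscribed symbol fails at construction
  d <- rhs(0, model$init, params, model$channels)
  if (!is.list(d) || length(d[[1L]]) != length(species)) {
    stop("`rhs` must return a list whose first element has one derivative per species")
  }
  model
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, "\n", sep = "")
  cat("  species : ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  params  : ", length(x$params), "  channels: ", length(x$channels),
      "  horizon: ", x$horizon, "\n", sep = "")
  off <- x$channels[x$channels != 1]
  if (length(off)) {
    cat("  perturbed channels: ",
        paste(sprintf("%s=%g", names(off), off), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Channel multipliers of a model
#'
#' @param model an [ode_model()].
#' @return named numeric vector of channel multipliers (1 = unperturbed).
#' @export
model_channels <- function(model) {
  stopifnot(inherits(model, "ode_model"))
  model$channels
}

#' Return a copy of a model with modified channel multipliers
#'
#' @param model an [ode_model()].
#' @param ... named channel = multiplier pairs, or a single named vector.
#' @return a new `ode_model`; the input is unmodified.
#' @export
set_channels <- function(model, ...) {
  stopifnot(inherits(model, "ode_model"))
  vals <- c(...)
  if (length(vals) == 0L) return(model)
  unknown <- setdiff(names(vals), names(model$channels))
  if (length(unknown)) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "),
         "; valid channels are: ", paste(names(model$channels), collapse = ", "))
  }
  model$channels[names(vals)] <- vals
  model
}

#' Integrate an ODE model into a trajectory
#'
#' Uses the stiff-capable adaptive integrator of \pkg{deSolve} (`lsoda`) with
#' tight default tolerances and a dense output grid so that threshold
#' crossings can be located accurately by interpolation.
#'
#' @param model an [ode_model()].
#' @param horizon integration end time; defaults to `model$horizon`.
#' @param n_out number of equally spaced output points (>= 2000 by default so
#'   event localisation on the grid is well conditioned).
#' @param times explicit output grid overriding `horizon`/`n_out`.
#' @param params named vector of parameter overrides.
#' @param channels named vector of channel-multiplier overrides.
#' @param init named vector of initial-condition overrides.
#' @param rtol,atol relative and absolute integration tolerances.
#'
#' @return a `trajectory`: list with `times` (strictly increasing numeric
#'   vector), `states` (matrix, one column per species) and `model_ref`.
#' @export
integrate_model <- function(model, horizon = NULL, n_out = 2001L, times = NULL,
                            params = NULL, channels = NULL, init = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"))
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(model$params))
    if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    model$params[names(params)] <- params
  }
  if (!is.null(channels)) model <- set_channels(model, channels)
  if (!is.null(init)) {
    unknown <- setdiff(names(init), model$species)
    if (length(unknown)) stop("unknown species in `init`: ", paste(unknown, collapse = ", "))
    model$init[names(init)] <- init
  }
  if (is.null(times)) {
    if (is.null(horizon)) horizon <- model$horizon
    stopifnot(horizon > 0)
    times <- seq(0, horizon, length.out = max(2L, as.integer(n_out)))
  }
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  out <- deSolve::ode(
    y = model$init, times = times,
    func = function(t, y, p) model$rhs(t, y, p, model$channels),
    parms = model$params, method = "lsoda", rtol = rtol, atol = atol
  )
  states <- unname(out[, model$species, drop = FALSE])
  colnames(states) <- model$species
  bad <- which(!is.finite(states), arr.ind = TRUE)
  if (nrow(out) < length(times) || nrow(bad)) {
    if (nrow(bad)) {
      i <- bad[which.min(bad[, 1L]), , drop = FALSE]
      stop(sprintf("integration of '%s' produced a non-finite value for species '%s' at t = %g",
                   model$name, model$species[i[1L, 2L]], out[i[1L, 1L], 1L]),
           call. = FALSE)
    }
    stop(sprintf("integration of '%s' stopped early at t = %g",
                 model$name, out[nrow(out), 1L]), call. = FALSE)
  }
  structure(
    list(times = out[, 1L], states = states, model_ref = model$name),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$model_ref, ": ", ncol(x$states), " species over t = [",
      min(x$times), ", ", max(x$times), "], ", length(x$times), " points\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Write / read a trajectory as CSV
#'
#' The CSV has a `time` column followed by one column per species.
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @return `read_trajectory_csv` returns a `trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param model_ref identifier recorded on the trajectory read back.
#' @export
read_trajectory_csv <- function(path, model_ref = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time") stop("first CSV column must be 'time'")
  structure(
    list(times = df$time,
         states = as.matrix(df[, -1L, drop = FALSE]),
         model_ref = model_ref),
    class = "trajectory"
  )
}

#' Locate the earliest upward threshold crossing of a species
#'
#' Scans the trajectory for the first grid interval on which the species
#' rises through `level` and places the crossing by linear interpolation;
#' all other species are interpolated at the same time.
#'
#' @param traj a `trajectory`.
#' @param species species name.
#' @param level threshold value.
#' @return a `threshold_event`: list with `species`, `level`, `time` and
#'   `state_at_crossing` (named vector over all species).
#' @section Errors: if the series never rises through `level`, an error of
#'   class `sifr_no_crossing` is signalled, distinguishable from integration
#'   failures (which abort inside [integrate_model()]).
#' @export
first_crossing <- function(traj, species, level) {
  stopifnot(inherits(traj, "trajectory"))
  if (!species %in% colnames(traj$states)) {
    stop("species '", species, "' not in trajectory", call. = FALSE)
  }
  y <- traj$states[, species]
  n <- length(y)
  idx <- which(y[-n] < level & y[-1L] >= level)
  if (length(idx) == 0L) {
    stop(structure(
      class = c("sifr_no_crossing", "error", "condition"),
      list(message = sprintf("'%s' never rises through %g within the horizon", species, level),
           call = sys.call())
    ))
  }
  i <- idx[1L]
  f <- (level - y[i]) / (y[i + 1L] - y[i])
  tc <- traj$times[i] + f * (traj$times[i + 1L] - traj$times[i])
  state <- traj$states[i, ] + f * (traj$states[i + 1L, ] - traj$states[i, ])
  state[species] <- level
  structure(
    list(species = species, level = level, time = tc, state_at_crossing = state),
    class = "threshold_event"
  )
}

#' @export
print.threshold_event <- function(x, ...) {
  cat("<threshold_event> ", x$species, " crosses ", x$level, " at t = ",
      format(x$time, digits = 8), "\n", sep = "")
  invisible(x)
}
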