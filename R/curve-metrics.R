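#' Reduce a reporter time course to amplitude, peak time and duration
#'
#' The three scalar readouts used to compare signalling transients:
#' *amplitude* is the global maximum of the reporter series, *peak time* the
#' earliest time attaining it, and *duration* the time (from t = 0) at which
#' the series first falls to 50\% of the amplitude after the peak.  The peak
#' is refined by quadratic interpolation through the bracketing grid points
#' and the half-maximum crossing by linear interpolation, so the metrics are
#' stable under re-gridding.  If the series never falls to half maximum
#' within the horizon the duration is reported as the horizon with
#' `censored = TRUE`.
#'
#' @param traj a `trajectory` from [integrate_model()].
#' @param reporter species name (default `"Erk_a"`, the active-Erk reporter
#'   of the MAPK model).
#' @return object of class `curve_metrics`: list with `amplitude`,
#'   `peak_time`, `duration`, `censored` and `reporter`.
#' @export
curve_metrics <- function(traj, reporter = "Erk_a") {
  stopifnot(inherits(traj, "trajectory"))
  if (!reporter %in% colnames(traj$states)) {
    stop("reporter '", reporter, "' not in trajectory")
  }
  y <- traj$states[, reporter]
  tv <- traj$times
  i <- which.max(y)
  amp <- y[i]
  pt <- tv[i]
  if (i > 1L && i < length(y)) {
    ## quadratic refinement of an interior maximum
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      d <- (y1 - y3) / (2 * denom)
      d <- max(-0.5, min(0.5, d))
      pt <- tv[i] + d * (tv[i + 1L] - tv[i])
      amp <- y2 - 0.25 * (y1 - y3) * d
    }
  }
  half <- amp / 2
  censored <- TRUE
  dur <- tv[length(tv)]
  after <- which(tv > pt)
  if (length(after)) {
    k <- after[which(y[after] <= half)[1L]]
    if (!is.na(k) && k > 1L) {
      f <- (half - y[k - 1L]) / (y[k] - y[k - 1L])
      if (!is.finite(f)) f <- 0
      dur <- tv[k - 1L] + f * (tv[k] - tv[k - 1L])
      censored <- FALSE
    }
  }
  structure(
    list(amplitude = unname(amp), peak_time = unname(pt),
         duration = unname(dur), censored = censored, reporter = reporter),
    class = "curve_metrics"
  )
}

#' @export
print.curve_metrics <- function(x, ...) {
  cat(sprintf("<curve_metrics> %s: amplitude %.6g, peak time %.6g, duration %.6g%s\n",
              x$reporter, x$amplitude, x$peak_time, x$duration,
              if (x$censored) " (censored)" else ""))
  invisible(x)
}

#' @rdname curve_metrics
#' @export
mapk_metrics <- function(traj, reporter = "Erk_a") curve_metrics(traj, reporter)

#' Per-metric deviation between two reporter curves
#'
#' Differences are `a - b` (conventionally mutant minus wild type) for each
#' of amplitude, duration and peak time.  A censored duration on either side
#' flags the duration difference.
#'
#' @param traj_a,traj_b trajectories sharing the reporter.
#' @param reporter species name.
#' @return list with `d_amplitude`, `d_duration`, `d_peak_time` and
#'   `censored` (logical: either duration censored).
#' @export
curve_deviation <- function(traj_a, traj_b, reporter = "Erk_a") {
  ma <- curve_metrics(traj_a, reporter)
  mb <- curve_metrics(traj_b, reporter)
  list(
    d_amplitude = ma$amplitude - mb$amplitude,
    d_duration = ma$duration - mb$duration,
    d_peak_time = ma$peak_time - mb$peak_time,
    censored = ma$censored || mb$censored
  )
}

#' CycB concentration at mitotic entry
#'
#' Integrates a G2-M-shaped model until active MPF first rises through
#' `level` (default 2.0, the mitotic-entry threshold) and returns the CycB
#' concentration at that instant.  The crossing is located by the
#' integrator's root finder, so the readout converges with the integration
#' tolerances rather than with the output grid.
#'
#' @param model an [ode_model()] with species `CycB` and `MPF`.
#' @param channels,params,init optional overrides, as in [integrate_model()].
#' @param level MPF threshold.
#' @param horizon search horizon (defaults to `model$horizon`).
#' @param rtol,atol integration tolerances.
#' @return the CycB value at the crossing (scalar).
#' @section Errors: signals `sifr_no_crossing` if MPF stays below `level`.
#' @export
g2m_readout <- function(model, channels = NULL, params = NULL, init = NULL,
                        level = 2.0, horizon = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"))
  if (!all(c("CycB", "MPF") %in% model$species)) {
    stop("`model` must contain CycB and MPF species")
  }
  ev <- threshold_crossing(model, species = "MPF", level = level,
                           channels = channels, params = params, init = init,
                           horizon = horizon, rtol = rtol, atol = atol)
  unname(ev$state_at_crossing[["CycB"]])
}

#' Root-located threshold crossing of a model species
#'
#' Lower-level engine behind [g2m_readout()]: integrates with a root
#' function on `species - level` and stops at the first upward crossing.
#'
#' @inheritParams g2m_readout
#' @param species species whose crossing is sought.
#' @return a `threshold_event`.
#' @export
threshold_crossing <- function(model, species, level, channels = NULL,
                               params = NULL, init = NULL, horizon = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"))
  if (!species %in% model$species) stop("unknown species '", species, "'")
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(model$params))
    if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    model$params[names(params)] <- params
  }
  if (!is.null(channels)) model <- set_channels(model, channels)
  if (!is.null(init)) model$init[names(init)] <- init
  if (is.null(horizon)) horizon <- model$horizon
  si <- match(species, model$species)
  below_start <- model$init[[si]] < level
  out <- deSolve::lsodar(
    y = model$init, times = c(0, horizon),
    func = function(t, y, p) model$rhs(t, y, p, model$channels),
    parms = model$params, rtol = rtol, atol = atol,
    rootfunc = function(t, y, p) y[si] - level
  )
  last <- out[nrow(out), ]
  crossed <- abs(last[[si + 1L]] - level) <= max(1e-6 * max(1, abs(level)), 10 * atol)
  if (!crossed || (!below_start && last[[1L]] == 0)) {
    stop(structure(
      class = c("sifr_no_crossing", "error", "condition"),
      list(message = sprintf("'%s' never rises through %g within horizon %g of model '%s'",
                             species, level, horizon, model$name),
           call = sys.call())
    ))
  }
  state <- last[-1L]
  names(state) <- model$species
  structure(
    list(species = species, level = level, time = unname(last[[1L]]),
         state_at_crossing = state),
    class = "threshold_event"
  )
}
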