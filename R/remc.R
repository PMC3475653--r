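#' Chi-squared deviation of a model from reference time courses
#'
#' The energy used by the replica-exchange sampler: the sum over reference
#' points of squared residuals between the observed values and the model
#' trajectory, scaled by the per-point noise standard deviation,
#' \deqn{E = \sum_i \left(\frac{y_i - \hat y(t_i)}{\sigma_i}\right)^2.}
#' An integration failure yields `Inf` (the move is simply rejected) rather
#' than an exception, so a sampler excursion into pathological parameter
#' space cannot abort a run.
#'
#' @param model an [ode_model()].
#' @param params named vector of parameter overrides to evaluate.
#' @param reference data.frame with columns `time`, `species`, `value`,
#'   `sigma`; times must lie within the model horizon.
#' @param rtol,atol integration tolerances (looser than the exploration
#'   default is fine for sampling).
#' @return non-negative scalar (possibly `Inf`).
#' @export
chisq_energy <- function(model, params = NULL, reference,
                         rtol = 1e-6, atol = 1e-8) {
  stopifnot(all(c("time", "species", "value", "sigma") %in% names(reference)))
  times <- sort(unique(c(0, reference$time)))
  traj <- tryCatch(
    suppressWarnings(
      integrate_model(model, times = times, params = params, rtol = rtol, atol = atol)
    ),
    error = function(e) NULL
  )
  if (is.null(traj)) return(Inf)
  idx_t <- match(reference$time, traj$times)
  idx_s <- match(reference$species, colnames(traj$states))
  if (anyNA(idx_t) || anyNA(idx_s)) {
    stop("reference rows outside the trajectory grid or species set")
  }
  pred <- traj$states[cbind(idx_t, idx_s)]
  sum(((reference$value - pred) / reference$sigma)^2)
}

#' Metropolis acceptance decision
#'
#' Accepts the proposed state with probability
#' `min(1, exp(-beta * (e_new - e_old)))`; downhill moves are always
#' accepted, and `beta -> Inf` degenerates to greedy descent.
#'
#' @param e_old,e_new energies of the current and proposed states.
#' @param beta inverse temperature (> 0).
#' @param u uniform deviate in \[0, 1\]; drawn from the session RNG when not
#'   supplied.
#' @return logical.
#' @export
metropolis_accept <- function(e_old, e_new, beta, u = stats::runif(1)) {
  stopifnot(beta > 0)
  if (!is.finite(e_new)) return(FALSE)
  if (e_new <= e_old) return(TRUE)
  u < exp(-beta * (e_new - e_old))
}

#' Replica-swap acceptance decision
#'
#' For adjacent replicas m and m+1, the configuration exchange is accepted
#' with probability `min(1, exp(d_beta * d_E))`, where
#' `d_beta = beta_{m+1} - beta_m` and `d_E = E_{m+1} - E_m`.  A low-energy
#' state held by the hotter replica therefore always migrates towards the
#' colder one.
#'
#' @param e_m,e_m1 energies of replicas m and m+1.
#' @param beta_m,beta_m1 their inverse temperatures.
#' @param u uniform deviate in \[0, 1\].
#' @return logical.
#' @export
swap_accept <- function(e_m, e_m1, beta_m, beta_m1, u = stats::runif(1)) {
  arg <- (beta_m1 - beta_m) * (e_m1 - e_m)
  if (!is.finite(arg)) arg <- if (is.nan(arg)) 0 else arg
  if (arg >= 0) return(TRUE)
  u < exp(arg)
}

#' Draw a logarithmically mixed step proposal
#'
#' `delta_x = s * d * 10^e` with `d` uniform on the integers 1..9, `e`
#' uniform on the integers `e_min..e_max`, and `s = +/-1` with equal
#' probability.  The resulting step-size distribution mixes scales: sharp
#' near zero, with long tails up to `9 * 10^e_max`, which lets the sampler
#' combine fine local moves with occasional large jumps.
#'
#' @param n number of proposals.
#' @param e_min,e_max integer exponent bounds of the smallest and largest
#'   step scale.
#' @return numeric vector of length `n`.
#' @export
propose_step <- function(n = 1L, e_min = -4L, e_max = -1L) {
  stopifnot(e_min <= e_max)
  d <- sample(1:9, n, replace = TRUE)
  e <- sample(seq.int(e_min, e_max), n, replace = TRUE)
  s <- sample(c(-1, 1), n, replace = TRUE)
  s * d * 10^e
}

#' Replica-exchange Monte Carlo calibration of model parameters
#'
#' Runs parallel Metropolis chains at the inverse temperatures `betas`
#' (ordered hot to cold, i.e. increasing), each perturbing one randomly
#' chosen free parameter per iteration by a [propose_step()] increment
#' (non-positive proposals are rejected outright), and attempts a
#' configuration swap between a randomly chosen adjacent pair every
#' `swap_interval` iterations.  All randomness flows from `seed`, so a
#' repeated call reproduces the run exactly.
#'
#' @param model an [ode_model()].
#' @param reference reference time courses (see [chisq_energy()]).
#' @param free_params named vector of starting values for the parameters
#'   being calibrated; all other parameters stay at the model values.
#' @param betas increasing vector of inverse temperatures, one per replica.
#' @param n_iter Metropolis iterations per replica.
#' @param swap_interval iterations between swap attempts.
#' @param e_min,e_max step-scale exponent bounds.
#' @param seed integer RNG seed.
#' @param rtol,atol integration tolerances for the energy evaluations.
#' @return list with `chains` (per replica, matrix of sampled parameter
#'   vectors, one row per iteration), `energies` (matrix, iterations x
#'   replicas), `best_params`, `best_energy`, `swap_attempts`,
#'   `swap_accepts` and `acceptance_rate` (per replica).
#' @export
run_remc <- function(model, reference, free_params, betas, n_iter,
                     swap_interval = 10L, e_min = -4L, e_max = -1L,
                     seed = 1L, rtol = 1e-6, atol = 1e-8) {
  stopifnot(length(betas) >= 1L, all(betas > 0), !is.unsorted(betas, strictly = TRUE))
  stopifnot(length(free_params) >= 1L, !is.null(names(free_params)))
  unknown <- setdiff(names(free_params), names(model$params))
  if (length(unknown)) stop("unknown free parameter(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  n_rep <- length(betas)
  n_par <- length(free_params)
  pars <- matrix(rep(free_params, n_rep), nrow = n_rep, byrow = TRUE,
                 dimnames = list(NULL, names(free_params)))
  energy_of <- function(p) chisq_energy(model, params = p, reference = reference,
                                        rtol = rtol, atol = atol)
  energies <- apply(pars, 1L, energy_of)
  if (all(!is.finite(energies))) {
    stop("all replicas fail to integrate at the starting parameters")
  }
  chains <- lapply(seq_len(n_rep), function(i) {
    matrix(NA_real_, nrow = n_iter, ncol = n_par,
           dimnames = list(NULL, names(free_params)))
  })
  energy_trace <- matrix(NA_real_, nrow = n_iter, ncol = n_rep)
  accepts <- integer(n_rep)
  swap_attempts <- 0L
  swap_accepts <- 0L
  best_energy <- min(energies)
  best_params <- pars[which.min(energies), , drop = TRUE]
  consecutive_failures <- 0L
  if (n_iter > 0L) for (it in seq_len(n_iter)) {
    for (m in seq_len(n_rep)) {
      j <- if (n_par == 1L) 1L else sample.int(n_par, 1L)
      step <- propose_step(1L, e_min, e_max)
      cand <- pars[m, ]
      cand[j] <- cand[j] + step
      if (cand[j] > 0) {
        e_new <- energy_of(cand)
        if (metropolis_accept(energies[m], e_new, betas[m])) {
          pars[m, ] <- cand
          energies[m] <- e_new
          accepts[m] <- accepts[m] + 1L
          if (e_new < best_energy) {
            best_energy <- e_new
            best_params <- cand
          }
        }
      }
      chains[[m]][it, ] <- pars[m, ]
    }
    energy_trace[it, ] <- energies
    if (all(!is.finite(energies))) {
      consecutive_failures <- consecutive_failures + 1L
      if (consecutive_failures >= 10L) {
        stop("all replicas stuck on non-finite energy for 10 consecutive iterations; ",
             "check the reference data and starting parameters")
      }
    } else {
      consecutive_failures <- 0L
    }
    if (n_rep > 1L && it %% swap_interval == 0L) {
      m <- if (n_rep == 2L) 1L else sample.int(n_rep - 1L, 1L)
      swap_attempts <- swap_attempts + 1L
      if (swap_accept(energies[m], energies[m + 1L], betas[m], betas[m + 1L])) {
        swap_accepts <- swap_accepts + 1L
        tmp <- pars[m, ]; pars[m, ] <- pars[m + 1L, ]; pars[m + 1L, ] <- tmp
        tmpE <- energies[m]; energies[m] <- energies[m + 1L]; energies[m + 1L] <- tmpE
      }
    }
  }
  list(
    chains = chains,
    energies = energy_trace,
    best_params = best_params,
    best_energy = best_energy,
    swap_attempts = swap_attempts,
    swap_accepts = swap_accepts,
    acceptance_rate = if (n_iter > 0L) accepts / n_iter else rep(0, n_rep),
    betas = betas,
    final_params = pars,
    final_energies = energies
  )
}
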