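test_that("integration is deterministic and dense enough for event work", {
  m <- g2m_model()
  t1 <- integrate_model(m)
  t2 <- integrate_model(m)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$times, t2$times)
  expect_gte(length(t1$times), 2000L)
  expect_true(!is.unsorted(t1$times, strictly = TRUE))
  expect_true(all(is.finite(t1$states)))
})

test_that("the G2-M system reaches mitotic entry (MPF exceeds 2)", {
  traj <- integrate_model(g2m_model())
  expect_gt(max(traj$states[, "MPF"]), 2.0)
})

test_that("zero synthesis from zero initial conditions stays at the zero fixed point", {
  # the MAPK model has no synthesis terms at all: the zero state is fixed
  mk <- mapk_model()
  zeros <- stats::setNames(rep(0, length(mk$species)), mk$species)
  traj <- integrate_model(mk, init = zeros, n_out = 201L)
  expect_true(all(abs(traj$states) < 1e-12))

  # in the G2-M model the cyclin pool is the only synthesised quantity:
  # with synthesis off and an empty pool, CycB and MPF never leave zero
  m <- g2m_model()
  tg <- integrate_model(m, channels = c(cycb_synthesis = 0),
                        init = c(CycB = 0, MPF = 0), n_out = 201L)
  expect_true(all(abs(tg$states[, c("CycB", "MPF")]) < 1e-10))
})

test_that("the MAPK reporter is a transient pulse: rises then decays to a low level", {
  traj <- integrate_model(mapk_model(), n_out = 4001L)
  erk <- traj$states[, "Erk_a"]
  peak <- max(erk)
  expect_gt(peak, 10 * erk[1L] + 1)          # rises well above the start
  expect_lt(erk[length(erk)], 0.05 * peak)   # and relaxes back down
})

test_that("integration blow-up fails loudly, naming the species", {
  explode <- ode_model(
    name = "explode", species = "x", params = c(a = 1), init = c(x = 1),
    horizon = 5,
    rhs = function(t, y, p, ch) list(p[["a"]] * y[[1L]]^2),
    channels = character()
  )
  expect_error(suppressWarnings(integrate_model(explode)), "x")
})

test_that("first_crossing interpolates linearly and flags missing crossings", {
  tt <- seq(0, 5, by = 0.5)
  lin <- make_trajectory(tt, s = tt)
  ev <- first_crossing(lin, "s", 2.0)
  expect_equal(ev$time, 2.0)
  expect_equal(unname(ev$state_at_crossing[["s"]]), 2.0)

  flat <- make_trajectory(tt, s = rep(1, length(tt)))
  expect_error(first_crossing(flat, "s", 2.0), class = "sifr_no_crossing")
  expect_error(first_crossing(lin, "nope", 1), "not in trajectory")
})

test_that("grid-based and root-located crossings agree on the G2-M model", {
  m <- g2m_model()
  dense <- integrate_model(m, n_out = 40001L)
  ev_grid <- first_crossing(dense, "MPF", 2.0)
  ev_root <- threshold_crossing(m, "MPF", 2.0)
  expect_equal(ev_grid$time, ev_root$time, tolerance = 1e-6)
  expect_equal(unname(ev_grid$state_at_crossing[["CycB"]]),
               unname(ev_root$state_at_crossing[["CycB"]]), tolerance = 1e-6)
})

test_that("apply_perturbation scales channels by 1 + weight * delta", {
  m <- g2m_model()

  null_spec <- perturbation_spec(c(mpf_degradation = 1), delta = 0)
  expect_identical(model_channels(apply_perturbation(m, null_spec)),
                   model_channels(m))

  single <- perturbation_spec(c(mpf_degradation = 1), delta = 0.1)
  expect_equal(model_channels(apply_perturbation(m, single))[["mpf_degradation"]], 1.1)

  pair <- perturbation_spec(c(cycb_degradation = 0.3, mpf_degradation = 0.7), delta = 0.1)
  ch <- model_channels(apply_perturbation(m, pair))
  expect_equal(ch[["cycb_degradation"]], 1.03)
  expect_equal(ch[["mpf_degradation"]], 1.07)
  expect_equal(unname(model_channels(m)), rep(1, length(model_channels(m))))

  expect_error(apply_perturbation(m, perturbation_spec(c(bogus = 1))), "valid channels")
})

test_that("perturbation followed by its inverse restores all multipliers", {
  m <- g2m_model()
  spec <- perturbation_spec(c(cycb_degradation = 0.3, mpf_degradation = 0.7), delta = 0.1)
  p <- apply_perturbation(m, spec)
  restored <- set_channels(p,
    cycb_degradation = p$channels[["cycb_degradation"]] / 1.03,
    mpf_degradation = p$channels[["mpf_degradation"]] / 1.07
  )
  expect_true(all(abs(model_channels(restored) - 1) < 1e-12))
})

test_that("perturbation specs validate their invariants", {
  expect_error(perturbation_spec(c(a = 0.3, b = 0.6)), "sum to 1")
  expect_error(perturbation_spec(c(0.5, 0.5)), "named")
  s <- perturbation_spec(c(a = 0.25, b = 0.75), delta = 0.2, label = "ab")
  expect_equal(sum(s$components), 1)
  expect_equal(s$label, "ab")
})

test_that("halving integrator tolerances leaves the G2-M readout stable", {
  m <- g2m_model()
  s1 <- g2m_readout(m, rtol = 1e-8, atol = 1e-10)
  s2 <- g2m_readout(m, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(s2 - s1) / s1, 1e-4)
})

test_that("trajectories round-trip through CSV", {
  traj <- integrate_model(g2m_model(), n_out = 101L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$times, traj$times)
  expect_equal(unname(back$states), unname(traj$states), tolerance = 1e-12)
  expect_identical(colnames(back$states), colnames(traj$states))
})
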