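test_that("a channel on a zero-rate term has zero control", {
  m <- linear_decay_model()
  cc <- control_coefficient(m, decay_readout,
                            perturbation_spec(c(dead_term = 1), delta = 0.1))
  expect_lt(abs(cc$value), 1e-8)
})

test_that("the decay-model coefficient matches its closed form", {
  # s(T) = exp(-k(1+d)T) so C(d) = (exp(-k T d) - 1)/d, and C -> -kT as d -> 0
  k <- 0.5; T <- 2
  m <- linear_decay_model(k = k, horizon = T)
  for (d in c(0.1, 0.05)) {
    cc <- control_coefficient(m, decay_readout,
                              perturbation_spec(c(decay = 1), delta = d))
    expect_equal(cc$value, (exp(-k * T * d) - 1) / d, tolerance = 1e-6)
  }
})

test_that("Richardson extrapolation of the coefficient recovers the analytic derivative", {
  k <- 0.5; T <- 2
  m <- linear_decay_model(k = k, horizon = T)
  C_at <- function(d) control_coefficient(
    m, decay_readout, perturbation_spec(c(decay = 1), delta = d))$value
  c1 <- C_at(0.02); c2 <- C_at(0.01)
  expect_equal(2 * c2 - c1, -k * T, tolerance = 1e-4)
  # halving delta roughly halves the first-order truncation error
  err1 <- abs(c1 - (-k * T)); err2 <- abs(c2 - (-k * T))
  expect_equal(err1 / err2, 2, tolerance = 0.1)
})

test_that("the three mutation specs carry the published weights", {
  specs <- g2m_mutation_specs()
  expect_equal(unname(specs$kd_CycB$components[c("cycb_degradation", "mpf_degradation")]),
               c(0.3, 0.7))
  expect_equal(unname(specs$kd_Cdk1$components[["mpf_degradation"]]), 1.0)
  expect_equal(unname(specs$J_combined$components[c("J_iwee", "J_a25")]),
               c(0.9, 0.1))
  for (s in specs) {
    expect_equal(sum(s$components), 1, tolerance = 1e-12)
    expect_equal(s$delta, 0.1)
  }
})

test_that("G2-M coefficients are frozen regression values", {
  m <- g2m_model()
  specs <- g2m_mutation_specs()
  vals <- vapply(specs, function(s) control_coefficient(m, g2m_readout, s)$value,
                 numeric(1))
  expect_equal(unname(vals), c(0.0029738, 0.0077776, 0.0116267), tolerance = 1e-3)
})

test_that("a composite coefficient is near the weighted sum of its parts at small delta", {
  m <- g2m_model()
  d <- 0.01
  C_of <- function(comp) control_coefficient(
    m, g2m_readout, perturbation_spec(comp, delta = d))$value
  c_cycb <- C_of(c(cycb_degradation = 1))
  c_mpf <- C_of(c(mpf_degradation = 1))
  c_comp <- C_of(c(cycb_degradation = 0.3, mpf_degradation = 0.7))
  expect_lt(abs(c_comp - (0.3 * c_cycb + 0.7 * c_mpf)), 0.1 * abs(c_comp))
})

test_that("faster Erk deactivation lowers the pulse amplitude", {
  cv <- mapk_control_vector(mapk_model(),
                            perturbation_spec(c(erk_deactivation = 1), delta = 0.1))
  expect_lt(cv$amplitude, 0)
  expect_false(cv$censored)
})

test_that("Ras-level and Mek-level perturbations give distinct control vectors", {
  m <- mapk_model()
  ras <- mapk_control_vector(m, perturbation_spec(c(ras_activation = 1), delta = 0.1))
  mek <- mapk_control_vector(m, perturbation_spec(c(mek_activation = 1), delta = 0.1))
  v_ras <- c(ras$amplitude, ras$duration, ras$peak_time)
  v_mek <- c(mek$amplitude, mek$duration, mek$peak_time)
  expect_gt(sqrt(sum((v_ras - v_mek)^2)), 0.1)
  # they even disagree on the sign of the peak-time response
  expect_false(identical(sign(v_ras), sign(v_mek)))
})

test_that("an empty target list yields an empty sweep table", {
  sw <- sensitivity_sweep(g2m_model(), channels = character())
  expect_s3_class(sw, "data.frame")
  expect_equal(nrow(sw), 0L)
})

test_that("per-target failures are recorded without aborting the sweep", {
  sw <- sensitivity_sweep(g2m_model(), channels = c("cycb_synthesis", "bogus"))
  expect_equal(nrow(sw), 2L)
  expect_true(is.na(sw$value[sw$target == "bogus"]))
  expect_match(sw$error[sw$target == "bogus"], "unknown")
  expect_true(is.finite(sw$value[sw$target == "cycb_synthesis"]))
})

test_that("Cdc25-side control dominates Wee1-side control in the G2-M sweep", {
  groups <- g2m_channel_groups()
  sw <- sensitivity_sweep(g2m_model(),
                          channels = c(groups$cdc25, groups$wee1))
  maxabs <- function(chs) max(abs(sw$value[sw$target %in% chs]), na.rm = TRUE)
  expect_gt(maxabs(groups$cdc25), maxabs(groups$wee1))
})

test_that("MAPK initial-condition sweep returns three finite coefficients per protein", {
  sw <- sensitivity_sweep(mapk_model(), channels = character(),
                          inits = c("ShcGS", "RasGDP", "Raf", "Mek", "Erk"))
  expect_equal(nrow(sw), 15L)
  expect_true(all(is.finite(sw$value)))
  expect_setequal(unique(sw$readout), c("amplitude", "duration", "peak_time"))
})

test_that("the Cdc25-Wee1 asymmetry persists across calibration-sampled parameter sets", {
  # sample k_d values consistent with a noisy wild-type time course, then
  # check the control asymmetry on each sampled model
  m <- g2m_model()
  ref <- generate_reference_timecourse(m, times = seq(2, 12, by = 2),
                                       species = c("CycB", "MPF"),
                                       noise_sigma = 0.05, seed = 31)
  fit <- run_remc(m, ref, free_params = c(k_d = 0.005), betas = c(0.5, 1),
                  n_iter = 300, seed = 13)
  cold <- fit$chains[[2L]]
  e_cold <- fit$energies[, 2L]
  good <- unique(cold[is.finite(e_cold) & e_cold <= min(e_cold) + 5, 1L])
  kds <- good[round(seq(1L, length(good), length.out = min(3L, length(good))))]
  expect_gte(length(kds), 1L)
  groups <- g2m_channel_groups()
  for (kd in kds) {
    m_kd <- m
    m_kd$params[["k_d"]] <- kd
    sw <- sensitivity_sweep(m_kd, channels = c(groups$cdc25, groups$wee1))
    maxabs <- function(chs) max(abs(sw$value[sw$target %in% chs]), na.rm = TRUE)
    expect_gt(maxabs(groups$cdc25), maxabs(groups$wee1))
  }
})
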