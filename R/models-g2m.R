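#' The fission-yeast G2-M transition model
#'
#' A four-variable reduction of the Novak-Tyson description of mitotic entry.
#' `CycB` is the total cyclin B pool (all cyclin is Cdk1-bound, with Cdk1 in
#' excess, so the pool equals active MPF plus Wee1-phosphorylated preMPF),
#' `MPF` the active fraction of that pool, and `Wee1`/`Cdc25` the active
#' fractions of the inhibitory kinase and activating phosphatase:
#'
#' \deqn{dCycB/dt = k_S - k_d CycB}
#' \deqn{dMPF/dt  = k_S - k_d MPF + V_{25}(CycB - MPF) - V_{wee} MPF}
#' \deqn{V_{25}  = k'_{25} + k''_{25} Cdc25,\quad V_{wee} = k'_{wee} + k''_{wee} Wee1}
#' \deqn{dWee1/dt  = k_{awee}(1-Wee1)/(J_{awee}+1-Wee1) - k_{iwee} MPF\, Wee1/(J_{iwee}+Wee1)}
#' \deqn{dCdc25/dt = k_{a25} MPF (1-Cdc25)/(J_{a25}+1-Cdc25) - k_{i25} Cdc25/(J_{i25}+Cdc25)}
#'
#' Newly synthesised cyclin enters as active MPF (unphosphorylated dimer);
#' Wee1 is inactivated by MPF and reactivated by an unmodelled phosphatase,
#' Cdc25 the converse.  `J_iwee`/`J_a25` are the Michaelis constants of MPF
#' acting on Wee1 and Cdc25, `J_awee`/`J_i25` those of the phosphatase.
#' All quantities are dimensionless.  Mitotic entry is read out as the CycB
#' concentration at the first upward crossing of active MPF through 2.0
#' (see [g2m_readout()]).
#'
#' Every additive rate term (and every Michaelis constant) carries its own
#' perturbation channel, so composite mutations can weight, say, the
#' monomeric-cyclin and complexed-cyclin degradation terms differently.
#' The basal (enzyme-independent) parts of \eqn{V_{25}} and \eqn{V_{wee}}
#' are separate channels from the Cdc25- and Wee1-proportional parts.
#'
#' @return an [ode_model()] with species CycB, MPF, Wee1, Cdc25.
#' @export
g2m_model <- function() {
  params <- c(
    k_S = 0.2, k_d = 0.008,
    k25p = 0.008, k25pp = 0.89, kweep = 0.03, kweepp = 0.18,
    k_awee = 0.61, k_iwee = 0.71, k_a25 = 0.80, k_i25 = 0.35,
    J_awee = 0.90, J_iwee = 0.21, J_a25 = 0.19, J_i25 = 0.93
  )
  init <- c(CycB = 0.01, MPF = 0.01, Wee1 = 1.0, Cdc25 = 0.01)
  channels <- c(
    "cycb_synthesis", "cycb_degradation", "mpf_degradation",
    "mpf_activation_basal", "mpf_activation_cdc25",
    "mpf_inactivation_basal", "mpf_inactivation_wee1",
    "wee1_activation", "wee1_inactivation",
    "cdc25_activation", "cdc25_inactivation",
    "J_awee", "J_iwee", "J_a25", "J_i25"
  )
  rhs <- function(t, y, p, ch) {
    CycB <- y[[1L]]; MPF <- y[[2L]]; Wee1 <- y[[3L]]; Cdc25 <- y[[4L]]
    V25  <- ch[["mpf_activation_basal"]]   * p[["k25p"]] +
            ch[["mpf_activation_cdc25"]]   * p[["k25pp"]] * Cdc25
    Vwee <- ch[["mpf_inactivation_basal"]] * p[["kweep"]] +
            ch[["mpf_inactivation_wee1"]]  * p[["kweepp"]] * Wee1
    syn  <- ch[["cycb_synthesis"]] * p[["k_S"]]
    dCycB <- syn - ch[["cycb_degradation"]] * p[["k_d"]] * CycB
    dMPF  <- syn - ch[["mpf_degradation"]] * p[["k_d"]] * MPF +
             V25 * (CycB - MPF) - Vwee * MPF
    dWee1 <- ch[["wee1_activation"]] * p[["k_awee"]] * (1 - Wee1) /
               (ch[["J_awee"]] * p[["J_awee"]] + 1 - Wee1) -
             ch[["wee1_inactivation"]] * p[["k_iwee"]] * MPF * Wee1 /
               (ch[["J_iwee"]] * p[["J_iwee"]] + Wee1)
    dCdc25 <- ch[["cdc25_activation"]] * p[["k_a25"]] * MPF * (1 - Cdc25) /
                (ch[["J_a25"]] * p[["J_a25"]] + 1 - Cdc25) -
              ch[["cdc25_inactivation"]] * p[["k_i25"]] * Cdc25 /
                (ch[["J_i25"]] * p[["J_i25"]] + Cdc25)
    list(c(dCycB, dMPF, dWee1, dCdc25))
  }
  ode_model(
    name = "g2m", species = names(init), params = params, init = init,
    horizon = 100, rhs = rhs, channels = channels,
    units = list(time = "dimensionless", concentration = "dimensionless")
  )
}

#' Channel groups of the G2-M model
#'
#' Channels grouped by the enzyme that catalyses the underlying reaction,
#' used by the Wee1/Cdc25 asymmetry analysis.  The basal (enzyme-free)
#' phosphorylation/dephosphorylation terms of MPF belong to neither group.
#'
#' @return named list of character vectors.
#' @export
g2m_channel_groups <- function() {
  list(
    cdc25 = c("mpf_activation_cdc25", "cdc25_activation", "cdc25_inactivation",
              "J_a25", "J_i25"),
    wee1 = c("mpf_inactivation_wee1", "wee1_activation", "wee1_inactivation",
             "J_awee", "J_iwee"),
    basal = c("mpf_activation_basal", "mpf_inactivation_basal"),
    turnover = c("cycb_synthesis", "cycb_degradation", "mpf_degradation")
  )
}
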