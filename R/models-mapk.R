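#' The reduced human MAPK cascade model
#'
#' A 9-species, 12-constant reduction of the Ras-Raf-Mek-Erk relay.  An
#' active Shc-Grb2-Sos complex (`ShcGS`) loads Ras with GTP; RasGTP drives
#' the interconversion of Raf between inactive and active forms; active Raf
#' phosphorylates Mek; active Mek phosphorylates Erk; active Erk feeds back
#' by inactivating ShcGS, which terminates the stimulus and produces the
#' characteristic transient pulse of Erk activation.  Concentrations are in
#' molecules per cell, time in minutes.
#'
#' Reaction fluxes (channel names in parentheses):
#' \deqn{v_1 = c_1 ShcGS\, RasGDP / (c_1/c_2 + RasGDP)} Ras activation
#'   (`ras_activation`); `c_1` is the turnover rate and `c_2` the
#'   low-substrate specificity constant, so the implied Michaelis constant
#'   is \eqn{c_1/c_2}.
#' \deqn{v_2 = c_3 RasGTP} Ras inactivation by GTP hydrolysis
#'   (`ras_inactivation`).
#' \deqn{v_3 = c_4 RasGTP\, Raf/(Raf + Raf^*)} RasGTP-mediated Raf
#'   activation (`raf_activation`); \deqn{v_4 = c_5 Raf^*} the reverse
#'   conversion (`raf_deactivation`).
#' \deqn{v_5 = c_6 Raf^* Mek/(Mek + Mek^*)} Mek activation by active Raf
#'   (`mek_activation`); \deqn{v_6 = c_7 Mek^*/(Mek + Mek^*)} Mek
#'   dephosphorylation by a saturated phosphatase with maximal velocity
#'   `c_7` (`mek_deactivation`).
#' \deqn{v_7 = c_8 f_{Mek} Erk/(c_9 + Erk)} Erk activation, with
#'   \eqn{f_{Mek} = Mek^*/(Mek + Mek^*)} the active-Mek fraction, maximal
#'   velocity `c_8` and Michaelis constant `c_9` (`erk_activation`, Michaelis
#'   channel `erk_activation_km`).
#' \deqn{v_8 = c_{10} c_{11} Erk^*/(c_{11} + Erk^*)} Erk dephosphorylation:
#'   first order with rate `c_10` below the phosphatase Michaelis constant
#'   `c_11`, zero order above it (`erk_deactivation`, `erk_deactivation_km`).
#' \deqn{v_9 = c_{12} Erk^* ShcGS} negative feedback (`feedback`).
#'
#' Activation/deactivation pairs only interconvert the active and inactive
#' forms, so Ras, Raf, Mek and Erk totals are conserved along trajectories;
#' ShcGS only decays (through the feedback) and is not replenished on the
#' time scale of one stimulus.
#'
#' @return an [ode_model()] with species ShcGS, RasGDP, RasGTP, Raf, Raf_a,
#'   Mek, Mek_a, Erk, Erk_a (`_a` marking active forms; the reporter used by
#'   the curve metrics is `Erk_a`).
#' @export
mapk_model <- function() {
  params <- c(
    c_1 = 69, c_2 = 7.7e-4, c_3 = 14, c_4 = 50, c_5 = 0.78,
    c_6 = 8.3, c_7 = 9e4, c_8 = 4e5, c_9 = 6e5, c_10 = 15,
    c_11 = 1.53e3, c_12 = 4e-6
  )
  init <- c(
    ShcGS = 20000, RasGDP = 20000, RasGTP = 0, Raf = 10000, Raf_a = 0,
    Mek = 360000, Mek_a = 0, Erk = 750000, Erk_a = 0
  )
  channels <- c(
    "ras_activation", "ras_activation_km", "ras_inactivation",
    "raf_activation", "raf_deactivation",
    "mek_activation", "mek_deactivation",
    "erk_activation", "erk_activation_km",
    "erk_deactivation", "erk_deactivation_km",
    "feedback"
  )
  rhs <- function(t, y, p, ch) {
    ShcGS <- y[[1L]]; RasGDP <- y[[2L]]; RasGTP <- y[[3L]]
    Raf <- y[[4L]]; Rafa <- y[[5L]]; Mek <- y[[6L]]; Meka <- y[[7L]]
    Erk <- y[[8L]]; Erka <- y[[9L]]
    raf_tot <- Raf + Rafa
    mek_tot <- Mek + Meka
    f_mek <- if (mek_tot > 0) Meka / mek_tot else 0
    km1 <- ch[["ras_activation"]] * p[["c_1"]] / (ch[["ras_activation_km"]] * p[["c_2"]])
    v1 <- ch[["ras_activation"]] * p[["c_1"]] * ShcGS * RasGDP / (km1 + RasGDP)
    v2 <- ch[["ras_inactivation"]] * p[["c_3"]] * RasGTP
    v3 <- if (raf_tot > 0) ch[["raf_activation"]] * p[["c_4"]] * RasGTP * Raf / raf_tot else 0
    v4 <- ch[["raf_deactivation"]] * p[["c_5"]] * Rafa
    v5 <- ch[["mek_activation"]] * p[["c_6"]] * Rafa *
      (if (mek_tot > 0) Mek / mek_tot else 0)
    v6 <- ch[["mek_deactivation"]] * p[["c_7"]] * f_mek
    v7 <- ch[["erk_activation"]] * p[["c_8"]] * f_mek * Erk /
      (ch[["erk_activation_km"]] * p[["c_9"]] + Erk)
    km11 <- ch[["erk_deactivation_km"]] * p[["c_11"]]
    v8 <- ch[["erk_deactivation"]] * p[["c_10"]] * km11 * Erka / (km11 + Erka)
    v9 <- ch[["feedback"]] * p[["c_12"]] * Erka * ShcGS
    list(c(
      -v9,            # ShcGS
      -v1 + v2,       # RasGDP
      v1 - v2,        # RasGTP
      -v3 + v4,       # Raf
      v3 - v4,        # Raf_a
      -v5 + v6,       # Mek
      v5 - v6,        # Mek_a
      -v7 + v8,       # Erk
      v7 - v8         # Erk_a
    ))
  }
  ode_model(
    name = "mapk_reduced", species = names(init), params = params, init = init,
    horizon = 100, rhs = rhs, channels = channels,
    units = list(time = "min", concentration = "molecules/cell")
  )
}

#' Catalogue of built-in models
#'
#' @return data.frame with columns `key`, `species`, `n_params` and
#'   `provenance`; keys are accepted by [get_model()].
#' @export
model_catalog <- function() {
  data.frame(
    key = c("g2m", "mapk_reduced"),
    species = c("CycB, MPF, Wee1, Cdc25",
                "ShcGS, RasGDP, RasGTP, Raf, Raf_a, Mek, Mek_a, Erk, Erk_a"),
    n_params = c(14L, 12L),
    provenance = c(
      "fission-yeast G2-M transition (Novak-Tyson-derived reduction)",
      "reduced human Ras-Raf-Mek-Erk cascade (Brightman-Fell-derived reduction)"
    ),
    stringsAsFactors = FALSE
  )
}

#' Fetch a built-in model by key
#'
#' @param key one of `model_catalog()$key`.
#' @return an [ode_model()].
#' @export
get_model <- function(key) {
  switch(key,
    g2m = g2m_model(),
    mapk_reduced = mapk_model(),
    stop("unknown model key '", key, "'; known keys: ",
         paste(model_catalog()$key, collapse = ", "))
  )
}

#' Load a MAPK-structured model variant from a YAML or JSON config
#'
#' The config must provide `params` (all twelve `c_1` ... `c_12`) and
#' `initial_conditions` (all nine species); `horizon` is optional.  This is
#' how alternative initial-concentration/parameter sets (for example, values
#' calibrated to experimental HeLa-cell measurements) are plugged into the
#' same cascade structure.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an [ode_model()] sharing the built-in cascade structure.
#' @export
load_model_variant <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- mapk_model()
  for (field in c("params", "initial_conditions")) {
    if (is.null(cfg[[field]])) stop("variant config is missing '", field, "'")
  }
  par <- unlist(cfg$params)
  ini <- unlist(cfg$initial_conditions)
  missing_par <- setdiff(names(base$params), names(par))
  if (length(missing_par)) {
    stop("variant config is missing parameter(s): ", paste(missing_par, collapse = ", "))
  }
  missing_ini <- setdiff(base$species, names(ini))
  if (length(missing_ini)) {
    stop("variant config is missing initial condition(s): ",
         paste(missing_ini, collapse = ", "))
  }
  base$params <- par[names(base$params)]
  base$init <- ini[base$species]
  if (!is.null(cfg$horizon)) base$horizon <- cfg$horizon
  if (!is.null(cfg$name)) base$name <- cfg$name
  base
}
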