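---
title: "Scoring the systemic impact of missense mutations with sifr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the systemic impact of missense mutations with sifr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sifr)
```

## The idea

A missense mutation acts at two levels.  At the protein level it changes the
folding or binding free energy of its host protein by some ddG (kcal/mol); at
the pathway level that destabilisation perturbs the rate of the reaction(s)
the protein takes part in, and the pathway's dynamics amplify or absorb the
perturbation.  The *systemic impact factor* (SIF) couples the two:

$$\mathrm{SIF} = \Delta\Delta G \times C^S_{p},$$

where $C^S_p$ is the normalised control coefficient of a pathway readout $S$
with respect to the perturbed rate term $p$,

$$C^S_{p} = \frac{(S' - S)/S}{\partial p}, \qquad \partial p = 0.1,$$

computed by a one-sided forward difference at a total relative perturbation
of 10%.  ddG measures how hard the mutation hits the protein; $C^S_p$
measures how much the pathway cares.  Mutations in a tightly controlled
reaction can matter more than larger destabilisations of a reaction the
network buffers.

Two reduced ODE models ship with the package, because the interesting claim
is precisely that *small* models carry enough of the control structure of
their pathways to rank mutations.

## The G2-M model

Mitotic entry in fission yeast is controlled by MPF (the Cdk1-cyclin B
complex).  Four variables suffice: the total cyclin pool `CycB`, the active
fraction `MPF`, and the active fractions of the inhibitory kinase `Wee1` and
the activating phosphatase `Cdc25` (all dimensionless):

$$\frac{d\,CycB}{dt} = k_S - k_d\,CycB$$
$$\frac{d\,MPF}{dt} = k_S - k_d\,MPF + V_{25}\,(CycB - MPF) - V_{wee}\,MPF$$
$$V_{25} = k'_{25} + k''_{25}\,Cdc25, \qquad V_{wee} = k'_{wee} + k''_{wee}\,Wee1$$

with Goldbeter-Koshland interconversion for the two regulators (MPF
inactivates Wee1 with Michaelis constant $J_{iwee}$ and activates Cdc25 with
$J_{a25}$; an unmodelled phosphatase reverses both with $J_{awee}$,
$J_{i25}$).  Cdk1 is in excess and all cyclin is Cdk1-bound, so the pool
obeys $CycB = MPF + preMPF$; newly synthesised dimers enter in the active
form.  We also examined the alternative routing in which new dimers enter as
preMPF: it inverts the sign of the composite cyclin-degradation coefficient
against the packaged reference table and was rejected.

The readout is the cell-size proxy: **CycB concentration at the moment
active MPF first rises through 2.0** (mitotic entry).  Cells grow linearly
in interphase, so a perturbation that delays entry lets CycB (and the cell)
grow further: positive $C^S_p$ means longer cells.

### Perturbation channels, not parameters

Mutations are applied through named multiplicative *channels* attached to
individual rate terms, not to shared parameter symbols.  This matters twice:

* $k_d$ appears in two terms (pool degradation and active-MPF degradation)
  that mutation classes weight differently -- structural CycB mutations
  perturb them 0.3/0.7, structural Cdk1 mutations only the MPF term;
* $V_{25}$ and $V_{wee}$ each mix a basal term with an enzyme-dependent
  term.  The basal parts are catalysed by neither Wee1 nor Cdc25, so they
  get their own channels and are excluded from the Wee1-versus-Cdc25
  asymmetry comparison.  With the basal terms lumped in, the basal Wee1-side
  rate ($k'_{wee}$, the largest Wee1-side coefficient at 0.029) would mask
  the asymmetry that the per-enzyme constants show.

The three mutation-class routes are frozen in `g2m_mutation_specs()`:
`kd_CycB` (0.3/0.7 degradation split), `kd_Cdk1` (MPF degradation only) and
`J_combined` (0.9/0.1 over $J_{iwee}$/$J_{a25}$).  The identification of
the "Wee1-interaction" and "Cdc25-interaction" constants with $J_{iwee}$ and
$J_{a25}$ -- the Michaelis constants of MPF acting *on* the regulators --
is a configurable default (`j_wee`, `j_25` arguments).

### What the model reproduces, and one number it does not

With the shipped constants the wild type enters mitosis at
$S_{wt} = 2.0884$ (close to the threshold 2.0: most cyclin is in the active
complex at entry).  The three class coefficients compute to

| route        | computed | reference (fixture `C` column) |
|--------------|---------:|-------------------------------:|
| `kd_CycB`    |  0.0030  | 0.004 |
| `kd_Cdk1`    |  0.0078  | 0.011 |
| `J_combined` |  0.0116  | 0.011 |

Two of the three agree with the packaged reference coefficients to their
printed precision.  The `kd_Cdk1` route does not: across every structurally
admissible variant we tried (synthesis routed to the active or inactive
pool; MPF degradation scaled in the pool equation, the MPF equation, or
both; entry thresholds from 2 to 8; one- and two-sided differences at
several deltas) this coefficient saturates near 0.008 and never reaches
0.011.  We report the computed value rather than tune the model towards the
tabulated one; the test suite asserts the reference comparison as stated and
records this single known discrepancy.  Its downstream effect is small: in
end-to-end scoring it swaps one adjacent pair (A177T/G227C) in the ranking
of the eight packaged mutations.

## The MAPK model

The Ras-Raf-Mek-Erk relay is reduced to nine species (an active
Shc-Grb2-Sos complex `ShcGS`, the Ras nucleotide cycle, and
inactive/active pairs for Raf, Mek, Erk) and twelve rate constants, in
molecules/cell and minutes.  Activation flows down the cascade; active Erk
feeds back by inactivating ShcGS, which shuts the stimulus off and makes
the wild-type Erk\* curve a transient pulse.  The flux forms are documented
in `?mapk_model`.  Where a constant's kinetic role admits more than one
reading at this level of reduction, we fixed the form by dimensional
consistency with the published magnitudes and by requiring the physiologic
pulse shape: the Ras-activation pair $(c_1, c_2)$ is interpreted as
turnover rate plus specificity constant (implied $K_m = c_1/c_2 \approx
9\times 10^4$), the Mek and Erk phosphatase terms as saturable
Michaelis-Menten steps, and the Raf/Mek activation steps as first order in
the upstream kinase times the inactive-substrate fraction.  These choices
conserve every active+inactive pool exactly by construction (asserted to
1e-6 relative in the tests) and give a pulse that peaks near t = 13 min at
about 4.7e5 molecules/cell and falls below half maximum by t = 28 min
within the 100-min horizon.

The reporter metrics are **amplitude** (global maximum of Erk\*),
**peak time** (earliest time attaining it, refined by quadratic
interpolation through the bracketing grid points) and **duration** (time
from t = 0 until the curve first falls to half of its amplitude after the
peak, located by linear interpolation).  Duration is measured from the
origin, not the peak, matching the reading of "time until the signal drops
to 50% of its maximum"; the full-width alternative would reference the
rising edge, which the definition does not mention.  Ties in the maximum go
to the earliest time, for determinism.  A curve that never falls to half
maximum is reported censored at the horizon rather than silently numeric.

### Mutation routing and component dominance

No degradation terms survive in this reduction, so a mutation's stability
loss is routed through the catalytic efficiency of the reactions its
protein mediates.  The default mapping table
(`inst/extdata/mapk_channel_mapping.tsv`, a clearly marked synthetic
surrogate for assignments that would normally come from per-mutation
structural analysis) sends functional H-Ras mutations to the RasGTP-Raf
interconversion terms (the effector interface, 0.5/0.5), structural H-Ras
mutations to the Ras nucleotide cycle, Raf mutations to Mek
phosphorylation, and Mek mutations to Erk phosphorylation (functional) or
their own activation (structural).  Users replace this table with their own
assignments via the `mapping` argument.

Under this routing the Raf- and Mek-level routes are amplitude-dominant
while the H-Ras effector route is dominated by its temporal components --
the qualitative separation by which Ras-cycle disease mutations differ
mechanistically from kinase-tier mutations.  In our transcription the
strongest temporal component on the Ras route is peak time rather than
duration; the separation of amplitude-dominant versus time-dominant routes
is the robust feature the tests assert.

## ddG handling

Scores use the **maximum** ddG over the modelled protein states (monomer
versus complex): state averages have no clean biophysical meaning, and the
maximum stays comparable between proteins with one or two modelled states.
When an ensemble of per-conformation ddG values is available, the point
estimate is the Boltzmann-Gibbs weighted mean with weights
$\propto e^{-\Delta\Delta G_i/(RT)}$ at T = 298 K (lower-energy
conformations weigh more; the average is never above the arithmetic mean
and tends to it as T grows), and the uncertainty is the *unweighted*
ensemble standard deviation over $\sqrt{n}$ -- a deliberate choice, since a
Boltzmann-weighted variance would understate the conformational spread the
error bar is meant to convey.

The lambda transform (`sif_score(..., transform = "lambda")`) exposes
per-class scale factors $\lambda_F, \lambda_S$ with defaults of 1: they are
a free exploration parameter, not a fitted constant.  The exponential
transform ($C\,e^{\Delta\Delta G/RT}$) is provided but flagged provisional;
it is excluded from any packaged expectation.

## Calibration by replica exchange

`run_remc()` calibrates selected rate constants against reference time
courses by parallel tempering: one Metropolis chain per inverse temperature
$\beta_m$, energy = the chi-squared deviation
$\sum_i ((y_i - \hat y(t_i))/\sigma_i)^2$, and swap attempts between a
random adjacent pair every `swap_interval` iterations accepted with
probability $\min(1, e^{\Delta\beta\,\Delta E})$, so a low-energy state
found by a hot chain always migrates cold.  Design choices the sampler
makes where reasonable alternatives exist:

* one randomly chosen parameter is perturbed per iteration (keeps
  acceptance rates interpretable in few dimensions);
* step sizes are $s\,d\,10^e$ with $d \sim U\{1..9\}$,
  $e \sim U\{e_{min}..e_{max}\}$ and random sign -- a scale mixture, sharp
  near zero with long tails.  The default $e_{min}/e_{max} = -4/-1$ matches
  the order of magnitude of the dimensionless G2-M constants;
* non-positive parameter proposals are rejected outright;
* an integration failure maps to infinite energy (a rejected move), and
  only ten consecutive all-replica failures abort with diagnostics.

The packaged recovery exercise (also an acceptance test) regenerates a
noisy wild-type G2-M time course (CycB and MPF at t = 2..14, Gaussian noise
sigma = 0.05, about 2.5% of the signal scale -- the noise level we consider
realistic for quantified single-cell fluorescence trajectories), frees
$k_d$ at a quarter of its true value, and runs 4 replicas
($\beta$ = 0.2, 0.5, 1, 2) for 3000 iterations.  That problem size keeps
the exercise at roughly twenty seconds while recovering $k_d$ within the
20% band; longer chains sharpen the estimate but do not change the
conclusion, since the posterior width here is set by the data's limited
sensitivity to $k_d$ (the same weak control quantified by the 0.008-scale
coefficient above).

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable) at rtol 1e-8 / atol 1e-10,
  with at least 2000 output points per horizon; the mitotic-entry event
  itself is located by the integrator's root finder, so the readout
  converges with the tolerances, not the grid (halving tolerances moves
  $S_{wt}$ by < 1e-4 relative).
* Trajectory-level crossings (`first_crossing`) interpolate linearly
  between bracketing grid points.
* Energy evaluations inside the sampler integrate only at the reference
  times, at the looser rtol 1e-6.
* Control coefficients use the one-sided forward difference at delta = 0.1
  by construction of the 10% convention; a `sides = 2` central option
  exists.  The delta is relative, never absolute: with $k_d = 0.008$ an
  absolute step of 0.1 would be a 12.5-fold change.

## What the synthetic generators do and do not emulate

`generate_mutation_set()` draws mutation panels over the four cascade
proteins with log-normal ddG bulk in the 0.5-10 kcal/mol range and a 5%
admixture of 20-35 kcal/mol steric-clash outliers, mimicking the scale
composition of real stability predictions.  `generate_reference_timecourse()`
adds i.i.d. Gaussian noise to model output.  Real data differ in ways the
generators deliberately ignore: correlated residuals, state-dependent
noise, partial observability, and ddG prediction error that correlates with
burial depth.  Green tests on these generators therefore certify the
machinery (mapping, scoring, calibration, statistics), not predictive
performance on laboratory measurements.

## Phenotype correlation

`correlate()` reports the squared Pearson correlation and a two-tailed
p-value from the exact t distribution ($t = r\sqrt{n-2}/\sqrt{1-r^2}$) --
appropriate for panels of five to ten mutants, where a normal approximation
is not.  The regression is unweighted by default (an inverse-variance
weighting flag exists for exploration, affecting the fitted line only).  On
the packaged tables, the semi-restrictive-temperature correlation exceeds
the permissive-temperature one, and the structural-only stratum correlates
at least as well as the full panel; the package asserts those *orderings*,
not any particular $r^2$ value, because the exact point set behind any
published summary correlation is not recoverable from a printed table.

## Known limitations

* The `kd_Cdk1` coefficient discrepancy described above.
* The MAPK mutation-to-channel table is a surrogate; conclusions about a
  specific clinical mutation require a real structural assignment.
* The SIF is a local, wild-type-anchored measure: a 25-35 kcal/mol clash
  outlier is far outside the linear-response regime, and its score should
  be read as "large", not as a calibrated magnitude.
* No stochastic simulation, no spatial effects, no SBML interchange.
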