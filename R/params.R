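#' Kinetic parameters of the radical-chain autoxidation mechanism
#'
#' Bundles the rate constants and initial concentrations that define an
#' (optionally inhibited) lipid autoxidation experiment:
#'
#' \itemize{
#'   \item initiation at constant rate \eqn{R_i} producing carbon radicals R•;
#'   \item R• + O2 -> ROO• (near diffusion controlled, \code{k_R_O2});
#'   \item propagation ROO• + RH -> ROOH + R• (\code{kp});
#'   \item self-termination 2 ROO• -> products (\code{kt});
#'   \item inhibition ROO• + AH -> ROOH + A• (\code{kinh});
#'   \item radical-radical trapping A• + ROO• -> ROOA (\code{k_ROO_A}).
#' }
#'
#' Substrate consumption is assumed negligible over the observation window, so
#' \code{RH0} acts as a constant; the antioxidant \code{AH0} is depleted.
#'
#' @param kp propagation rate constant, 1/(M s). Effective per-substrate-molecule
#'   value (per-H values times the number of abstractable positions).
#' @param kt termination rate constant for 2 ROO• self-reaction, 1/(M s).
#' @param Ri initiation rate, M/s. Constant throughout the run.
#' @param RH0 oxidizable substrate concentration, M.
#' @param AH0 chain-breaking antioxidant concentration, M (0 for uninhibited).
#' @param kinh inhibition rate constant, 1/(M s).
#' @param k_ROO_A rate constant for A• + ROO• coupling, 1/(M s).
#' @param k_R_O2 rate constant for R• + O2, 1/(M s).
#' @param n antioxidant stoichiometric factor (radicals trapped per AH);
#'   2 when A• quantitatively traps a second peroxyl radical.
#' @param a_sink_s1 optional first-order decay of A• (1/s) representing side
#'   reactions (dimerization, reaction with O2) that waste the radical; reduces
#'   the effective stoichiometric factor towards 1.
#' @param RH_imp0,kp_imp concentration (M) and propagation constant (1/(M s)) of
#'   a trace, highly oxidizable impurity; it is consumed during the run and is
#'   responsible for the initial oxidation burst of almost fully saturated oils.
#' @param temperature_C metadata only; the constants themselves must already
#'   refer to the working temperature.
#'
#' @return An object of class \code{kinetic_params} (a validated list).
#' @seealso [steady_rate()], [inhibited_rate()], [inhibition_duration()],
#'   [simulate_autoxidation()]
#' @examples
#' p <- kinetic_params(kp = 1, kt = 1e7, Ri = 1e-8, RH0 = 1)
#' steady_rate(p)
#' @export
kinetic_params <- function(kp = 1, kt = 1e7, Ri = 1e-8, RH0 = 1,
                           AH0 = 0, kinh = 1e4, k_ROO_A = 1e8,
                           k_R_O2 = 1e9, n = 2, a_sink_s1 = 0,
                           RH_imp0 = 0, kp_imp = 0,
                           temperature_C = 130) {
  p <- list(kp = kp, kt = kt, Ri = Ri, RH0 = RH0, AH0 = AH0,
            kinh = kinh, k_ROO_A = k_ROO_A, k_R_O2 = k_R_O2, n = n,
            a_sink_s1 = a_sink_s1, RH_imp0 = RH_imp0, kp_imp = kp_imp,
            temperature_C = temperature_C)
  num <- setdiff(names(p), "temperature_C")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("kinetic_params: '", f, "' must be a single finite number")
    if (v < 0)
      stop("kinetic_params: '", f, "' must be non-negative (got ", v, ")")
  }
  if (p$n <= 0) stop("kinetic_params: stoichiometric factor 'n' must be > 0")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Radical-chain autoxidation parameters (", x$temperature_C, " degC)\n",
      sep = "")
  cat(sprintf("  kp      = %.4g 1/(M s)   kt    = %.4g 1/(M s)\n", x$kp, x$kt))
  cat(sprintf("  Ri      = %.4g M/s      RH0   = %.4g M\n", x$Ri, x$RH0))
  if (x$AH0 > 0)
    cat(sprintf("  AH0     = %.4g M       kinh  = %.4g 1/(M s)   n = %g\n",
                x$AH0, x$kinh, x$n))
  if (x$RH_imp0 > 0)
    cat(sprintf("  impurity: RH_imp0 = %.4g M, kp_imp = %.4g 1/(M s)\n",
                x$RH_imp0, x$kp_imp))
  invisible(x)
}

#' Vessel and acquisition protocol for headspace oxygen-uptake runs
#'
#' Describes the isotherm measurement: a stirred diluted oil sample in a sealed
#' flask, a headspace optical O2 probe sampling every few seconds, re-aeration
#' once a set fraction of the O2 charge is consumed, and a dead time at the
#' start of each run during which readings are unreliable (thermal
#' equilibration and O2 diffusion into the condenser).
#'
#' @param liquid_volume_L liquid volume, L. Default 0.008 (1 mL oil + 7 mL
#'   diluent).
#' @param headspace_volume_L gas headspace volume, L.
#' @param initial_O2_fraction O2 mole fraction of the charge gas (air: 0.209).
#' @param pressure_atm total pressure, atm.
#' @param headspace_temperature_C headspace gas temperature used for the
#'   gas-amount conversion, degC (the condenser keeps the probe region near
#'   ambient, far below the bath temperature).
#' @param o2_solubility_M dissolved O2 concentration in the air-saturated
#'   liquid, M (typical air-saturated organic solvent: ~2 mM); sets the
#'   liquid-phase O2 scale for the R• + O2 step and the (small) dissolved
#'   contribution to the accessible O2 reservoir.
#' @param reaeration_threshold fraction of the O2 charge consumed that triggers
#'   re-aeration (the uptake rate visibly slows beyond ~75 % depletion).
#' @param o2_floor_fraction fraction of the initial O2 below which readings are
#'   discarded as O2-limited when joining segments. Defaults to
#'   \code{1 - reaeration_threshold}.
#' @param dead_time_s dead time excluded at the start of a run, s.
#' @param sampling_interval_s probe sampling interval, s.
#'
#' @return An object of class \code{vessel_protocol}.
#' @examples
#' vessel_protocol()
#' @export
vessel_protocol <- function(liquid_volume_L = 0.008,
                            headspace_volume_L = 0.015,
                            initial_O2_fraction = 0.209,
                            pressure_atm = 1,
                            headspace_temperature_C = 25,
                            o2_solubility_M = 0.002,
                            reaeration_threshold = 0.75,
                            o2_floor_fraction = 1 - reaeration_threshold,
                            dead_time_s = 1000,
                            sampling_interval_s = 10) {
  p <- list(liquid_volume_L = liquid_volume_L,
            headspace_volume_L = headspace_volume_L,
            initial_O2_fraction = initial_O2_fraction,
            pressure_atm = pressure_atm,
            headspace_temperature_C = headspace_temperature_C,
            o2_solubility_M = o2_solubility_M,
            reaeration_threshold = reaeration_threshold,
            o2_floor_fraction = o2_floor_fraction,
            dead_time_s = dead_time_s,
            sampling_interval_s = sampling_interval_s)
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("vessel_protocol: '", f, "' must be a single non-negative number")
  }
  if (p$liquid_volume_L <= 0 || p$headspace_volume_L <= 0)
    stop("vessel_protocol: volumes must be > 0")
  if (p$reaeration_threshold <= 0 || p$reaeration_threshold >= 1)
    stop("vessel_protocol: reaeration_threshold must be in (0, 1)")
  if (p$o2_floor_fraction >= 1)
    stop("vessel_protocol: o2_floor_fraction must be < 1")
  if (p$sampling_interval_s <= 0)
    stop("vessel_protocol: sampling_interval_s must be > 0")
  structure(p, class = "vessel_protocol")
}

#' @export
print.vessel_protocol <- function(x, ...) {
  cat("Headspace oxygen-uptake protocol\n")
  cat(sprintf("  liquid %.1f mL, headspace %.1f mL, %.3f atm O2 fraction %.3f\n",
              x$liquid_volume_L * 1e3, x$headspace_volume_L * 1e3,
              x$pressure_atm, x$initial_O2_fraction))
  cat(sprintf("  O2 charge: %.0f nmol; re-aerate at %.0f%% consumed; floor %.0f%%\n",
              o2_capacity_nmol(x), 100 * x$reaeration_threshold,
              100 * x$o2_floor_fraction))
  cat(sprintf("  sampling %g s, dead time %g s\n",
              x$sampling_interval_s, x$dead_time_s))
  invisible(x)
}

#' Total accessible O2 charge of the vessel
#'
#' Headspace gas O2 (ideal gas at the headspace temperature) plus dissolved O2,
#' in nanomoles. This is the reservoir depleted by the reaction; gas/liquid
#' transfer is treated as instantaneous (well-stirred, dilution chosen so that
#' transfer is not rate limiting).
#'
#' @param protocol a [vessel_protocol()].
#' @return O2 amount in nmol.
#' @export
o2_capacity_nmol <- function(protocol) {
  R_atm <- 0.082057  # L atm / (mol K)
  gas_mol <- protocol$pressure_atm * protocol$initial_O2_fraction *
    protocol$headspace_volume_L /
    (R_atm * (protocol$headspace_temperature_C + 273.15))
  diss_mol <- protocol$o2_solubility_M * protocol$liquid_volume_L
  (gas_mol + diss_mol) * 1e9
}

#' Closed-form steady oxygen-consumption rate
#'
#' Steady-state rate of O2 consumption of the uninhibited radical chain,
#' \deqn{R_{st} = \frac{k_p}{\sqrt{2 k_t}} [RH] \sqrt{R_i} + R_i,}
#' obtained by applying the steady-state approximation to all radical species
#' with constant initiation and negligible substrate consumption. Any
#' antioxidant in \code{params} is ignored (the steady regime is reached after
#' the antioxidant is spent).
#'
#' @param params a [kinetic_params()] object.
#' @return rate in M/s (liquid phase); convert with [vessel_rate_from_molar()].
#' @examples
#' steady_rate(kinetic_params(kp = 1, kt = 5e6, Ri = 1e-8, RH0 = 1))
#' @export
steady_rate <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$kp / sqrt(2 * params$kt) * params$RH0 * sqrt(params$Ri) + params$Ri
}

#' Closed-form inhibited oxygen-consumption rate
#'
#' Rate of O2 consumption at the beginning of the induction period, when
#' peroxyl radicals are removed only by the antioxidant (rate-limiting H-atom
#' transfer) and by the coupling of its radical:
#' \deqn{R_{in} = \frac{k_p [RH] R_i}{n\, k_{inh} [AH]} + R_i.}
#'
#' @param params a [kinetic_params()] with \code{AH0 > 0} and \code{kinh > 0}.
#' @return rate in M/s.
#' @examples
#' inhibited_rate(kinetic_params(Ri = 1e-8, AH0 = 2.36e-3))
#' @export
inhibited_rate <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$AH0 <= 0 || params$kinh <= 0)
    stop("inhibited_rate: requires AH0 > 0 and kinh > 0 ",
         "(no-antioxidant regime: use steady_rate())")
  params$kp * params$RH0 * params$Ri /
    (params$n * params$kinh * params$AH0) + params$Ri
}

#' Closed-form duration of the induction period
#'
#' The inhibition period ends when the antioxidant is spent; with each AH
#' molecule trapping \code{n} radicals delivered at constant rate \eqn{R_i},
#' \deqn{\tau = \frac{n [AH]}{R_i}.}
#'
#' @param params a [kinetic_params()] with \code{Ri > 0}.
#' @return duration in s (0 when \code{AH0 = 0}).
#' @examples
#' inhibition_duration(kinetic_params(Ri = 5e-8, AH0 = 2.36e-3, n = 2))
#' @export
inhibition_duration <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$Ri <= 0)
    stop("inhibition_duration: Ri must be > 0 (zero initiation gives an ",
         "unbounded inhibition period)")
  params$n * params$AH0 / params$Ri
}

#' Convert a liquid-phase molar rate to a whole-vessel rate
#'
#' Oxygen uptake happens in the liquid; the probe reports the depletion of the
#' whole accessible reservoir. A molar rate r (M/s) corresponds to
#' \code{r * liquid_volume_L * 1e9} nmol/s.
#'
#' @param rate_Ms rate in M/s (non-negative).
#' @param protocol a [vessel_protocol()].
#' @return rate in nmol/s.
#' @seealso [molar_rate_from_vessel()] for the inverse.
#' @export
vessel_rate_from_molar <- function(rate_Ms, protocol) {
  if (any(rate_Ms < 0)) stop("vessel_rate_from_molar: rate must be >= 0")
  rate_Ms * protocol$liquid_volume_L * 1e9
}

#' @rdname vessel_rate_from_molar
#' @param rate_nmol_s rate in nmol/s.
#' @export
molar_rate_from_vessel <- function(rate_nmol_s, protocol) {
  if (any(rate_nmol_s < 0)) stop("molar_rate_from_vessel: rate must be >= 0")
  rate_nmol_s / (protocol$liquid_volume_L * 1e9)
}

#' Reference propagation/termination rate constants (30 degC, per H)
#'
#' Literature per-hydrogen propagation rate constants for peroxyl-radical
#' H-abstraction from saturated, allylic and bis-allylic positions, and the
#' (nearly structure-independent) peroxyl self-termination constant, at 30
#' degC. Shipped for orientation when mapping a composition to effective
#' constants; the simulator always takes explicit constants and no temperature
#' extrapolation is attempted.
#'
#' @return data.frame with columns \code{position}, \code{kp_per_H_M_s} and the
#'   termination constant in \code{attr(, "kt_M_s")}.
#' @export
reference_rate_constants <- function() {
  out <- data.frame(
    position = c("saturated", "allylic", "bis-allylic"),
    kp_per_H_M_s = c(0.004, 0.22, 31),
    stringsAsFactors = FALSE
  )
  attr(out, "kt_M_s") <- 1e7
  attr(out, "temperature_C") <- 30
  out
}

#' Propyl gallate dose conversion
#'
#' The standard-addition protocol doses 500 mg/L propyl gallate (molar mass
#' 212.20 g/mol) into the diluted sample, i.e. 2.36e-3 M.
#'
#' @param mg_per_L dose in mg per litre of sample.
#' @return molar concentration.
#' @export
pg_molar_from_mg_L <- function(mg_per_L = 500) {
  mg_per_L / 1000 / 212.20
}
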