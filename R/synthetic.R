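# Seeded generators for oil panels and multi-segment O2 traces with the
# statistical structure the kinetic analyses assume, so every pipeline stage
# is testable without laboratory data. Generating truths are attached as
# sidecar attributes for recovery tests.

#' Bis-allylic methylene concentration from fatty-acid composition
#'
#' Counts one bis-allylic CH2 per di-unsaturated and two per tri-unsaturated
#' fatty-acid chain, and converts the per-chain count to a molar concentration
#' using the oil density and a mean fatty-acid molar mass. The neat basis
#' refers to the undiluted oil; the diluted basis applies the 1 mL in 8 mL
#' measurement dilution.
#'
#' @param DI_pct,TRI_pct percent of di- and tri-unsaturated fatty acids.
#' @param basis \code{"neat"} or \code{"diluted"}.
#' @param density_g_mL oil density (default 0.92).
#' @param mean_chain_mw mean fatty-acid molar mass, g/mol (default 280).
#' @param dilution_factor liquid dilution applied on the diluted basis.
#' @return molar concentration of bis-allylic CH2 groups.
#' @examples
#' compute_bis_allylic(DI_pct = 100, TRI_pct = 0)   # 3.29 M
#' compute_bis_allylic(DI_pct = 0, TRI_pct = 0)     # 0
#' @export
compute_bis_allylic <- function(DI_pct, TRI_pct, basis = c("neat", "diluted"),
                                density_g_mL = 0.92, mean_chain_mw = 280,
                                dilution_factor = 1 / 8) {
  basis <- match.arg(basis)
  if (any(DI_pct < 0 | DI_pct > 100) || any(TRI_pct < 0 | TRI_pct > 100))
    stop("compute_bis_allylic: percentages must be in [0, 100]")
  chains_M <- density_g_mL * 1000 / mean_chain_mw
  per_chain <- DI_pct / 100 * 1 + TRI_pct / 100 * 2
  out <- chains_M * per_chain
  if (basis == "diluted") out <- out * dilution_factor
  out
}

#' Configuration of the synthetic oil-panel generator
#'
#' The generator emulates a bench panel of bio-oil feedstocks: a fatty-acid
#' composition sampled on the SAT/MO/DI/TRI simplex, acid value and iron
#' content with a minority of heavily contaminated samples, an intrinsic
#' antioxidant pool, and kinetic descriptors derived from the package's own
#' rate laws — initiation proportional to the bis-allylic content
#' (\code{Ri = c_Ri * (ba_offset + [bis-allylic])}, amplified by iron), the
#' induction period from the inhibition-duration law, and the steady rate from
#' a composition regression. PG is modelled as ineffective in high-iron /
#' high-acid oils.
#'
#' @param n_oils number of oils.
#' @param seed RNG seed (mandatory: panels are reproducible artifacts).
#' @param comp_alpha Dirichlet concentration for (SAT, MO, DI, TRI) percents.
#' @param acidity_hi_prob,acidity_lo_range,acidity_hi_range acid value
#'   sampling: most oils are mildly acidic, a minority (used cooking oils,
#'   free fatty acids) very acidic, mg KOH/g.
#' @param iron_hi_prob,iron_lo_range,iron_hi_range iron content sampling, ppm.
#' @param nAH_range intrinsic antioxidant pool as n*[AH], M; a fraction
#'   \code{no_antiox_prob} of oils carries none (Type A).
#' @param no_antiox_prob probability of a Type A (antioxidant-free) oil.
#' @param c_Ri initiation proportionality constant, 1/s: \code{Ri = c_Ri *
#'   (ba_offset + [bis-allylic]) * iron_multiplier}. The default is the value
#'   implied by the packaged hyperbolic PG-effect model together with the
#'   inhibition-duration law at the standard PG dose and n = 2.
#' @param ba_offset baseline initiation expressed as an equivalent bis-allylic
#'   concentration, M.
#' @param iron_Ri_coeff per-ppm multiplicative enhancement of Ri by iron.
#' @param pg_molar,n_pg PG dose (M) and its stoichiometric factor, used to
#'   construct tau_PG.
#' @param flag_iron_ppm,flag_acidity exclusion thresholds marking oils where
#'   PG is taken to be ineffective.
#' @param rst_model composition model generating R_st (see [predict_rst()]).
#' @param noise_rel multiplicative noise applied to the measured descriptors.
#' @param osi_factor,osi_noise_rel OSI is generated as a scaled, noisy version
#'   of tau (the two methods rank stability similarly; OSI is longer).
#' @return object of class \code{panel_config}.
#' @export
panel_generator_config <- function(n_oils = 30L, seed,
                                   comp_alpha = c(SAT = 2, MO = 3, DI = 2.5,
                                                  TRI = 1),
                                   acidity_hi_prob = 0.2,
                                   acidity_lo_range = c(0, 10),
                                   acidity_hi_range = c(15, 200),
                                   iron_hi_prob = 0.2,
                                   iron_lo_range = c(0, 2),
                                   iron_hi_range = c(5, 50),
                                   nAH_range = c(0.002, 0.02),
                                   no_antiox_prob = 0.3,
                                   c_Ri = 2 * pg_molar_from_mg_L(500) / 3.0e4,
                                   ba_offset = 0.080,
                                   iron_Ri_coeff = 0.2,
                                   pg_molar = pg_molar_from_mg_L(500),
                                   n_pg = 2,
                                   flag_iron_ppm = 5,
                                   flag_acidity = 15,
                                   rst_model = "unsaturation_acidity",
                                   noise_rel = 0.05,
                                   osi_factor = 1.5,
                                   osi_noise_rel = 0.1) {
  if (missing(seed)) stop("panel_generator_config: an explicit seed is required")
  if (c_Ri <= 0)
    stop("panel_generator_config: c_Ri must be > 0 (zero initiation with ",
         "antioxidants present gives unbounded induction periods)")
  cfg <- as.list(environment())
  cfg$n_oils <- as.integer(n_oils)
  structure(cfg, class = "panel_config")
}

r_dirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              ncol = length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic oil panel
#'
#' Draws \code{n_oils} oil records (composition, acid value, iron, bis-allylic
#' concentration, induction periods with and without PG, initial/steady rates,
#' OSI, exclusion flags) according to a [panel_generator_config()]. The
#' generating ground truth — per-oil initiation rate and antioxidant pool and
#' the generating model coefficients — is attached as \code{attr(, "truth")}
#' so recovery tests can compare estimates against it.
#'
#' @param config a [panel_generator_config()].
#' @return data.frame of oil records (one row per oil) with a \code{truth}
#'   attribute.
#' @examples
#' panel <- generate_oil_panel(panel_generator_config(n_oils = 10, seed = 1))
#' head(panel)
#' @export
generate_oil_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  n <- config$n_oils

  comp <- r_dirichlet(n, config$comp_alpha) * 100
  colnames(comp) <- c("SAT_pct", "MO_pct", "DI_pct", "TRI_pct")

  runif_rng <- function(n, r) stats::runif(n, r[1], r[2])
  hi_a <- stats::runif(n) < config$acidity_hi_prob
  acidity <- ifelse(hi_a, runif_rng(n, config$acidity_hi_range),
                    runif_rng(n, config$acidity_lo_range))
  hi_fe <- stats::runif(n) < config$iron_hi_prob
  iron <- ifelse(hi_fe, runif_rng(n, config$iron_hi_range),
                 runif_rng(n, config$iron_lo_range))

  ba <- compute_bis_allylic(comp[, "DI_pct"], comp[, "TRI_pct"])
  iron_mult <- 1 + config$iron_Ri_coeff * iron
  Ri <- config$c_Ri * (config$ba_offset + ba) * iron_mult

  nAH <- ifelse(stats::runif(n) < config$no_antiox_prob, 0,
                runif_rng(n, config$nAH_range))
  tau <- nAH / Ri
  flagged <- iron > config$flag_iron_ppm | acidity > config$flag_acidity
  pg_ext <- config$n_pg * config$pg_molar / Ri
  # in flagged oils PG is destroyed by metal/acid chemistry before it can trap
  # radicals: the measured extension is indistinguishable from zero
  pg_ext[flagged] <- 0
  tau_PG <- tau + pg_ext

  mnoise <- function(x) x * (1 + stats::rnorm(n, sd = config$noise_rel))
  rst_true <- predict_rst(config$rst_model,
                          data.frame(MO_pct = comp[, "MO_pct"],
                                     DI_pct = comp[, "DI_pct"],
                                     TRI_pct = comp[, "TRI_pct"],
                                     acidity_mgKOH_g = acidity))
  rst <- pmax(mnoise(rst_true), 0.5)
  rin <- ifelse(nAH > 0, rst * stats::runif(n, 0.03, 0.15), rst)
  osi <- (tau / 3600) * config$osi_factor *
    (1 + stats::rnorm(n, sd = config$osi_noise_rel))

  panel <- data.frame(
    oil_id = sprintf("SYN%03d", seq_len(n)),
    as.data.frame(comp),
    bis_allylic_M = ba,
    acidity_mgKOH_g = acidity,
    iron_ppm = iron,
    peroxide_mEqO2_kg = stats::runif(n, 0, 23.5),
    tau_s = mnoise(tau),
    tau_PG_s = mnoise(tau_PG),
    R_in_nmol_s = rin,
    R_st_nmol_s = rst,
    OSI_h = osi,
    excluded_flag = flagged,
    stringsAsFactors = FALSE
  )
  panel$tau_PG_s <- pmax(panel$tau_PG_s, panel$tau_s)
  panel$tau_PG_s[flagged] <- panel$tau_s[flagged]
  attr(panel, "truth") <- list(
    config = config,
    Ri = Ri, nAH = nAH, tau = tau, tau_PG = tau_PG,
    R_st = rst_true,
    rst_coefficients = if (is.character(config$rst_model))
      rst_reference_models()[[config$rst_model]] else config$rst_model
  )
  panel
}

#' Generate a PG-effect calibration panel from a known model
#'
#' Draws bis-allylic concentrations uniformly on a range and computes the PG
#' inhibition extension from either the hyperbolic model
#' \eqn{a/(b + x)} or the reciprocal line \eqn{1/(slope\,x + intercept)},
#' with multiplicative Gaussian noise — the standard recovery design for the
#' PG-effect fits.
#'
#' @param n_oils number of oils.
#' @param seed RNG seed.
#' @param ba_range bis-allylic concentration range, M.
#' @param model \code{"hyperbolic"} or \code{"reciprocal"}.
#' @param a,b hyperbolic parameters (s M and M).
#' @param slope,intercept reciprocal-line parameters (1/(s M) and 1/s).
#' @param noise_rel relative noise on the generated effect.
#' @return data.frame with \code{oil_id}, \code{bis_allylic_M}, \code{tau_s}
#'   (0), \code{tau_PG_s} (= effect), and a \code{truth} attribute.
#' @export
generate_pg_effect_panel <- function(n_oils = 20L, seed,
                                     ba_range = c(0.05, 3),
                                     model = c("hyperbolic", "reciprocal"),
                                     a = 3.0e4, b = 0.080,
                                     slope = 1.2e-4, intercept = -2.2e-5,
                                     noise_rel = 0.05) {
  model <- match.arg(model)
  if (missing(seed)) stop("generate_pg_effect_panel: seed is required")
  set.seed(seed)
  x <- stats::runif(n_oils, ba_range[1], ba_range[2])
  eff <- switch(model,
    hyperbolic = a / (b + x),
    reciprocal = {
      recip <- slope * x + intercept
      if (any(recip <= 0))
        stop("generate_pg_effect_panel: reciprocal line non-positive on the ",
             "requested range; raise the lower bis-allylic bound")
      1 / recip
    })
  eff_obs <- eff * (1 + stats::rnorm(n_oils, sd = noise_rel))
  out <- data.frame(oil_id = sprintf("PGCAL%03d", seq_len(n_oils)),
                    bis_allylic_M = x,
                    tau_s = 0,
                    tau_PG_s = pmax(eff_obs, 1),
                    excluded_flag = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(model = model, a = a, b = b, slope = slope,
                             intercept = intercept, noise_rel = noise_rel,
                             seed = seed)
  out
}

#' Map an oil record to radical-chain kinetic parameters
#'
#' Builds the [kinetic_params()] that reproduce an oil's measured descriptors:
#' the initiation rate from the record's \code{Ri} (or from \code{Ri_over_n}
#' times \code{n}), the antioxidant pool from the induction period
#' (\eqn{[AH] = \tau R_i / n}), and the effective propagation activity
#' \eqn{k_p [RH]} by inverting the steady-rate law at the given termination
#' constant. Optional impurity fields produce the Type C initial burst.
#'
#' @param oil one-row data.frame (or list) with \code{R_st_nmol_s},
#'   \code{tau_s}, and \code{Ri} (M/s) or \code{Ri_over_n}.
#' @param protocol a [vessel_protocol()] (for the nmol/s conversion).
#' @param kt termination constant, 1/(M s).
#' @param kinh antioxidant inhibition constant, 1/(M s); the default is a
#'   potent phenolic (gallate-like) antioxidant.
#' @param n stoichiometric factor.
#' @param RH_imp0,kp_imp optional trace-impurity pool (M) and its propagation
#'   constant; defaults 0.
#' @return a [kinetic_params()].
#' @export
oil_to_kinetic_params <- function(oil, protocol = vessel_protocol(),
                                  kt = 1e7, kinh = 1e5, n = 2,
                                  RH_imp0 = 0, kp_imp = 0) {
  oil <- as.list(oil)
  Ri <- oil$Ri
  if (is.null(Ri) && !is.null(oil$Ri_over_n)) Ri <- oil$Ri_over_n * n
  if (is.null(Ri)) stop("oil_to_kinetic_params: need Ri or Ri_over_n")
  rst_M <- molar_rate_from_vessel(oil$R_st_nmol_s, protocol)
  if (rst_M <= Ri)
    stop("oil_to_kinetic_params: R_st must exceed the initiation rate")
  kpRH <- (rst_M - Ri) * sqrt(2 * kt) / sqrt(Ri)
  AH0 <- if (!is.null(oil$tau_s) && is.finite(oil$tau_s))
    oil$tau_s * Ri / n else 0
  kinetic_params(kp = kpRH, kt = kt, Ri = Ri, RH0 = 1, AH0 = AH0,
                 kinh = kinh, n = n, RH_imp0 = RH_imp0, kp_imp = kp_imp)
}

#' Generate a synthetic multi-segment O2 trace for an oil
#'
#' Runs the mechanistic simulator for the oil's kinetic parameters under the
#' measurement protocol, then applies the instrument model: multiplicative
#' Gaussian reading noise and a decaying dead-time artifact (thermal
#' equilibration distorts the first ~1000 s of each run). The generating
#' ground truth (tau, R_in, R_st, oil type) is attached as
#' \code{attr(, "truth")}.
#'
#' @param oil as in [oil_to_kinetic_params()].
#' @param protocol a [vessel_protocol()].
#' @param noise_rel relative reading noise (default 0.5 %).
#' @param dead_time_amp relative amplitude of the dead-time artifact.
#' @param seed RNG seed.
#' @param t_end_s simulation horizon; default covers 1.3 tau plus enough
#'   steady-phase depletion cycles for a stable late slope.
#' @param ... further arguments to [oil_to_kinetic_params()].
#' @return an \code{o2_trace_set} with a \code{truth} attribute.
#' @export
generate_trace_set <- function(oil, protocol = vessel_protocol(),
                               noise_rel = 0.005, dead_time_amp = 0.02,
                               seed, t_end_s = NULL, ...) {
  if (missing(seed)) stop("generate_trace_set: seed is required")
  params <- oil_to_kinetic_params(oil, protocol, ...)
  rst_nmol <- vessel_rate_from_molar(steady_rate(params), protocol)
  tau <- if (params$AH0 > 0) inhibition_duration(params) else 0
  if (is.null(t_end_s)) {
    deplete_s <- o2_capacity_nmol(protocol) *
      protocol$reaeration_threshold / rst_nmol
    t_end_s <- 1.3 * tau + 2.5 * deplete_s
  }
  set.seed(seed)
  tr <- simulate_autoxidation(params, protocol, t_end_s = t_end_s,
                              noise_model = list(rel_sd = noise_rel))
  # dead-time artifact: readings ramp onto the true value
  dt <- protocol$dead_time_s
  if (dead_time_amp > 0 && dt > 0 && length(tr) > 0) {
    s1 <- tr[[1]]
    early <- s1$time_s < dt
    s1$o2_nmol[early] <- s1$o2_nmol[early] *
      (1 + dead_time_amp * (1 - s1$time_s[early] / dt))
    tr[[1]] <- s1
  }
  rin_nmol <- if (params$AH0 > 0)
    vessel_rate_from_molar(inhibited_rate(params), protocol) else rst_nmol
  attr(tr, "truth") <- list(
    params = params,
    tau_s = tau,
    R_in_nmol_s = rin_nmol,
    R_st_nmol_s = rst_nmol,
    oil_type = if (params$AH0 > 0) "B"
               else if (params$RH_imp0 > 0) "C" else "A",
    seed = seed
  )
  tr
}
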