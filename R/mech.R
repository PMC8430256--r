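#' Myofilament model parameters
#'
#' Constants of the contraction model: calcium-troponin binding rates,
#' regulatory-unit transition rates with temperature factors, the
#' four-state crossbridge cycle rates, distortion/force constants,
#' sarcomere geometry, passive-force parameters, and the dynamics of
#' sarcomere length. Rates are in 1/ms (binding in 1/(uM ms)), lengths in
#' um, temperature in degrees Celsius, forces normalized; `Tmax` converts
#' normalized active force to kPa.
#'
#' @param TmpC Operating temperature (deg C). At 37 the Q10 factors are 1.
#' @param SL0 Initial sarcomere length (um), within `[1.4, 2.4]`.
#' @param KSE Series-element stiffness (normalized force per um).
#' @param Tmax Normalized-force to kPa scale (kPa per unit). The default
#'   is a pipeline calibration chosen so that the all-100% conductance
#'   configuration lifts the 20 kPa contraction weight at both pacing
#'   rates while the 25%-CaL region stays below it; it absorbs the
#'   unstated conversion between the contraction model's normalized
#'   force and physical tension and is not a physiological maximum.
#' @param mech_dt_ms Internal integration step for the twitch (ms).
#' @param contraction_mode "series_elastic" (afterload = KSE (SL - SL0))
#'   or "isotonic" (constant afterload `afterload_const`).
#' @param afterload_const Constant afterload for isotonic mode
#'   (normalized force).
#' @param ... Overrides for any other constant.
#' @return Named list of parameters.
#' @export
mechParameters <- function(TmpC = 37, SL0 = 1.9, KSE = 1, Tmax = 300,
                           mech_dt_ms = 0.002,
                           contraction_mode = c("series_elastic",
                                                "isotonic"),
                           afterload_const = 0, ...) {
  contraction_mode <- match.arg(contraction_mode)
  stopifnot(SL0 >= 1.4, SL0 <= 2.4, KSE > 0, Tmax > 0, mech_dt_ms > 0)
  p <- list(
    # calcium-troponin binding (uM^-1 ms^-1, ms^-1)
    kon = 0.05, koffL = 0.25, koffH = 0.025, Qkon = 1.5, Qkoff = 1.3,
    # regulatory N <-> P transitions; base rates chosen so that the
    # fully activated limit satisfies knpT >> kpnT (permtot <= 1 scales
    # knpT down, inverse_permtot >= 1 scales kpnT up)
    knp = 0.5, kpn = 0.05, Qknp = 1.6, Qkpn = 1.6,
    perm50 = 0.5, nperm = 15,
    # crossbridge cycle (ms^-1)
    fapp = 0.5, Qfapp = 6.25, gapp = 0.07, Qgapp = 2.5, gslmod = 6,
    hf = 2, Qhf = 6.25, hfmdc = 5, hb = 0.4, Qhb = 6.25, hbmdc = 0,
    gxb = 0.07, Qgxb = 6.25, sigmap = 8, sigman = 1, xbmodsp = 1,
    # distortion
    x0 = 0.007, xPsi = 2,
    # sarcomere geometry (um)
    SLrest = 1.9, SLmin = 1.4, SLmax = 2.4,
    len_thick = 1.65, len_hbare = 0.1, len_thin = 1.2,
    # passive force
    PCon_t = 0.002, PExp_t = 10, SL_c = 2.25, PCon_c = 0.02, PExp_c = 70,
    # length dynamics
    visc = 0.003, mass = 5e-5,
    TmpC = TmpC, SL0 = SL0, KSE = KSE, Tmax = Tmax,
    mech_dt_ms = mech_dt_ms,
    mode = if (contraction_mode == "series_elastic") 0L else 1L,
    afterload_const = afterload_const)
  upd <- list(...)
  if (length(upd)) {
    bad <- setdiff(names(upd), names(p))
    if (length(bad)) stop("unknown mech parameters: ",
                          paste(bad, collapse = ", "))
    p <- modifyList(p, upd)
  }
  p
}

qfact <- function(q, TmpC) q^((TmpC - 37) / 10)

# single-overlap fractions of the thick and thin filaments
sovfThick <- function(SL, p) {
  ze <- pmin(p$len_thick / 2, SL / 2)
  cle <- pmax(SL / 2 - (SL - p$len_thin), p$len_hbare / 2)
  (ze - cle) * 2 / (p$len_thick - p$len_hbare)
}
sovfThin <- function(SL, p) {
  ze <- pmin(p$len_thick / 2, SL / 2)
  cle <- pmax(SL / 2 - (SL - p$len_thin), p$len_hbare / 2)
  (ze - cle) / p$len_thin
}

passiveForce <- function(SL, p) {
  sign(SL - p$SLrest) * p$PCon_t * (exp(p$PExp_t * abs(SL - p$SLrest)) - 1) +
    (SL >= p$SL_c) * p$PCon_c * (exp(p$PExp_c * (SL - p$SL_c)) - 1)
}

#' Advance the calcium-troponin binding fractions
#'
#' Explicit-Euler step of the two binding ODEs
#' d/dt CaTropX = konT Cai (1 - CaTropX) - koffXT CaTropX for the
#' high- (slow off-rate) and low-affinity (fast off-rate) sites.
#'
#' @param caTropH,caTropL Bound fractions in `[0, 1]`.
#' @param cai Calcium concentration in uM.
#' @param params See [mechParameters()].
#' @param dt Step (ms).
#' @return List with advanced `caTropH`, `caTropL`.
#' @export
troponinUpdate <- function(caTropH, caTropL, cai, params = mechParameters(),
                           dt = params$mech_dt_ms) {
  stopifnot(caTropH >= 0, caTropH <= 1, caTropL >= 0, caTropL <= 1,
            cai >= 0, dt > 0)
  qt <- (params$TmpC - 37) / 10
  konT <- params$kon * params$Qkon^qt
  koffHT <- params$koffH * params$Qkoff^qt
  koffLT <- params$koffL * params$Qkoff^qt
  h <- caTropH + dt * (konT * cai * (1 - caTropH) - koffHT * caTropH)
  l <- caTropL + dt * (konT * cai * (1 - caTropL) - koffLT * caTropL)
  list(caTropH = min(max(h, 0), 1), caTropL = min(max(l, 0), 1))
}

#' Regulatory-unit transition rates
#'
#' The fraction of calcium-bound thin-filament regulatory units is the
#' overlap-weighted mix of the two troponin populations,
#' Trop_Regulatory = (1 - SOVF_thin) CaTropL + SOVF_thin CaTropH.
#' Activation follows
#' permtot = sqrt(1 / (1 + (perm50 / Trop_Regulatory)^nperm)) with the
#' inverse capped at 100, and the non-permissive <-> permissive rates are
#' knpT = knp permtot Qknp^((TmpC-37)/10) and
#' kpnT = kpn min(1/permtot, 100) Qkpn^((TmpC-37)/10).
#'
#' @param SL Sarcomere length (um), within the operating range.
#' @param caTropH,caTropL Bound fractions.
#' @param params See [mechParameters()].
#' @return List with `knpT`, `kpnT` (1/ms), `permtot`, `inverse_permtot`
#'   and `trop_regulatory`.
#' @export
regulatoryRates <- function(SL, caTropH, caTropL,
                            params = mechParameters()) {
  stopifnot(SL >= params$SLmin, SL <= params$SLmax)
  sv <- sovfThin(SL, params)
  treg <- (1 - sv) * caTropL + sv * caTropH
  permtot <- if (treg <= 0) 0 else
    sqrt(1 / (1 + (params$perm50 / treg)^params$nperm))
  inv <- if (permtot > 0) min(1 / permtot, 100) else 100
  qt <- (params$TmpC - 37) / 10
  list(knpT = params$knp * permtot * params$Qknp^qt,
       kpnT = params$kpn * inv * params$Qkpn^qt,
       permtot = permtot, inverse_permtot = inv, trop_regulatory = treg)
}

# strain- and temperature-adjusted crossbridge rates at a mech state
xbRates <- function(state, params) {
  qt <- (params$TmpC - 37) / 10
  fappT <- params$fapp * params$xbmodsp * params$Qfapp^qt
  gapslmd <- 1 + (1 - sovfThick(state$SL, params)) * params$gslmod
  gappT <- params$gapp * gapslmd * params$xbmodsp * params$Qgapp^qt
  hfmd <- exp(-sign(state$xXBprer) * params$hfmdc *
                (state$xXBprer / params$x0)^2)
  hbmd <- exp(sign(state$xXBpostr - params$x0) * params$hbmdc *
                ((state$xXBpostr - params$x0) / params$x0)^2)
  hfT <- params$hf * hfmd * params$xbmodsp * params$Qhf^qt
  hbT <- params$hb * hbmd * params$xbmodsp * params$Qhb^qt
  gxbmd <- if (state$xXBpostr <= params$x0)
    exp(params$sigmap * ((params$x0 - state$xXBpostr) / params$x0)^2)
  else
    exp(params$sigman * ((state$xXBpostr - params$x0) / params$x0)^2)
  gxbT <- params$gxb * gxbmd * params$xbmodsp * params$Qgxb^qt
  list(fappT = fappT, gappT = gappT, hfT = hfT, hbT = hbT, gxbT = gxbT)
}

#' Duty fractions of the strongly bound crossbridge states
#'
#' Closed-form steady occupancies of the pre- and post-rotation states
#' under maximal activation, used to normalize the distortion dynamics.
#'
#' @param rates List with `fappT`, `gappT`, `hfT`, `hbT`, `gxbT` (1/ms).
#' @return List with `prer` and `postr` duty fractions.
#' @export
dutyFractions <- function(rates) {
  d <- with(rates, gxbT * hfT + fappT * hfT + gappT * hbT + gappT * gxbT +
              fappT * hbT + fappT * gxbT)
  list(prer = with(rates, fappT * hbT + fappT * gxbT) / d,
       postr = with(rates, fappT * hfT) / d)
}

#' Advance the regulatory and crossbridge occupancies
#'
#' Explicit-Euler step of the two-state no-crossbridge pair (N_NoXB,
#' P_NoXB) and the four-state crossbridge cycle (N_XB, P_XB, XB_PreR,
#' XB_PostR). Both pools conserve their sums exactly under the update.
#'
#' @param state List with occupancies `NNoXB`, `PNoXB`, `NXB`, `PXB`,
#'   `XBprer`, `XBpostr` (plus ignored extra fields).
#' @param rates Regulatory (`knpT`, `kpnT`) and crossbridge
#'   (`fappT`, `gappT`, `hfT`, `hbT`, `gxbT`) rates, 1/ms.
#' @param dt Step (ms).
#' @return The state with advanced occupancies.
#' @export
xbCycleUpdate <- function(state, rates, dt) {
  if (min(state$NNoXB, state$PNoXB, state$NXB, state$PXB, state$XBprer,
          state$XBpostr) < -1e-9)
    stop("invalid state: negative occupancy")
  with(rates, {
    dN0 <- -knpT * state$NNoXB + kpnT * state$PNoXB
    dN <- -knpT * state$NXB + kpnT * state$PXB
    dP <- knpT * state$NXB - (kpnT + fappT) * state$PXB +
      gappT * state$XBprer + gxbT * state$XBpostr
    dPre <- fappT * state$PXB - (gappT + hfT) * state$XBprer +
      hbT * state$XBpostr
    dPost <- hfT * state$XBprer - (hbT + gxbT) * state$XBpostr
    state$NNoXB <- state$NNoXB + dt * dN0
    state$PNoXB <- state$PNoXB - dt * dN0
    state$NXB <- state$NXB + dt * dN
    state$PXB <- state$PXB + dt * dP
    state$XBprer <- state$XBprer + dt * dPre
    state$XBpostr <- state$XBpostr + dt * dPost
    state
  })
}

#' Advance the mean crossbridge distortions
#'
#' The mean strains of the strongly bound states follow
#' dxXB_PreR/dt = dSL/dt / 2 + (phi / DutyFract_PreR)
#'   (fappT (-xXB_PreR) + hbT (xXB_PostR - x0 - xXB_PreR)) and
#' dxXB_PostR/dt = dSL/dt / 2 + (phi / DutyFract_PostR)
#'   hfT (xXB_PreR + x0 - xXB_PostR),
#' combining crossbridge turnover with the shared filament-sliding
#' advection term.
#'
#' @param xXBprer,xXBpostr Mean distortions (um).
#' @param dSLdt Sarcomere shortening velocity (um/ms).
#' @param rates Crossbridge rates (`fappT`, `hbT`, `hfT`, ...), 1/ms.
#' @param params See [mechParameters()].
#' @param dt Step (ms).
#' @return List with advanced `xXBprer`, `xXBpostr`.
#' @export
distortionUpdate <- function(xXBprer, xXBpostr, dSLdt, rates,
                             params = mechParameters(),
                             dt = params$mech_dt_ms) {
  duty <- dutyFractions(rates)
  # with all crossbridge rates zero the turnover terms vanish identically
  # (0/0 in the duty normalization is taken as 0): pure advection remains
  tpre <- rates$fappT * (-xXBprer) +
    rates$hbT * (xXBpostr - params$x0 - xXBprer)
  tpost <- rates$hfT * (xXBprer + params$x0 - xXBpostr)
  dpre <- 0.5 * dSLdt +
    if (tpre == 0) 0 else (params$xPsi / duty$prer) * tpre
  dpost <- 0.5 * dSLdt +
    if (tpost == 0) 0 else (params$xPsi / duty$postr) * tpost
  list(xXBprer = xXBprer + dt * dpre, xXBpostr = xXBpostr + dt * dpost)
}

#' Force balance of the contracting cell
#'
#' Normalized active force
#' F_active = SOVF_thick(SL) (xXB_PreR XB_PreR + xXB_PostR XB_PostR) /
#' (x0 XB_PostR_Max), passive (titin + collagen) force, preload (passive
#' force at SL0) and the series-elastic afterload KSE (SL - SL0). The
#' integrand of the force integral is
#' F_active + F_passive - F_preload - F_afterload in the tension-positive
#' convention; `F_contraction` is the same balance expressed in the
#' shortening direction (contractile force negative on SL), which is what
#' the length dynamics integrate - at the series-elastic equilibrium the
#' active force is balanced by KSE (SL0 - SL), so the activated cell
#' shortens below SL0.
#'
#' @param state List with `XBprer`, `XBpostr`, `xXBprer`, `xXBpostr`, `SL`.
#' @param params See [mechParameters()].
#' @return List with `F_active`, `F_passive`, `F_preload`, `F_afterload`
#'   and `F_integrand` (all normalized force).
#' @export
totalForce <- function(state, params = mechParameters()) {
  xbmax <- with(params, fapp * hf /
                  (gxb * hf + fapp * hf + gapp * hb + gapp * gxb +
                     fapp * hb + fapp * gxb))
  fa <- sovfThick(state$SL, params) *
    (state$xXBprer * state$XBprer + state$xXBpostr * state$XBpostr) /
    (params$x0 * xbmax)
  fp <- passiveForce(state$SL, params)
  fpre <- passiveForce(params$SL0, params)
  faft <- if (params$mode == 0) params$KSE * (state$SL - params$SL0)
  else params$afterload_const
  fcon <- if (params$mode == 0) -(fa + fp - fpre + faft)
  else -(fa + fp - fpre) + params$afterload_const
  list(F_active = fa, F_passive = fp, F_preload = fpre,
       F_afterload = faft, F_integrand = fa + fp - fpre - faft,
       F_contraction = fcon)
}

#' Advance sarcomere length and the force integral
#'
#' Accumulates Integral_Force by the force-balance integrand and advances
#' SL by dSL/dt = (Integral_Force + (SL0 - SL) viscosity) / mass. The
#' inertial mass term prevents instantaneous changes in shortening
#' velocity.
#'
#' @param state List with `SL`, `Intf` plus the occupancy/distortion
#'   fields used by [totalForce()].
#' @param params See [mechParameters()].
#' @param dt Step (ms).
#' @return The state with advanced `SL` and `Intf`, plus `dSLdt`.
#' @export
stepSL <- function(state, params = mechParameters(),
                   dt = params$mech_dt_ms) {
  f <- totalForce(state, params)
  dSLdt <- (state$Intf + (params$SL0 - state$SL) * params$visc) /
    params$mass
  if (state$SL < params$SLmin || state$SL > params$SLmax) dSLdt <- 0
  state$SL <- state$SL + dt * dSLdt
  state$Intf <- state$Intf + dt * f$F_contraction
  if (state$SL < 1.2 || state$SL > 2.6)
    stop(sprintf("mechanics divergence: SL = %.3f um out of [1.2, 2.6]",
                 state$SL))
  state$dSLdt <- dSLdt
  state
}

#' Resting mechanical state
#'
#' @param params See [mechParameters()].
#' @return Named list of the 12 mechanical state variables.
#' @export
mechInitialState <- function(params = mechParameters()) {
  as.list(.rice_initial_state(params))
}

#' Run a twitch driven by a calcium transient
#'
#' Integrates the full mechanical system over one beat, driven by an
#' externally supplied Cai(t) (one-way coupling: no feedback of force or
#' length on the ionic model). The mechanics are first equilibrated at the
#' trace's initial calcium level, so the normalized length starts at 1.
#'
#' @param trace An `ep_trace` from [runPacedEP()], or a list with `time`
#'   (ms) and `Cai` (mM) sampled on a uniform grid.
#' @param params See [mechParameters()].
#' @param equil_ms Pre-equilibration duration at the initial calcium
#'   level (ms).
#' @return A `mech_trace`: list with `time`, `tension_norm`,
#'   `tension_kPa`, `length_norm`, `SL` and divergence flags.
#' @export
#' @examples
#' \donttest{
#' tr <- runPacedEP(conductanceScaling(), bcl = 600, n_beats = 5)
#' tw <- runTwitch(tr)
#' min(tw$length_norm)
#' }
runTwitch <- function(trace, params = mechParameters(), equil_ms = 2000) {
  if (inherits(trace, "ep_trace") && isTRUE(trace$diverged))
    stop("cannot run mechanics on a diverged EP trace")
  out <- .rice_run_twitch(as.numeric(trace$time), as.numeric(trace$Cai),
                          params, params$mech_dt_ms, equil_ms)
  out$Tmax <- params$Tmax
  class(out) <- "mech_trace"
  if (out$diverged)
    warning(sprintf("mechanics divergence at t = %.2f ms",
                    out$diverged_time))
  out
}

#' @export
print.mech_trace <- function(x, ...) {
  cat("<mech_trace>", length(x$time), "samples, dt", x$dt, "ms\n")
  if (x$diverged) cat("  DIVERGED at t =", x$diverged_time, "ms\n")
  else cat(sprintf("  peak tension %.3g kPa; min normalized length %.4f\n",
                   max(x$tension_kPa), min(x$length_norm)))
  invisible(x)
}

#' Export a twitch as delimited text
#'
#' @param mech A `mech_trace` from [runTwitch()].
#' @param file Output path.
#' @param sep Field separator.
#' @return The file path, invisibly.
#' @export
exportTwitch <- function(mech, file, sep = ",") {
  df <- data.frame(time_ms = mech$time, tension_norm = mech$tension_norm,
                   tension_kPa = mech$tension_kPa,
                   length_norm = mech$length_norm)
  write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}
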