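#' Electrophysiology model parameters
#'
#' Constants of the human ventricular myocyte model: maximum conductances
#' and permeabilities, exchanger/pump scales, ryanodine-receptor rate
#' constants, compartment volumes and buffering parameters. These mirror
#' the values compiled into the stepping kernel and are exposed for
#' inspection and testing; the kernel itself is parameterized by the
#' per-channel scaling vector, the cell type and the stimulus settings.
#'
#' Units: conductances nS/pF (permeability for CaL in cm^3/(uF s)),
#' volumes um^3, F in C/mmol, rates 1/ms, concentrations mM.
#'
#' @return Named list of model constants.
#' @export
epParameters <- function() {
  p <- list(
    Cm = 0.185, F = 96.4867, R = 8314.472, T = 310,
    Ko = 5.4, Nao = 140, Cao = 2,
    GNa = 14.838, GCaL = 3.980e-5, Gto_epi = 0.294, Gto_endo = 0.073,
    GKr = 0.153, GKs_epi = 0.392, GKs_M = 0.098, GK1 = 5.405,
    GpK = 0.0146, GpCa = 0.1238, GbNa = 0.00029, GbCa = 0.000592,
    kNaCa = 1000, kNaK = 2.724,
    V_c = 16.404, V_SR = 1.094, V_SS = 0.05468,
    Vrel = 0.102, Vxfer = 0.0038, Vleak = 0.00036,
    Vmaxup = 0.006375, Kup = 0.00025,
    k1_prime = 0.15, k2_prime = 0.045, k3 = 0.060, k4 = 0.005,
    maxsr = 2.5, minsr = 1.0, EC = 1.5,
    Bufc = 0.2, Kbufc = 0.001, Bufsr = 10, Kbufsr = 0.3,
    Bufss = 0.4, Kbufss = 0.00025)
  stopifnot(all(vapply(p, function(x) is.finite(x) && x > 0, logical(1)) |
                  names(p) %in% c("Cm")))
  p
}

#' Electrophysiology protocol configuration
#'
#' @param cell_type One of "epi", "endo", "M" (transmural variant).
#' @param dt_ms Internal integration step (explicit scheme; keep <= 0.02).
#' @param output_dt_ms Output sampling step of the returned trace.
#' @param stim_amplitude Stimulus current in pA/pF (negative = depolarizing).
#' @param stim_duration_ms Stimulus duration.
#' @param n_beats Number of paced beats before the recorded final beat.
#' @param bcl_ms Basic cycle length.
#' @return Named list of protocol settings.
#' @export
epConfig <- function(cell_type = "endo", dt_ms = 0.02, output_dt_ms = 1,
                     stim_amplitude = -52, stim_duration_ms = 1,
                     n_beats = 50, bcl_ms = 1000) {
  stopifnot(cell_type %in% c("epi", "endo", "M"),
            dt_ms > 0, dt_ms <= 0.02 + 1e-12,
            output_dt_ms >= dt_ms, stim_duration_ms > 0, n_beats >= 1)
  list(cell_type = cell_type, dt_ms = dt_ms, output_dt_ms = output_dt_ms,
       stim_amplitude = stim_amplitude,
       stim_duration_ms = stim_duration_ms,
       n_beats = n_beats, bcl_ms = bcl_ms)
}

cellTypeCode <- function(cell_type) {
  match(cell_type, c("epi", "endo", "M")) - 1L
}

#' Initial state of the ventricular cell model
#'
#' Two published starting points of the model lineage. `"protocol"` (the
#' default used by paced runs) is the model family's published initial
#' values (Nai 11.6 mM, Ki 138.3 mM, Cai 0.2 uM, CaSR 0.2 mM), from
#' which the 50 pre-pacing beats of the protocol bring the cell to its
#' working steady state. `"rest"` is the quiescent resting state of the
#' calcium-dynamics variant (Nai 7.67 mM, Cai 0.07 uM, CaSR 1.3 mM),
#' the natural reference for stimulus-free stability checks. Both share
#' V = -86.2 mV and the resting gate values.
#'
#' @param variant `"protocol"` or `"rest"`.
#' @return Named numeric vector of the 19 state variables.
#' @export
epInitialState <- function(variant = c("protocol", "rest")) {
  variant <- match.arg(variant)
  s <- .tp06_initial_state()
  if (variant == "protocol") {
    s[["Nai"]] <- 11.6
    s[["Ki"]] <- 138.3
    s[["Cai"]] <- 2e-4
    s[["CaSS"]] <- 2e-4
    s[["CaSR"]] <- 0.2
  }
  s
}

#' Ryanodine-receptor update (reduced Markov model)
#'
#' The four-state Markov ryanodine receptor is tracked through the
#' aggregate Rbar = R + O. The opening rate k1 and closing rate k2 depend
#' on the SR calcium load through the factor
#' kcasr = maxsr - (maxsr - minsr) / (1 + (EC/CaSR)^2); k3 and k4 are
#' constant. The open fraction is algebraic,
#' O = k1 CaSS^2 Rbar / (k3 + k1 CaSS^2), the release flux is
#' Irel = Vrel O (CaSR - CaSS), and Rbar advances by explicit Euler on
#' dRbar/dt = -k2 CaSS Rbar + k4 (1 - Rbar).
#'
#' @param rbar Aggregate closed+open fraction, in `[0, 1]`.
#' @param cass Diadic subspace free calcium (mM).
#' @param casr SR free calcium (mM).
#' @param dt Time step (ms).
#' @param params Model constants, see [epParameters()].
#' @return List with `rbar` (advanced), `O` (open fraction at the input
#'   state) and `Irel` (mM/ms).
#' @export
ryrUpdate <- function(rbar, cass, casr, dt, params = epParameters()) {
  if (!is.finite(rbar) || rbar < 0 || rbar > 1)
    stop("invalid state: rbar must be in [0, 1]")
  if (cass < 0 || casr < 0)
    stop("invalid state: negative calcium concentration")
  stopifnot(dt > 0)
  kcasr <- params$maxsr -
    (params$maxsr - params$minsr) / (1 + (params$EC / casr)^2)
  k1 <- params$k1_prime / kcasr
  k2 <- params$k2_prime * kcasr
  O <- k1 * cass^2 * rbar / (params$k3 + k1 * cass^2)
  irel <- params$Vrel * O * (casr - cass)
  rbar2 <- rbar + dt * (-k2 * cass * rbar + params$k4 * (1 - rbar))
  list(rbar = min(max(rbar2, 0), 1), O = O, Irel = irel)
}

#' Transmembrane currents at a given state
#'
#' Evaluates the twelve transmembrane currents of the source model at a
#' fixed state, applying the per-channel conductance scaling to the ten
#' scalable currents. The Na/Ca exchanger and Na/K pump are never scaled.
#'
#' @param state Named state vector (see [epInitialState()]).
#' @param scaling Conductance scaling, see [conductanceScaling()].
#' @param cell_type Transmural variant, "epi" (default), "endo" or "M".
#' @return Named vector of currents in pA/pF.
#' @export
computeCurrents <- function(state, scaling = conductanceScaling(),
                            cell_type = "epi") {
  scaling <- assertScaling(scaling)
  .tp06_currents(as.numeric(state), as.numeric(scaling),
                 cellTypeCode(cell_type))
}

#' Advance the electrophysiology state
#'
#' Operator-split step: Rush-Larsen exponential update for the
#' Hodgkin-Huxley gates, explicit Euler for the membrane potential,
#' intracellular concentrations and the ryanodine-receptor aggregate.
#'
#' @inheritParams computeCurrents
#' @param dt Step size in ms (<= 0.02 for the explicit scheme).
#' @param i_stim Stimulus current in pA/pF (negative depolarizes).
#' @param n_steps Number of consecutive steps to take.
#' @return The advanced named state vector.
#' @export
stepEP <- function(state, scaling = conductanceScaling(), dt = 0.02,
                   i_stim = 0, cell_type = "epi", n_steps = 1L) {
  stopifnot(dt > 0, dt <= 0.02 + 1e-12)
  scaling <- assertScaling(scaling)
  .tp06_step(as.numeric(state), as.numeric(scaling), dt, i_stim,
             cellTypeCode(cell_type), as.integer(n_steps))
}

#' One explicit-Euler update of the three calcium compartments
#'
#' Reference implementation (in R) of the calcium balance
#' equations with instantaneous buffering, evaluated at the input state:
#' dCai_total/dt = -(IbCa + IpCa - 2 INaCa) Cm / (2 Vc F)
#'                 + (V_SR/V_c)(Ileak - Iup) + Ixfer,
#' dCaSR_total/dt = Iup - Ileak - Irel,
#' dCaSS_total/dt = -ICaL Cm / (2 V_SS F) + (V_SR/V_SS) Irel
#'                 - (V_c/V_SS) Ixfer.
#' Used to cross-check the compiled stepping kernel.
#'
#' @inheritParams computeCurrents
#' @param dt Step size (ms).
#' @param params Model constants, see [epParameters()].
#' @return List with advanced `Cai`, `CaSR`, `CaSS` (mM).
#' @export
updateCalcium <- function(state, scaling = conductanceScaling(), dt = 0.02,
                          cell_type = "epi", params = epParameters()) {
  cur <- computeCurrents(state, scaling, cell_type)
  cai <- state[["Cai"]]; casr <- state[["CaSR"]]; cass <- state[["CaSS"]]
  if (cai < 0 || casr < 0 || cass < 0)
    stop("invalid state: negative calcium concentration")
  ry <- ryrUpdate(state[["Rbar"]], cass, casr, dt, params)
  ileak <- params$Vleak * (casr - cai)
  iup <- params$Vmaxup / (1 + params$Kup^2 / cai^2)
  ixfer <- params$Vxfer * (cass - cai)
  bc <- 1 / (1 + params$Bufc * params$Kbufc / (cai + params$Kbufc)^2)
  bsr <- 1 / (1 + params$Bufsr * params$Kbufsr / (casr + params$Kbufsr)^2)
  bss <- 1 / (1 + params$Bufss * params$Kbufss / (cass + params$Kbufss)^2)
  dcai <- bc * (-(cur[["IbCa"]] + cur[["IpCa"]] - 2 * cur[["INaCa"]]) *
                  params$Cm / (2 * params$V_c * params$F) +
                  (params$V_SR / params$V_c) * (ileak - iup) + ixfer)
  dcasr <- bsr * (iup - ileak - ry$Irel)
  dcass <- bss * (-cur[["ICaL"]] * params$Cm /
                    (2 * params$V_SS * params$F) +
                    (params$V_SR / params$V_SS) * ry$Irel -
                    (params$V_c / params$V_SS) * ixfer)
  list(Cai = cai + dt * dcai, CaSR = casr + dt * dcasr,
       CaSS = cass + dt * dcass)
}

#' Paced single-cell electrophysiology run
#'
#' Applies the stimulus at the start of each cycle for `n_beats` cycles and
#' returns the final beat's membrane potential and intracellular calcium,
#' sampled at the output step. The 50-beat default washes out
#' initial-condition sensitivity before the recorded beat.
#'
#' @param scaling Conductance scaling, see [conductanceScaling()].
#' @param bcl Basic cycle length in ms (>= 300).
#' @param n_beats Number of paced beats (the last is recorded).
#' @param config Protocol settings, see [epConfig()].
#' @param init Optional initial state (defaults to
#'   `epInitialState("protocol")`).
#' @return An `ep_trace`: list with `time`, `V` (mV), `Cai` (mM), `dt`,
#'   `bcl`, `stim_onset`, `final_state` and divergence flags.
#' @export
#' @examples
#' \donttest{
#' tr <- runPacedEP(conductanceScaling(), bcl = 600, n_beats = 5)
#' max(tr$Cai) * 1000 # peak Cai in uM
#' }
runPacedEP <- function(scaling = conductanceScaling(), bcl = config$bcl_ms,
                       n_beats = config$n_beats, config = epConfig(),
                       init = NULL) {
  scaling <- assertScaling(scaling)
  stopifnot(bcl >= 300, n_beats >= 1)
  if (is.null(init)) init <- epInitialState("protocol")
  out <- .tp06_run_paced(as.numeric(scaling), bcl, as.integer(n_beats),
                         config$dt_ms, config$output_dt_ms,
                         config$stim_amplitude, config$stim_duration_ms,
                         cellTypeCode(config$cell_type), init)
  out$scaling <- scaling
  class(out) <- "ep_trace"
  if (out$diverged)
    warning(sprintf("EP divergence in beat %d (variable %s)",
                    out$diverged_beat, out$diverged_var))
  out
}

#' @export
print.ep_trace <- function(x, ...) {
  cat("<ep_trace> final beat, BCL", x$bcl, "ms, dt", x$dt, "ms,",
      length(x$V), "samples\n")
  if (x$diverged) {
    cat("  DIVERGED in beat", x$diverged_beat, "(", x$diverged_var, ")\n")
  } else {
    cat(sprintf("  V range [%.1f, %.1f] mV; peak Cai %.4g uM\n",
                min(x$V), max(x$V), max(x$Cai) * 1000))
  }
  invisible(x)
}

#' Export an electrophysiology trace as delimited text
#'
#' @param trace An `ep_trace` from [runPacedEP()].
#' @param file Output path.
#' @param sep Field separator ("," or "\t").
#' @return The file path, invisibly.
#' @export
exportTrace <- function(trace, file, sep = ",") {
  df <- data.frame(time_ms = trace$time, V_mV = trace$V,
                   Cai_mM = trace$Cai)
  write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}
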