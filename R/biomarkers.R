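#' Action-potential onset time
#'
#' The onset is the earliest sample time at which the membrane potential
#' reaches -40 mV or above.
#'
#' @param trace An `ep_trace` (or list with `time` and `V`).
#' @param threshold Onset threshold (mV).
#' @return Onset time in ms, or `NA` if the threshold is never reached.
#' @export
apOnset <- function(trace, threshold = -40) {
  i <- which(trace$V >= threshold)
  if (!length(i)) return(NA_real_)
  trace$time[i[1]]
}

# first downward linear-interpolated crossing of `level` at or after index i0
crossDown <- function(time, y, level, i0 = 1L) {
  n <- length(y)
  if (i0 >= n) return(NA_real_)
  idx <- which(y[i0:(n - 1)] > level & y[(i0 + 1):n] <= level)
  if (!length(idx)) return(NA_real_)
  i <- i0 + idx[1] - 1L
  time[i] + (time[i + 1] - time[i]) * (y[i] - level) / (y[i] - y[i + 1])
}

# first upward linear-interpolated crossing of `level`
crossUp <- function(time, y, level, i0 = 1L) {
  n <- length(y)
  if (i0 >= n) return(NA_real_)
  idx <- which(y[i0:(n - 1)] < level & y[(i0 + 1):n] >= level)
  if (!length(idx)) return(NA_real_)
  i <- i0 + idx[1] - 1L
  time[i] + (time[i + 1] - time[i]) * (level - y[i]) / (y[i + 1] - y[i])
}

#' Action potential duration at 90% repolarization
#'
#' The amplitude is V_peak - V_rest, with V_rest the pre-stimulus
#' potential (first sample of the beat). APD90 is the time from the
#' maximum-upstroke instant to the first subsequent downward crossing of
#' V_rest + 0.1 amplitude, linearly interpolated between samples. If the
#' potential never repolarizes within the beat the beat length is
#' returned, with attribute `no_repol = TRUE`.
#'
#' @param trace An `ep_trace` covering one beat.
#' @return APD90 in ms (`NA` if the beat has no action potential,
#'   i.e. peak V <= 0 mV).
#' @export
apd90 <- function(trace) {
  v <- trace$V
  t <- trace$time
  vrest <- v[1]
  vpeak <- max(v)
  if (vpeak <= 0) return(NA_real_)
  iup <- which.max(diff(v)) + 1L    # sample at the maximum-upstroke step
  tup <- t[iup]
  level <- vrest + 0.1 * (vpeak - vrest)
  tcross <- crossDown(t, v, level, i0 = which.max(v))
  if (is.na(tcross)) {
    out <- trace$bcl
    attr(out, "no_repol") <- TRUE
    return(out)
  }
  tcross - tup
}

#' Calcium-transient attributes
#'
#' Extracts from the final beat's Cai(t): the resting concentration (last
#' sample of the beat), the maximum, the transient duration (width of the
#' interval where Cai exceeds peak - 0.9 (peak - rest), i.e. the 90%
#' window, linearly interpolated), and the upstroke slope: 0.9 (peak -
#' rest) divided by the time from the upward crossing of the 10%-rise
#' level to the peak.
#'
#' @param trace An `ep_trace` (Cai in mM).
#' @return List with `max_cai`, `rest_cai` (mM), `cai_duration` (ms) and
#'   `cai_slope` (mM/ms); duration and slope are `NA` for a flat trace.
#' @export
caiAttributes <- function(trace) {
  ca <- trace$Cai
  t <- trace$time
  rest <- ca[length(ca)]
  ipk <- which.max(ca)
  peak <- ca[ipk]
  if (peak <= rest || peak - rest < .Machine$double.eps * 10)
    return(list(max_cai = peak, rest_cai = rest,
                cai_duration = NA_real_, cai_slope = NA_real_))
  level <- peak - 0.9 * (peak - rest)   # == rest + 0.1 (peak - rest)
  tup <- crossUp(t, ca, level)
  tdn <- crossDown(t, ca, level, i0 = ipk)
  dur <- if (is.na(tup) || is.na(tdn)) NA_real_ else tdn - tup
  slope <- if (is.na(tup) || t[ipk] <= tup) NA_real_ else
    0.9 * (peak - rest) / (t[ipk] - tup)
  list(max_cai = peak, rest_cai = rest, cai_duration = dur,
       cai_slope = slope)
}

#' Contraction onset of a twitch
#'
#' A case counts as contracting only if the physical tension reaches
#' `tension_threshold` (the "weight" the cell must lift) and the
#' normalized length falls to `length_threshold` or below. The onset is
#' the linearly interpolated time of the length crossing; absent for
#' no-contraction cases.
#'
#' @param mech A `mech_trace` from [runTwitch()].
#' @param tension_threshold Weight criterion in kPa.
#' @param length_threshold Shortening criterion (fraction of rest length).
#' @return List with `contracted` (logical) and `onset` (ms or `NA`).
#' @export
contractionOnset <- function(mech, tension_threshold = 20,
                             length_threshold = 0.99) {
  reaches_tension <- max(mech$tension_kPa) >= tension_threshold
  onset <- crossDown(mech$time, mech$length_norm, length_threshold)
  contracted <- reaches_tension && !is.na(onset)
  list(contracted = contracted, onset = if (contracted) onset else NA_real_)
}

biomarkerColumns <- function() {
  c("case_id", "bcl_ms", "apd90_ms", "max_cai_mM", "rest_cai_mM",
    "cai_dur_ms", "cai_slope_mM_per_ms", "ap_onset_ms",
    "contraction_onset_ms", "emd_ms", "contracted", "diverged")
}

emptyRecord <- function(case_id, bcl) {
  data.frame(case_id = as.numeric(case_id), bcl_ms = as.numeric(bcl), apd90_ms = NA_real_,
             max_cai_mM = NA_real_, rest_cai_mM = NA_real_,
             cai_dur_ms = NA_real_, cai_slope_mM_per_ms = NA_real_,
             ap_onset_ms = NA_real_, contraction_onset_ms = NA_real_,
             emd_ms = NA_real_, contracted = FALSE, diverged = FALSE)
}

#' Run one electromechanical case and extract all biomarkers
#'
#' Chains the paced electrophysiology run, the calcium-driven twitch and
#' the biomarker extractors. The electromechanical delay is the time from
#' the action-potential onset (V reaching -40 mV) to the onset of cell
#' shortening (normalized length falling to 99%, gated by the 20 kPa
#' tension criterion). Divergence of either model is recorded in the
#' `diverged` flag rather than thrown.
#'
#' @param scaling Conductance scaling, see [conductanceScaling()].
#' @param bcl Basic cycle length (ms).
#' @param config Protocol settings, see [epConfig()] (the `bcl_ms` and
#'   `n_beats` entries are honored unless overridden by arguments).
#' @param mech_params See [mechParameters()].
#' @param case_id Identifier stored in the record (sweep index).
#' @param tension_threshold,length_threshold Contraction criteria.
#' @return A one-row data.frame (a biomarker record) with columns
#'   `case_id`, `bcl_ms`, `apd90_ms`, `max_cai_mM`, `rest_cai_mM`,
#'   `cai_dur_ms`, `cai_slope_mM_per_ms`, `ap_onset_ms`,
#'   `contraction_onset_ms`, `emd_ms`, `contracted`, `diverged`.
#' @export
runCase <- function(scaling, bcl = config$bcl_ms, config = epConfig(),
                    mech_params = mechParameters(), case_id = NA_integer_,
                    tension_threshold = 20, length_threshold = 0.99) {
  rec <- emptyRecord(case_id, bcl)
  tr <- withCallingHandlers(
    runPacedEP(scaling, bcl = bcl, config = config),
    warning = function(w) invokeRestart("muffleWarning"))
  if (tr$diverged) {
    rec$diverged <- TRUE
    return(rec)
  }
  rec$apd90_ms <- as.numeric(apd90(tr))
  ca <- caiAttributes(tr)
  rec$max_cai_mM <- ca$max_cai
  rec$rest_cai_mM <- ca$rest_cai
  rec$cai_dur_ms <- ca$cai_duration
  rec$cai_slope_mM_per_ms <- ca$cai_slope
  rec$ap_onset_ms <- apOnset(tr)

  tw <- withCallingHandlers(
    runTwitch(tr, params = mech_params),
    warning = function(w) invokeRestart("muffleWarning"))
  if (tw$diverged) {
    rec$diverged <- TRUE
    return(rec)
  }
  co <- contractionOnset(tw, tension_threshold, length_threshold)
  rec$contracted <- co$contracted
  if (co$contracted && !is.na(rec$ap_onset_ms)) {
    rec$contraction_onset_ms <- co$onset
    rec$emd_ms <- co$onset - rec$ap_onset_ms
  } else {
    rec$contracted <- FALSE
  }
  rec
}
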