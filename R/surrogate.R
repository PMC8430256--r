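#' Analytic surrogate response specification
#'
#' A fast, deterministic stand-in for the coupled ODE pipeline: biomarker
#' records are computed from closed-form response curves with the
#' qualitative structure of the real sweep (APD driven up by CaL and down
#' by Ks/Kr/K1 with a CaL x Ks interaction; peak calcium up with CaL/bCa
#' and down with Ks/Kr; EMD maximal at intermediate CaL levels;
#' no-contraction at low CaL when bCa is low). It exists so the sweep,
#' table and stacking machinery are fully testable without ODE cost; the
#' default effect magnitudes span realistic dynamic ranges (APD up to
#' ~580 ms, EMD up to ~83 ms, peak Cai up to ~3 uM) and are test
#' fixtures, not physiological claims.
#'
#' @param noise Additive Gaussian noise amplitude (0 = pure function of
#'   levels and BCL).
#' @param seed Base seed for the noise stream.
#' @return A `surrogate_spec` list of base values and effect
#'   coefficients.
#' @export
surrogateSpec <- function(noise = 0, seed = 1) {
  structure(list(
    base = list(
      apd90 = c(`600` = 298, `1000` = 306),
      max_cai = c(`600` = 1.247e-3, `1000` = 0.889e-3),  # mM
      rest_cai = c(`600` = 9.5e-5, `1000` = 8.0e-5),
      cai_dur = c(`600` = 310, `1000` = 330),
      cai_slope = c(`600` = 2.2e-5, `1000` = 1.8e-5),    # mM/ms
      emd = 12, ap_onset = 1.2),
    coef = list(
      apd_cal = 150, apd_ks = 170, apd_kr = 60, apd_k1 = 55,
      apd_cal_ks = 70,
      cai_cal_pow = 1.3, cai_ks = 1.0, cai_bca = 0.45, cai_kr = 0.35,
      emd_amp = 52, emd_bca = 0.35,
      emd_bump = c(0, 1, 0.75, 0)),     # by CaL level 0:3
    noise = noise, seed = seed,
    noise_sd = c(apd90 = 5, max_cai = 2e-5, rest_cai = 2e-6,
                 cai_dur = 5, cai_slope = 1e-6, emd = 2)),
    class = "surrogate_spec")
}

factorToLevel <- function(f) {
  lv <- match(round(f, 6), round(sweepLevels(), 6)) - 1L
  if (anyNA(lv))
    stop("surrogate factors must be one of ",
         paste(sweepLevels(), collapse = ", "))
  lv
}

#' One surrogate biomarker record
#'
#' Evaluates the analytic response curves at a conductance configuration,
#' producing a record schema-identical to [runCase()] output.
#'
#' @param scaling Named length-10 factor vector (levels 25-100%).
#' @param bcl Basic cycle length (600 or 1000 treated as the two pacing
#'   conditions; others interpolate nothing and use the 1000 ms bases).
#' @param spec A `surrogate_spec`.
#' @param case_id Stored case identifier.
#' @param seed Overrides the spec's base seed for the noise stream.
#' @return One-row biomarker record data.frame.
#' @export
surrogateRecord <- function(scaling, bcl, spec = surrogateSpec(),
                            case_id = NA_integer_, seed = spec$seed) {
  f <- assertScaling(scaling)
  key <- if (as.character(bcl) %in% c("600", "1000")) as.character(bcl)
  else "1000"
  b <- spec$base
  k <- spec$coef
  lvl_cal <- factorToLevel(f[["CaL"]])
  lvl_bca <- factorToLevel(f[["bCa"]])

  apd <- b$apd90[[key]] - k$apd_cal * (1 - f[["CaL"]]) +
    k$apd_ks * (1 - f[["Ks"]]) + k$apd_kr * (1 - f[["Kr"]]) +
    k$apd_k1 * (1 - f[["K1"]]) +
    k$apd_cal_ks * (1 - f[["Ks"]]) * f[["CaL"]]
  maxca <- b$max_cai[[key]] * f[["CaL"]]^k$cai_cal_pow *
    (1 + k$cai_ks * (1 - f[["Ks"]])) *
    (1 - k$cai_bca + k$cai_bca * f[["bCa"]]) *
    (1 + k$cai_kr * (1 - f[["Kr"]]))
  restca <- b$rest_cai[[key]] * (0.7 + 0.3 * f[["CaL"]]) *
    (1 + 0.5 * (1 - f[["Ks"]]))
  dur <- b$cai_dur[[key]] + 180 * (1 - f[["CaL"]]) + 90 * (1 - f[["Ks"]])
  slope <- b$cai_slope[[key]] * f[["CaL"]]^1.5 *
    (1 + 0.8 * (1 - f[["Ks"]]))
  contracted <- !(lvl_cal == 0L && lvl_bca <= 1L)
  emd <- if (contracted)
    b$emd + k$emd_amp * k$emd_bump[lvl_cal + 1L] *
      (1 + k$emd_bca * (1 - f[["bCa"]]))
  else NA_real_

  if (spec$noise > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed((seed * 1009 + (if (is.na(case_id)) 0 else case_id) * 7 +
                bcl) %% 2147483647)
    ns <- spec$noise * spec$noise_sd
    apd <- apd + rnorm(1, 0, ns[["apd90"]])
    maxca <- maxca + rnorm(1, 0, ns[["max_cai"]])
    restca <- restca + rnorm(1, 0, ns[["rest_cai"]])
    dur <- dur + rnorm(1, 0, ns[["cai_dur"]])
    slope <- slope + rnorm(1, 0, ns[["cai_slope"]])
    if (contracted) emd <- emd + rnorm(1, 0, ns[["emd"]])
  }

  rec <- emptyRecord(case_id, bcl)
  rec$apd90_ms <- apd
  rec$max_cai_mM <- maxca
  rec$rest_cai_mM <- restca
  rec$cai_dur_ms <- dur
  rec$cai_slope_mM_per_ms <- slope
  rec$ap_onset_ms <- b$ap_onset
  rec$contracted <- contracted
  if (contracted) {
    rec$emd_ms <- emd
    rec$contraction_onset_ms <- b$ap_onset + emd
  }
  rec
}

#' Per-case runner backed by the surrogate
#'
#' Adapter with the calling convention of [runCase()], for plugging the
#' surrogate into [runSweep()].
#'
#' @param spec A `surrogate_spec`.
#' @param seed Noise-stream seed.
#' @return A function `(scaling, bcl, config, mech_params, case_id)`.
#' @export
surrogateRunner <- function(spec = surrogateSpec(), seed = spec$seed) {
  function(scaling, bcl, config = NULL, mech_params = NULL,
           case_id = NA_integer_) {
    surrogateRecord(scaling, bcl, spec, case_id = case_id, seed = seed)
  }
}

#' Generate a full surrogate results table
#'
#' Schema-identical to the real sweep output (same columns, sentinels and
#' metadata attributes), built from the analytic surrogate.
#'
#' @inheritParams enumerateScalings
#' @param bcls Basic cycle lengths.
#' @param spec A `surrogate_spec`.
#' @param seed Noise-stream seed.
#' @return Results table data.frame.
#' @export
generateSurrogateSweep <- function(channels = channelIds(),
                                   levels = sweepLevels(), bcls = 600,
                                   spec = surrogateSpec(),
                                   seed = spec$seed) {
  enum <- enumerateScalings(channels, levels)
  runSweep(enum, bcls, runner = surrogateRunner(spec, seed), quiet = TRUE)
}
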