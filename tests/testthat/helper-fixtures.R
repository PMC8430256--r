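# Shared fixtures, computed once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

# final-beat trace of the all-100% configuration, 50 paced beats
normalTrace <- function(bcl) {
  key <- paste0("tr", bcl)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- runPacedEP(conductanceScaling(), bcl = bcl,
                                      n_beats = 50,
                                      config = epConfig(bcl_ms = bcl))
  .fixture_env[[key]]
}

normalTwitch <- function(bcl) {
  key <- paste0("tw", bcl)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- runTwitch(normalTrace(bcl))
  .fixture_env[[key]]
}

# smooth synthetic calcium transient (mM) on a 1-ms grid
syntheticCai <- function(amp_uM = 1.1, rest_uM = 0.1, t_peak = 40,
                         tau_decay = 80, dur = 600) {
  t <- seq(0, dur - 1)
  rise <- (t / t_peak)^2 * exp(2 * (1 - t / t_peak))
  ca <- rest_uM + amp_uM * rise * exp(-pmax(t - t_peak, 0) / tau_decay) /
    max(rise * exp(-pmax(t - t_peak, 0) / tau_decay))
  list(time = t, Cai = ca / 1000)
}

# 4-channel surrogate table used by stacking tests
surrogateTable4 <- function(noise = 0, seed = 1, bcl = 600) {
  key <- paste("tab4", noise, seed, bcl)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generateSurrogateSweep(
      c("CaL", "Kr", "Ks", "K1"), bcls = bcl,
      spec = surrogateSpec(noise = noise, seed = seed))
  .fixture_env[[key]]
}
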