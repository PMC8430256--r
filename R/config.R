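#' Read a plain-text (YAML) configuration file
#'
#' Recognized keys mirror the arguments of [epConfig()] (cell_type,
#' dt_ms, output_dt_ms, stim_amplitude, stim_duration_ms, n_beats,
#' bcl_ms) and [mechParameters()] (TmpC, SL0_um, KSE, T_max_kPa,
#' mech_dt_ms, contraction_mode); unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return List with elements `ep` (an [epConfig()] list) and `mech`
#'   (a [mechParameters()] list).
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  ep_keys <- c("cell_type", "dt_ms", "output_dt_ms", "stim_amplitude",
               "stim_duration_ms", "n_beats", "bcl_ms")
  mech_keys <- c("TmpC", "SL0_um", "KSE", "T_max_kPa", "mech_dt_ms",
                 "contraction_mode")
  bad <- setdiff(names(raw), c(ep_keys, mech_keys))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  ep <- do.call(epConfig, raw[intersect(names(raw), ep_keys)])
  mech_args <- raw[intersect(names(raw), mech_keys)]
  names(mech_args)[names(mech_args) == "SL0_um"] <- "SL0"
  names(mech_args)[names(mech_args) == "T_max_kPa"] <- "Tmax"
  mech <- do.call(mechParameters, mech_args)
  list(ep = ep, mech = mech)
}
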