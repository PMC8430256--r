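#' The ten scalable channels of the ventricular cell model
#'
#' Canonical ordering of the ten sarcolemmal channels/transporters whose
#' maximum conductance (or permeability) can be scaled: fast sodium (Na),
#' L-type calcium (CaL), transient outward (to), rapid (Kr) and slow (Ks)
#' delayed-rectifier potassium, inward-rectifier potassium (K1), plateau
#' potassium (pK) and calcium (pCa), and background sodium (bNa) and
#' calcium (bCa). The Na/Ca exchanger and Na/K pump are never scaled.
#' This ordering is used for sweep indexing and stacking layouts.
#'
#' @return Character vector of the ten channel names, in canonical order.
#' @export
#' @examples
#' channelIds()
channelIds <- function() {
  c("Na", "CaL", "to", "Kr", "Ks", "K1", "pK", "pCa", "bNa", "bCa")
}

#' The four conductance levels of the population sweep
#'
#' Factors applied to each channel's maximum conductance: 25, 50, 75 and
#' 100% of the source-model value. Level codes 0:3 map to these factors.
#'
#' @return Numeric vector c(0.25, 0.5, 0.75, 1).
#' @export
sweepLevels <- function() c(0.25, 0.50, 0.75, 1.00)

#' Build a conductance-scaling vector
#'
#' Dimensionless multipliers applied to the maximum conductance of each of
#' the ten scalable channels. Channels not named default to 1 (100%).
#' Arbitrary positive factors are accepted by the simulator; the sweep
#' enumerator only produces factors in `sweepLevels()`.
#'
#' @param ... Named factors, e.g. `CaL = 0.5, bCa = 0.25`.
#' @param factors Optionally, a full named vector instead of `...`.
#' @return Named numeric vector of length 10 in canonical channel order.
#' @export
#' @examples
#' conductanceScaling(CaL = 0.5, bCa = 0.25)
conductanceScaling <- function(..., factors = NULL) {
  out <- setNames(rep(1, 10), channelIds())
  upd <- if (is.null(factors)) c(...) else factors
  if (length(upd)) {
    if (is.null(names(upd)) || !all(names(upd) %in% channelIds()))
      stop("scaling factors must be named by channel: ",
           paste(channelIds(), collapse = ", "))
    out[names(upd)] <- upd
  }
  if (any(!is.finite(out)) || any(out <= 0))
    stop("all scaling factors must be finite and positive")
  out
}

assertScaling <- function(scaling) {
  if (!is.numeric(scaling) || length(scaling) != 10L)
    stop("scaling must be a numeric vector of length 10")
  if (!is.null(names(scaling))) {
    if (!setequal(names(scaling), channelIds()))
      stop("scaling names must be the 10 canonical channels")
    scaling <- scaling[channelIds()]
  } else {
    names(scaling) <- channelIds()
  }
  if (any(!is.finite(scaling)) || any(scaling <= 0))
    stop("all scaling factors must be finite and positive")
  scaling
}
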