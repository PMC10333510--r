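#' Band-limited spatial signature component
#'
#' One planted oscillatory component of a class signature: a narrow-band
#' (Gaussian spectral window) stochastic oscillation added to a set of
#' target channels.
#'
#' @param channels character vector of 10/20 channel labels the component
#'   is added to.
#' @param freq center frequency in Hz; must lie inside the analysis band
#'   (0.5, 70).
#' @param bandwidth full spectral width (Hz) of the Gaussian window.
#' @param amplitude RMS amplitude in microvolts (>= 0).
#' @return A list of class `sig_component`.
#' @export
signature_component <- function(channels, freq, bandwidth = 2, amplitude = 5) {
  stopifnot(length(channels) >= 1, length(freq) == 1, length(amplitude) == 1)
  if (freq <= 0.5 || freq >= 70)
    stop("component center frequency must lie in (0.5, 70) Hz, got ", freq,
         call. = FALSE)
  if (amplitude < 0) stop("component amplitude must be >= 0", call. = FALSE)
  if (bandwidth <= 0) stop("component bandwidth must be > 0", call. = FALSE)
  structure(list(channels = as.character(channels), freq = freq,
                 bandwidth = bandwidth, amplitude = amplitude),
            class = "sig_component")
}

#' Class-specific EEG signature
#'
#' Bundles the oscillatory components planted for one diagnostic class by
#' the cohort simulator.
#'
#' @param class_label one of `class_levels()`.
#' @param components list of [signature_component()] objects (may be empty:
#'   the class then carries background activity only).
#' @param overlap_with optional label of a class whose signature shares
#'   components with this one (bookkeeping only; the sharing itself is
#'   expressed by listing the same component).
#' @return A list of class `class_signature`.
#' @export
class_signature <- function(class_label, components = list(),
                            overlap_with = NULL) {
  stopifnot(class_label %in% class_levels())
  for (co in components)
    if (!inherits(co, "sig_component"))
      stop("components must be built with signature_component()", call. = FALSE)
  structure(list(class_label = class_label, components = components,
                 overlap_with = overlap_with),
            class = "class_signature")
}

#' Default class signatures
#'
#' The planted spatio-spectral structure the simulator uses unless told
#' otherwise. Schizophrenia carries a left-lateralized posterior gamma
#' enhancement (40 Hz on O1 and P3; gamma-band abnormalities are among the
#' most replicated EEG findings in schizophrenia). Depression and bipolar
#' disorder share one frontal beta component (25 Hz on Fp1 and F8) and
#' differ only in its amplitude, which deliberately makes the two classes
#' partially confusable — the qualitative structure expected of the MDD/BP
#' pair. Normal controls carry background activity only. Band choices favor
#' rhythms faster than ~20 Hz because the network's convolution kernels span
#' at most 32 ms; see the methods vignette for the rationale.
#'
#' @param sz_amp,mdd_amp,bp_amp RMS amplitudes (microvolt) of the planted
#'   components; defaults 12, 16 and 13.
#' @return Named list of [class_signature()] objects, one per class.
#' @export
default_signatures <- function(sz_amp = 12, mdd_amp = 16, bp_amp = 13) {
  frontal_mdd <- signature_component(c("Fp1", "F8"), freq = 25, bandwidth = 4,
                                     amplitude = mdd_amp)
  frontal_bp <- signature_component(c("Fp1", "F8"), freq = 25, bandwidth = 4,
                                    amplitude = bp_amp)
  posterior_sz <- signature_component(c("O1", "P3"), freq = 40, bandwidth = 4,
                                      amplitude = sz_amp)
  list(
    NC  = class_signature("NC", list()),
    MDD = class_signature("MDD", list(frontal_mdd), overlap_with = "BP"),
    BP  = class_signature("BP", list(frontal_bp), overlap_with = "MDD"),
    SZ  = class_signature("SZ", list(posterior_sz))
  )
}
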