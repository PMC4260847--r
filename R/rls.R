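# Adaptive cancellation of cardiac interference in the leg EMG.
#
# The canceller is a recursive-least-squares (RLS) adaptive filter: the
# filter predicts the leg-EMG sample from the reference channel (the ECG,
# or a time-advanced copy of the leg channel itself) and the error sequence
# -- the part of the EMG the reference cannot explain -- is returned as the
# cleaned signal. Cardiac interference is predictable from the reference;
# broadband muscle activity is not, so it passes through.

#' RLS canceller configuration
#'
#' @param n_weights number of filter taps (default 5).
#' @param forgetting exponential forgetting factor λ in (0, 1]; values near
#'   1 track slow heart-rate change without chasing EMG bursts.
#' @param init_delta initial diagonal of the inverse-correlation matrix;
#'   larger values adapt faster from the zero-weight start.
#' @param self_ref_advance reference advance in samples, used only by
#'   [self_reference_cancel()] (default 5).
#' @return An object of class `rls_config`.
#' @export
rls_config <- function(n_weights = 5L, forgetting = 0.999, init_delta = 100,
                       self_ref_advance = 5L) {
  n_weights <- as.integer(n_weights)
  self_ref_advance <- as.integer(self_ref_advance)
  if (n_weights < 1L) stop("rls_config: n_weights must be >= 1")
  if (forgetting <= 0 || forgetting > 1)
    stop("rls_config: forgetting must be in (0, 1]")
  if (init_delta <= 0) stop("rls_config: init_delta must be > 0")
  structure(list(n_weights = n_weights, forgetting = forgetting,
                 init_delta = init_delta,
                 self_ref_advance = self_ref_advance),
            class = "rls_config")
}

#' Remove ECG interference from a leg-EMG trace using a reference channel
#'
#' Returns the RLS error sequence: the leg EMG minus the filter's prediction
#' from the ECG reference, i.e. the EMG without cardiac interference. The
#' first `n_weights` samples (filter warm-up) are passed through unchanged.
#' A constant-zero reference makes the canceller a no-op (with a warning).
#'
#' @param signal leg-EMG [signal_trace()].
#' @param reference ECG [signal_trace()] at the same fs and length (resample
#'   first if needed, see [resample_trace()]).
#' @param cfg an [rls_config()].
#' @return Cleaned [signal_trace()], same length and fs as `signal`.
#' @export
rls_cancel <- function(signal, reference, cfg = rls_config()) {
  stopifnot(inherits(signal, "signal_trace"),
            inherits(reference, "signal_trace"),
            inherits(cfg, "rls_config"))
  if (signal$fs != reference$fs)
    stop("rls_cancel: fs mismatch; resample the reference (resample_trace)")
  if (length(signal$samples) != length(reference$samples))
    stop("rls_cancel: length mismatch")
  if (!all(is.finite(signal$samples)) || !all(is.finite(reference$samples)))
    stop("rls_cancel: non-finite samples")
  if (all(reference$samples == 0)) {
    warning("rls_cancel: constant-zero reference; returning input unchanged")
    return(signal)
  }
  out <- rls_core(signal$samples, reference$samples, cfg$n_weights,
                  cfg$forgetting, cfg$init_delta, warmup = cfg$n_weights)
  signal_trace(out, fs = signal$fs, label = signal$label,
               start_time = signal$start_time)
}

#' Remove periodic cardiac interference without an ECG channel
#'
#' Uses a time-advanced copy of the leg channel itself as the reference: a
#' short filter with a small advance can predict the smooth, highly periodic
#' QRS interference across the advance, but not broadband EMG bursts, so
#' only the cardiac component is cancelled. The default is a five-weight
#' filter with a five-sample advance. The first
#' `n_weights + self_ref_advance` samples are passed through unchanged.
#'
#' @param signal leg-EMG [signal_trace()].
#' @param cfg an [rls_config()]; `self_ref_advance` must be >= 1.
#' @return Cleaned [signal_trace()], same length and fs as `signal`.
#' @export
self_reference_cancel <- function(signal, cfg = rls_config()) {
  stopifnot(inherits(signal, "signal_trace"), inherits(cfg, "rls_config"))
  adv <- cfg$self_ref_advance
  if (adv < 1L) stop("self_reference_cancel: self_ref_advance must be >= 1")
  n <- length(signal$samples)
  if (adv >= n) stop("self_reference_cancel: advance >= signal length")
  if (!all(is.finite(signal$samples)))
    stop("self_reference_cancel: non-finite samples")
  if (all(signal$samples == 0)) return(signal)
  ref <- c(signal$samples[(adv + 1L):n], numeric(adv))
  out <- rls_core(signal$samples, ref, cfg$n_weights, cfg$forgetting,
                  cfg$init_delta, warmup = cfg$n_weights + adv)
  signal_trace(out, fs = signal$fs, label = signal$label,
               start_time = signal$start_time)
}
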