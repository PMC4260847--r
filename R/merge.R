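#' Merge left and right leg EMG channels into one trace
#'
#' Clinical scoring rules allow the two anterior tibialis channels to be
#' combined into a single leg EMG. The default merge is the per-sample mean,
#' which approximates a hardware-combined channel while keeping the µV
#' scale; `sum` and `max_rect` (per-sample max of the rectified signals) are
#' alternatives.
#'
#' @param left,right [signal_trace()] objects with equal `fs`; lengths may
#'   differ by at most one sample (the shorter length is used).
#' @param rule `"mean"`, `"sum"` or `"max_rect"`.
#' @return A merged [signal_trace()].
#' @export
merge_leg_channels <- function(left, right, rule = c("mean", "sum", "max_rect")) {
  rule <- match.arg(rule)
  stopifnot(inherits(left, "signal_trace"), inherits(right, "signal_trace"))
  if (left$fs != right$fs)
    stop("merge_leg_channels: sampling rates differ (", left$fs, " vs ",
         right$fs, " Hz); resample one channel first (resample_trace)")
  nl <- length(left$samples); nr <- length(right$samples)
  if (abs(nl - nr) > 1L)
    stop("merge_leg_channels: length mismatch beyond 1 sample (",
         nl, " vs ", nr, ")")
  n <- min(nl, nr)
  a <- left$samples[seq_len(n)]; b <- right$samples[seq_len(n)]
  merged <- switch(rule,
    mean = (a + b) / 2,
    sum = a + b,
    max_rect = pmax(abs(a), abs(b)))
  signal_trace(merged, fs = left$fs, label = "LEG",
               start_time = left$start_time)
}

#' Resample a trace to a target sampling rate
#'
#' Linear interpolation onto the target sample grid (sample k maps to time
#' `k / fs`). Used to bring an ECG reference channel onto the leg-EMG rate
#' before adaptive cancellation; the canceller exploits QRS periodicity, not
#' fine morphology, so interpolation error is immaterial there.
#'
#' @param x a [signal_trace()].
#' @param fs_out target sampling rate (Hz).
#' @return A [signal_trace()] at `fs_out` covering the same span.
#' @export
resample_trace <- function(x, fs_out) {
  stopifnot(inherits(x, "signal_trace"), fs_out > 0)
  if (x$fs == fs_out) return(x)
  n_in <- length(x$samples)
  t_in <- (seq_len(n_in) - 1L) / x$fs
  n_out <- max(1L, round(n_in * fs_out / x$fs))
  t_out <- (seq_len(n_out) - 1L) / fs_out
  y <- stats::approx(t_in, x$samples, xout = t_out, rule = 2)$y
  signal_trace(y, fs = fs_out, label = x$label, start_time = x$start_time)
}
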