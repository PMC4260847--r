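# QRS detection and PLM-locked heart-rate response.

#' Detect R peaks in an ECG trace
#'
#' A Pan-Tompkins-style energy detector: baseline wander is removed with a
#' 0.6-s moving-mean subtraction, the signal is differentiated and squared,
#' integrated over a 0.15-s moving window, and peaks of the integrated
#' energy above an adaptive threshold are kept with a 250-ms refractory
#' period. Each detection is refined to the maximum of the rectified
#' detrended ECG within ±80 ms.
#'
#' @param ecg an ECG [signal_trace()]; fs >= 100 Hz recommended.
#' @param refractory_s minimum peak separation (default 0.25 s).
#' @param threshold_frac energy threshold as a fraction of the 99th
#'   percentile of integrated energy (default 0.2).
#' @return Numeric vector of R-peak times in seconds, strictly increasing;
#'   empty (with a warning) for a flat trace.
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.25, threshold_frac = 0.2) {
  stopifnot(inherits(ecg, "signal_trace"))
  x <- ecg$samples; fs <- ecg$fs; n <- length(x)
  if (max(x) - min(x) < .Machine$double.eps * 100) {
    warning("detect_r_peaks: flat ECG; no peaks")
    return(numeric())
  }
  detr <- x - moving_mean(x, max(3L, round(0.6 * fs)))
  der <- c(0, diff(detr))
  energy <- moving_mean(der^2, max(1L, round(0.15 * fs)))
  thr <- threshold_frac * stats::quantile(energy, 0.99, names = FALSE)
  if (thr <= 0) {
    warning("detect_r_peaks: no QRS energy; no peaks")
    return(numeric())
  }
  above <- energy > thr
  # contiguous supra-threshold regions -> one candidate peak each
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  if (nrow(regions) == 0L) return(numeric())
  half <- round(0.08 * fs)
  peaks <- apply(regions, 1, function(rg) {
    i0 <- max(1L, rg[1] - half); i1 <- min(n, rg[2] + half)
    i0 + which.max(abs(detr[i0:i1])) - 1L
  })
  peaks <- sort(unique(peaks))
  # enforce refractory period, keeping the larger peak
  if (length(peaks) > 1L) {
    keep <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- keep[length(keep)]
      if ((p - last) / fs >= refractory_s) {
        keep <- c(keep, p)
      } else if (abs(detr[p]) > abs(detr[last])) {
        keep[length(keep)] <- p
      }
    }
    peaks <- keep
  }
  (peaks - 1L) / fs
}

#' Heart-rate response around a single PLM onset
#'
#' Instantaneous heart rate (60/RR) is taken for the ten cardiac cycles
#' before and the ten after the movement onset; the rate of the cycle
#' immediately preceding onset is subtracted from all twenty values, so the
#' baseline cycle is 0 by construction. `delta` is the largest normalized
#' post-onset rate minus the smallest normalized pre-onset rate; `slope` is
#' `delta` divided by the number of cycles separating that minimum and
#' maximum (0 when the rate never changes).
#'
#' @param r_peaks strictly increasing R-peak times (seconds).
#' @param plm_onset_s movement onset time (seconds).
#' @param n_cycles cycles on each side (default 10).
#' @return List of class `hr_response` with `pre_hr`, `post_hr` (normalized
#'   bpm), `delta` (bpm), `slope` (bpm/cycle); `NULL` when fewer than
#'   `n_cycles` cycles are available on either side.
#' @export
hr_response <- function(r_peaks, plm_onset_s, n_cycles = 10L) {
  k <- findInterval(plm_onset_s, r_peaks, left.open = TRUE)
  # k = index of the last peak < onset; cycle i ends at peak i+1
  # pre cycles end at peaks (k - n_cycles + 1) .. k  -> need k - n_cycles >= 1
  if (k - n_cycles < 1L || k + n_cycles > length(r_peaks)) return(NULL)
  rr_ends <- (k - n_cycles + 1L):(k + n_cycles)
  hr <- 60 / (r_peaks[rr_ends] - r_peaks[rr_ends - 1L])
  baseline <- hr[n_cycles]          # cycle just prior to onset
  hr <- hr - baseline
  pre <- hr[seq_len(n_cycles)]
  post <- hr[(n_cycles + 1L):(2L * n_cycles)]
  delta <- max(post) - min(pre)
  if (delta == 0) {
    slope <- 0
  } else {
    pos_min <- which.min(pre)                  # position 1..n among all 2n
    pos_max <- n_cycles + which.max(post)
    slope <- delta / max(1L, pos_max - pos_min)
  }
  structure(list(pre_hr = pre, post_hr = post, delta = delta, slope = slope),
            class = "hr_response")
}
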