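#' Event-detection parameters
#'
#' Thresholds for the sigma cascade that turns dF/F0 traces into binary
#' events. Defaults are the standard operating point at 20 Hz: a candidate
#' onset must rise at least `rise_sigma_1` (3) sigma within `rise_window_1`
#' (1 s); it is kept only if the rise reaches `rise_sigma_2` (15) sigma
#' within `rise_window_2` (2 s) of onset, the event area under the curve is
#' at least `auc_sigma` (250) sigma-frames, and the peak crosses
#' `abs_peak_min` (0.0125) absolute dF/F0. The neuron is then marked active
#' from onset until the signal drops `decay_fraction` (30%) from the event
#' peak, capped at `max_active_s` (2 s). Sigma is the SD of dF/F0 over the
#' least active `sigma_quantile` (50%) of the recording.
#'
#' @param frame_rate Frames per second.
#' @param rise_sigma_1,rise_window_1 Candidate-onset rise threshold (sigma)
#'   and window (s).
#' @param rise_sigma_2,rise_window_2 Confirmation rise threshold and window.
#' @param auc_sigma Minimum event area under the curve, in sigma-frames.
#' @param abs_peak_min Absolute dF/F0 floor for the event peak.
#' @param decay_fraction Fractional drop from peak that ends the active period.
#' @param max_active_s Cap on the active period, seconds from onset.
#' @param sigma_quantile Least-active fraction of frames used to estimate
#'   sigma.
#' @param smooth_s Smoothing window (s) used to rank frames by activity.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(frame_rate = 20, rise_sigma_1 = 3,
                             rise_window_1 = 1, rise_sigma_2 = 15,
                             rise_window_2 = 2, auc_sigma = 250,
                             abs_peak_min = 0.0125, decay_fraction = 0.30,
                             max_active_s = 2, sigma_quantile = 0.5,
                             smooth_s = 1) {
  stopifnot(frame_rate > 0, rise_sigma_1 > 0, rise_sigma_2 > 0,
            auc_sigma > 0, abs_peak_min > 0,
            decay_fraction > 0, decay_fraction < 1,
            sigma_quantile > 0, sigma_quantile <= 1)
  structure(list(frame_rate = frame_rate, rise_sigma_1 = rise_sigma_1,
                 rise_window_1 = rise_window_1, rise_sigma_2 = rise_sigma_2,
                 rise_window_2 = rise_window_2, auc_sigma = auc_sigma,
                 abs_peak_min = abs_peak_min, decay_fraction = decay_fraction,
                 max_active_s = max_active_s, sigma_quantile = sigma_quantile,
                 smooth_s = smooth_s),
            class = "detection_params")
}

# Linear-phase FIR low-pass (Kaiser design): passband edge 0.5, stopband
# edge 0.65 in normalized frequency (Nyquist = 1), 1 dB passband ripple,
# 25 dB stopband attenuation. The group delay is compensated so the output
# is aligned with the input.
design_lowpass <- function(passband = 0.5, stopband = 0.65,
                           ripple_db = 1, atten_db = 25) {
  dev_pass <- (10^(ripple_db / 20) - 1) / (10^(ripple_db / 20) + 1)
  dev_stop <- 10^(-atten_db / 20)
  ko <- signal::kaiserord(c(passband, stopband), c(1, 0),
                          c(dev_pass, dev_stop))
  n <- ko$n
  if (n %% 2 == 1) n <- n + 1          # even order -> integer group delay
  as.numeric(signal::fir1(n, ko$Wc, window = signal::kaiser(n + 1, ko$beta)))
}

apply_fir <- function(x, h) {
  d <- (length(h) - 1) / 2
  xp <- c(rep(x[1], d), x, rep(x[length(x)], d))   # edge replication
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  as.numeric(y[(2 * d + 1):length(xp)])
}

#' Surround-correct, normalize and low-pass filter fluorescence traces
#'
#' The neuropil-corrected signal is the ROI mean minus the surrounding
#' annulus mean; dF/F0 uses F0 = median of the surround signal; a
#' linear-phase FIR low-pass (normalized passband edge 0.5, stopband edge
#' 0.65, 1 dB ripple, 25 dB attenuation) removes high-frequency noise.
#'
#' @param roi,surround Numeric matrices (frames x neurons) or vectors: per-ROI
#'   mean and annulus mean fluorescence.
#' @param lowpass Apply the low-pass filter (default TRUE).
#' @return Matrix of corrected dF/F0 traces, frames x neurons.
#' @export
preprocess_traces <- function(roi, surround, lowpass = TRUE) {
  roi <- as.matrix(roi); surround <- as.matrix(surround)
  if (!all(dim(roi) == dim(surround)))
    stop("roi and surround traces must have equal dimensions")
  if (anyNA(roi) || anyNA(surround) || !all(is.finite(roi)) ||
      !all(is.finite(surround)))
    stop("non-finite samples in traces")
  h <- if (lowpass) design_lowpass() else NULL
  out <- matrix(0, nrow(roi), ncol(roi))
  for (j in seq_len(ncol(roi))) {
    corrected <- roi[, j] - surround[, j]
    f0 <- median(surround[, j])
    if (!is.finite(f0) || f0 == 0)
      stop(sprintf("F0 (median surround) is zero for trace %d", j))
    x <- corrected / f0
    out[, j] <- if (lowpass) apply_fir(x, h) else x
  }
  out
}

#' Estimate the noise SD over the least active fraction of a trace
#'
#' Frames are ranked by the 1-s-smoothed absolute dF/F0 and sigma is the SD
#' of the raw trace over the least active half (robust to transients).
#'
#' @param x Numeric dF/F0 trace.
#' @param params A [detection_params()].
#' @return Sigma; 0 (with a `degenerate` attribute) for a constant trace, in
#'   which case detection is disabled for the neuron.
#' @export
estimate_sigma <- function(x, params = detection_params()) {
  if (length(x) < 100) stop("trace too short to estimate sigma")
  w <- max(1L, round(params$frame_rate * params$smooth_s))
  sm <- stats::filter(abs(x), rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- abs(x)[is.na(sm)]   # edges: fall back to the raw samples
  keep <- sm <= quantile(sm, params$sigma_quantile)
  s <- sd(x[keep])
  if (!is.finite(s) || s == 0) {
    s <- 0
    attr(s, "degenerate") <- TRUE
  }
  s
}

# trailing window max-minus-min rise over the last `w` frames at each frame
trailing_rise <- function(x, w) {
  runmin <- Reduce(pmin, lapply(0:(w - 1), function(k)
    c(rep(Inf, k), x[seq_len(length(x) - k)])))
  x - runmin
}

#' Detect calcium events in one dF/F0 trace
#'
#' Applies the sigma-threshold cascade described in [detection_params()] and
#' returns the binary active-frame row plus an event table. Candidates whose
#' extent overlaps an accepted event are merged into it.
#'
#' @param x Numeric dF/F0 trace.
#' @param sigma Noise SD (from [estimate_sigma()]); `sigma <= 0` disables
#'   detection and returns an empty row.
#' @param params A [detection_params()].
#' @return Integer 0/1 vector of length `length(x)` with an `events`
#'   attribute: a tibble with 0-based `onset`, `peak_frame`, `active_end`
#'   (exclusive), `peak` and `auc` (sigma-frames).
#' @export
detect_events <- function(x, sigma, params = detection_params()) {
  n <- length(x)
  row <- integer(n)
  events <- tibble::tibble(onset = integer(), peak_frame = integer(),
                           active_end = integer(), peak = numeric(),
                           auc = numeric())
  if (sigma <= 0 || all(x == 0)) {
    attr(row, "events") <- events
    return(row)
  }
  w1 <- max(2L, round(params$frame_rate * params$rise_window_1))
  w2 <- max(2L, round(params$frame_rate * params$rise_window_2))
  maxlen <- max(1L, round(params$frame_rate * params$max_active_s))
  rise <- trailing_rise(x, w1)
  cand <- which(rise >= params$rise_sigma_1 * sigma)
  clear_until <- 0L                     # end (exclusive, 1-based) of last event
  for (t in cand) {
    if (t <= clear_until) next
    win <- max(1L, t - w1 + 1L):t
    onset <- win[which.min(x[win])]
    if (onset <= clear_until) next
    # confirmation rise within w2 of onset
    conf_win <- onset:min(onset + w2 - 1L, n)
    conf_hits <- conf_win[x[conf_win] - x[onset] >=
                            params$rise_sigma_2 * sigma]
    if (length(conf_hits) == 0) next
    # pre-event baseline: median of the window preceding the onset (robust
    # against the onset itself being a noise minimum)
    baseline <- median(x[max(1L, onset - w1 + 1L):onset])
    # event extent: onset until return to the baseline (a one-sigma band
    # around it counts as returned), searched only after the confirming
    # rise so pre-rise noise bumps cannot close the extent early
    established <- conf_hits[1]
    after <- if (established < n) (established + 1L):n else integer(0)
    ret <- after[x[after] <= baseline + sigma]
    extent_end <- if (length(ret)) ret[1] else n
    ev <- onset:extent_end
    peak_rel <- which.max(x[ev])
    peak_frame <- ev[peak_rel]
    peak <- x[peak_frame]
    auc <- sum(x[ev] - baseline) / sigma
    if (auc < params$auc_sigma) { clear_until <- extent_end; next }
    if (peak < params$abs_peak_min) { clear_until <- extent_end; next }
    # active period: onset until the signal drops decay_fraction from peak,
    # capped at max_active_s from onset (end exclusive)
    post <- if (peak_frame < n) (peak_frame + 1L):n else integer(0)
    drop <- post[x[post] <= (1 - params$decay_fraction) * peak]
    end_excl <- if (length(drop)) drop[1] else n + 1L
    end_excl <- min(end_excl, onset + maxlen)
    row[onset:(end_excl - 1L)] <- 1L
    events <- dplyr::bind_rows(events, tibble::tibble(
      onset = as.integer(onset - 1L), peak_frame = as.integer(peak_frame - 1L),
      active_end = as.integer(end_excl - 1L), peak = peak, auc = auc))
    clear_until <- max(extent_end, end_excl - 1L)
  }
  attr(row, "events") <- events
  row
}

#' Build an event raster from a matrix of dF/F0 traces
#'
#' Estimates sigma per neuron and runs [detect_events()] on each trace.
#'
#' @param traces Numeric matrix, frames x neurons, of corrected dF/F0.
#' @param params A [detection_params()].
#' @return Binary event raster (neurons x frames) with attribute `sigma`
#'   (per-neuron noise SD).
#' @export
detect_events_matrix <- function(traces, params = detection_params()) {
  traces <- as.matrix(traces)
  N <- ncol(traces)
  raster <- matrix(0L, N, nrow(traces))
  sig <- numeric(N)
  for (j in seq_len(N)) {
    sig[j] <- estimate_sigma(traces[, j], params)
    raster[j, ] <- detect_events(traces[, j], sig[j], params)
  }
  attr(raster, "sigma") <- sig
  raster
}
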