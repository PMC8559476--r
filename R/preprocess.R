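#' Epoch a continuous recording and baseline-correct
#'
#' Cuts fixed-length epochs around each event onset and subtracts the
#' per-channel mean of the prestimulus baseline from every epoch.
#'
#' @param recording list with `data` (channels x samples), `sfreq` (Hz) and
#'   optionally `t0` (time of the first sample, s; default 0).
#' @param events event table with an `onset_ms` column (see
#'   [build_session()]); remaining columns are carried into the trial
#'   metadata.
#' @param window epoch window around onset, seconds (default 100 ms before
#'   to 400 ms after the sound onset).
#' @param baseline baseline interval within the window (default the 100 ms
#'   prestimulus period).
#' @return object of class `"epoch_set"`: `epochs` (trial x channel x
#'   time), `times` (s, relative to onset), `sfreq`, and `trials` (data
#'   frame of per-trial metadata).
#' @export
epoch_and_baseline <- function(recording, events, window = c(-0.1, 0.4),
                               baseline = c(-0.1, 0)) {
  stopifnot(window[1] <= baseline[1], baseline[2] <= window[2])
  fs <- recording$sfreq
  t0 <- recording$t0 %||% 0
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1)
  times <- rel / fs
  n_ch <- nrow(recording$data)
  n_samp <- ncol(recording$data)
  onsets <- round((events$onset_ms / 1000 - t0) * fs)
  if (any(onsets + rel[1] < 0) || any(onsets + rel[length(rel)] >= n_samp))
    stopf("epoch window extends outside the available data")
  n_tr <- nrow(events)
  ep <- array(0, c(n_tr, n_ch, length(rel)))
  bidx <- which(times >= baseline[1] & times < baseline[2])
  for (i in seq_len(n_tr)) {
    seg <- recording$data[, onsets[i] + rel + 1, drop = FALSE]
    seg <- seg - rowMeans(seg[, bidx, drop = FALSE])
    ep[i, , ] <- seg
  }
  structure(list(epochs = ep, times = times, sfreq = fs,
                 trials = as.data.frame(events)),
            class = "epoch_set")
}

#' Low-pass filter and resample epochs
#'
#' Zero-phase 4th-order Butterworth low-pass (applied forward and backward
#' with `signal::filtfilt`) followed by polyphase resampling to the
#' analysis rate.
#'
#' @param epochs an `epoch_set`.
#' @param cutoff low-pass cut-off (Hz).
#' @param out_rate output sampling rate (Hz).
#' @return a new `epoch_set` at `out_rate`.
#' @export
lowpass_resample <- function(epochs, cutoff = 35, out_rate = 256) {
  fs <- epochs$sfreq
  if (fs < 2 * cutoff) stopf("input rate must be at least twice the cut-off")
  if (cutoff > out_rate / 2) stopf("cut-off above the Nyquist of the output rate")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  frac <- gcd_int(round(out_rate), round(fs))
  p <- round(out_rate) / frac
  q <- round(fs) / frac
  d <- dim(epochs$epochs)
  n_out <- ceiling(d[3] * p / q)
  out <- array(0, c(d[1], d[2], n_out))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      xf <- signal::filtfilt(bf, epochs$epochs[i, j, ])
      out[i, j, ] <- signal::resample(xf, p, q)[seq_len(n_out)]
    }
  }
  times <- epochs$times[1] + (seq_len(n_out) - 1) / out_rate
  structure(list(epochs = out, times = times, sfreq = out_rate,
                 trials = epochs$trials),
            class = "epoch_set")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Average deviants and a matched selection of standards
#'
#' Computes the deviant ERF for one deviant feature and the average of an
#' equal number of standards. Standards are matched by within-melody note
#' position where possible; remaining slots are filled by a seeded random
#' draw without replacement. The selection is recorded in the output.
#'
#' @param epochs an `epoch_set` whose `trials` include `feature` and,
#'   if available, `note_index` (within-melody position).
#' @param feature deviant feature to average (default `"pitch"`).
#' @param seed integer seed for the random fallback draw.
#' @return object of class `"evoked_dataset"` with fields `standard` and
#'   `deviant` (channels x time), `times`, `n_deviants`, and the matched
#'   standard trial indices in `meta$matched_standards`.
#' @export
average_matched <- function(epochs, feature = "pitch", seed = 1) {
  tr <- epochs$trials
  dev_i <- which(tr$feature == feature)
  std_i <- which(tr$feature == "standard")
  if (length(std_i) < length(dev_i))
    stopf("fewer standards (%d) than deviants (%d)", length(std_i), length(dev_i))
  sel <- integer(0)
  avail <- std_i
  rng <- local_rng(seed)
  if (!is.null(tr$note_index)) {
    for (i in dev_i) {
      cand <- avail[tr$note_index[avail] == tr$note_index[i]]
      pick <- if (length(cand)) cand[rng(length(cand))] else NA_integer_
      if (!is.na(pick)) { sel <- c(sel, pick); avail <- setdiff(avail, pick) }
      else sel <- c(sel, NA_integer_)
    }
    for (j in which(is.na(sel))) {
      pick <- avail[rng(length(avail))]
      sel[j] <- pick
      avail <- setdiff(avail, pick)
    }
  } else {
    sel <- avail[sample_idx(rng, length(avail), length(dev_i))]
  }
  avg <- function(idx) {
    m <- apply(epochs$epochs[idx, , , drop = FALSE], c(2, 3), mean)
    matrix(m, dim(epochs$epochs)[2], dim(epochs$epochs)[3])
  }
  evoked_dataset(standard = avg(sel), deviant = avg(dev_i),
                 times = epochs$times,
                 meta = list(feature = feature, n_deviants = length(dev_i),
                             matched_standards = sel, seed = seed))
}

# deterministic uniform integer generator independent of the global RNG
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  function(n) {
    state <<- (state * 48271) %% 2147483647
    1L + as.integer(state %% n)
  }
}

sample_idx <- function(rng, n, k) {
  pool <- seq_len(n)
  out <- integer(k)
  for (i in seq_len(k)) {
    j <- rng(length(pool))
    out[i] <- pool[j]
    pool <- pool[-j]
  }
  out
}

#' Crop an evoked dataset to the fit window and mean-centre
#'
#' Crops to the analysis window (default 0-300 ms) and removes each
#' channel's temporal mean, matching the convention used when fitting.
#' The operation is idempotent.
#'
#' @param evoked an `evoked_dataset`.
#' @param window window to retain (s).
#' @return the cropped, centred `evoked_dataset`.
#' @export
crop_center <- function(evoked, window = c(0, 0.3)) {
  dt <- stats::median(diff(evoked$times))
  if (window[1] < min(evoked$times) - dt - 1e-9 ||
      window[2] > max(evoked$times) + dt + 1e-9)
    stopf("window outside the evoked span")
  keep <- evoked$times >= window[1] - 1e-9 & evoked$times <= window[2] + 1e-9
  for (f in c("standard", "deviant")) {
    if (!is.null(evoked[[f]])) {
      m <- evoked[[f]][, keep, drop = FALSE]
      evoked[[f]] <- m - rowMeans(m)
    }
  }
  evoked$times <- evoked$times[keep]
  evoked
}
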