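# helper: a continuous synthetic recording with an evoked template at each
# event onset plus optional sinusoidal/noise background
make_recording <- function(events, n_ch = 4, sfreq = 1000,
                           template = NULL, extra = 0) {
  dur <- max(events$onset_ms) / 1000 + 1
  n <- round(dur * sfreq)
  X <- matrix(extra, n_ch, n)
  if (!is.null(template)) {
    for (on in events$onset_ms) {
      i0 <- round(on / 1000 * sfreq)
      idx <- i0 + seq_len(ncol(template))
      X[, idx] <- X[, idx] + template
    }
  }
  list(data = X, sfreq = sfreq, t0 = -0.5)
}

test_that("epoching yields one baseline-zero epoch per trigger event", {
  ev <- build_session("HP", blocks = 1, melodies_per_block = 2, seed = 4)
  tpl <- matrix(rep(sin(seq(0, pi, length.out = 200)), each = 4), 4)
  rec <- make_recording(ev, template = tpl, extra = 0.7)
  es <- epoch_and_baseline(rec, ev)
  expect_equal(dim(es$epochs)[1], nrow(ev))
  bidx <- es$times < 0
  bmeans <- apply(es$epochs[, , bidx], c(1, 2), mean)
  expect_lt(max(abs(bmeans)), 1e-12 * max(abs(es$epochs)))
  # a constant-offset recording is annihilated by baseline correction
  rec0 <- make_recording(ev, extra = 3.2)
  es0 <- epoch_and_baseline(rec0, ev)
  expect_equal(max(abs(es0$epochs)), 0)
  # window outside the data errors
  late <- ev; late$onset_ms <- late$onset_ms + 1e6
  expect_error(epoch_and_baseline(rec, late), "outside")
})

test_that("low-pass + resample passes 5 Hz, suppresses 70 Hz, and lands at 256 Hz", {
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  mk <- function(f) {
    ep <- array(0, c(1, 1, length(t)))
    ep[1, 1, ] <- sin(2 * pi * f * t)
    structure(list(epochs = ep, times = t, sfreq = fs,
                   trials = data.frame(feature = "standard")),
              class = "epoch_set")
  }
  amp <- function(es) {
    mid <- es$epochs[1, 1, ]
    mid <- mid[round(length(mid) * 0.2):round(length(mid) * 0.8)]
    (max(mid) - min(mid)) / 2
  }
  lo <- lowpass_resample(mk(5))
  expect_equal(lo$sfreq, 256)
  expect_equal(dim(lo$epochs)[3], ceiling(length(t) * 256 / 1000))
  expect_gt(20 * log10(amp(lo)), -1)
  hi <- lowpass_resample(mk(70))
  expect_lt(20 * log10(amp(hi)), -20)
  expect_error(lowpass_resample(mk(5), cutoff = 600), "twice the cut-off")
  expect_error(lowpass_resample(mk(5), cutoff = 120, out_rate = 200), "Nyquist")
})

test_that("matched averaging pairs each deviant with a position-matched standard", {
  ev <- build_session("LP", blocks = 1, melodies_per_block = 6, seed = 2)
  n_tr <- nrow(ev)
  ep <- array(0, c(n_tr, 2, 10))
  ep[, 1, ] <- ev$note_index  # encode position to verify matching
  es <- structure(list(epochs = ep, times = seq(0, 0.09, 0.01), sfreq = 100,
                       trials = ev), class = "epoch_set")
  out <- average_matched(es, feature = "pitch", seed = 7)
  n_dev <- sum(ev$feature == "pitch")
  expect_equal(out$meta$n_deviants, n_dev)
  expect_length(out$meta$matched_standards, n_dev)
  expect_equal(anyDuplicated(out$meta$matched_standards), 0)
  expect_true(all(ev$feature[out$meta$matched_standards] == "standard"))
  # with positions available, matched standards share the deviants' positions
  expect_setequal(ev$note_index[out$meta$matched_standards],
                  ev$note_index[ev$feature == "pitch"])
  # identical standard and deviant responses give a null difference wave
  expect_equal(out$deviant - out$standard,
               matrix(0, 2, 10), ignore_attr = TRUE)
  few <- es
  few$trials$feature[few$trials$feature == "standard"] <- "timbre"
  expect_error(average_matched(few, feature = "pitch"), "fewer standards")
})

test_that("averaging reduces white-noise SD as 1/sqrt(n)", {
  ev <- evoked_dataset(matrix(0, 2, 50), matrix(0, 2, 50),
                       times = seq(0, 49) / 256)
  es <- simulate_epochs(ev, n = 144, noise_sd = 1, seed = 8)
  out <- average_matched(es, feature = "pitch", seed = 1)
  # trial noise sd = sqrt(144); averaging 144 must return it to about 1
  expect_equal(sd(out$deviant), 1, tolerance = 0.2)
  expect_equal(sd(out$standard), 1, tolerance = 0.2)
})

test_that("crop-and-centre is window-true and idempotent", {
  tt <- seq(-0.1, 0.4, by = 1 / 256)
  ev <- with_fixed_seed(11, evoked_dataset(matrix(rnorm(10 * length(tt)) + 2, 10),
                                           matrix(rnorm(10 * length(tt)) - 1, 10),
                                           times = tt))
  cr <- crop_center(ev)
  expect_gte(min(cr$times), 0)
  expect_lte(max(cr$times), 0.3)
  expect_lt(max(abs(rowMeans(cr$standard))), 1e-12)
  cr2 <- crop_center(cr)
  expect_equal(cr2$standard, cr$standard)
  expect_equal(cr2$times, cr$times)
  expect_error(crop_center(ev, c(-1, 0.3)), "outside")
})

test_that("the evoked container round-trips through its on-disk form", {
  tt <- seq(0, 0.1, by = 1 / 256)
  ev <- with_fixed_seed(12, evoked_dataset(
    matrix(rnorm(5 * length(tt)), 5), matrix(rnorm(5 * length(tt)), 5),
    times = tt, channels = default_sensors()[1:5, ],
    meta = list(subject = "S01", condition = "HP", musicianship = "musician")))
  d <- file.path(tempdir(), "ev_roundtrip")
  write_evoked(ev, d)
  back <- read_evoked(d)
  expect_equal(back$standard, ev$standard, tolerance = 1e-12)
  expect_equal(back$deviant, ev$deviant, tolerance = 1e-12)
  expect_equal(back$times, ev$times, tolerance = 1e-12)
  expect_equal(back$meta$subject, "S01")
  ef <- tempfile(fileext = ".tsv")
  evs <- build_session("HP", blocks = 1, melodies_per_block = 1, seed = 1)
  write_events(evs, ef)
  expect_equal(read_events(ef)$midi, evs$midi)
})
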