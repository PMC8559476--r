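# Synthetic cohorts with known ground truth: true condition modulations
# drawn from the group GLM plus between-subject noise, and sensor-level
# evoked responses generated through the circuit and dipole forward model
# at a configurable signal-to-noise ratio.

#' Default cohort: two groups of twenty subjects
#'
#' @param n_per_group subjects per group (default from the study
#'   configuration: 20 musicians and 20 nonmusicians).
#' @return data frame with `subject` and `musicianship`.
#' @export
cohort_subjects <- function(n_per_group = cmc_defaults()$study$n_per_group) {
  data.frame(
    subject = sprintf("S%02d", seq_len(2 * n_per_group)),
    musicianship = rep(c("musician", "nonmusician"), each = n_per_group),
    stringsAsFactors = FALSE
  )
}

#' Simulate ground-truth condition modulations for a cohort
#'
#' Each design row's true B vector is `X_i beta_true` plus independent
#' Gaussian between-subject noise with standard deviation `re_sd`,
#' reproducible from the seed.
#'
#' @param design a `group_design`.
#' @param beta_true matrix of true effects, effects x B-parameters (rows
#'   named by design columns, columns by B-parameter names).
#' @param re_sd between-subject random-effects SD (log-scaling units).
#' @param seed integer seed.
#' @return object of class `"cohort_truth"`: the design, `beta_true`,
#'   `re_sd`, `seed` and the row-wise true modulations `B` (rows x
#'   parameters).
#' @export
simulate_cohort <- function(design, beta_true,
                            re_sd = cmc_defaults()$study$random_effects_sd,
                            seed = 1) {
  X <- design$X
  stopifnot(nrow(beta_true) == ncol(X))
  Bt <- with_seed(seed, {
    mu <- X %*% beta_true
    mu + matrix(stats::rnorm(length(mu), 0, re_sd), nrow(mu))
  })
  colnames(Bt) <- colnames(beta_true)
  structure(list(design = design, beta_true = beta_true, re_sd = re_sd,
                 seed = seed, B = Bt),
            class = "cohort_truth")
}

#' Synthesise sensor-level evoked datasets for a cohort
#'
#' Generates each design row's standard and deviant ERFs through the
#' canonical microcircuit and dipole forward model at the row's true
#' condition modulation, then adds white Gaussian sensor noise scaled so
#' that the cohort's grand-average difference-wave RMS over the residual
#' noise RMS equals `snr`.
#'
#' @param truth a `cohort_truth`.
#' @param network the `mmn_network` used for generation.
#' @param obs an `mmn_observation` for the network.
#' @param snr signal-to-noise ratio (grand-average difference-wave RMS /
#'   noise RMS), > 0.
#' @param seed integer seed for the noise.
#' @param times time grid (default the 0-300 ms analysis grid).
#' @param params optional baseline `cmc_params`.
#' @return list of `evoked_dataset` objects (one per design row, metadata
#'   in `meta`), with attributes `noise_sd` and `noiseless` (the
#'   noise-free predictions).
#' @export
synthesize_dataset <- function(truth, network, obs, snr = cmc_defaults()$study$snr,
                               seed = 1, times = dcm_times(), params = NULL) {
  stopifnot(snr > 0)
  params <- params %||% cmc_params(network)
  rows <- truth$design$rows
  n <- nrow(rows)
  clean <- vector("list", n)
  for (i in seq_len(n)) {
    B <- condition_modulation(network, values = truth$B[i, ])
    clean[[i]] <- predict_erf(params, B, obs, times)
  }
  diffs <- vapply(clean, function(pr) pr$deviant - pr$standard,
                  matrix(0, nrow(obs$L), length(times)))
  grand_diff <- apply(diffs, c(1, 2), mean)
  noise_sd <- sqrt(mean(grand_diff^2)) / snr
  out <- with_seed(seed, lapply(seq_len(n), function(i) {
    pr <- clean[[i]]
    evoked_dataset(
      standard = pr$standard + matrix(stats::rnorm(length(pr$standard), 0, noise_sd),
                                      nrow(pr$standard)),
      deviant = pr$deviant + matrix(stats::rnorm(length(pr$deviant), 0, noise_sd),
                                    nrow(pr$deviant)),
      times = times, channels = obs$sensors,
      meta = list(subject = rows$subject[i], musicianship = rows$musicianship[i],
                  condition = rows$condition[i], snr = snr, noise_sd = noise_sd)
    )
  }))
  attr(out, "noise_sd") <- noise_sd
  attr(out, "noiseless") <- clean
  out
}

#' Simulate trial-level epochs around an evoked response
#'
#' Emits single-trial epochs whose average reproduces the evoked response
#' at the given average-level noise SD: each trial adds white noise with
#' SD `noise_sd * sqrt(n)`. Used to exercise the preprocessing pipeline.
#'
#' @param evoked an `evoked_dataset` (noise-free or measured).
#' @param n trials per trial type.
#' @param noise_sd average-level noise SD.
#' @param seed integer seed.
#' @return an `epoch_set` with `n` standard and `n` pitch-deviant trials.
#' @export
simulate_epochs <- function(evoked, n = 144, noise_sd = 1, seed = 1) {
  n_ch <- nrow(evoked$standard)
  n_t <- length(evoked$times)
  trial_sd <- noise_sd * sqrt(n)
  with_seed(seed, {
    ep <- array(0, c(2 * n, n_ch, n_t))
    for (i in seq_len(n))
      ep[i, , ] <- evoked$standard + matrix(stats::rnorm(n_ch * n_t, 0, trial_sd), n_ch)
    for (i in seq_len(n))
      ep[n + i, , ] <- evoked$deviant + matrix(stats::rnorm(n_ch * n_t, 0, trial_sd), n_ch)
    structure(list(
      epochs = ep, times = evoked$times, sfreq = 1 / stats::median(diff(evoked$times)),
      trials = data.frame(feature = rep(c("standard", "pitch"), each = n),
                          note_index = rep(NA_integer_, 2 * n))
    ), class = "epoch_set")
  })
}
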