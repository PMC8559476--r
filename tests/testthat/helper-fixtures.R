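# Shared fixtures, built lazily and cached for the whole run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_net5 <- function() fx_get("net5", default_network)
fx_net3 <- function() fx_get("net3", reduced_network)
fx_obs3 <- function() fx_get("obs3", function() observation_model(fx_net3(), k = 4))
fx_obs5 <- function() fx_get("obs5", function() observation_model(fx_net5()))

# a fitted reduced-network dataset with known truth, reused across tests
fx_fit_example <- function() fx_get("fit_example", function() {
  net <- fx_net3()
  obs <- fx_obs3()
  p <- cmc_params(net)
  tt <- dcm_times()
  bn <- b_names(net)
  b_true <- stats::setNames(c(-0.5, -0.4, -0.45, -0.2, -0.3), bn)
  pr <- predict_erf(p, condition_modulation(net, b_true), obs, tt)
  noise_sd <- sqrt(mean((pr$deviant - pr$standard)^2)) / 5
  ev <- with_fixed_seed(99, evoked_dataset(
    pr$standard + matrix(rnorm(length(pr$standard), 0, noise_sd), nrow(pr$standard)),
    pr$deviant + matrix(rnorm(length(pr$deviant), 0, noise_sd), nrow(pr$deviant)),
    tt))
  fit <- suppressWarnings(
    fit_dcm(crop_center(ev), obs, default_priors(net),
            settings = dcm_settings(max_iter = 20)))
  list(net = net, obs = obs, b_true = b_true, fit = fit, evoked = ev,
       noise_sd = noise_sd)
})

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# first-level "fits" for PEB tests: exact Gaussian posteriors around given
# measurements, bypassing the integrator
make_linear_fits <- function(theta_obs, obs_var, prior_sd = 0.25, network) {
  bn <- b_names(network)
  priors <- default_priors(network)
  lapply(seq_len(nrow(theta_obs)), function(i) {
    v_post <- 1 / (1 / obs_var + 1 / prior_sd^2)
    mu <- v_post * theta_obs[i, ] / obs_var
    structure(list(
      b_mean = stats::setNames(mu, bn),
      b_cov = diag(v_post, length(bn), length(bn)) |>
        `dimnames<-`(list(bn, bn)),
      priors = priors
    ), class = "dcm_fit")
  })
}
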