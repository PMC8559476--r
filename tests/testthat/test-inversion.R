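test_that("default priors pin everything outside the model's freed set", {
  net <- fx_net5()
  space <- enumerate_models(net)
  pr_null <- default_priors(net, model = space[[1]])
  b_rows <- startsWith(pr_null$name, "B_")
  expect_true(all(pr_null$sd[b_rows] == 0))
  pr_full <- default_priors(net, model = space[[16]])
  expect_equal(sum(pr_full$sd[startsWith(pr_full$name, "B_")] > 0), 11)
  expect_true(all(pr_full$mean == 0 | startsWith(pr_full$name, "q_")))
  # prior-mean parameters generate identical standard and deviant responses
  obs <- fx_obs5()
  pr0 <- predict_erf(cmc_params(net), condition_modulation(net), obs)
  expect_equal(pr0$standard, pr0$deviant)
})

test_that("variational Laplace matches closed-form Bayesian linear regression", {
  set.seed(101)
  n <- 4; N <- 60
  G <- matrix(rnorm(N * n), N, n)
  th <- c(0.5, -0.3, 0.2, 0.1)
  sig <- 0.1
  y <- drop(G %*% th) + rnorm(N, 0, sig)
  pE <- setNames(rep(0, n), paste0("t", 1:n))
  pC <- diag(0.5, n)
  lam <- log(1 / sig^2)
  vl <- fit_vl(y, function(b) drop(G %*% b), pE, pC, hE = lam, hC = 1e-8)
  Sp <- solve(crossprod(G) / sig^2 + solve(pC))
  mp <- drop(Sp %*% crossprod(G, y) / sig^2)
  expect_lt(max(abs(vl$mu - mp)) / max(abs(mp)), 1e-3)
  expect_lt(max(abs(vl$Sigma - Sp)) / max(abs(Sp)), 1e-3)
  Cy <- sig^2 * diag(N) + G %*% pC %*% t(G)
  logZ <- -0.5 * (N * log(2 * pi) + determinant(Cy)$modulus +
                    drop(t(y) %*% solve(Cy, y)))
  expect_lt(abs(vl$F - logZ) / abs(logZ), 1e-3)
})

test_that("accepted-step free energy is non-decreasing and internally consistent", {
  fit <- fx_fit_example()$fit
  Fa <- fit$trace$F[fit$trace$accepted]
  expect_true(all(diff(Fa) >= 0))
  fe <- free_energy(fit)
  expect_identical(fe$F, fit$F)
  expect_equal(fe$accuracy - fe$kl_theta - fe$kl_lambda, fit$F)
})

test_that("posterior equals prior gives zero parameter KL", {
  vl <- list(mu = c(a = 0, b = 0), pE = c(a = 0, b = 0),
             pC = diag(0.25, 2), Sigma = diag(0.25, 2),
             lambda = 1, v_lambda = 4, hE = 1, hC = 4,
             e = rep(0, 10), y = rep(0, 10), J = matrix(0, 10, 2))
  fe <- free_energy(vl)
  expect_equal(fe$kl_theta, 0)
  expect_equal(fe$kl_lambda, 0)
  vl$Sigma <- matrix(0, 2, 2)
  expect_error(free_energy(vl), "singular")
})

test_that("an unused (zero-variance) parameter leaves the fit unchanged", {
  ex <- fx_fit_example()
  pr2 <- default_priors(ex$net, free = c("B", "tau"))
  pr2$sd[startsWith(pr2$name, "tau_")] <- 0   # declared but pinned
  fit2 <- suppressWarnings(fit_dcm(crop_center(ex$evoked), ex$obs, pr2,
                                   settings = dcm_settings(max_iter = 20)))
  expect_equal(fit2$F, ex$fit$F)
  expect_equal(fit2$b_mean, ex$fit$b_mean)
})

test_that("data generated at the prior mean are explained without leaving the prior", {
  net <- fx_net3()
  obs <- fx_obs3()
  p <- cmc_params(net)
  pr <- predict_erf(p, condition_modulation(net), obs)
  tiny <- 1e-4 * sd(pr$standard)
  ev <- with_fixed_seed(21, evoked_dataset(
    pr$standard + matrix(rnorm(length(pr$standard), 0, tiny), nrow(pr$standard)),
    pr$deviant + matrix(rnorm(length(pr$deviant), 0, tiny), nrow(pr$deviant)),
    pr$times))
  priors <- default_priors(net)
  fit <- suppressWarnings(fit_dcm(crop_center(ev), obs, priors,
                                  settings = dcm_settings(max_iter = 12)))
  # posterior stays within two prior SDs of the (zero) prior means
  expect_true(all(abs(fit$mu) <= 2 * 0.25))
  expect_gt(fit$residual_var_explained, 0.99)
})

test_that("shrinking the prior variance pulls the posterior toward the prior mean", {
  set.seed(77)
  G <- matrix(rnorm(30), 30, 1)
  y <- drop(G * 1.0) + rnorm(30, 0, 0.2)
  mus <- vapply(c(1, 0.1, 0.01), function(v) {
    fit_vl(y, function(b) drop(G %*% b), c(t1 = 0), diag(v, 1),
           hE = log(25), hC = 1e-8)$mu
  }, 0)
  expect_true(all(diff(abs(mus)) < 0))
})

test_that("parameter recovery across a synthetic group attains r >= 0.7", {
  # 20 fits at the reference SNR (difference wave ~5x residual noise)
  net <- fx_net3()
  obs <- fx_obs3()
  subjects <- cohort_subjects(5)
  design <- build_design(subjects)
  truth <- simulate_cohort(design, scenario_effects("deviance", net), seed = 31)
  data <- synthesize_dataset(truth, net, obs, seed = 32)
  priors <- default_priors(net)
  est <- t(vapply(data, function(ev) {
    suppressWarnings(fit_dcm(crop_center(ev), obs, priors,
                             settings = dcm_settings(max_iter = 12, conv_n = 2)))$b_mean
  }, numeric(length(b_names(net)))))
  expect_gte(cor(as.vector(truth$B), as.vector(est)), 0.7)
})

test_that("the five-source model fits with freed dipole parameters (smoke)", {
  net <- fx_net5()
  obs <- fx_obs5()
  p <- cmc_params(net)
  B <- condition_modulation(net, c(int_rA1 = -0.4, int_lA1 = -0.4))
  pr <- predict_erf(p, B, obs)
  noise_sd <- sqrt(mean((pr$deviant - pr$standard)^2)) / 5
  ev <- with_fixed_seed(55, evoked_dataset(
    pr$standard + matrix(rnorm(length(pr$standard), 0, noise_sd), nrow(pr$standard)),
    pr$deviant + matrix(rnorm(length(pr$deviant), 0, noise_sd), nrow(pr$deviant)),
    pr$times))
  priors <- default_priors(net, free = c("B", "obs"))
  fit <- suppressWarnings(fit_dcm(crop_center(ev), obs, priors,
                                  settings = dcm_settings(max_iter = 4, conv_n = 2)))
  expect_true(is.finite(fit$F))
  expect_gt(nrow(fit$trace), 1)
  expect_true(all(diff(fit$trace$F[fit$trace$accepted]) >= 0))
  # dipole moment-vector and location parameters took part in the fit
  expect_true(any(startsWith(names(fit$mu), "q_")))
  expect_true(any(startsWith(names(fit$mu), "loc_")))
  # the modulated intrinsic gains move in the disinhibition direction
  expect_lt(mean(fit$b_mean[c("int_rA1", "int_lA1")]), 0)
})

test_that("fits serialise to JSON and back", {
  fit <- fx_fit_example()$fit
  tf <- tempfile(fileext = ".json")
  write_dcm_fit(fit, tf)
  back <- read_dcm_fit(tf)
  expect_equal(back$b_mean, fit$b_mean, tolerance = 1e-12)
  expect_equal(back$b_cov, fit$b_cov, tolerance = 1e-12)
  expect_equal(back$F, fit$F, tolerance = 1e-12)
  expect_equal(attr(back$priors, "network")$nodes$name,
               fx_net3()$nodes$name)
})
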