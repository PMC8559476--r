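# a hand-built PEB result whose posterior equals its prior: every reduced
# model then has identical (zero) evidence
null_peb <- function(network = reduced_network()) {
  bp <- b_names(network)
  eff <- c("deviance", "predictability", "musicianship", "interaction")
  nm <- as.vector(outer(bp, eff, function(b, e) paste(e, b, sep = ":")))
  nb <- length(nm)
  structure(list(
    beta_mean = stats::setNames(rep(0, nb), nm),
    beta_cov = diag(0.0625, nb), beta0_mean = stats::setNames(rep(0, nb), nm),
    beta0_cov = diag(0.0625, nb),
    gamma = 0, gamma_var = 1, sigma_b = stats::setNames(rep(0.004, length(bp)), bp),
    F = 0, b_params = bp, effects = eff, network = network
  ), class = "peb_result")
}

test_that("the group design has two centred rows per subject and product interaction", {
  subjects <- cohort_subjects(20)
  d <- build_design(subjects)
  expect_equal(dim(d$X), c(80, 4))
  expect_equal(colnames(d$X),
               c("deviance", "predictability", "musicianship", "interaction"))
  expect_true(all(d$X[, "deviance"] == 1))
  expect_lt(abs(mean(d$X[, "predictability"])), 1e-12)
  expect_lt(abs(mean(d$X[, "musicianship"])), 1e-12)
  expect_equal(d$X[, "interaction"],
               d$X[, "predictability"] * d$X[, "musicianship"])
  expect_lt(abs(mean(d$X[, "interaction"])), 1e-12)
  expect_error(build_design(data.frame(subject = "S1", musicianship = "pianist")),
               "musician")
})

test_that("PEB reduces to a precision-weighted average in the single-effect case", {
  net <- fx_net3()
  bn <- b_names(net)
  set.seed(5)
  n <- 12
  theta <- matrix(rnorm(n * length(bn), 0.3, 0.2), n)
  obs_var <- 0.02
  fits <- make_linear_fits(theta, obs_var, network = net)
  subjects <- cohort_subjects(n / 4)  # any balanced grouping
  design <- build_design(subjects)
  g_fix <- 2
  peb <- fit_peb(fits, design, gamma_range = c(g_fix, g_fix))
  # closed form with the same fixed between-subject covariance
  v0 <- 0.0625
  sb <- exp(-g_fix) * v0 / 16
  lam <- 1 / obs_var                 # likelihood precision per entry
  w <- 1 / (1 / lam + sb)
  X <- design$X
  prior_prec <- 1 / 0.0625
  for (j in seq_along(bn)) {
    idx <- paste("deviance", bn[j], sep = ":")
    # per-parameter posterior over the 4 effects
    XtW <- t(X) %*% (w * X)
    post_prec <- XtW + diag(prior_prec, 4)
    post_mean <- solve(post_prec, t(X) %*% (w * theta[, j]))
    expect_equal(unname(peb$beta_mean[paste(colnames(X), bn[j], sep = ":")]),
                 unname(drop(post_mean)), tolerance = 1e-6)
  }
})

test_that("vanishing between-subject variance shrinks subjects to the group prediction", {
  net <- fx_net3()
  bn <- b_names(net)
  set.seed(6)
  theta <- matrix(rnorm(8 * length(bn), 0, 0.3), 8)
  fits <- make_linear_fits(theta, 0.05, network = net)
  design <- build_design(cohort_subjects(2))
  peb <- fit_peb(fits, design, gamma_range = c(12, 12))  # Sigma_b ~ 0
  subj <- peb_subject_effects(peb)
  bmat <- matrix(peb$beta_mean, length(bn), 4)
  pred <- design$X %*% t(bmat)
  expect_equal(unname(subj), unname(pred), tolerance = 1e-4)
})

test_that("PEB recovers the sign of group effects of at least 0.3 log-units", {
  net <- fx_net3()
  bn <- b_names(net)
  hits <- 0
  for (rep in 1:20) {
    set.seed(rep + 400)
    design <- build_design(cohort_subjects(5))
    beta_true <- matrix(0, 4, length(bn),
                        dimnames = list(colnames(design$X), bn))
    beta_true["deviance", "int_rA1"] <- -0.4
    beta_true["musicianship", "int_lA1"] <- 0.3
    theta <- design$X %*% beta_true + matrix(rnorm(20 * length(bn), 0, 0.15), 20)
    fits <- make_linear_fits(theta, 0.02, network = net)
    peb <- fit_peb(fits, design)
    ok <- peb$beta_mean["deviance:int_rA1"] < 0 &&
      peb$beta_mean["musicianship:int_lA1"] > 0
    hits <- hits + ok
  }
  expect_gte(hits / 20, 0.9)
})

test_that("a rank-deficient design is rejected with a clear error", {
  net <- fx_net3()
  fits <- make_linear_fits(matrix(0, 4, 5), 0.1, network = net)
  design <- build_design(cohort_subjects(1))
  design$X[, "musicianship"] <- design$X[, "predictability"]
  design$X[, "interaction"] <- 0.5 * design$X[, "predictability"]
  expect_error(fit_peb(fits, design), "rank deficient")
})

test_that("Bayesian model reduction is exact on a linear-Gaussian toy", {
  set.seed(9)
  n <- 3; N <- 40
  G <- matrix(rnorm(N * n), N, n)
  sig <- 0.15
  y <- drop(G %*% c(0.6, 0, -0.4)) + rnorm(N, 0, sig)
  evidence <- function(C0) {
    Cy <- sig^2 * diag(N) + G %*% C0 %*% t(G)
    -0.5 * drop(N * log(2 * pi) + determinant(Cy)$modulus +
                  t(y) %*% solve(Cy, y))
  }
  C_full <- diag(0.5, n)
  C_red <- diag(c(0.5, 1e-8, 0.5))   # second parameter pinned
  Sp <- solve(crossprod(G) / sig^2 + solve(C_full))
  mp <- drop(Sp %*% crossprod(G, y) / sig^2)
  bmr <- reduced_evidence(list(mean = mp, cov = Sp),
                          list(mean = rep(0, n), cov = C_full),
                          list(mean = rep(0, n), cov = C_red))
  expect_lt(abs(bmr$dF - (evidence(C_red) - evidence(C_full))), 1e-6)
  # identical prior: no change in evidence
  same <- reduced_evidence(list(mean = mp, cov = Sp),
                           list(mean = rep(0, n), cov = C_full),
                           list(mean = rep(0, n), cov = C_full))
  expect_equal(same$dF, 0, tolerance = 1e-10)
  expect_equal(same$mean, mp, tolerance = 1e-8)
  expect_error(reduced_evidence(list(mean = mp, cov = Sp),
                                list(mean = rep(0, n), cov = C_full),
                                list(mean = rep(0, n), cov = diag(1, n))),
               "not nested")
})

test_that("pruning a truly null parameter usually raises the evidence", {
  wins <- 0
  for (rep in 1:50) {
    set.seed(rep)
    G <- matrix(rnorm(30 * 2), 30, 2)
    y <- drop(G %*% c(0.8, 0)) + rnorm(30, 0, 0.2)
    C0 <- diag(0.5, 2)
    Sp <- solve(crossprod(G) / 0.04 + solve(C0))
    mp <- drop(Sp %*% crossprod(G, y) / 0.04)
    dF <- reduced_evidence(list(mean = mp, cov = Sp),
                           list(mean = c(0, 0), cov = C0),
                           list(mean = c(0, 0), cov = diag(c(0.5, 1e-8))))$dF
    wins <- wins + (dF > 0)
  }
  expect_gt(wins / 50, 0.5)
})

test_that("factor comparison is at chance for symmetric evidence and bounded in [0,1]", {
  peb <- null_peb()
  space <- enumerate_models(peb$network)
  for (fac in peb$effects) {
    cf <- compare_factor(peb, fac, space)
    expect_equal(cf$probability, 0.5, tolerance = 1e-6)
    expect_true(all(cf$models$post_prob >= 0 & cf$models$post_prob <= 1))
    for (fam in names(peb$network$families)) {
      expect_equal(compare_factor(peb, fac, space, family = fam)$probability,
                   0.5, tolerance = 1e-6)
    }
  }
  expect_error(compare_factor(peb, "age", space), "unknown factor")
})

test_that("family posteriors are uniform at 8/16 under flat evidence and can exceed 1 in total", {
  peb5 <- null_peb(fx_net5())
  space5 <- enumerate_models(fx_net5())
  fp <- family_posterior(peb5, "deviance", space5)
  expect_equal(fp$probability, rep(0.5, 4), tolerance = 1e-6)
  expect_gt(sum(fp$probability), 1)  # overlapping families
  expect_true(all(fp$probability >= 0 & fp$probability <= 1))
})

test_that("model averaging reduces to the reduced posterior for a single model", {
  peb <- null_peb()
  full_prior <- list(mean = peb$beta0_mean, cov = peb$beta0_cov)
  one <- bma_models(peb, list(full_prior))
  expect_equal(one$mean, unname(peb$beta_mean), tolerance = 1e-9)
  expect_equal(one$sd, sqrt(diag(peb$beta_cov)), tolerance = 1e-6)
  # equal-evidence two-model mixture averages the means
  peb2 <- null_peb()
  peb2$beta_mean[] <- 0.1
  m1 <- list(mean = peb2$beta0_mean, cov = peb2$beta0_cov)
  shifted <- peb2$beta0_mean; shifted[] <- 0.2
  m2 <- list(mean = shifted, cov = peb2$beta0_cov)
  mix <- bma_models(peb2, list(m1, m2))
  r1 <- reduced_evidence(list(mean = peb2$beta_mean, cov = peb2$beta_cov), m1, m1)
  r2 <- reduced_evidence(list(mean = peb2$beta_mean, cov = peb2$beta_cov), m1, m2)
  w <- exp(c(r1$dF, r2$dF)); w <- w / sum(w)
  expect_equal(mix$mean, drop(cbind(r1$mean, r2$mean) %*% w), tolerance = 1e-8)
})

test_that("credible intervals from model averaging attain nominal coverage", {
  # reduced-scale hierarchical replicates: truth drawn from the two-model
  # generative mixture (effect present or absent with equal probability)
  covered <- 0
  n_rep <- 100
  for (rep in seq_len(n_rep)) {
    set.seed(rep + 900)
    beta_sd <- 0.25; re_sd <- 0.1; s <- 0.05; n <- 12
    present <- rep %% 2 == 0
    beta_true <- if (present) rnorm(1, 0, beta_sd) else 0
    yobs <- beta_true + rnorm(n, 0, sqrt(re_sd^2 + s^2))
    # exact single-parameter "PEB": posterior under the full prior
    lik_prec <- n / (re_sd^2 + s^2)
    post_var <- 1 / (lik_prec + 1 / beta_sd^2)
    post_mean <- post_var * lik_prec * mean(yobs)
    peb <- structure(list(
      beta_mean = c(`deviance:b` = post_mean),
      beta_cov = matrix(post_var, 1, 1),
      beta0_mean = c(`deviance:b` = 0),
      beta0_cov = matrix(beta_sd^2, 1, 1),
      b_params = "b", effects = "deviance"
    ), class = "peb_result")
    mix <- bma_models(peb, list(
      list(mean = 0, cov = matrix(beta_sd^2, 1, 1)),
      list(mean = 0, cov = matrix(1e-8, 1, 1))
    ))
    covered <- covered + (beta_true >= mix$ci_lower && beta_true <= mix$ci_upper)
  }
  expect_gte(covered / n_rep, 0.90)
  expect_lte(covered / n_rep, 1.00)
})

test_that("greedy reduction prunes null effects, keeps large ones, and ignores ordering", {
  net <- fx_net3()
  bn <- b_names(net)
  prune_rates <- c(); keep_hits <- 0
  for (rep in 1:10) {
    set.seed(rep + 50)
    design <- build_design(cohort_subjects(5))
    beta_true <- matrix(0, 4, length(bn), dimnames = list(colnames(design$X), bn))
    beta_true["deviance", "int_rA1"] <- -0.6
    theta <- design$X %*% beta_true + matrix(rnorm(20 * length(bn), 0, 0.1), 20)
    fits <- make_linear_fits(theta, 0.02, network = net)
    peb <- fit_peb(fits, design)
    red <- bmr_greedy(peb)
    is_null <- !(red$factor == "deviance" & red$parameter == "int_rA1")
    prune_rates <- c(prune_rates, mean(!red$retained[is_null]))
    keep_hits <- keep_hits +
      (red$retained[!is_null] && red$probability[!is_null] > 0.9)
    expect_true(all(red$mean[!red$retained] == 0))
  }
  expect_gte(mean(prune_rates), 0.9)
  expect_gte(keep_hits / 10, 0.9)
  # permutation invariance: permuting the parameter order permutes the result
  set.seed(1234)
  design <- build_design(cohort_subjects(4))
  beta_true <- matrix(0, 4, length(bn), dimnames = list(colnames(design$X), bn))
  beta_true["deviance", "int_lA1"] <- -0.5
  theta <- design$X %*% beta_true + matrix(rnorm(16 * length(bn), 0, 0.1), 16)
  fits <- make_linear_fits(theta, 0.02, network = net)
  peb <- fit_peb(fits, design)
  red <- bmr_greedy(peb)
  perm <- rev(seq_along(peb$beta_mean))
  peb_p <- peb
  peb_p$beta_mean <- peb$beta_mean[perm]
  peb_p$beta_cov <- peb$beta_cov[perm, perm]
  peb_p$beta0_mean <- peb$beta0_mean[perm]
  peb_p$beta0_cov <- peb$beta0_cov[perm, perm]
  red_p <- bmr_greedy(peb_p)
  kept <- names(peb$beta_mean)[attr(red, "kept")]
  kept_p <- names(peb_p$beta_mean)[attr(red_p, "kept")]
  expect_setequal(kept, kept_p)
})
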