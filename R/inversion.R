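# Single-subject variational-Laplace inversion: Gaussian shrinkage priors
# over log-scaling parameters, Gauss-Newton optimisation of a free-energy
# bound with Levenberg-Marquardt safeguarding, and a Gaussian noise model
# with one shared log-precision over spatial modes.

#' Default priors for a DCM
#'
#' Zero-mean Gaussian priors over the log-scaling parameters of the model.
#' Condition-modulation (B) parameters freed by the model carry variance
#' 1/16; B entries outside the model's freed set and every structurally
#' absent parameter are pinned (zero variance). Optional parameter families
#' (`free`) extend the free set beyond B: baseline extrinsic log-scalings
#' (`"A"`), intrinsic gains (`"G"`), input gains (`"C"`), time-constant
#' scalings (`"tau"`), thalamic input timing (`"input"`) and dipole
#' moment-vectors/locations (`"obs"`).
#'
#' @param network an `mmn_network`.
#' @param model a model definition from [enumerate_models()]; default the
#'   full model (all B-parameters freed).
#' @param free character vector of additional free parameter families.
#' @param b_sd prior standard deviation of freed B-parameters.
#' @return object of class `"prior_spec"`: data frame (`name`, `mean`,
#'   `sd`) with attributes `lambda` (hyperprior on the log noise
#'   precision) and `network`.
#' @export
default_priors <- function(network, model = NULL, free = "B", b_sd = 0.25) {
  bn <- b_names(network)
  freed <- if (is.null(model)) bn else intersect(bn, model$b_free)
  rows <- list(data.frame(
    name = paste0("B_", bn), mean = 0,
    sd = ifelse(bn %in% freed & "B" %in% free, b_sd, 0)
  ))
  fe <- network$forward; be <- network$backward
  a_names <- c(if (nrow(fe)) paste0("A_fwd_", fe$from, "_", fe$to),
               if (nrow(be)) paste0("A_bwd_", be$from, "_", be$to))
  rows <- c(rows, list(data.frame(
    name = a_names, mean = 0, sd = if ("A" %in% free) 0.25 else 0)))
  rows <- c(rows, list(data.frame(
    name = paste0("G_", network$nodes$name), mean = 0,
    sd = if ("G" %in% free) 0.25 else 0)))
  inp <- network$nodes$name[network$nodes$receives_input]
  rows <- c(rows, list(data.frame(
    name = paste0("C_", inp), mean = 0, sd = if ("C" %in% free) 0.25 else 0)))
  rows <- c(rows, list(data.frame(
    name = paste0("tau_", cmc_populations), mean = 0,
    sd = if ("tau" %in% free) 0.125 else 0)))
  rows <- c(rows, list(data.frame(
    name = c("u_latency", "u_width"), mean = 0,
    sd = if ("input" %in% free) 0.125 else 0)))
  cfg <- cmc_defaults()$observation
  pairs <- dipole_pairs(network)
  mom <- cfg$dipole_moment_nAm
  ori <- c(0, 0.6, 0.8) * mom
  obs_rows <- do.call(rbind, lapply(names(pairs), function(pn) {
    rbind(
      data.frame(name = paste0("q_", pn, "_", c("x", "y", "z")),
                 mean = ori, sd = if ("obs" %in% free) 0.5 * mom else 0),
      data.frame(name = paste0("loc_", pn, "_", c("x", "y", "z")),
                 mean = 0,
                 sd = if ("obs" %in% free) cfg$location_prior_sd_m else 0)
    )
  }))
  rows <- c(rows, list(obs_rows))
  pr <- do.call(rbind, rows)
  rownames(pr) <- NULL
  structure(pr, lambda = list(mean = 0, sd = 4), network = network,
            class = c("prior_spec", "data.frame"))
}

# symmetric dipole pairs: one parameter block per left/right pair (keyed by
# the stem) plus one block per unpaired source
dipole_pairs <- function(network) {
  nm <- network$nodes$name
  stem <- sub("^[lr]", "", nm)
  out <- list()
  for (st in unique(stem)) {
    members <- nm[stem == st]
    out[[if (length(members) > 1) st else members[1]]] <- members
  }
  out
}

#' Inversion settings
#'
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol free-energy convergence tolerance (nats).
#' @param conv_n consecutive small accepted improvements required.
#' @param fd_frac finite-difference step as a fraction of the prior SD.
#' @return list of settings.
#' @export
dcm_settings <- function(max_iter = 64, tol = 0.01, conv_n = 3,
                         fd_frac = 1 / 16) {
  list(max_iter = max_iter, tol = tol, conv_n = conv_n, fd_frac = fd_frac)
}

#' Variational-Laplace fit of a nonlinear Gaussian model
#'
#' Fits `y = g(theta) + e`, `e ~ N(0, exp(-lambda) I)`, with Gaussian
#' priors on `theta` and on the log noise precision `lambda`, by
#' Gauss-Newton ascent on the variational free energy with
#' Levenberg-Marquardt regularisation. Steps that would decrease the free
#' energy are rejected and the regulariser increased, so the accepted-step
#' free-energy sequence is non-decreasing.
#'
#' @param y data vector.
#' @param g prediction function taking a named parameter vector.
#' @param pE,pC prior mean vector and covariance matrix (free parameters
#'   only).
#' @param hE,hC hyperprior mean and variance of `lambda`.
#' @param settings from [dcm_settings()].
#' @param jacobian optional analytic Jacobian function (used by the
#'   linear-model oracle tests); default central finite differences with
#'   per-parameter steps scaled to the prior SD.
#' @return list: posterior mean `mu` and covariance `Sigma`, noise
#'   posterior `lambda`/`v_lambda`, free energy `F`, per-iteration `trace`
#'   (`F`, `accepted`), `converged`, residuals `e`, Jacobian `J`.
#' @export
fit_vl <- function(y, g, pE, pC, hE = 0, hC = 16,
                   settings = dcm_settings(), jacobian = NULL) {
  n <- length(pE)
  N <- length(y)
  P0 <- sym_inv(pC)
  sd0 <- sqrt(diag(pC))
  fd <- pmax(sd0 * settings$fd_frac, 1e-6)
  numj <- function(mu) {
    g0 <- NULL
    J <- matrix(0, N, n)
    for (j in seq_len(n)) {
      up <- mu; up[j] <- up[j] + fd[j]
      dn <- mu; dn[j] <- dn[j] - fd[j]
      J[, j] <- (g(up) - g(dn)) / (2 * fd[j])
    }
    J
  }
  jac <- jacobian %||% numj

  lambda <- hE
  mu <- pE
  state_F <- function(mu, lambda, v_lambda, e, J, Sigma) {
    Pi <- exp(lambda)
    S <- sum(e^2) + sum(Sigma * crossprod(J))
    acc <- -0.5 * Pi * S + 0.5 * N * lambda - 0.5 * N * log(2 * pi)
    d <- mu - pE
    klt <- 0.5 * (sum(P0 * Sigma) + drop(t(d) %*% P0 %*% d) - n +
                    sym_logdet(pC) - sym_logdet(Sigma))
    kll <- 0.5 * (v_lambda / hC + (lambda - hE)^2 / hC - 1 +
                    log(hC / v_lambda))
    list(F = acc - klt - kll, accuracy = acc, kl_theta = klt, kl_lambda = kll)
  }

  best <- NULL
  rho <- 1e-4
  trace <- data.frame(F = numeric(0), accepted = logical(0))
  small_steps <- 0
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    e <- y - g(mu)
    if (!all(is.finite(e))) {
      if (is.null(best)) stopf("non-finite prediction at the prior mean")
      ok <- FALSE
    } else {
      J <- jac(mu)
      JJ <- crossprod(J)
      # alternate noise and covariance updates (concave in lambda)
      for (r in 1:4) {
        Sigma <- sym_inv(exp(lambda) * JJ + P0)
        S <- sum(e^2) + sum(Sigma * JJ)
        for (nw in 1:8) {
          g1 <- -0.5 * exp(lambda) * S + 0.5 * N - (lambda - hE) / hC
          g2 <- -0.5 * exp(lambda) * S - 1 / hC
          step <- g1 / g2
          lambda <- lambda - max(min(step, 4), -4)
          if (abs(step) < 1e-6) break
        }
      }
      v_lambda <- 1 / (0.5 * exp(lambda) * S + 1 / hC)
      Fs <- state_F(mu, lambda, v_lambda, e, J, Sigma)
      ok <- is.finite(Fs$F) && (is.null(best) || Fs$F > best$F)
    }
    if (ok) {
      dF <- if (is.null(best)) Inf else Fs$F - best$F
      best <- list(mu = mu, Sigma = Sigma, lambda = lambda,
                   v_lambda = v_lambda, F = Fs$F, parts = Fs, e = e, J = J,
                   JJ = JJ)
      trace <- rbind(trace, data.frame(F = Fs$F, accepted = TRUE))
      rho <- max(rho / 4, 1e-8)
      small_steps <- if (dF < settings$tol) small_steps + 1 else 0
      if (small_steps >= settings$conv_n) { converged <- TRUE; break }
    } else {
      trace <- rbind(trace, data.frame(
        F = if (exists("Fs", inherits = FALSE) && is.finite(Fs$F)) Fs$F else NA_real_,
        accepted = FALSE))
      rho <- rho * 8
      lambda <- best$lambda
      if (rho > 1e8) break
    }
    H <- exp(best$lambda) * best$JJ + P0
    grad <- exp(best$lambda) * crossprod(best$J, best$e) - P0 %*% (best$mu - pE)
    R <- H + rho * diag(pmax(diag(H), 1e-10), n)
    mu <- stats::setNames(best$mu + drop(solve(R, grad)), names(pE))
  }
  names(best$mu) <- names(pE)
  c(best, list(trace = trace, converged = converged, n_iter = it,
               y = y, pE = pE, pC = pC, hE = hE, hC = hC))
}

#' Fit a DCM to one subject-condition dataset
#'
#' Inverts the canonical-microcircuit network model on a mean-centred
#' 0-300 ms evoked dataset: standard and deviant responses are fitted
#' jointly, with the standard generated by the baseline connectivity and
#' the deviant by the baseline plus the condition modulation B. Sensor
#' data are reduced to `obs$k` leading spatial modes and rescaled to unit
#' variance before inversion; the fit is deterministic given data, priors
#' and settings.
#'
#' @param data an `evoked_dataset` (cropped and centred, see
#'   [crop_center()]).
#' @param obs an `mmn_observation` for the network.
#' @param priors a `prior_spec` from [default_priors()].
#' @param params optional baseline `cmc_params` (defaults to
#'   `cmc_params(network)`).
#' @param settings from [dcm_settings()].
#' @return object of class `"dcm_fit"`: named posterior means (`mu`) and
#'   covariance over free parameters, the full B posterior (`b_mean`,
#'   `b_cov`) in canonical order with pinned entries at zero, noise
#'   posterior, free energy and trace, channel-space predictions, and a
#'   convergence flag (non-convergence warns but returns a usable fit).
#' @export
fit_dcm <- function(data, obs, priors, params = NULL,
                    settings = dcm_settings()) {
  network <- attr(priors, "network")
  params <- params %||% cmc_params(network)
  k <- obs$k
  red <- reduce_spatial_modes(list(data$standard, data$deviant), k)
  U <- red$projector
  center <- function(m) m - rowMeans(m)
  y_modes <- lapply(red$scores, center)
  scale_ <- stats::sd(unlist(y_modes))
  if (scale_ <= 0) stopf("data have zero variance")
  y <- c(y_modes[[1]], y_modes[[2]]) / scale_
  free <- priors$sd > 0
  pE <- stats::setNames(priors$mean[free], priors$name[free])
  pC <- diag(priors$sd[free]^2, sum(free))
  g <- dcm_predictor(network, obs, params, priors, U, data$times, scale_)
  lam <- attr(priors, "lambda")
  vl <- fit_vl(y, g, pE, pC, hE = lam$mean, hC = lam$sd^2, settings = settings)
  if (!vl$converged)
    warning("fit did not converge within the iteration limit; returning the best iterate")
  bn <- b_names(network)
  b_mean <- stats::setNames(rep(0, length(bn)), bn)
  bidx <- match(paste0("B_", bn), names(pE))
  b_mean[!is.na(bidx)] <- vl$mu[stats::na.omit(bidx)]
  b_cov <- matrix(0, length(bn), length(bn), dimnames = list(bn, bn))
  have <- which(!is.na(bidx))
  b_cov[have, have] <- vl$Sigma[stats::na.omit(bidx), stats::na.omit(bidx)]
  pred_modes <- g(vl$mu) * scale_
  Tn <- length(data$times)
  pred <- list(
    standard = U %*% matrix(pred_modes[seq_len(k * Tn)], k, Tn),
    deviant = U %*% matrix(pred_modes[k * Tn + seq_len(k * Tn)], k, Tn)
  )
  structure(list(
    mu = vl$mu, Sigma = vl$Sigma, lambda = vl$lambda,
    v_lambda = vl$v_lambda, F = vl$F, F_parts = vl$parts,
    trace = vl$trace, converged = vl$converged,
    b_mean = b_mean, b_cov = b_cov,
    priors = priors, settings = settings, scale = scale_,
    projector = U, predicted = pred, times = data$times,
    residual_var_explained = 1 - sum(vl$e^2) / sum(vl$y^2),
    meta = data$meta, vl = vl
  ), class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> F = %.2f nats, %d free parameters, %s\n",
              x$F, length(x$mu),
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  variance explained: %.1f%%; noise log-precision %.2f\n",
              100 * x$residual_var_explained, x$lambda))
  invisible(x)
}

# Build the prediction function mapping a named free-parameter vector to
# the concatenated, centred, scaled mode-space (standard, deviant) pair.
dcm_predictor <- function(network, obs, base_params, priors, U, times, scale_) {
  bn <- b_names(network)
  all_names <- priors$name
  cfg <- cmc_defaults()
  pairs <- dipole_pairs(network)
  has_obs <- any(priors$sd[startsWith(all_names, "q_") |
                            startsWith(all_names, "loc_")] > 0)
  L_red0 <- t(U) %*% obs$L
  function(theta) {
    gp <- function(nm, default = 0) if (nm %in% names(theta)) theta[[nm]] else default
    p <- base_params
    for (nd in network$nodes$name) p$G[nd] <- p$G[nd] + gp(paste0("G_", nd))
    fe <- network$forward
    for (i in seq_len(nrow(fe)))
      p$AF[fe$to[i], fe$from[i]] <- p$AF[fe$to[i], fe$from[i]] +
        gp(paste0("A_fwd_", fe$from[i], "_", fe$to[i]))
    be <- network$backward
    for (i in seq_len(nrow(be)))
      p$AB[be$to[i], be$from[i]] <- p$AB[be$to[i], be$from[i]] +
        gp(paste0("A_bwd_", be$from[i], "_", be$to[i]))
    for (nd in names(p$C)[p$C != 0])
      p$C[nd] <- p$C[nd] * exp(gp(paste0("C_", nd)))
    for (pop in cmc_populations)
      p$tau[pop] <- p$tau[pop] * exp(gp(paste0("tau_", pop)))
    input <- list(peak_s = cfg$input$peak_s * exp(gp("u_latency")),
                  width_s = cfg$input$width_s * exp(gp("u_width")))
    bvals <- stats::setNames(vapply(bn, function(b) gp(paste0("B_", b)), 0), bn)
    B <- condition_modulation(network, values = bvals)
    y_std <- integrate_cmc(p, times, input = input)
    y_dev <- integrate_cmc(p, times, B = B, deviant = TRUE, input = input)
    L_red <- if (has_obs) {
      t(U) %*% rebuild_gain(network, obs, pairs, theta)
    } else L_red0
    m_std <- L_red %*% t(y_std)
    m_dev <- L_red %*% t(y_dev)
    c(m_std - rowMeans(m_std), m_dev - rowMeans(m_dev)) / scale_
  }
}

# Rebuild the dipole gain matrix from free moment-vector / location
# parameters, mirroring paired sources through the sagittal plane.
rebuild_gain <- function(network, obs, pairs, theta) {
  nodes <- network$nodes
  dip <- obs$dipoles
  gp <- function(nm, default) if (nm %in% names(theta)) theta[[nm]] else default
  for (pn in names(pairs)) {
    members <- pairs[[pn]]
    q0 <- c(dip$ox[dip$name == members[1]], dip$oy[dip$name == members[1]],
            dip$oz[dip$name == members[1]]) * dip$moment[dip$name == members[1]]
    q <- c(gp(paste0("q_", pn, "_x"), q0[1]),
           gp(paste0("q_", pn, "_y"), q0[2]),
           gp(paste0("q_", pn, "_z"), q0[3]))
    dl <- c(gp(paste0("loc_", pn, "_x"), 0),
            gp(paste0("loc_", pn, "_y"), 0),
            gp(paste0("loc_", pn, "_z"), 0))
    for (m in members) {
      i <- which(dip$name == m)
      mirror <- nodes$hemisphere[nodes$name == m] == "right" && length(members) > 1
      s <- if (mirror) c(-1, 1, 1) else c(1, 1, 1)
      qm <- q * s
      dip$x[i] <- dip$x[i] + dl[1] * s[1]
      dip$y[i] <- dip$y[i] + dl[2]
      dip$z[i] <- dip$z[i] + dl[3]
      nrm <- sqrt(sum(qm^2))
      dip$ox[i] <- qm[1] / nrm; dip$oy[i] <- qm[2] / nrm; dip$oz[i] <- qm[3] / nrm
      dip$moment[i] <- nrm
    }
  }
  build_gain(dip, obs$sensors, center = obs$center, head_radius = obs$head_radius)
}

#' Free energy of a fitted model
#'
#' Recomputes the variational free energy of a fit from its posterior:
#' the expected Gaussian log-likelihood (accuracy) minus the
#' Kullback-Leibler divergences of the parameter and noise posteriors from
#' their priors. Equals the optimiser's internal final value exactly.
#'
#' @param fit a `dcm_fit` or the list returned by [fit_vl()].
#' @return list: `F`, `accuracy`, `kl_theta`, `kl_lambda`.
#' @export
free_energy <- function(fit) {
  vl <- if (inherits(fit, "dcm_fit")) fit$vl else fit
  n <- length(vl$mu)
  N <- length(vl$y)
  Sigma <- vl$Sigma
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stopf("singular posterior covariance")
  JJ <- crossprod(vl$J)
  S <- sum(vl$e^2) + sum(Sigma * JJ)
  acc <- -0.5 * exp(vl$lambda) * S + 0.5 * N * vl$lambda - 0.5 * N * log(2 * pi)
  d <- vl$mu - vl$pE
  P0 <- sym_inv(vl$pC)
  klt <- 0.5 * (sum(P0 * Sigma) + drop(t(d) %*% P0 %*% d) - n +
                  sym_logdet(vl$pC) - sym_logdet(Sigma))
  kll <- 0.5 * (vl$v_lambda / vl$hC + (vl$lambda - vl$hE)^2 / vl$hC - 1 +
                  log(vl$hC / vl$v_lambda))
  list(F = acc - klt - kll, accuracy = acc, kl_theta = klt, kl_lambda = kll)
}
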