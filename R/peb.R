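# Group-level parametric empirical Bayes over first-level condition
# modulations (B), with Bayesian model reduction, family inference and
# Bayesian model averaging.  The second level is a Gaussian GLM over the
# first-level posteriors: theta_i = X_i beta + eps_i, with an estimated
# between-subject precision hyperparameter.

#' Build the group-level design matrix
#'
#' Two rows per subject (one per predictability condition), four columns:
#' a constant modelling the average condition modulation (the stimulus
#' deviance / MMN effect, since B-parameters already encode the
#' standard-to-deviant change), melodic predictability, musicianship, and
#' their interaction. Non-constant columns are mean-centred and the
#' interaction is the product of the centred factors.
#'
#' @param subjects data frame with columns `subject` and `musicianship`
#'   (`"musician"` / `"nonmusician"`).
#' @param conditions condition labels; every subject contributes one row
#'   per condition (default HP, LP).
#' @return object of class `"group_design"`: design matrix `X` (rows x 4)
#'   and `rows` (subject, musicianship, condition per row).
#' @export
build_design <- function(subjects, conditions = c("HP", "LP")) {
  stopifnot(all(c("subject", "musicianship") %in% names(subjects)))
  if (anyNA(match(subjects$musicianship, c("musician", "nonmusician"))))
    stopf("musicianship must be 'musician' or 'nonmusician'")
  rows <- merge(subjects, data.frame(condition = conditions), by = NULL)
  rows <- rows[order(match(rows$subject, subjects$subject),
                     match(rows$condition, conditions)), ]
  per_subj <- table(rows$subject)
  if (any(per_subj != length(conditions)))
    stopf("every subject must contribute all conditions")
  pred <- ifelse(rows$condition == conditions[1], 0.5, -0.5)
  mus <- ifelse(rows$musicianship == "musician", 0.5, -0.5)
  pred <- pred - mean(pred)
  mus <- mus - mean(mus)
  X <- cbind(deviance = 1, predictability = pred, musicianship = mus,
             interaction = pred * mus)
  rownames(X) <- NULL
  structure(list(X = X, rows = rows[, c("subject", "musicianship", "condition")]),
            class = "group_design")
}

#' Fit a parametric-empirical-Bayes model over first-level fits
#'
#' Treats each first-level posterior over the freed B-parameters as data
#' for the group GLM. First-level likelihood precisions are recovered from
#' the posteriors by subtracting the prior precision; the between-subject
#' covariance is `exp(-gamma) * V` with `V` the B prior covariance divided
#' by 16 and `gamma` estimated by maximising the (exact, linear-Gaussian)
#' second-level free energy under a standard-normal hyperprior.
#'
#' @param fits list of `dcm_fit` objects, one per design row, in order.
#' @param design a `group_design`; rank deficiency is an error.
#' @param beta_sd prior standard deviation of second-level effects.
#' @param gamma_range search interval for the log precision-scaling.
#' @return object of class `"peb_result"`: `beta_mean` / `beta_cov`
#'   (effects stacked parameter-fastest), prior (`beta0_cov`), `gamma`,
#'   `gamma_var`, between-subject variances `sigma_b`, free energy `F`,
#'   parameter and effect names, the design, and the network.
#' @export
fit_peb <- function(fits, design, beta_sd = 0.25, gamma_range = c(-6, 6)) {
  X <- design$X
  if (qr(X)$rank < ncol(X))
    stopf("design matrix is rank deficient (check columns: %s)",
          paste(colnames(X), collapse = ", "))
  n <- length(fits)
  stopifnot(n == nrow(X))
  pr <- fits[[1]]$priors
  bsel <- startsWith(pr$name, "B_") & pr$sd > 0
  b_par <- sub("^B_", "", pr$name[bsel])
  p <- length(b_par)
  m <- ncol(X)
  v0 <- pr$sd[bsel]^2
  # first-level likelihood summaries
  Lam <- vector("list", n); rvec <- vector("list", n)
  P0 <- diag(1 / v0, p)
  for (i in seq_len(n)) {
    fi <- fits[[i]]
    idx <- match(b_par, names(fi$b_mean))
    Si <- fi$b_cov[idx, idx, drop = FALSE]
    mui <- fi$b_mean[idx]
    Pi <- sym_inv(Si)
    L <- Pi - P0
    es <- eigen((L + t(L)) / 2, symmetric = TRUE)
    L <- es$vectors %*% diag(pmax(es$values, 0), p) %*% t(es$vectors)
    Lam[[i]] <- L
    rvec[[i]] <- drop(Pi %*% mui)   # prior mean is zero
  }
  V <- diag(v0 / 16, p)
  B0 <- diag(beta_sd^2, m * p)
  B0inv <- diag(1 / beta_sd^2, m * p)
  Ip <- diag(1, p)

  evidence <- function(gamma) {
    Sb <- exp(-gamma) * V
    Sbinv <- diag(1 / diag(Sb), p)
    Q <- matrix(0, m * p, m * p)
    u <- numeric(m * p)
    const <- 0
    for (i in seq_len(n)) {
      L <- Lam[[i]]; r <- rvec[[i]]
      A <- Ip + Sb %*% L                 # (I + Sb Lam)
      W <- L %*% solve(A)                # likelihood precision seen by beta
      W <- (W + t(W)) / 2
      M <- L + Sbinv
      const <- const - 0.5 * determinant(A)$modulus +
        0.5 * drop(t(r) %*% solve(M, r))
      wi <- drop(solve(t(A), r))         # (I + Lam Sb)^{-1} r
      xi <- X[i, ]
      Q <- Q + kronecker(tcrossprod(xi), W)
      u <- u + kronecker(xi, wi)
    }
    Pp <- Q + B0inv
    mb <- solve(Pp, u)
    Fg <- const - 0.5 * (determinant(diag(1, m * p) + B0 %*% Q)$modulus) +
      0.5 * drop(t(u) %*% mb) + stats::dnorm(gamma, 0, 1, log = TRUE)
    list(F = as.numeric(Fg), beta_mean = drop(mb), beta_cov = sym_inv(Pp))
  }
  gamma <- if (diff(range(gamma_range)) <= 0) gamma_range[1] else
    stats::optimize(function(g) evidence(g)$F, gamma_range, maximum = TRUE)$maximum
  fin <- evidence(gamma)
  eps <- 1e-3
  d2 <- (evidence(gamma + eps)$F - 2 * fin$F + evidence(gamma - eps)$F) / eps^2
  gamma_var <- if (d2 < 0) -1 / d2 else Inf
  nm <- as.vector(outer(b_par, colnames(X), function(b, e) paste(e, b, sep = ":")))
  beta_mean <- stats::setNames(fin$beta_mean, nm)
  beta_cov <- fin$beta_cov
  dimnames(beta_cov) <- list(nm, nm)
  structure(list(
    beta_mean = beta_mean, beta_cov = beta_cov,
    beta0_mean = stats::setNames(rep(0, m * p), nm),
    beta0_cov = `dimnames<-`(B0, list(nm, nm)),
    gamma = gamma, gamma_var = gamma_var,
    sigma_b = stats::setNames(exp(-gamma) * diag(V), b_par),
    F = fin$F, b_params = b_par, effects = colnames(X),
    design = design, network = attr(pr, "network"),
    first_level = list(Lam = Lam, r = rvec)
  ), class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf("<peb_result> %d effects x %d B-parameters over %d first-level fits\n",
              length(x$effects), length(x$b_params), nrow(x$design$X)))
  cat(sprintf("  F = %.2f, between-subject SD (gamma = %.2f): %.3f\n",
              x$F, x$gamma, sqrt(mean(x$sigma_b))))
  invisible(x)
}

#' Empirical-Bayes subject-level estimates
#'
#' Re-estimates each first-level B vector under the empirical prior
#' `N(X_i beta, Sigma_b)` implied by the group model: the posterior
#' precision-weighted combination of the subject's likelihood and the
#' group prediction. As the between-subject variance goes to zero every
#' subject shrinks to its group-predicted value.
#'
#' @param peb a `peb_result`.
#' @return matrix, design rows x B-parameters.
#' @export
peb_subject_effects <- function(peb) {
  p <- length(peb$b_params)
  m <- length(peb$effects)
  Sb_inv <- diag(1 / peb$sigma_b, p)
  X <- peb$design$X
  beta_mat <- matrix(peb$beta_mean, p, m)   # param-fast layout
  out <- matrix(0, nrow(X), p, dimnames = list(NULL, peb$b_params))
  for (i in seq_len(nrow(X))) {
    mu_i <- drop(beta_mat %*% X[i, ])
    L <- peb$first_level$Lam[[i]]
    out[i, ] <- drop(solve(L + Sb_inv,
                           peb$first_level$r[[i]] + Sb_inv %*% mu_i))
  }
  out
}

# variance used to pin a parameter in a reduced prior
.pin_var <- 1e-8

#' Analytic evidence change for a reduced prior (Bayesian model reduction)
#'
#' Given a Gaussian posterior obtained under a Gaussian prior, computes the
#' change in log evidence (and the reduced posterior) if the prior is
#' replaced by a nested one with shrunk or pinned variances, without
#' refitting.
#'
#' @param posterior,prior,reduced_prior lists with `mean` and `cov`.
#' @return list: `dF`, `mean`, `cov` (reduced posterior).
#' @export
reduced_evidence <- function(posterior, prior, reduced_prior) {
  if (any(diag(as.matrix(reduced_prior$cov)) >
            diag(as.matrix(prior$cov)) + 1e-12))
    stopf("reduced prior is not nested in the prior (a variance increased)")
  P <- sym_inv(as.matrix(posterior$cov))
  P0 <- sym_inv(as.matrix(prior$cov))
  Pr <- sym_inv(as.matrix(reduced_prior$cov))
  Ps <- P + Pr - P0
  rhs <- drop(P %*% posterior$mean + Pr %*% reduced_prior$mean -
                P0 %*% prior$mean)
  ms <- drop(solve(Ps, rhs))
  dF <- 0.5 * (sym_logdet(Pr) - sym_logdet(P0) + sym_logdet(P) - sym_logdet(Ps)) +
    0.5 * (drop(t(ms) %*% Ps %*% ms) -
             drop(t(posterior$mean) %*% P %*% posterior$mean) +
             drop(t(prior$mean) %*% P0 %*% prior$mean) -
             drop(t(reduced_prior$mean) %*% Pr %*% reduced_prior$mean))
  list(dF = as.numeric(dF), mean = ms, cov = sym_inv(Ps))
}

# reduced second-level prior freeing only `keep` (logical/index over beta)
peb_reduced_prior <- function(peb, keep) {
  v <- diag(peb$beta0_cov)
  keep_l <- rep(FALSE, length(v))
  keep_l[keep] <- TRUE
  v[!keep_l] <- .pin_var
  list(mean = peb$beta0_mean, cov = diag(v, length(v)))
}

peb_posterior <- function(peb) list(mean = peb$beta_mean, cov = peb$beta_cov)
peb_prior <- function(peb) list(mean = peb$beta0_mean, cov = peb$beta0_cov)

# indices of a factor's block, optionally restricted to given B names
beta_index <- function(peb, factor, params = peb$b_params) {
  if (!factor %in% peb$effects)
    stopf("unknown factor '%s'", factor)
  match(paste(factor, params, sep = ":"), names(peb$beta_mean))
}

# evidence of each model in the space, applied to one factor's block:
# the factor's entries outside the model's freed set are pinned
factor_model_evidence <- function(peb, factor, space) {
  post <- peb_posterior(peb); pri <- peb_prior(peb)
  all_idx <- seq_along(peb$beta_mean)
  fac_idx <- beta_index(peb, factor)
  vapply(space, function(m) {
    freed <- fac_idx[peb$b_params %in% m$b_free]
    keep <- setdiff(all_idx, setdiff(fac_idx, freed))
    reduced_evidence(post, pri, peb_reduced_prior(peb, keep))$dF
  }, 0)
}

#' Posterior probability that a factor modulates connectivity
#'
#' Pools the evidence of all second-level models in which the factor is
#' switched on (some B-parameters are modulated by it) against all models
#' in which it is switched off -- the latter pool being the null model
#' when no family is given, or the family-off half of the space when
#' `family` is supplied. Pools receive equal prior probability and models
#' within a pool are weighted uniformly.
#'
#' @param peb a `peb_result`.
#' @param factor design-matrix column name.
#' @param space an `mmn_model_space` over the B-parameter families.
#' @param family optional family name: compare family-on vs family-off
#'   models instead of any-effect vs null.
#' @return list: `probability`, and `models` (per-model evidence and
#'   posterior probability under uniform model priors).
#' @export
compare_factor <- function(peb, factor, space, family = NULL) {
  F_m <- factor_model_evidence(peb, factor, space)
  null_i <- which(vapply(space, function(m) !any(m$switches), TRUE))
  on <- if (is.null(family)) seq_along(space)[-null_i]
  else which(vapply(space, function(m) isTRUE(m$switches[[family]]), TRUE))
  off <- setdiff(seq_along(space), on)
  lp_on <- logsumexp(F_m[on]) - log(length(on))
  lp_off <- logsumexp(F_m[off]) - log(length(off))
  prob <- 1 / (1 + exp(lp_off - lp_on))
  post <- exp(F_m - logsumexp(F_m))
  tab <- data.frame(index = vapply(space, `[[`, 1L, "index"),
                    name = vapply(space, `[[`, "", "name"),
                    F = F_m, post_prob = post)
  list(probability = prob, models = tab)
}

#' Family posterior probabilities for a factor
#'
#' Summed posterior model probabilities (uniform model priors) of each
#' family's members. Families overlap, so probabilities may sum above 1
#' across families.
#'
#' @inheritParams compare_factor
#' @return data frame: `family`, `probability`.
#' @export
family_posterior <- function(peb, factor, space) {
  F_m <- factor_model_evidence(peb, factor, space)
  post <- exp(F_m - logsumexp(F_m))
  fams <- names(space[[1]]$switches)
  data.frame(
    family = fams,
    probability = vapply(fams, function(f) {
      sum(post[vapply(space, function(m) isTRUE(m$switches[[f]]), TRUE)])
    }, 0),
    row.names = NULL
  )
}

#' Bayesian model averaging of second-level effects
#'
#' Averages the reduced posteriors of a set of models weighted by their
#' posterior probabilities (uniform model priors). Each beta entry is
#' summarised by the mixture mean and central 95% credible interval.
#'
#' `bma_models()` averages over an explicit list of reduced priors;
#' `bma()` applies the factor-wise model space: for each factor, its block
#' is averaged over the 2^4 models of the space.
#'
#' @param peb a `peb_result`.
#' @param reduced_priors list of reduced priors (each a list with `mean`
#'   and `cov`) defining the model set.
#' @return data frame: `name`, `mean`, `sd`, `ci_lower`, `ci_upper`.
#' @export
bma_models <- function(peb, reduced_priors) {
  post <- peb_posterior(peb); pri <- peb_prior(peb)
  red <- lapply(reduced_priors, function(rp) reduced_evidence(post, pri, rp))
  F_m <- vapply(red, `[[`, 0, "dF")
  w <- exp(F_m - logsumexp(F_m))
  means <- vapply(red, function(r) r$mean, numeric(length(peb$beta_mean)))
  vars <- vapply(red, function(r) diag(as.matrix(r$cov)),
                 numeric(length(peb$beta_mean)))
  if (is.null(dim(means))) { means <- matrix(means, 1); vars <- matrix(vars, 1) }
  mix_mean <- drop(means %*% w)
  mix_var <- drop(vars %*% w) + drop((means - mix_mean)^2 %*% w)
  qs <- vapply(seq_along(mix_mean), function(j) {
    mixture_quantiles(means[j, ], sqrt(vars[j, ]), w, c(0.025, 0.975))
  }, numeric(2))
  data.frame(name = names(peb$beta_mean), mean = mix_mean, sd = sqrt(mix_var),
             ci_lower = qs[1, ], ci_upper = qs[2, ], row.names = NULL)
}

#' @rdname bma_models
#' @param space an `mmn_model_space`.
#' @export
bma <- function(peb, space) {
  out <- NULL
  all_idx <- seq_along(peb$beta_mean)
  for (fac in peb$effects) {
    fac_idx <- beta_index(peb, fac)
    rps <- lapply(space, function(m) {
      freed <- fac_idx[peb$b_params %in% m$b_free]
      peb_reduced_prior(peb, setdiff(all_idx, setdiff(fac_idx, freed)))
    })
    tab <- bma_models(peb, rps)[fac_idx, ]
    out <- rbind(out, cbind(factor = fac, parameter = peb$b_params, tab))
  }
  rownames(out) <- NULL
  out
}

# quantiles of a univariate Gaussian mixture by root finding
mixture_quantiles <- function(mu, sd, w, probs) {
  sd <- pmax(sd, 1e-12)
  cdf <- function(x) sum(w * stats::pnorm(x, mu, sd))
  lo <- min(mu - 8 * sd); hi <- max(mu + 8 * sd)
  vapply(probs, function(pr) {
    stats::uniroot(function(x) cdf(x) - pr, c(lo, hi), tol = 1e-8)$root
  }, 0)
}

#' Greedy Bayesian model reduction over second-level parameters
#'
#' Iteratively prunes (pins to zero) the beta entry whose removal most
#' increases the second-level evidence, until no single removal improves
#' it; ties are broken in canonical parameter order. Each parameter's
#' posterior probability is the sigmoid of the log-evidence difference
#' between the final model with and without it; pruned parameters are
#' reported as exactly zero.
#'
#' @param peb a `peb_result`.
#' @return data frame: `factor`, `parameter`, `retained`, `mean`, `sd`,
#'   `probability`; the final retained index set and evidence gain are
#'   attached as attributes.
#' @export
bmr_greedy <- function(peb) {
  post <- peb_posterior(peb); pri <- peb_prior(peb)
  nb <- length(peb$beta_mean)
  dF_of <- function(keep) reduced_evidence(post, pri, peb_reduced_prior(peb, keep))$dF
  keep <- seq_len(nb)
  F_cur <- dF_of(keep)  # zero by construction (reduced prior = prior)
  repeat {
    gains <- vapply(keep, function(j) dF_of(setdiff(keep, j)) - F_cur, 0)
    if (!length(gains) || max(gains) <= 0) break
    drop_j <- keep[which.max(gains)]
    keep <- setdiff(keep, drop_j)
    F_cur <- F_cur + max(gains)
  }
  probs <- numeric(nb)
  for (j in seq_len(nb)) {
    if (j %in% keep) {
      dFj <- dF_of(keep) - dF_of(setdiff(keep, j))
    } else {
      dFj <- dF_of(union(keep, j)) - dF_of(keep)
    }
    probs[j] <- stats::plogis(dFj)
  }
  fin <- reduced_evidence(post, pri, peb_reduced_prior(peb, keep))
  mean_f <- fin$mean
  sd_f <- sqrt(diag(as.matrix(fin$cov)))
  retained <- seq_len(nb) %in% keep
  mean_f[!retained] <- 0
  sd_f[!retained] <- 0
  eff <- rep(peb$effects, each = length(peb$b_params))
  par <- rep(peb$b_params, length(peb$effects))
  out <- data.frame(factor = eff, parameter = par, retained = retained,
                    mean = mean_f, sd = sd_f, probability = probs,
                    row.names = NULL)
  attr(out, "kept") <- keep
  attr(out, "F_gain") <- F_cur
  out
}
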