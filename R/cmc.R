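#' Canonical-microcircuit model defaults
#'
#' Reads the versioned base-value configuration shipped with the package:
#' population time constants, the baseline-subtracted sigmoid, the signed
#' intrinsic and extrinsic base couplings, conduction delays, thalamic input
#' shape, integration settings and study-condition defaults.
#'
#' @return nested list of defaults (see
#'   `system.file("extdata", "cmc_defaults.yaml", package = "mmndcm")`).
#' @export
cmc_defaults <- function() {
  if (is.null(.mmndcm_env$defaults)) {
    path <- system.file("extdata", "cmc_defaults.yaml", package = "mmndcm")
    .mmndcm_env$defaults <- yaml::read_yaml(path)
  }
  .mmndcm_env$defaults
}

.mmndcm_env <- new.env(parent = emptyenv())

#' Sigmoid population firing rate
#'
#' Baseline-subtracted logistic transform of membrane voltage into a
#' normalised firing rate, so that `firing_rate(0) = 0` and the resting
#' state of the circuit is a fixed point.
#'
#' @param voltage membrane depolarisation (mV); any numeric shape.
#' @param slope sigmoid slope (1/mV), > 0.
#' @param max_rate peak rate, > 0; output lies in
#'   `(-max_rate/2, max_rate/2)`.
#' @return firing rate(s), same shape as `voltage`.
#' @export
firing_rate <- function(voltage, slope = cmc_defaults()$sigmoid$slope,
                        max_rate = cmc_defaults()$sigmoid$max) {
  if (any(!is.finite(voltage))) stopf("non-finite voltage")
  stopifnot(slope > 0, max_rate > 0)
  max_rate * (stats::plogis(slope * voltage) - 0.5)
}

#' Thalamic input drive
#'
#' Gaussian bump of subcortical drive entering the spiny stellate cells of
#' the input (A1) nodes, peaking by default 60 ms after sound onset.
#'
#' @param t time(s) in seconds.
#' @param peak_latency peak time (s).
#' @param width Gaussian standard deviation (s), > 0.
#' @param amplitude value at the peak.
#' @return input drive u(t), same shape as `t`.
#' @export
thalamic_input <- function(t, peak_latency = cmc_defaults()$input$peak_s,
                           width = cmc_defaults()$input$width_s,
                           amplitude = cmc_defaults()$input$amplitude) {
  if (width <= 0) stopf("input width must be > 0")
  amplitude * exp(-(t - peak_latency)^2 / (2 * width^2))
}

cmc_populations <- c("ss", "sp", "ii", "dp")
cmc_state_cols <- c("v_ss", "i_ss", "v_sp", "i_sp", "v_ii", "i_ii", "v_dp", "i_dp")
cmc_intrinsic_order <- c("ss_ss", "sp_ss", "ii_ss", "ii_ii", "ss_ii",
                         "dp_ii", "sp_sp", "ss_sp", "ii_dp", "dp_dp")

#' Construct canonical-microcircuit parameters for a network
#'
#' Builds the parameter set of the neural-mass model on a given network:
#' log-scaling matrices for forward (`AF`) and backward (`AB`) extrinsic
#' connections (structurally off entries are `NA` and never free), the
#' per-source superficial-pyramidal self-inhibition log-gain `G`, linear
#' input gains `C` (nonzero only for the A1 nodes), population time
#' constants, sigmoid shape and conduction delays.
#'
#' All log-scalings default to zero, i.e. connection strengths equal the
#' signed base values recorded in [cmc_defaults()].
#'
#' @param network an `mmn_network`.
#' @param AF,AB optional log-scaling matrices (target x source); `NA` off
#'   the edge set.
#' @param G optional per-source intrinsic log-gains.
#' @param C optional per-source linear input gains.
#' @param tau,sigmoid,delays,input,integration optional overrides of the
#'   configured defaults.
#' @return object of class `"cmc_params"`.
#' @export
cmc_params <- function(network, AF = NULL, AB = NULL, G = NULL, C = NULL,
                       tau = NULL, sigmoid = NULL, delays = NULL,
                       input = NULL, integration = NULL) {
  cfg <- cmc_defaults()
  n <- nrow(network$nodes)
  nm <- network$nodes$name
  edge_matrix <- function(edges) {
    M <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
    if (nrow(edges)) M[cbind(edges$to, edges$from)] <- 0
    M
  }
  AF0 <- edge_matrix(network$forward)
  AB0 <- edge_matrix(network$backward)
  if (!is.null(AF)) { check_edges(AF, AF0, "AF"); AF0 <- AF }
  if (!is.null(AB)) { check_edges(AB, AB0, "AB"); AB0 <- AB }
  G0 <- stats::setNames(rep(0, n), nm)
  if (!is.null(G)) G0[names(G)] <- G
  C0 <- stats::setNames(ifelse(network$nodes$receives_input, 1, 0), nm)
  if (!is.null(C)) C0[names(C)] <- C
  p <- structure(list(
    network = network,
    n = n,
    AF = AF0, AB = AB0, G = G0, C = C0,
    tau = unlist(tau %||% cfg$tau)[cmc_populations],
    sigmoid = sigmoid %||% cfg$sigmoid,
    delays = delays %||% cfg$delays,
    intrinsic = unlist(cfg$intrinsic)[cmc_intrinsic_order],
    extrinsic = cfg$extrinsic,
    input = input %||% cfg$input,
    integration = integration %||% cfg$integration
  ), class = "cmc_params")
  stopifnot(all(p$tau > 0))
  if (any(!is.finite(p$G)) || any(!is.finite(p$AF[!is.na(AF0)])) ||
      any(!is.finite(p$AB[!is.na(AB0)])))
    stopf("log-scaling parameters must be finite")
  p
}

check_edges <- function(M, template, what) {
  if (!identical(dim(M), dim(template)))
    stopf("%s has wrong dimensions", what)
  if (any(is.na(template) & !is.na(M)))
    stopf("%s has finite entries off the network edge set", what)
}

#' Condition-modulation (B) parameter vector
#'
#' A named, canonically ordered vector of log-scaling increments applied to
#' connections during deviant processing, together with the switch mask of
#' a model from the model space. Masked-off entries are exactly zero.
#'
#' @param network an `mmn_network`.
#' @param values named numeric vector of B entries (subset of [b_names()]).
#' @param model optional model definition from [enumerate_models()]; its
#'   freed set becomes the mask (default: all parameters free).
#' @return object of class `"condition_modulation"`: numeric vector with a
#'   `mask` attribute.
#' @export
condition_modulation <- function(network, values = NULL, model = NULL) {
  nm <- b_names(network)
  b <- stats::setNames(rep(0, length(nm)), nm)
  mask <- if (is.null(model)) rep(TRUE, length(nm)) else nm %in% model$b_free
  if (!is.null(values)) {
    bad <- setdiff(names(values), nm)
    if (length(bad)) stopf("unknown connection name(s): %s", paste(bad, collapse = ", "))
    b[names(values)] <- values
  }
  b[!mask] <- 0
  structure(b, mask = stats::setNames(mask, nm), class = "condition_modulation")
}

#' Apply a condition modulation to parameters
#'
#' Under the deviant condition, each modulated connection strength is
#' multiplied by `exp(B)`; under the standard condition parameters are
#' returned unchanged. Inputs are never mutated.
#'
#' @param params a `cmc_params` object.
#' @param B a [condition_modulation()] or named numeric vector of B entries.
#' @param is_deviant logical flag.
#' @return a new `cmc_params`.
#' @export
apply_modulation <- function(params, B, is_deviant = TRUE) {
  if (!is_deviant || is.null(B)) return(params)
  if (!inherits(B, "condition_modulation"))
    B <- condition_modulation(params$network, values = B)
  for (nm in names(B)[B != 0]) {
    parts <- strsplit(nm, "_")[[1]]
    kind <- parts[1]
    if (kind == "int") {
      params$G[parts[2]] <- params$G[parts[2]] + B[[nm]]
    } else if (kind == "fwd") {
      params$AF[parts[3], parts[2]] <- params$AF[parts[3], parts[2]] + B[[nm]]
    } else if (kind == "bwd") {
      params$AB[parts[3], parts[2]] <- params$AB[parts[3], parts[2]] + B[[nm]]
    } else stopf("unknown connection name '%s'", nm)
  }
  if (any(!is.finite(params$G))) stopf("modulated G not finite")
  params
}

# effective (signed, linear) coupling structures used by the integrators
cmc_effective <- function(params) {
  ex <- params$extrinsic
  AFexp <- exp(params$AF); AFexp[is.na(AFexp)] <- 0
  ABexp <- exp(params$AB); ABexp[is.na(ABexp)] <- 0
  gi <- matrix(rep(params$intrinsic, each = params$n), params$n,
               dimnames = list(params$network$nodes$name, cmc_intrinsic_order))
  gi[, "sp_sp"] <- gi[, "sp_sp"] * exp(params$G)
  list(
    AFss = ex$forward$ss * AFexp,
    AFdp = ex$forward$dp * AFexp,
    ABsp = ex$backward$sp * ABexp,
    ABii = ex$backward$ii * ABexp,
    gi = gi,
    C = params$C
  )
}

#' Canonical-microcircuit state derivative
#'
#' Right-hand side of the coupled second-order (current/voltage) kinetics.
#' Forward afferents (from superficial pyramidal cells of source regions)
#' target spiny stellate and deep pyramidal populations; backward afferents
#' (from deep pyramidal cells) inhibit superficial pyramidal cells and
#' inhibitory interneurons. Intrinsic couplings follow the fixed-sign
#' canonical-microcircuit topology in [cmc_defaults()].
#'
#' @param state matrix `n_sources x 8` with columns
#'   `v_ss, i_ss, v_sp, i_sp, v_ii, i_ii, v_dp, i_dp` (voltage mV,
#'   current mV/s).
#' @param params a `cmc_params`.
#' @param u_t scalar input drive at the current time.
#' @param state_intr,state_extr delayed states seen by intrinsic and
#'   extrinsic synapses (default: the instantaneous state, i.e. no delay).
#' @return matrix of the same shape as `state`.
#' @export
state_derivative <- function(state, params, u_t = 0,
                             state_intr = state, state_extr = state) {
  if (!is.matrix(state) || !identical(dim(state), c(params$n, 8L)))
    stopf("state must be an n_sources x 8 matrix")
  if (any(!is.finite(state))) stopf("state must be finite")
  eff <- cmc_effective(params)
  dx <- cmc_deriv_r(state, state_intr, state_extr, eff, params, u_t)
  dimnames(dx) <- dimnames(state)
  dx
}

# plain-R derivative used by state_derivative and the reference integrator
cmc_deriv_r <- function(Y, Yi, Ye, eff, params, u_t) {
  sg <- params$sigmoid
  Si <- sg$max * (stats::plogis(sg$slope * Yi[, c(1, 3, 5, 7), drop = FALSE]) - 0.5)
  Se <- sg$max * (stats::plogis(sg$slope * Ye[, c(1, 3, 5, 7), drop = FALSE]) - 0.5)
  g <- eff$gi
  U <- cbind(
    ss = g[, "ss_ss"] * Si[, 1] + g[, "sp_ss"] * Si[, 2] + g[, "ii_ss"] * Si[, 3] +
      drop(eff$AFss %*% Se[, 2]) + eff$C * u_t,
    sp = g[, "sp_sp"] * Si[, 2] + g[, "ss_sp"] * Si[, 1] +
      drop(eff$ABsp %*% Se[, 4]),
    ii = g[, "ii_ii"] * Si[, 3] + g[, "ss_ii"] * Si[, 1] + g[, "dp_ii"] * Si[, 4] +
      drop(eff$ABii %*% Se[, 4]),
    dp = g[, "ii_dp"] * Si[, 3] + g[, "dp_dp"] * Si[, 4] +
      drop(eff$AFdp %*% Se[, 2])
  )
  tau <- params$tau
  dx <- matrix(0, nrow(Y), 8)
  for (p in 1:4) {
    v <- 2 * p - 1; cur <- 2 * p
    dx[, v] <- Y[, cur]
    dx[, cur] <- (U[, p] - 2 * Y[, cur] - Y[, v] / tau[p]) / tau[p]
  }
  dx
}

#' Integrate the canonical-microcircuit model
#'
#' Deterministic fixed-step fourth-order Runge-Kutta integration of the
#' network dynamics with conduction delays handled by linear interpolation
#' into the state history on the integration grid. The observable output is
#' the superficial-pyramidal depolarisation of each source, sampled onto
#' the requested time grid.
#'
#' @param params a `cmc_params`.
#' @param times strictly increasing output time grid (s).
#' @param B optional condition modulation applied when `deviant = TRUE`.
#' @param deviant logical; apply `B`?
#' @param input list with `peak_s`, `width_s`, `amplitude` overriding the
#'   thalamic input defaults.
#' @param step internal integration step (s), at most 1 ms.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation used for cross-checks).
#' @param full_state return the complete state trajectory as an attribute.
#' @return matrix `length(times) x n_sources` of superficial-pyramidal
#'   voltage, with node names as columns. If `full_state`, the fine-grid
#'   trajectory is attached as attribute `"state"`.
#' @export
integrate_cmc <- function(params, times, B = NULL, deviant = FALSE,
                          input = NULL, step = NULL,
                          engine = c("cpp", "r"), full_state = FALSE) {
  engine <- match.arg(engine)
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  step <- step %||% params$integration$step_s
  if (step > 0.001 + 1e-12) stopf("integration step must be <= 1 ms")
  params <- apply_modulation(params, B, is_deviant = deviant)
  inp <- utils::modifyList(params$input, input %||% list())
  d_i <- params$delays$intrinsic / 1000 / step
  d_e <- params$delays$extrinsic / 1000 / step
  if (min(d_i, d_e) < 1 - 1e-9)
    stopf("integration step must not exceed the shortest conduction delay")
  t0 <- min(times[1], 0)
  n_steps <- ceiling((times[length(times)] - t0) / step - 1e-9)
  tu <- t0 + (0:(2 * n_steps)) * (step / 2)
  u <- thalamic_input(tu, inp$peak_s, inp$width_s, inp$amplitude)
  eff <- cmc_effective(params)
  if (engine == "cpp") {
    res <- cmc_integrate_cpp(eff$AFss, eff$AFdp, eff$ABsp, eff$ABii, eff$gi,
                             eff$C, params$tau, params$sigmoid$slope,
                             params$sigmoid$max, u, step, d_i, d_e,
                             n_steps, full_state,
                             params$integration$divergence_bound)
  } else {
    res <- cmc_integrate_r(eff, params, u, step, d_i, d_e, n_steps,
                           full_state, params$integration$divergence_bound)
  }
  if (res$diverged)
    stopf(paste0("integration diverged (state norm %.3g): G = [%s], ",
                 "max|B-scaled AF| = %.3g, max|AB| = %.3g"),
          res$maxnorm, paste(sprintf("%.2f", params$G), collapse = ", "),
          max(abs(eff$AFss)), max(abs(eff$ABsp)))
  tg <- t0 + (0:n_steps) * step
  out <- apply(res$vsp, 2, function(col) stats::approx(tg, col, xout = times)$y)
  out <- matrix(out, nrow = length(times),
                dimnames = list(NULL, params$network$nodes$name))
  if (full_state) attr(out, "state") <- res$X
  out
}

# reference RK4 integrator in R; mirrors the compiled engine exactly
cmc_integrate_r <- function(eff, params, u, h, d_i, d_e, n_steps,
                            full_state, bound) {
  n <- params$n
  hist <- array(0, c(n_steps + 1, n, 8))
  vsp <- matrix(0, n_steps + 1, n)
  delayed <- function(k_frac) {
    if (k_frac <= 0) return(array(hist[1, , ], c(n, 8)))
    lo <- floor(k_frac); w <- k_frac - lo
    H <- (1 - w) * hist[lo + 1, , , drop = FALSE] +
      w * hist[lo + 2, , , drop = FALSE]
    array(H, c(n, 8))
  }
  Y <- matrix(0, n, 8)
  diverged <- FALSE; maxnorm <- 0
  for (k in 0:(n_steps - 1)) {
    ks <- vector("list", 4)
    cc <- c(0, 0.5, 0.5, 1)
    for (s in 1:4) {
      Ys <- if (s == 1) Y else Y + h * cc[s] * ks[[s - 1]]
      Yi <- delayed(k + cc[s] - d_i)
      Ye <- delayed(k + cc[s] - d_e)
      ks[[s]] <- cmc_deriv_r(Ys, Yi, Ye, eff, params, u[2 * k + 2 * cc[s] + 1])
    }
    Y <- Y + (h / 6) * (ks[[1]] + 2 * ks[[2]] + 2 * ks[[3]] + ks[[4]])
    maxnorm <- max(maxnorm, max(abs(Y)))
    if (!all(is.finite(Y)) || maxnorm > bound) { diverged <- TRUE; break }
    hist[k + 2, , ] <- Y
    vsp[k + 2, ] <- Y[, 3]
  }
  list(vsp = vsp, diverged = diverged, maxnorm = maxnorm,
       X = if (full_state) hist else NULL)
}
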