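# Structured-text serialisation of networks, model spaces and fits.

#' Serialise networks, model spaces and fits to structured text
#'
#' Networks and fits are written as JSON; model spaces as TSV (one row per
#' model: index, switches, freed parameters). Fits store the parameter
#' names, posterior means and covariance, noise posterior, free energy and
#' iteration trace -- everything the group level needs -- plus the priors
#' and the network, so a fit file is self-contained.
#'
#' @param network an `mmn_network`.
#' @param path output file.
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(list(nodes = network$nodes, forward = network$forward,
                            backward = network$backward),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_network(x$nodes, x$forward, x$backward)
}

#' @rdname write_network
#' @param space an `mmn_model_space`.
#' @export
write_model_space <- function(space, path) {
  utils::write.table(model_space_table(space), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param fit a `dcm_fit`.
#' @export
write_dcm_fit <- function(fit, path) {
  pr <- fit$priors
  jsonlite::write_json(list(
    parameters = names(fit$mu),
    mu = unname(fit$mu),
    Sigma = fit$Sigma,
    b_params = names(fit$b_mean),
    b_mean = unname(fit$b_mean),
    b_cov = fit$b_cov,
    lambda = fit$lambda, v_lambda = fit$v_lambda,
    F = fit$F, converged = fit$converged,
    trace = fit$trace,
    priors = data.frame(name = pr$name, mean = pr$mean, sd = pr$sd),
    lambda_prior = attr(pr, "lambda"),
    network = list(nodes = attr(pr, "network")$nodes,
                   forward = attr(pr, "network")$forward,
                   backward = attr(pr, "network")$backward),
    meta = fit$meta
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_dcm_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- new_network(x$network$nodes, x$network$forward, x$network$backward)
  pr <- structure(data.frame(name = x$priors$name, mean = x$priors$mean,
                             sd = x$priors$sd),
                  lambda = as.list(x$lambda_prior), network = net,
                  class = c("prior_spec", "data.frame"))
  structure(list(
    mu = stats::setNames(x$mu, x$parameters),
    Sigma = matrix(unlist(x$Sigma), length(x$parameters)),
    b_mean = stats::setNames(x$b_mean, x$b_params),
    b_cov = matrix(unlist(x$b_cov), length(x$b_params),
                   dimnames = list(x$b_params, x$b_params)),
    lambda = x$lambda, v_lambda = x$v_lambda,
    F = x$F, converged = x$converged,
    trace = as.data.frame(x$trace),
    priors = pr, meta = as.list(x$meta)
  ), class = "dcm_fit")
}
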