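#' Auditory cortical network specifications
#'
#' `default_network()` returns the five-source auditory network used
#' throughout the package: bilateral primary auditory cortex (lA1, rA1),
#' bilateral anterior superior temporal gyrus (lSTG, rSTG), and the right
#' frontal operculum (rFOP), with MNI coordinate priors, a hierarchical
#' forward/backward edge layout, and thalamic input entering both A1 nodes.
#' `reduced_network()` returns a three-source variant (lA1, rA1, rSTG)
#' suitable for fast simulation studies.
#'
#' The default edge layout is: forward lA1->lSTG, rA1->rSTG, rSTG->rFOP;
#' backward lSTG->lA1, rSTG->rA1, rFOP->rSTG. Opercular connections are
#' restricted to the right hemisphere, mirroring the right-lateralised
#' frontal operculum; the edge sets are plain data frames and can be edited
#' before constructing parameters if another layout is wanted.
#'
#' @param opercular logical; include the rFOP node and its edges
#'   (default `TRUE`).
#' @return An object of class `"mmn_network"`: a list with elements
#'   `nodes` (data frame: name, hemisphere, x, y, z, receives_input,
#'   opercular), `forward` and `backward` (data frames with `from`, `to`),
#'   and `families` (named list mapping each modulation family to the
#'   B-parameter names it frees).
#' @export
default_network <- function(opercular = TRUE) {
  nodes <- data.frame(
    name = c("lA1", "rA1", "lSTG", "rSTG", "rFOP"),
    hemisphere = c("left", "right", "left", "right", "right"),
    x = c(-50, 46, -58, 56, 50),
    y = c(-16, -16, -6, 2, 4),
    z = c(-4, 0, 6, -1, 12),
    receives_input = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    opercular = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  forward <- data.frame(
    from = c("lA1", "rA1", "rSTG"),
    to   = c("lSTG", "rSTG", "rFOP"),
    stringsAsFactors = FALSE
  )
  backward <- data.frame(
    from = c("lSTG", "rSTG", "rFOP"),
    to   = c("lA1", "rA1", "rSTG"),
    stringsAsFactors = FALSE
  )
  if (!opercular) {
    nodes <- nodes[!nodes$opercular, ]
    forward <- forward[forward$to != "rFOP", ]
    backward <- backward[backward$from != "rFOP", ]
  }
  new_network(nodes, forward, backward)
}

#' @rdname default_network
#' @export
reduced_network <- function() {
  full <- default_network(opercular = FALSE)
  keep <- c("lA1", "rA1", "rSTG")
  nodes <- full$nodes[full$nodes$name %in% keep, ]
  forward <- full$forward[full$forward$from %in% keep & full$forward$to %in% keep, ]
  backward <- full$backward[full$backward$from %in% keep & full$backward$to %in% keep, ]
  new_network(nodes, forward, backward)
}

new_network <- function(nodes, forward, backward) {
  stopifnot(!anyDuplicated(nodes$name))
  for (e in list(forward, backward)) {
    if (nrow(e)) {
      stopifnot(all(e$from %in% nodes$name), all(e$to %in% nodes$name))
      if (any(e$from == e$to)) stopf("self-edges are not allowed in extrinsic sets")
    }
  }
  net <- structure(
    list(nodes = nodes, forward = forward, backward = backward),
    class = "mmn_network"
  )
  net$families <- family_inventory(net)
  net
}

#' @export
print.mmn_network <- function(x, ...) {
  cat(sprintf("<mmn_network> %d sources: %s\n", nrow(x$nodes),
              paste(x$nodes$name, collapse = ", ")))
  cat(sprintf("  forward : %s\n",
              paste(paste0(x$forward$from, "->", x$forward$to), collapse = ", ")))
  cat(sprintf("  backward: %s\n",
              paste(paste0(x$backward$from, "->", x$backward$to), collapse = ", ")))
  cat(sprintf("  B-parameters (%d): %s\n", length(b_names(x)),
              paste(b_names(x), collapse = ", ")))
  invisible(x)
}

# Map each modulation family to the B-parameter names it frees.  Temporal
# (non-opercular) intrinsic gains and A1<->STG extrinsic edges form the
# intrinsic/forward/backward families; everything touching the operculum
# (forward in, backward out, own intrinsic gain) forms the opercular family.
family_inventory <- function(network) {
  nodes <- network$nodes
  fop <- nodes$name[nodes$opercular]
  temporal <- nodes$name[!nodes$opercular]
  fwd <- network$forward
  bwd <- network$backward
  fwd_core <- fwd[!(fwd$from %in% fop | fwd$to %in% fop), , drop = FALSE]
  bwd_core <- bwd[!(bwd$from %in% fop | bwd$to %in% fop), , drop = FALSE]
  fwd_op <- fwd[fwd$from %in% fop | fwd$to %in% fop, , drop = FALSE]
  bwd_op <- bwd[bwd$from %in% fop | bwd$to %in% fop, , drop = FALSE]
  inv <- list(
    intrinsic = paste0("int_", temporal),
    forward = if (nrow(fwd_core)) paste0("fwd_", fwd_core$from, "_", fwd_core$to) else character(0),
    backward = if (nrow(bwd_core)) paste0("bwd_", bwd_core$from, "_", bwd_core$to) else character(0),
    opercular = c(
      if (nrow(fwd_op)) paste0("fwd_", fwd_op$from, "_", fwd_op$to) else character(0),
      if (nrow(bwd_op)) paste0("bwd_", bwd_op$from, "_", bwd_op$to) else character(0),
      if (length(fop)) paste0("int_", fop) else character(0)
    )
  )
  inv[vapply(inv, length, 1L) > 0]
}

#' Canonical condition-modulation (B) parameter names
#'
#' Returns the stable, canonically ordered vector of B-parameter names for a
#' network: intrinsic gains first, then forward, backward and opercular
#' connections. All modules index B-parameters by these names.
#'
#' @param network an `mmn_network`.
#' @return character vector of parameter names.
#' @export
b_names <- function(network) {
  unname(unlist(network$families))
}

#' Enumerate the condition-modulation model space
#'
#' Builds the model space obtained by switching each modulation family on or
#' off. With the four default families this yields `2^4 = 16` models: a null
#' model in which no connection is modulated, and 15 models grouped into the
#' (overlapping) intrinsic, forward, backward and opercular families.
#'
#' Models are ordered by binary counting over the switches with the first
#' family least significant, so the null model always comes first.
#'
#' @param network an `mmn_network`.
#' @param families character vector of family names to switch over; defaults
#'   to all families present in the network.
#' @return An object of class `"mmn_model_space"`: a list of model
#'   definitions, each with `index`, `name`, `switches` (named logical) and
#'   `b_free` (character vector of freed B-parameter names).
#' @export
enumerate_models <- function(network, families = names(network$families)) {
  if (!all(families %in% names(network$families)))
    stopf("unknown family: %s",
          paste(setdiff(families, names(network$families)), collapse = ", "))
  k <- length(families)
  n_models <- 2L^k
  space <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    bits <- as.logical(bitwAnd(i - 1L, bitwShiftL(1L, seq_len(k) - 1L)))
    switches <- stats::setNames(bits, families)
    b_free <- unname(unlist(network$families[families[bits]]))
    space[[i]] <- list(
      index = i,
      name = if (any(bits)) paste(families[bits], collapse = "+") else "null",
      switches = switches,
      b_free = b_free %||% character(0)
    )
  }
  structure(space, class = "mmn_model_space", network = network)
}

#' @export
print.mmn_model_space <- function(x, ...) {
  cat(sprintf("<mmn_model_space> %d models over families: %s\n",
              length(x), paste(names(x[[1]]$switches), collapse = ", ")))
  invisible(x)
}

#' Members of a modulation family
#'
#' Returns the subset of a model space whose family switch is on. Families
#' are not mutually exclusive: a model belongs to every family it switches
#' on, and the null model belongs to none.
#'
#' @param family family name (e.g. `"intrinsic"`).
#' @param space an `mmn_model_space`.
#' @return list of model definitions.
#' @export
family_members <- function(family, space) {
  fams <- names(space[[1]]$switches)
  if (!family %in% fams)
    stopf("unknown family '%s'; available: %s", family, paste(fams, collapse = ", "))
  Filter(function(m) isTRUE(m$switches[[family]]), space)
}

#' Freed B-parameters of a model
#'
#' @param model a model definition from [enumerate_models()].
#' @param network the `mmn_network` the space was built on.
#' @return character vector of freed B-parameter names in canonical order.
#' @export
b_inventory <- function(model, network) {
  ord <- b_names(network)
  ord[ord %in% model$b_free]
}

#' Tabulate a model space
#'
#' @param space an `mmn_model_space`.
#' @return data frame with one row per model: index, name, one logical
#'   column per family switch, and the freed parameter list. Suitable for
#'   TSV export.
#' @export
model_space_table <- function(space) {
  fams <- names(space[[1]]$switches)
  tab <- data.frame(index = vapply(space, `[[`, 1L, "index"),
                    name = vapply(space, `[[`, "", "name"),
                    stringsAsFactors = FALSE)
  for (f in fams) tab[[f]] <- vapply(space, function(m) m$switches[[f]], TRUE)
  tab$b_free <- vapply(space, function(m) paste(m$b_free, collapse = ","), "")
  tab
}
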