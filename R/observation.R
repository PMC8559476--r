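#' Synthetic magnetometer layout
#'
#' `make_sensor_layout()` constructs a deterministic, left-right symmetric
#' array of `n` magnetometers on a spherical cap above the conductor
#' sphere: `n/2` Fibonacci-spaced points on the right half-cap, mirrored
#' through the sagittal plane. Sensor normals are radial (pointing out of
#' the sphere). `default_sensors()` reads the 102-channel layout shipped as
#' a fixture, which equals `make_sensor_layout(102)`.
#'
#' @param n number of channels (even).
#' @param radius distance of sensors from the sphere centre (m).
#' @param center conductor sphere centre (m).
#' @param cap_angle polar half-angle of the cap (radians).
#' @return data frame: `name`, positions `x, y, z` (m) and unit normals
#'   `nx, ny, nz`.
#' @export
make_sensor_layout <- function(n = 102,
                               radius = cmc_defaults()$observation$sensor_radius_m,
                               center = unlist(cmc_defaults()$observation$sphere_center_m),
                               cap_angle = 1.95) {
  stopifnot(n %% 2 == 0)
  m <- n / 2
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(m)
  cosa <- cos(cap_angle)
  z <- 1 - (1 - cosa) * (k - 0.5) / m
  theta <- acos(z)
  # phi restricted to the x > 0 half, avoiding the sagittal plane
  phi <- (k * golden) %% pi - pi / 2
  phi <- sign(phi + 1e-9) * (0.06 + (pi / 2 - 0.06) * abs(phi) / (pi / 2))
  right <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), z)
  left <- right * matrix(c(-1, 1, 1), m, 3, byrow = TRUE)
  dirs <- rbind(right, left)
  pos <- sweep(dirs * radius, 2, center, "+")
  data.frame(
    name = sprintf("MEG%03d", seq_len(n)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    nx = dirs[, 1], ny = dirs[, 2], nz = dirs[, 3],
    stringsAsFactors = FALSE
  )
}

#' @rdname make_sensor_layout
#' @export
default_sensors <- function() {
  if (is.null(.mmndcm_env$sensors)) {
    path <- system.file("extdata", "sensor_layout_102.tsv", package = "mmndcm")
    .mmndcm_env$sensors <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .mmndcm_env$sensors
}

# Magnetic field of a current dipole in a spherical conductor (Sarvas 1987),
# projected onto sensor normals.  Positions in metres relative to an
# arbitrary frame; `center` is the conductor sphere centre.  Moment in nAm;
# output in fT.
sarvas_field <- function(dip_pos, dip_moment, sensors, center) {
  r0 <- dip_pos - center
  q <- dip_moment * 1e-9                      # nAm -> Am
  R <- cbind(sensors$x - center[1], sensors$y - center[2], sensors$z - center[3])
  A <- R - matrix(r0, nrow(R), 3, byrow = TRUE)
  a <- sqrt(rowSums(A^2))
  r <- sqrt(rowSums(R^2))
  ar <- rowSums(A * R)
  f <- a * (r * a + r^2 - rowSums(R * matrix(r0, nrow(R), 3, byrow = TRUE)))
  gradf <- (a^2 / r + ar / a + 2 * a + 2 * r) * R -
    (a + 2 * r + ar / a) %o% r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  qxr0_dot_r <- drop(R %*% qxr0)
  B <- (1e-7 / f^2) * (f %o% qxr0 - qxr0_dot_r * gradf)
  1e15 * rowSums(B * cbind(sensors$nx, sensors$ny, sensors$nz))
}

#' Point-dipole gain matrix in a spherical conductor
#'
#' Analytic single-sphere magnetic forward solution for point current
#' dipoles, evaluated at each sensor along its normal. The field is linear
#' in the dipole moment; a purely radial dipole produces no external
#' magnetic field.
#'
#' @param dipoles data frame with columns `x, y, z` (m), orientation
#'   `ox, oy, oz` and `moment` (nAm).
#' @param sensors sensor data frame as from [default_sensors()].
#' @param center conductor sphere centre (m).
#' @param head_radius conductor radius (m); dipoles must lie inside.
#' @return gain matrix, channels x sources, in fT.
#' @export
build_gain <- function(dipoles, sensors = default_sensors(),
                       center = unlist(cmc_defaults()$observation$sphere_center_m),
                       head_radius = cmc_defaults()$observation$head_radius_m) {
  L <- matrix(0, nrow(sensors), nrow(dipoles))
  for (j in seq_len(nrow(dipoles))) {
    pos <- c(dipoles$x[j], dipoles$y[j], dipoles$z[j])
    ori <- c(dipoles$ox[j], dipoles$oy[j], dipoles$oz[j])
    r0 <- pos - center
    if (sqrt(sum(r0^2)) >= head_radius)
      stopf("dipole %d lies outside the conductor sphere", j)
    rad <- if (sum(r0^2) > 0) r0 / sqrt(sum(r0^2)) else c(0, 0, 1)
    tang <- ori - sum(ori * rad) * rad
    if (sqrt(sum(r0^2)) < 1e-6 || sqrt(sum(tang^2)) < 1e-6 * sqrt(sum(ori^2)))
      warning(sprintf("dipole %d is (near-)radial or central: degenerate signal", j))
    L[, j] <- sarvas_field(pos, ori * dipoles$moment[j], sensors, center)
  }
  rownames(L) <- sensors$name
  L
}

#' Observation model: dipoles, gain and spatial modes
#'
#' Builds the sensor-level observation model for a network: one point
#' dipole per source at the node's MNI coordinate prior (converted to
#' metres in the conductor frame), with inter-hemispheric symmetry of
#' locations and orientations for homologous left/right pairs (unpaired
#' sources, e.g. the right frontal operculum, are unconstrained).
#'
#' @param network an `mmn_network`.
#' @param sensors sensor layout data frame.
#' @param k number of spatial modes retained during inversion.
#' @param moment dipole moment (nAm), recycled over sources.
#' @param orientations optional matrix (sources x 3) of dipole
#'   orientations; default is a mirror-symmetric tangential-ish direction.
#' @param loc_offset optional matrix (sources x 3, m) added to the
#'   coordinate priors.
#' @param symmetric impose inter-hemispheric dipole symmetry: homologous
#'   left/right pairs (same name up to the l/r prefix) are moved to the
#'   mirrored mean of their coordinate priors and share a mirrored
#'   orientation. Unpaired sources are unconstrained.
#' @return object of class `"mmn_observation"`: dipoles, sensors, gain
#'   matrix `L` (channels x sources), `k`, sphere geometry.
#' @export
observation_model <- function(network, sensors = default_sensors(),
                              k = cmc_defaults()$observation$n_modes,
                              moment = cmc_defaults()$observation$dipole_moment_nAm,
                              orientations = NULL, loc_offset = NULL,
                              symmetric = TRUE) {
  cfg <- cmc_defaults()$observation
  nodes <- network$nodes
  ns <- nrow(nodes)
  pos <- cbind(nodes$x, nodes$y, nodes$z) / 1000
  if (symmetric) {
    stem <- sub("^[lr]", "", nodes$name)
    for (st in unique(stem[duplicated(stem)])) {
      i <- which(stem == st & nodes$hemisphere == "left")
      j <- which(stem == st & nodes$hemisphere == "right")
      if (length(i) == 1 && length(j) == 1) {
        left <- (pos[i, ] + pos[j, ] * c(-1, 1, 1)) / 2
        pos[i, ] <- left
        pos[j, ] <- left * c(-1, 1, 1)
      }
    }
  }
  if (!is.null(loc_offset)) pos <- pos + loc_offset
  if (is.null(orientations)) {
    base <- c(0, 0.6, 0.8)
    orientations <- matrix(base, ns, 3, byrow = TRUE)
  }
  orientations <- orientations / sqrt(rowSums(orientations^2))
  dip <- data.frame(
    name = nodes$name, x = pos[, 1], y = pos[, 2], z = pos[, 3],
    ox = orientations[, 1], oy = orientations[, 2], oz = orientations[, 3],
    moment = rep_len(moment, ns)
  )
  L <- build_gain(dip, sensors,
                  center = unlist(cfg$sphere_center_m),
                  head_radius = cfg$head_radius_m)
  colnames(L) <- nodes$name
  structure(list(network = network, dipoles = dip, sensors = sensors,
                 L = L, k = k,
                 center = unlist(cfg$sphere_center_m),
                 head_radius = cfg$head_radius_m),
            class = "mmn_observation")
}

#' Predict standard and deviant sensor ERFs
#'
#' Integrates the circuit under the standard condition (baseline
#' connectivity only) and the deviant condition (baseline plus the
#' condition modulation B), projects source activity through the dipole
#' gain matrix, and removes each channel's temporal mean over the window,
#' as the data are mean-centred before fitting.
#'
#' @param params a `cmc_params`.
#' @param B condition modulation (applied to the deviant only).
#' @param obs an `mmn_observation`.
#' @param times output grid (s); default 0-300 ms at 256 Hz.
#' @param input optional thalamic input overrides.
#' @return list with `standard` and `deviant` (channels x time, fT,
#'   mean-centred per channel), `times`, and the source time courses as
#'   attribute `"sources"`.
#' @export
predict_erf <- function(params, B, obs, times = dcm_times(), input = NULL) {
  y_std <- integrate_cmc(params, times, input = input)
  y_dev <- integrate_cmc(params, times, B = B, deviant = TRUE, input = input)
  to_sensor <- function(y) {
    X <- obs$L %*% t(y)
    X - rowMeans(X)
  }
  out <- list(standard = to_sensor(y_std), deviant = to_sensor(y_dev),
              times = times)
  attr(out, "sources") <- list(standard = y_std, deviant = y_dev)
  out
}

#' Default DCM analysis time grid: 0-300 ms at 256 Hz
#' @export
dcm_times <- function() seq(0, 0.3, by = 1 / 256)

#' Reduce sensor data to leading spatial modes
#'
#' Computes the `k` leading spatial singular vectors of the data
#' (channels x samples; several matrices are concatenated column-wise) and
#' the projected data. The projector columns are orthonormal and the
#' retained-variance fraction is reported.
#'
#' @param x matrix channels x samples, or a list of such matrices.
#' @param k number of modes, `1 <= k <= n_channels`.
#' @return list: `projector` (channels x k), `scores` (k x samples or list
#'   matching the input), `var_explained` (scalar in (0, 1]).
#' @export
reduce_spatial_modes <- function(x, k) {
  xs <- if (is.list(x)) x else list(x)
  X <- do.call(cbind, xs)
  if (k < 1 || k > nrow(X)) stopf("k must be in [1, %d]", nrow(X))
  sv <- svd(X, nu = k, nv = 0)
  U <- sv$u
  scores <- lapply(xs, function(m) t(U) %*% m)
  list(projector = U,
       scores = if (is.list(x)) scores else scores[[1]],
       var_explained = sum(sv$d[seq_len(k)]^2) / sum(sv$d^2))
}
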