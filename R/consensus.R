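#' Correlation-weighted consensus of positions
#'
#' The consensus position of a unit measured `N` times is the cc-weighted
#' mean of the per-measurement coordinates:
#' `(X, Y, Z) = sum(cc_i * (x_i, y_i, z_i)) / sum(cc_i)`.
#' Measurements with `cc <= 0` are dropped beforehand; an error is raised if
#' none remain.
#'
#' @param ms Tibble of measurements with columns `x, y, z, cc`.
#' @return Numeric length-3 consensus position.
#' @export
consensus_position <- function(ms) {
  ms <- ms[ms$cc > 0, , drop = FALSE]
  if (nrow(ms) == 0) stop("all measurements have cc <= 0; no consensus",
                          call. = FALSE)
  w <- ms$cc / sum(ms$cc)
  c(sum(w * ms$x), sum(w * ms$y), sum(w * ms$z))
}

#' Correlation-weighted consensus of orientations
#'
#' The consensus normal is the normalized cc-weighted sum of the
#' per-measurement normal vectors:
#' `n = sum(cc_i * n_i) / |sum(cc_i * n_i)|`.
#' The in-plane angle is combined as the cc-weighted circular mean of the
#' measurements' in-plane angles after parallel transport of each frame onto
#' the consensus normal (set `in_plane = "best"` to instead carry the
#' in-plane angle of the highest-cc measurement).
#'
#' @param ms Tibble of measurements with columns `phi, theta, psi, cc`.
#' @param in_plane `"weighted"` (default) or `"best"`.
#' @return List with `normal` (unit 3-vector), `in_plane` (degrees),
#'   `euler` (consensus triplet), `n` (measurements used).
#' @export
consensus_orientation <- function(ms, in_plane = c("weighted", "best")) {
  in_plane <- match.arg(in_plane)
  ms <- ms[ms$cc > 0, , drop = FALSE]
  if (nrow(ms) == 0) stop("all measurements have cc <= 0; no consensus",
                          call. = FALSE)
  normals <- t(vapply(seq_len(nrow(ms)), function(i)
    normal_from_euler(ms$phi[i], ms$theta[i]), numeric(3)))
  s <- colSums(ms$cc * normals)
  ns <- sqrt(sum(s^2))
  if (ns < 1e-9 * sum(ms$cc)) {
    stop("degenerate consensus: weighted normal sum vanishes ",
         "(antipodal normals)", call. = FALSE)
  }
  nbar <- s / ns
  # reference in-plane basis on the consensus normal
  e_ref <- canonical_tangent(nbar)
  angles <- vapply(seq_len(nrow(ms)), function(i) {
    R <- rotation_from_euler(ms$phi[i], ms$theta[i], ms$psi[i])
    xt <- align_rotation(normals[i, ], nbar) %*% R[, 1]
    rad2deg(atan2(sum(cross3(e_ref, as.vector(xt)) * nbar),
                  sum(e_ref * xt)))
  }, numeric(1))
  ip <- if (in_plane == "best") {
    angles[which.max(ms$cc)]
  } else {
    rad2deg(atan2(sum(ms$cc * sin(deg2rad(angles))),
                  sum(ms$cc * cos(deg2rad(angles)))))
  }
  Rip <- rodrigues(nbar, ip)
  euler <- euler_from_rotation(cbind(
    Rip %*% e_ref, cross3(nbar, as.vector(Rip %*% e_ref)), nbar))
  list(normal = nbar, in_plane = ip, euler = euler, n = nrow(ms))
}

canonical_tangent <- function(n) {
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * n) * n
  t1 / sqrt(sum(t1^2))
}

# Rotation by `deg` degrees about unit axis
rodrigues <- function(axis, deg) {
  a <- deg2rad(deg)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

#' Simulate per-neighbour pose measurements
#'
#' Generates, for every edge of the lattice, a noisy measurement of each
#' endpoint: ground-truth position plus isotropic Gaussian noise
#' (`sigma_pos` voxels per axis) and ground-truth orientation perturbed by a
#' random rotation with Gaussian-distributed per-axis angles (`sigma_ang`
#' degrees). Used to study the statistics of the consensus estimator
#' independently of the imaging chain.
#'
#' @param g A [lattice_graph] with ground-truth poses.
#' @param sigma_pos Positional noise, voxels per axis.
#' @param sigma_ang Angular noise, degrees per axis.
#' @param seed Integer seed.
#' @param cc Correlation weight given to every measurement.
#' @return Tibble of measurements: `unit_id`, `neighbor_id`, `x, y, z`,
#'   `phi, theta, psi`, `cc`.
#' @export
simulate_measurements <- function(g, sigma_pos = 1.5, sigma_ang = 8,
                                  seed = 1, cc = 1) {
  e <- g$edges
  pairs <- dplyr::bind_rows(
    tibble(unit_id = e$from, neighbor_id = e$to),
    tibble(unit_id = e$to, neighbor_id = e$from))
  pairs <- dplyr::arrange(pairs, .data$unit_id, .data$neighbor_id)
  u <- g$units
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      id <- pairs$unit_id[i]
      R <- rotation_from_euler(u$phi[id], u$theta[id], u$psi[id])
      dR <- rotation_from_euler(0, 0, 0)
      ang <- stats::rnorm(3, sd = sigma_ang)
      dR <- rot_z(ang[3]) %*% rot_x(ang[1]) %*%
        rodrigues(c(0, 1, 0), ang[2])
      eu <- euler_from_rotation(R %*% dR)
      tibble(unit_id = id, neighbor_id = pairs$neighbor_id[i],
             x = u$x[id] + stats::rnorm(1, sd = sigma_pos),
             y = u$y[id] + stats::rnorm(1, sd = sigma_pos),
             z = u$z[id] + stats::rnorm(1, sd = sigma_pos),
             phi = eu[["phi"]], theta = eu[["theta"]], psi = eu[["psi"]],
             cc = cc)
    })
  })
}

#' Render a pair reference for masked alignment
#'
#' Renders the two units of an edge in the pair's canonical frame: the
#' central unit at the box centre with its normal along +z and the neighbour
#' direction along +x. The reference records the central unit's in-plane spin
#' relative to the canonical frame so that alignment results can be mapped
#' back to full unit poses.
#'
#' @param g A [lattice_graph].
#' @param edge Length-2 integer vector `c(central, neighbor)`.
#' @param box Reference box side, voxels.
#' @param templates Templates per unit type (see [default_templates]).
#' @return A [density_volume] with attributes `pair_offset` (voxels,
#'   canonical frame), `spin_R` (3x3), `mask_radius` (angstroms).
#' @export
render_pair_reference <- function(g, edge, box, templates = default_templates()) {
  u <- g$units
  a <- edge[1]; b <- edge[2]
  d <- c(u$x[b] - u$x[a], u$y[b] - u$y[a], u$z[b] - u$z[a])
  F0 <- pair_frame(c(u$phi[a], u$theta[a], u$psi[a]), d)
  Ra <- rotation_from_euler(u$phi[a], u$theta[a], u$psi[a])
  Rb <- rotation_from_euler(u$phi[b], u$theta[b], u$psi[b])
  ctr <- box / 2
  d_can <- as.vector(t(F0) %*% d)
  ea <- euler_from_rotation(t(F0) %*% Ra)
  eb <- euler_from_rotation(t(F0) %*% Rb)
  rows <- dplyr::bind_rows(
    unit_row(ctr, ctr, ctr, ea, unit_type = u$unit_type[a]),
    unit_row(ctr + d_can[1], ctr + d_can[2], ctr + d_can[3], eb,
             unit_type = u$unit_type[b]))
  gg <- lattice_graph(rows, tibble(from = integer(), to = integer()),
                      closed = FALSE, voxel_size = g$voxel_size)
  ref <- render_density(gg, box, templates = templates, allow_clip = TRUE)
  attr(ref, "pair_offset") <- d_can
  attr(ref, "spin_R") <- t(F0) %*% Ra
  attr(ref, "mask_radius") <- 0.55 * sqrt(sum(d^2)) * g$voxel_size
  ref
}

# Canonical frame of a unit-neighbour pair: z = unit normal, x = in-plane
# projection of the neighbour direction.
pair_frame <- function(euler, d) {
  n <- normal_from_euler(euler[1], euler[2])
  x <- d - sum(d * n) * n
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("neighbour direction parallel to unit normal",
                      call. = FALSE)
  x <- x / nx
  cbind(x, cross3(n, x), n)
}

# Masked NCC between a subvolume and a reference over integer shifts up to
# max_shift voxels (FFT-based; wrap-around shifts beyond the bound ignored).
ncc_shift_search <- function(subgrid, refgrid, mask, max_shift) {
  nv <- dim(subgrid)
  m <- sum(mask)
  t0 <- mask * (refgrid - sum(refgrid * mask) / m)
  nrg <- sum(t0^2)
  if (nrg < 1e-12) return(list(shift = c(0, 0, 0), cc = 0))
  FV <- stats::fft(subgrid)
  num <- corr_fft(FV, t0, nv)
  s1 <- corr_fft(FV, mask, nv)
  s2 <- corr_fft(stats::fft(subgrid^2), mask, nv)
  denom <- sqrt(pmax(s2 - s1^2 / m, 0) * nrg)
  cc <- array(0, dim = nv)
  ok <- denom > 1e-6 * max(denom)
  cc[ok] <- num[ok] / denom[ok]
  ctr <- floor(nv / 2)
  ax <- abs(0:(nv[1] - 1) - ctr[1]) <= max_shift
  ay <- abs(0:(nv[2] - 1) - ctr[2]) <= max_shift
  az <- abs(0:(nv[3] - 1) - ctr[3]) <= max_shift
  ccw <- cc
  ccw[!ax, , ] <- -Inf; ccw[, !ay, ] <- -Inf; ccw[, , !az] <- -Inf
  li <- which.max(ccw)
  idx <- as.vector(arrayInd(li, nv))
  # sub-voxel refinement: 1D parabolic fit through the peak along each axis
  frac <- numeric(3)
  for (axn in 1:3) {
    if (idx[axn] > 1 && idx[axn] < nv[axn]) {
      lo_i <- idx; lo_i[axn] <- idx[axn] - 1
      hi_i <- idx; hi_i[axn] <- idx[axn] + 1
      y0 <- cc[matrix(lo_i, 1)]; y1 <- cc[li]; y2 <- cc[matrix(hi_i, 1)]
      den <- y0 - 2 * y1 + y2
      if (is.finite(den) && den < -1e-12) {
        frac[axn] <- max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
      }
    }
  }
  list(shift = idx - 1 - ctr + frac, cc = max(ccw))
}

small_rotation_grid <- function(range, step) {
  s <- seq(-range, range, by = step)
  g <- expand.grid(rx = s, ry = s, rz = s)
  g[order(abs(g$rx) + abs(g$ry) + abs(g$rz)), ]
}

#' Align one unit against a pair reference
#'
#' Local rigid refinement: a bounded search over integer translations and
#' small rotations maximizing the masked normalized cross-correlation between
#' the subvolume around the unit and the pair reference (central unit plus
#' the one neighbour, both covered by the mask). Returns the refined pose and
#' its correlation; when the search cannot improve on a degenerate landscape
#' the input pose is returned flagged.
#'
#' @param vol A [density_volume] containing the lattice.
#' @param unit,neighbor One-row particle-table entries (current poses).
#' @param reference A [render_pair_reference] volume.
#' @param max_shift Translation bound, voxels.
#' @param rot_range,rot_step Rotation search bound and step, degrees per axis
#'   (a second pass refines at `rot_step / 4`).
#' @return One-row tibble: refined `x, y, z, phi, theta, psi`, `cc`,
#'   `flagged`.
#' @export
align_unit_pair <- function(vol, unit, neighbor, reference,
                            max_shift = 3, rot_range = 8, rot_step = 4) {
  vs <- vol$voxel_size
  nb <- dim(reference$grid)[1]
  ctr <- round(c(unit$x, unit$y, unit$z))
  sub <- extract_box(vol$grid, ctr, nb)
  if (is.null(sub)) {
    return(tibble(x = unit$x, y = unit$y, z = unit$z, phi = unit$phi,
                  theta = unit$theta, psi = unit$psi, cc = 0, flagged = TRUE))
  }
  d <- c(neighbor$x - unit$x, neighbor$y - unit$y, neighbor$z - unit$z)
  F0 <- pair_frame(c(unit$phi, unit$theta, unit$psi), d)
  off_can <- attr(reference, "pair_offset")
  mrad_vox <- attr(reference, "mask_radius") / vs * 0.8
  best <- list(cc = -Inf)
  search_one <- function(rx, ry, rz) {
    dR <- rot_x(rx) %*% rodrigues(c(0, 1, 0), ry) %*% rot_z(rz)
    Rc <- F0 %*% dR
    ref_rot <- rotate_grid(reference$grid, Rc)
    nb_ctr <- nb / 2 + as.vector(Rc %*% off_can)
    mask <- spherical_mask(nb, mrad_vox) +
      spherical_mask(nb, mrad_vox, centre = nb_ctr)
    mask <- (mask > 0) * 1
    r <- ncc_shift_search(sub, ref_rot, mask, max_shift)
    if (r$cc > best$cc) best <<- list(cc = r$cc, shift = r$shift, R = Rc)
  }
  grid1 <- small_rotation_grid(rot_range, rot_step)
  for (i in seq_len(nrow(grid1))) {
    search_one(grid1$rx[i], grid1$ry[i], grid1$rz[i])
  }
  if (is.finite(best$cc) && best$cc > 0) {
    for (st in c(rot_step / 2, rot_step / 8)) {
      fine <- small_rotation_grid(st, st)
      F0_fine <- best$R
      for (i in seq_len(nrow(fine))) {
        dR <- rot_x(fine$rx[i]) %*% rodrigues(c(0, 1, 0), fine$ry[i]) %*%
          rot_z(fine$rz[i])
        Rc <- F0_fine %*% dR
        ref_rot <- rotate_grid(reference$grid, Rc)
        nb_ctr <- nb / 2 + as.vector(Rc %*% off_can)
        mask <- (spherical_mask(nb, mrad_vox) +
                   spherical_mask(nb, mrad_vox, centre = nb_ctr) > 0) * 1
        r <- ncc_shift_search(sub, ref_rot, mask, max_shift)
        if (r$cc > best$cc) best <- list(cc = r$cc, shift = r$shift, R = Rc)
      }
    }
  }
  if (!is.finite(best$cc) || best$cc <= 0.05) {
    return(tibble(x = unit$x, y = unit$y, z = unit$z, phi = unit$phi,
                  theta = unit$theta, psi = unit$psi,
                  cc = max(0, best$cc), flagged = TRUE))
  }
  pose_R <- best$R %*% attr(reference, "spin_R")
  eu <- euler_from_rotation(pose_R)
  tibble(x = ctr[1] + best$shift[1], y = ctr[2] + best$shift[2],
         z = ctr[3] + best$shift[3],
         phi = eu[["phi"]], theta = eu[["theta"]], psi = eu[["psi"]],
         cc = best$cc, flagged = FALSE)
}

# Extract a cubic box of side `box` centred (at floor(box/2)) on 0-based
# voxel `ctr`; NULL when out of bounds.
extract_box <- function(grid, ctr, box) {
  h <- floor(box / 2)
  lo <- ctr - h
  hi <- lo + box - 1
  d <- dim(grid)
  if (any(lo < 0) || any(hi > d - 1)) return(NULL)
  grid[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1]
}

#' Consensus alignment pass over a lattice
#'
#' Each unit is measured once per neighbour and the measurements are combined
#' with [consensus_position] and [consensus_orientation]. Measurements come
#' either from volume alignment ([align_unit_pair] against per-edge
#' references) or from a user-supplied measurement table (e.g.
#' [simulate_measurements]). Units whose measurements all carry `cc <= 0`
#' keep their prior pose and are flagged.
#'
#' @param g A [lattice_graph].
#' @param measurements Optional measurement tibble (columns `unit_id`,
#'   `x, y, z, phi, theta, psi, cc`). When `NULL`, measurements are computed
#'   from `vol`.
#' @param vol,templates,ref_box Volume alignment inputs (used when
#'   `measurements` is `NULL`).
#' @param in_plane Passed to [consensus_orientation].
#' @param ... Passed to [align_unit_pair].
#' @return The lattice with updated unit poses; the measurement table is
#'   attached as attribute `measurements` and per-unit flags as `flagged`.
#' @export
consensus_pass <- function(g, measurements = NULL, vol = NULL,
                           templates = default_templates(), ref_box = 32,
                           in_plane = "weighted", ...) {
  if (is.null(measurements)) {
    if (is.null(vol)) stop("either measurements or vol must be supplied",
                           call. = FALSE)
    e <- g$edges
    pairs <- dplyr::bind_rows(
      tibble(unit_id = e$from, neighbor_id = e$to),
      tibble(unit_id = e$to, neighbor_id = e$from))
    pairs <- dplyr::arrange(pairs, .data$unit_id, .data$neighbor_id)
    measurements <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      ref <- render_pair_reference(g, c(pairs$unit_id[i], pairs$neighbor_id[i]),
                                   ref_box, templates)
      m <- align_unit_pair(vol, g$units[pairs$unit_id[i], ],
                           g$units[pairs$neighbor_id[i], ], ref, ...)
      m$unit_id <- pairs$unit_id[i]; m$neighbor_id <- pairs$neighbor_id[i]
      m
    })
  }
  u <- g$units
  flagged <- logical(nrow(u))
  for (id in sort(unique(measurements$unit_id))) {
    ms <- measurements[measurements$unit_id == id, , drop = FALSE]
    if (all(ms$cc <= 0)) {
      flagged[id] <- TRUE
      next
    }
    p <- consensus_position(ms)
    o <- consensus_orientation(ms, in_plane = in_plane)
    u$x[id] <- p[1]; u$y[id] <- p[2]; u$z[id] <- p[3]
    u$phi[id] <- o$euler[["phi"]]; u$theta[id] <- o$euler[["theta"]]
    u$psi[id] <- o$euler[["psi"]]
    u$cc[id] <- stats::weighted.mean(ms$cc, ms$cc)
  }
  g$units <- u
  attr(g, "measurements") <- measurements
  attr(g, "flagged") <- flagged
  g
}
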