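#' Coarse pseudo-atom unit templates
#'
#' Each lattice unit is approximated by two stacked rings of Gaussian
#' pseudo-atoms in its local frame (z = outward normal), mimicking the
#' N-terminal-domain layer (outer, larger ring, above the mid-plane) and the
#' C-terminal-domain layer (inner, smaller ring, below it), plus a central
#' blob: 6 blobs per ring for hexamers, 5 for pentamers. The axial asymmetry
#' makes the outward direction identifiable. The C2 hexamer carries a
#' twofold weight modulation on the outer ring (opposite blobs equal,
#' adjacent ones not); the C6 hexamer and C5 pentamer are fully symmetric.
#' Templates obey their declared Cn symmetry exactly by construction.
#'
#' @param unit_type One of `"hexamer_C2"`, `"hexamer_C6"`, `"pentamer_C5"`.
#' @param ring_radius Radius of the outer blob ring in angstroms.
#' @param sigma Gaussian width of each blob in angstroms.
#' @return Tibble with columns `x, y, z, weight, sigma` (angstroms, local
#'   frame) and attributes `symmetry` (Cn order) and `sigma`.
#' @export
unit_template <- function(unit_type, ring_radius = NULL, sigma = 7) {
  n <- switch(unit_type,
              hexamer_C2 = 6L, hexamer_C6 = 6L, pentamer_C5 = 5L,
              stop("unknown unit_type: ", unit_type, call. = FALSE))
  if (is.null(ring_radius)) ring_radius <- if (n == 6L) 30 else 25
  ang <- 2 * pi * (seq_len(n) - 1) / n
  w <- rep(1, n)
  sym <- n
  if (unit_type == "hexamer_C2") {
    w <- c(1.4, 0.8, 1.0, 1.4, 0.8, 1.0)  # period 3 in index = C2 symmetric
    sym <- 2L
  }
  r_in <- ring_radius * 2 / 3
  tpl <- tibble(
    x = c(ring_radius * cos(ang), r_in * cos(ang), 0),
    y = c(ring_radius * sin(ang), r_in * sin(ang), 0),
    z = c(rep(5, n), rep(-8, n), 0),
    weight = c(w, rep(0.8, n), 1),
    sigma = rep(sigma, 2 * n + 1)
  )
  attr(tpl, "symmetry") <- as.integer(sym)
  attr(tpl, "sigma") <- sigma
  attr(tpl, "unit_type") <- unit_type
  tpl
}

#' Context template: central unit plus one ring of neighbours
#'
#' Augments a [unit_template] with one ring of neighbour-unit blobs (one
#' broad Gaussian per adjacent hexamer) at the lattice spacing, dipped below
#' the tangential plane according to the typical shell radius. Matching with
#' these context templates emulates a mask encompassing the central unit and
#' one ring of adjacent hexamers: positions without a coherent surrounding
#' lattice score poorly, which suppresses spurious correlation peaks.
#'
#' @inheritParams unit_template
#' @param spacing Lattice spacing to the neighbour ring, angstroms.
#' @param shell_radius Typical radius of curvature of the particle shell,
#'   angstroms; sets how far the neighbour ring dips below the plane.
#' @param neighbor_sigma,neighbor_weight Width and weight of each neighbour
#'   blob.
#' @return Template tibble as in [unit_template].
#' @export
context_template <- function(unit_type, ring_radius = NULL, sigma = 7,
                             spacing = 80, shell_radius = 230,
                             neighbor_sigma = 14, neighbor_weight = 3) {
  tpl <- unit_template(unit_type, ring_radius, sigma)
  n_nb <- if (unit_type == "pentamer_C5") 5L else 6L
  dip <- -(shell_radius - sqrt(shell_radius^2 - spacing^2))
  ang <- 2 * pi * (seq_len(n_nb) - 1) / n_nb
  tpl$sigma <- rep(sigma, nrow(tpl))
  nb <- tibble(x = spacing * cos(ang), y = spacing * sin(ang),
               z = rep(dip, n_nb), weight = rep(neighbor_weight, n_nb),
               sigma = rep(neighbor_sigma, n_nb))
  out <- dplyr::bind_rows(tpl, nb)
  attr(out, "symmetry") <- attr(tpl, "symmetry")
  attr(out, "sigma") <- sigma
  attr(out, "neighbor_sigma") <- neighbor_sigma
  attr(out, "unit_type") <- unit_type
  out
}

#' @rdname unit_template
#' @export
default_templates <- function(sigma = 7) {
  tpls <- lapply(unit_types, unit_template, sigma = sigma)
  names(tpls) <- unit_types
  tpls
}

# Maximum radial extent of a template including 3 sigma of blob width.
template_extent <- function(tpl) {
  sig <- if ("sigma" %in% names(tpl)) tpl$sigma else
    rep(attr(tpl, "sigma"), nrow(tpl))
  max(sqrt(tpl$x^2 + tpl$y^2 + tpl$z^2) + 3 * sig)
}

#' Render a lattice into a density volume
#'
#' Sums the Gaussian pseudo-atoms of every unit, rotated by the unit pose and
#' translated to the unit position. Linear in template amplitude. The lattice
#' must fit inside the box with at least one template radius of margin.
#'
#' @param g A [lattice_graph] (typically after [place_in_box]).
#' @param box Cubic box side in voxels.
#' @param templates Named list of templates per unit type
#'   (default [default_templates]).
#' @param voxel_size Angstroms per voxel; defaults to the lattice voxel size.
#' @param allow_clip Permit density extending beyond the box to be clipped
#'   (used for pair references); by default an overflowing lattice is an
#'   error.
#' @return A [density_volume] of dimension `box^3`.
#' @export
render_density <- function(g, box, templates = default_templates(),
                           voxel_size = g$voxel_size, allow_clip = FALSE) {
  u <- g$units
  ext <- max(vapply(templates[unique(u$unit_type)], template_extent,
                    numeric(1))) / voxel_size
  lo <- c(min(u$x), min(u$y), min(u$z)) - ext
  hi <- c(max(u$x), max(u$y), max(u$z)) + ext
  if (!allow_clip && (any(lo < 0) || any(hi > box - 1))) {
    stop(sprintf(
      paste0("lattice exceeds box: occupied extent [%.1f..%.1f, %.1f..%.1f, ",
             "%.1f..%.1f] voxels vs box [0..%d]"),
      lo[1], hi[1], lo[2], hi[2], lo[3], hi[3], box - 1), call. = FALSE)
  }
  grid <- array(0, dim = c(box, box, box))
  axes <- 0:(box - 1)
  for (i in seq_len(nrow(u))) {
    tpl <- templates[[u$unit_type[i]]]
    sig_atoms <- if ("sigma" %in% names(tpl)) tpl$sigma else
      rep(attr(tpl, "sigma"), nrow(tpl))
    R <- rotation_from_euler(u$phi[i], u$theta[i], u$psi[i])
    local_vox <- as.matrix(tpl[, c("x", "y", "z")]) / voxel_size
    pos <- t(R %*% t(local_vox)) +
      matrix(c(u$x[i], u$y[i], u$z[i]), nrow(tpl), 3, byrow = TRUE)
    for (a in seq_len(nrow(pos))) {
      sigma_vox <- sig_atoms[a] / voxel_size
      r <- ceiling(3 * sigma_vox)
      cx <- pos[a, ]
      if (any(cx + r < 0) || any(cx - r > box - 1)) next
      ix <- max(0, ceiling(cx[1] - r)):min(box - 1, floor(cx[1] + r))
      iy <- max(0, ceiling(cx[2] - r)):min(box - 1, floor(cx[2] + r))
      iz <- max(0, ceiling(cx[3] - r)):min(box - 1, floor(cx[3] + r))
      gx <- exp(-(ix - cx[1])^2 / (2 * sigma_vox^2))
      gy <- exp(-(iy - cx[2])^2 / (2 * sigma_vox^2))
      gz <- exp(-(iz - cx[3])^2 / (2 * sigma_vox^2))
      blob <- tpl$weight[a] * outer(outer(gx, gy), gz)
      grid[ix + 1, iy + 1, iz + 1] <- grid[ix + 1, iy + 1, iz + 1] + blob
    }
  }
  density_volume(grid, voxel_size)
}

#' Missing-wedge specification
#'
#' Models the limited tilt range of tomographic acquisition as a binary wedge
#' in Fourier space: with tilt axis x and beam along z, the sampled region is
#' the set of spatial frequencies whose (ky, kz) direction corresponds to a
#' tilt angle inside `[min_angle, max_angle]`.
#'
#' @param tilt_axis One of `"x"`, `"y"`, `"z"`.
#' @param min_angle,max_angle Covered tilt range in degrees
#'   (`min_angle < max_angle`).
#' @return Object of class `wedge_spec`.
#' @export
wedge_spec <- function(tilt_axis = "x", min_angle = -60, max_angle = 60) {
  if (!tilt_axis %in% c("x", "y", "z")) {
    stop("tilt_axis must be one of x, y, z", call. = FALSE)
  }
  if (min_angle >= max_angle) stop("min_angle must be < max_angle",
                                   call. = FALSE)
  structure(list(tilt_axis = tilt_axis, min_angle = min_angle,
                 max_angle = max_angle), class = "wedge_spec")
}

fft_freqs <- function(n) {
  idx <- 0:(n - 1)
  ifelse(idx > n / 2, idx - n, idx)
}

# Binary wedge mask in FFT layout for a cubic box, optionally rotated:
# a frequency k is kept when R_inv %*% k lies in the sampled wedge.
wedge_mask <- function(box, wedge, R = NULL) {
  k <- fft_freqs(box)
  kx <- array(rep(k, times = box * box), dim = c(box, box, box))
  ky <- aperm(kx, c(2, 1, 3))
  kz <- aperm(kx, c(3, 2, 1))
  if (!is.null(R)) {
    K <- rbind(as.vector(kx), as.vector(ky), as.vector(kz))
    K <- t(R) %*% K
    kx <- array(K[1, ], dim = c(box, box, box))
    ky <- array(K[2, ], dim = c(box, box, box))
    kz <- array(K[3, ], dim = c(box, box, box))
  }
  uv <- switch(wedge$tilt_axis,
               x = list(ky, kz),
               y = list(kx, kz),
               z = list(kx, ky))
  ang <- atan2(uv[[2]], uv[[1]]) * 180 / pi
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  mask <- ang >= wedge$min_angle & ang <= wedge$max_angle
  mask[uv[[1]] == 0 & uv[[2]] == 0] <- TRUE  # tilt-axis line is always sampled
  mask
}

#' Apply a missing-wedge Fourier mask
#'
#' Zeroes all Fourier coefficients outside the sampled wedge. Idempotent;
#' a wedge covering -90..+90 degrees is the identity.
#'
#' @param vol A [density_volume] with a cubic grid.
#' @param wedge A [wedge_spec].
#' @return The wedge-filtered [density_volume].
#' @export
apply_missing_wedge <- function(vol, wedge = wedge_spec()) {
  d <- dim(vol$grid)
  stopifnot(length(unique(d)) == 1)
  mask <- wedge_mask(d[1], wedge)
  ft <- stats::fft(vol$grid)
  ft[!mask] <- 0
  vol$grid <- Re(stats::fft(ft, inverse = TRUE)) / prod(d)
  vol
}

#' Add seeded Gaussian noise to a volume
#'
#' @param vol A [density_volume].
#' @param sigma Noise standard deviation (same intensity units as the volume).
#' @param seed Integer seed; identical seeds give identical noise.
#' @return The noisy [density_volume].
#' @export
add_noise <- function(vol, sigma, seed) {
  vol$grid <- vol$grid + withr::with_seed(
    seed, array(stats::rnorm(length(vol$grid), sd = sigma), dim = dim(vol$grid)))
  vol
}
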