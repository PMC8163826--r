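#' Extract subtomograms at table positions
#'
#' One cube per table row, centred (at voxel `floor(box/2)`) on the rounded
#' particle position. Rows whose box would leave the volume are skipped with
#' a warning.
#'
#' @param vol A [density_volume].
#' @param table Particle table.
#' @param box Cube side, voxels.
#' @return List with `stack` (list of 3D arrays) and `table` (the retained
#'   rows).
#' @export
extract_subtomograms <- function(vol, table, box) {
  table <- as_particle_table(table)
  stack <- list()
  keep <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    ctr <- round(c(table$x[i], table$y[i], table$z[i]))
    sub <- extract_box(vol$grid, ctr, box)
    if (is.null(sub)) next
    keep[i] <- TRUE
    stack[[length(stack) + 1]] <- sub
  }
  if (any(!keep)) {
    warning(sum(!keep), " particle(s) out of bounds; skipped", call. = FALSE)
  }
  list(stack = stack, table = table[keep, , drop = FALSE])
}

#' Remove duplicate particles by distance cutoff
#'
#' Greedy: particles are visited in decreasing cc (ties broken by row index)
#' and a particle is kept only when no already-kept particle lies within
#' `cutoff` angstroms.
#'
#' @param table Particle table.
#' @param cutoff Distance cutoff, angstroms.
#' @param voxel_size Angstroms per voxel.
#' @return The de-duplicated particle table.
#' @export
remove_duplicates <- function(table, cutoff, voxel_size) {
  table <- as_particle_table(table)
  ord <- order(-table$cc, seq_len(nrow(table)))
  pos <- as.matrix(table[, c("x", "y", "z")]) * voxel_size
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) > 0) {
      dd <- sqrt(rowSums((pos[kept, , drop = FALSE] -
                            matrix(pos[i, ], length(kept), 3,
                                   byrow = TRUE))^2))
      if (any(dd < cutoff)) next
    }
    kept <- c(kept, i)
  }
  table[sort(kept), , drop = FALSE]
}

#' Discard particles below a correlation threshold
#'
#' Rows with `cc` strictly below `min_cc` are removed.
#'
#' @param table Particle table.
#' @param min_cc Correlation threshold.
#' @return Filtered particle table.
#' @export
threshold_cc <- function(table, min_cc) {
  table <- as_particle_table(table)
  table[table$cc >= min_cc, , drop = FALSE]
}

#' Apply Cn symmetry about the box z axis
#'
#' Averages the volume over rotations by `k * 360 / n` degrees,
#' `k = 0 .. n-1`.
#'
#' @param vol A [density_volume] (cubic).
#' @param n Symmetry order (>= 1).
#' @return The symmetrized [density_volume].
#' @export
apply_symmetry <- function(vol, n) {
  stopifnot(n >= 1)
  if (n == 1) return(vol)
  acc <- vol$grid
  for (k in seq_len(n - 1)) {
    acc <- acc + rotate_grid(vol$grid, rot_z(k * 360 / n))
  }
  vol$grid <- acc / n
  vol
}

#' Wedge-mask-weighted average of a subtomogram stack
#'
#' Fourier-space average compensating the orientation-dependent missing
#' wedge: each subtomogram's spectrum is masked by its (rotated) binary wedge
#' mask, the masked spectra are summed and divided by the summed mask
#' coverage. Frequencies covered by no subtomogram are set to 0 and reported
#' via the `coverage` attribute (fraction of Fourier voxels covered at least
#' once).
#'
#' @param stack List of aligned 3D arrays (equal cubic dimensions).
#' @param masks List of binary Fourier masks, one per subtomogram — for a
#'   subtomogram that was rotated by `R` during alignment use
#'   `wedge_mask(box, wedge, R = t(R))`.
#' @param floor_coverage Minimum summed coverage used in the division.
#' @return A [density_volume] (voxel size 1 unless set by the caller) with
#'   attribute `coverage`.
#' @param voxel_size Angstroms per voxel of the result.
#' @export
weighted_average <- function(stack, masks, voxel_size = 1,
                             floor_coverage = 1e-3) {
  stopifnot(length(stack) == length(masks), length(stack) > 0)
  d <- dim(stack[[1]])
  Fsum <- array(0 + 0i, dim = d)
  W <- array(0, dim = d)
  for (i in seq_along(stack)) {
    Fsum <- Fsum + stats::fft(stack[[i]]) * masks[[i]]
    W <- W + masks[[i]]
  }
  covered <- W > 0
  Favg <- array(0 + 0i, dim = d)
  Favg[covered] <- Fsum[covered] / pmax(W[covered], floor_coverage)
  out <- density_volume(Re(stats::fft(Favg, inverse = TRUE)) / prod(d),
                        voxel_size)
  attr(out, "coverage") <- mean(covered)
  out
}

#' Soft spherical mask
#'
#' Value 1 inside `radius`, Gaussian falloff of width `sigma` outside
#' (a gaussian-filtered binary mask).
#'
#' @param box Cube side, voxels.
#' @param radius Radius, voxels.
#' @param sigma Falloff width, voxels.
#' @return 3D array in `[0, 1]`.
#' @export
gaussian_soft_mask <- function(box, radius, sigma = 2) {
  ax <- 0:(box - 1)
  dx2 <- (ax - box / 2)^2
  r <- sqrt(outer(outer(dx2, dx2, `+`), dx2, `+`))
  m <- array(1, dim = c(box, box, box))
  out <- r > radius
  m[out] <- exp(-(r[out] - radius)^2 / (2 * sigma^2))
  m
}

#' Fourier shell correlation of two volumes
#'
#' Per-shell normalized cross-spectral correlation of the (optionally soft
#' masked) maps. Shells are one Fourier voxel wide.
#'
#' @param a,b [density_volume]s of equal dimension and voxel size.
#' @param mask Optional soft real-space mask (3D array).
#' @return Tibble of class `fsc_curve` with columns `freq` (1/angstrom, shell
#'   centre), `fsc`, and `n_voxels` — the number of *independent* Fourier
#'   samples per shell (half the shell voxel count, by Hermitian symmetry of
#'   real maps), the count entering significance bands such as
#'   `3 / sqrt(n)`. The voxel size is attached as an attribute.
#' @export
fsc <- function(a, b, mask = NULL) {
  stopifnot(all(dim(a$grid) == dim(b$grid)),
            abs(a$voxel_size - b$voxel_size) < 1e-9)
  ga <- a$grid; gb <- b$grid
  if (!is.null(mask)) { ga <- ga * mask; gb <- gb * mask }
  d <- dim(ga); n <- d[1]
  FA <- stats::fft(ga); FB <- stats::fft(gb)
  k <- fft_freqs(n)
  kx <- array(rep(k, times = n * n), dim = d)
  ky <- aperm(kx, c(2, 1, 3)); kz <- aperm(kx, c(3, 2, 1))
  shell <- round(sqrt(kx^2 + ky^2 + kz^2))
  nmax <- floor(n / 2)
  num <- Re(FA * Conj(FB)); pa <- Mod(FA)^2; pb <- Mod(FB)^2
  vals <- vapply(1:nmax, function(s) {
    sel <- shell == s
    c(sum(num[sel]), sum(pa[sel]), sum(pb[sel]), sum(sel))
  }, numeric(4))
  curve <- tibble(
    freq = (1:nmax) / (n * a$voxel_size),
    fsc = vals[1, ] / sqrt(pmax(vals[2, ] * vals[3, ], 1e-300)),
    n_voxels = vals[4, ] / 2)
  class(curve) <- c("fsc_curve", class(curve))
  attr(curve, "voxel_size") <- a$voxel_size
  curve
}

#' Resolution at an FSC threshold
#'
#' Inverse frequency of the first crossing below `threshold`, linearly
#' interpolated between shells. When the curve never drops below the
#' threshold the Nyquist resolution is returned with attribute
#' `nyquist_limited = TRUE`.
#'
#' @param curve An [fsc] curve.
#' @param threshold FSC threshold (default 0.143).
#' @return Resolution in angstroms.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  below <- which(curve$fsc < threshold)
  if (length(below) == 0) {
    res <- 1 / curve$freq[nrow(curve)]
    attr(res, "nyquist_limited") <- TRUE
    return(res)
  }
  i <- below[1]
  if (i == 1) {
    res <- 1 / curve$freq[1]
    attr(res, "nyquist_limited") <- FALSE
    return(res)
  }
  f <- curve$freq[i - 1] + (curve$fsc[i - 1] - threshold) /
    (curve$fsc[i - 1] - curve$fsc[i]) * (curve$freq[i] - curve$freq[i - 1])
  res <- 1 / f
  attr(res, "nyquist_limited") <- FALSE
  res
}

#' Cylinder-parametric seed poses for a tube
#'
#' Initial oversampled subtomogram positions and orientations on a cylinder
#' fitted to the tube lattice: the axis is the principal component of the
#' unit positions, the radius the mean axial distance; seeds are placed on an
#' angular/axial grid `oversample` times denser than the unit lattice, with
#' radial normals.
#'
#' @param g A tube [lattice_graph] (annotation input).
#' @param oversample Linear oversampling factor (~2 gives ~4x more seeds than
#'   units).
#' @return Particle table of seed poses.
#' @export
seed_tube_poses <- function(g, oversample = 2) {
  u <- g$units
  pos <- as.matrix(u[, c("x", "y", "z")]) * g$voxel_size
  ctr <- colMeans(pos)
  pc <- stats::prcomp(pos)
  axis <- pc$rotation[, 1]
  rel <- sweep(pos, 2, ctr)
  t_ax <- rel %*% axis
  radial <- rel - t_ax %*% t(axis)
  radius <- mean(sqrt(rowSums(radial^2)))
  spacing <- if (is.finite(g$spacing)) g$spacing else
    stats::median(g$edges$distance)
  n_around <- max(6, round(2 * pi * radius / spacing) * oversample)
  dz <- spacing * sqrt(3) / 2 / oversample
  zr <- range(t_ax)
  e1 <- canonical_tangent(axis)
  e2 <- cross3(axis, e1)
  purrr::map_dfr(seq(zr[1], zr[2], by = dz), function(tz) {
    purrr::map_dfr(2 * pi * (seq_len(n_around) - 1) / n_around, function(a) {
      n <- cos(a) * e1 + sin(a) * e2
      p <- (ctr + tz * axis + radius * n) / g$voxel_size
      # circumferential in-plane axis, matching the tube lattice convention
      tang <- -sin(a) * e1 + cos(a) * e2
      e <- euler_from_frame(n, x_axis = tang)
      unit_row(p[1], p[2], p[3], e, cc = 1, unit_type = "hexamer_C2")
    })
  }) |> as_particle_table()
}

#' Iterative tube subtomogram averaging with FSC
#'
#' Full pipeline for a regular tube: cylinder-parametric seeding
#' ([seed_tube_poses]), iterative alignment of each subtomogram against the
#' current reference with duplicate-distance and correlation filtering, C2
#' symmetrization of the reference, then an even/odd half-set split with
#' independent averaging and mask-corrected FSC.
#'
#' @param vol A [density_volume] containing the tube.
#' @param g The annotated tube [lattice_graph] (seeding input).
#' @param box Subtomogram box side, voxels.
#' @param n_rounds Alignment rounds.
#' @param max_shift Translation search bound, voxels.
#' @param rot_range,rot_step Rotation search, degrees.
#' @param dup_cutoff Duplicate distance cutoff, angstroms (default
#'   `0.5 * spacing`).
#' @param min_cc Correlation threshold applied after the first round.
#' @param oversample Seeding oversampling factor.
#' @param reference Optional starting reference [density_volume] (e.g. a
#'   rendered hexamer template); by default the mean of the seeded
#'   subtomograms is used. Later rounds always align against the current
#'   data-derived average.
#' @param wedge Optional [wedge_spec] for wedge-weighted final averaging.
#' @return List: `average` (C2-symmetrized [density_volume]), `halves`,
#'   `fsc` curve, `resolution` (angstroms), `table` (final poses).
#' @export
run_tube_average <- function(vol, g, box = 16, n_rounds = 2, max_shift = 2,
                             rot_range = 6, rot_step = 3, dup_cutoff = NULL,
                             min_cc = 0.1, oversample = 2, reference = NULL,
                             wedge = NULL) {
  spacing <- if (is.finite(g$spacing)) g$spacing else
    stats::median(g$edges$distance)
  if (is.null(dup_cutoff)) dup_cutoff <- 0.6 * spacing
  table <- seed_tube_poses(g, oversample)
  rots <- vector("list", nrow(table))
  align_round <- function(table, reference) {
    res <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
      u <- table[i, ]
      ctr <- round(c(u$x, u$y, u$z))
      sub <- extract_box(vol$grid, ctr, box)
      if (is.null(sub)) {
        return(dplyr::mutate(u, cc = -1))
      }
      R0 <- rotation_from_euler(u$phi, u$theta, u$psi)
      best <- list(cc = -Inf)
      gr <- small_rotation_grid(rot_range, rot_step)
      mask <- spherical_mask(box, box / 2 - 1)
      for (k in seq_len(nrow(gr))) {
        Rc <- R0 %*% rot_x(gr$rx[k]) %*% rodrigues(c(0, 1, 0), gr$ry[k]) %*%
          rot_z(gr$rz[k])
        ref_rot <- rotate_grid(reference, Rc)
        r <- ncc_shift_search(sub, ref_rot, mask, max_shift)
        if (r$cc > best$cc) best <- list(cc = r$cc, shift = r$shift, R = Rc)
      }
      eu <- euler_from_rotation(best$R)
      tibble(x = ctr[1] + best$shift[1], y = ctr[2] + best$shift[2],
             z = ctr[3] + best$shift[3], phi = eu[["phi"]],
             theta = eu[["theta"]], psi = eu[["psi"]], cc = best$cc,
             unit_type = u$unit_type, network_id = u$network_id,
             group = u$group, subclass = u$subclass)
    })
    as_particle_table(res[res$cc > -1, , drop = FALSE])
  }
  mean_in_frame <- function(table, symmetrize = TRUE) {
    acc <- array(0, dim = c(box, box, box)); n_used <- 0
    for (i in seq_len(nrow(table))) {
      p <- c(table$x[i], table$y[i], table$z[i])
      sub <- extract_box(vol$grid, round(p), box)
      if (is.null(sub)) next
      R <- rotation_from_euler(table$phi[i], table$theta[i], table$psi[i])
      acc <- acc + rotate_grid(sub, t(R), pre_shift = p - round(p))
      n_used <- n_used + 1
    }
    out <- density_volume(acc / max(1, n_used), vol$voxel_size)
    if (symmetrize) out <- apply_symmetry(out, 2)
    out
  }
  if (is.null(reference)) reference <- mean_in_frame(table)
  stopifnot(all(dim(reference$grid) == box))
  for (r in seq_len(n_rounds)) {
    table <- align_round(table, reference$grid)
    table <- remove_duplicates(table, dup_cutoff, vol$voxel_size)
    table <- threshold_cc(table, min_cc)
    if (nrow(table) == 0) stop("all particles removed during tube averaging",
                               call. = FALSE)
    reference <- mean_in_frame(table)
  }
  # even/odd half-set split along the final table order
  idx <- seq_len(nrow(table))
  halves <- list(table[idx %% 2 == 1, ], table[idx %% 2 == 0, ])
  half_avg <- lapply(halves, function(tb) {
    if (is.null(wedge)) return(mean_in_frame(tb))
    stack <- list(); masks <- list()
    for (i in seq_len(nrow(tb))) {
      p <- c(tb$x[i], tb$y[i], tb$z[i])
      sub <- extract_box(vol$grid, round(p), box)
      if (is.null(sub)) next
      R <- rotation_from_euler(tb$phi[i], tb$theta[i], tb$psi[i])
      stack[[length(stack) + 1]] <- rotate_grid(sub, t(R),
                                                pre_shift = p - round(p))
      masks[[length(masks) + 1]] <- wedge_mask(box, wedge, R = t(R))
    }
    apply_symmetry(weighted_average(stack, masks,
                                    voxel_size = vol$voxel_size), 2)
  })
  softmask <- gaussian_soft_mask(box, box / 2 - 2)
  curve <- fsc(half_avg[[1]], half_avg[[2]], mask = softmask)
  final <- half_avg[[1]]
  final$grid <- (half_avg[[1]]$grid + half_avg[[2]]$grid) / 2
  list(average = final, halves = half_avg, fsc = curve,
       resolution = resolution_at(curve), table = table)
}
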