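#' Rotate a volume about its centre
#'
#' Trilinear interpolation; the returned volume is the input object rotated by
#' `R` (a voxel at position `x` takes the value of the input at
#' `t(R) %*% (x - centre) + centre`). Voxels mapping outside the input are 0.
#'
#' @param grid 3D array.
#' @param R 3x3 rotation matrix.
#' @param centre Rotation centre in 0-based voxel coordinates (default
#'   `dim/2`).
#' @param pre_shift Optional length-3 offset (voxels) added to the sampling
#'   position in the input volume, i.e. the output is additionally translated
#'   by `-pre_shift`; used to re-centre particles at fractional positions.
#' @return Rotated 3D array of the same dimension.
#' @export
rotate_grid <- function(grid, R, centre = dim(grid) / 2,
                        pre_shift = c(0, 0, 0)) {
  d <- dim(grid)
  ax <- 0:(d[1] - 1); ay <- 0:(d[2] - 1); az <- 0:(d[3] - 1)
  X <- array(rep(ax, times = d[2] * d[3]), dim = d)
  Y <- aperm(array(rep(ay, times = d[1] * d[3]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(rep(az, times = d[1] * d[2]), dim = d[c(3, 2, 1)]), c(3, 2, 1))
  P <- rbind(as.vector(X) - centre[1], as.vector(Y) - centre[2],
             as.vector(Z) - centre[3])
  Q <- t(R) %*% P
  qx <- Q[1, ] + centre[1] + pre_shift[1]
  qy <- Q[2, ] + centre[2] + pre_shift[2]
  qz <- Q[3, ] + centre[3] + pre_shift[3]
  fx <- floor(qx); fy <- floor(qy); fz <- floor(qz)
  wx <- qx - fx; wy <- qy - fy; wz <- qz - fz
  out <- numeric(length(qx))
  val <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
      iz >= 0 & iz <= d[3] - 1
    v <- numeric(length(ix))
    v[ok] <- grid[cbind(ix[ok] + 1, iy[ok] + 1, iz[ok] + 1)]
    v
  }
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) wx else 1 - wx) * (if (cy) wy else 1 - wy) *
      (if (cz) wz else 1 - wz)
    out <- out + w * val(fx + cx, fy + cy, fz + cz)
  }
  array(out, dim = d)
}

#' Band-pass filter a volume in Fourier space
#'
#' Keeps spatial frequencies between `1/low` and `1/high` (angstroms), with a
#' Gaussian roll-off two Fourier shells wide. The DC term is always removed
#' when `low` is finite.
#'
#' @param vol A [density_volume] (cubic grid).
#' @param low,high Band edges in angstroms, `low > high`.
#' @return The filtered [density_volume].
#' @export
band_pass <- function(vol, low = 425, high = 30) {
  stopifnot(low > high)
  d <- dim(vol$grid)
  n <- d[1]
  k <- fft_freqs(n)
  kx <- array(rep(k, times = n * n), dim = d)
  ky <- aperm(kx, c(2, 1, 3)); kz <- aperm(kx, c(3, 2, 1))
  f <- sqrt(kx^2 + ky^2 + kz^2) / (n * vol$voxel_size)  # 1/A
  flo <- 1 / low; fhi <- 1 / high
  width <- 2 / (n * vol$voxel_size)
  W <- array(1, dim = d)
  below <- f < flo; above <- f > fhi
  W[below] <- exp(-(f[below] - flo)^2 / (2 * width^2))
  W[above] <- exp(-(f[above] - fhi)^2 / (2 * width^2))
  W[f == 0] <- 0
  vol$grid <- Re(stats::fft(stats::fft(vol$grid) * W, inverse = TRUE)) / prod(d)
  vol
}

#' Template-matching configuration
#'
#' @param phi_step In-plane spin step in degrees (must divide 360).
#' @param other_step Arc spacing of the orientation net over the normal
#'   sphere, degrees.
#' @param bandpass Length-2, band-pass edges in angstroms `c(low, high)`,
#'   `low > high`.
#' @param mask_radius Spherical template mask radius in angstroms (`NULL` for
#'   the largest mask fitting the template box).
#' @param peak_min_separation Minimum separation of accepted peaks, angstroms.
#' @param cc_min Minimum correlation for a peak to be considered.
#' @param variance_floor Local standard deviations below this fraction of the
#'   volume-wide maximum are floored in the correlation normalization,
#'   suppressing unstable correlation values in near-empty regions.
#' @return A `match_config` list.
#' @export
match_config <- function(phi_step = 10, other_step = 15,
                         bandpass = c(425, 30), mask_radius = NULL,
                         peak_min_separation = 60, cc_min = 0.1,
                         variance_floor = 0.2) {
  if (360 %% phi_step != 0) stop("phi_step must divide 360", call. = FALSE)
  if (bandpass[1] <= bandpass[2]) {
    stop("bandpass must be c(low, high) with low > high (angstroms)",
         call. = FALSE)
  }
  structure(list(phi_step = phi_step, other_step = other_step,
                 bandpass = bandpass, mask_radius = mask_radius,
                 peak_min_separation = peak_min_separation, cc_min = cc_min,
                 variance_floor = variance_floor),
            class = "match_config")
}

spherical_mask <- function(box, radius_vox, centre = box / 2) {
  if (length(centre) == 1) centre <- rep(centre, 3)
  ax <- 0:(box - 1)
  r2 <- outer(outer((ax - centre[1])^2, (ax - centre[2])^2, `+`),
              (ax - centre[3])^2, `+`)
  (r2 <= radius_vox^2) * 1
}

# Place a small array into a large FFT-layout array so that template voxel
# `centre` lands at index (1,1,1) with wrap-around.
pad_centered <- function(tgrid, nv) {
  nt <- dim(tgrid)
  out <- array(0, dim = nv)
  ix <- ((0:(nt[1] - 1) - floor(nt[1] / 2)) %% nv[1]) + 1
  iy <- ((0:(nt[2] - 1) - floor(nt[2] / 2)) %% nv[2]) + 1
  iz <- ((0:(nt[3] - 1) - floor(nt[3] / 2)) %% nv[3]) + 1
  out[ix, iy, iz] <- tgrid
  out
}

corr_fft <- function(FV, small_grid, nv) {
  FT <- stats::fft(pad_centered(small_grid, nv))
  Re(stats::fft(FV * Conj(FT), inverse = TRUE)) / prod(nv)
}

#' Locally normalized cross-correlation map
#'
#' Correlates a band-pass-filtered, spherically masked template at a fixed
#' orientation against the band-pass-filtered volume at every voxel shift
#' (FFT-based, fast normalized cross-correlation). The value at voxel
#' `(i, j, k)` (0-based) is the correlation coefficient with the template
#' centred there; values lie in `[-1, 1]`. A volume that is constant after
#' filtering yields 0 everywhere.
#'
#' @param vol A [density_volume].
#' @param template A [density_volume] with the same voxel size and a box no
#'   larger than the volume.
#' @param euler Euler triplet `c(phi, theta, psi)` for the template
#'   orientation.
#' @param cfg A [match_config].
#' @param vol_prefiltered Set `TRUE` when `vol` is already band-pass filtered
#'   (used by [scan_orientations] to avoid refiltering).
#' @return 3D correlation array with the volume's dimensions.
#' @export
cc_map <- function(vol, template, euler = c(0, 0, 0), cfg = match_config(),
                   vol_prefiltered = FALSE) {
  nv <- dim(vol$grid); nt <- dim(template$grid)
  if (any(nt > nv)) stop("template box exceeds volume box", call. = FALSE)
  if (!vol_prefiltered) vol <- band_pass(vol, cfg$bandpass[1], cfg$bandpass[2])
  tf <- band_pass(template, cfg$bandpass[1], cfg$bandpass[2])
  R <- rotation_from_euler(euler[1], euler[2], euler[3])
  tgrid <- rotate_grid(tf$grid, R)
  rad <- if (is.null(cfg$mask_radius)) (min(nt) / 2 - 1) else
    cfg$mask_radius / vol$voxel_size
  mask <- spherical_mask(nt[1], rad)
  m <- sum(mask)
  t0 <- mask * (tgrid - sum(tgrid * mask) / m)
  nrg <- sum(t0^2)
  if (nrg < 1e-12) stop("template is degenerate (all-zero after filtering)",
                        call. = FALSE)
  FV <- stats::fft(vol$grid)
  num <- corr_fft(FV, t0, nv)
  s1 <- corr_fft(FV, mask, nv)
  FV2 <- stats::fft(vol$grid^2)
  s2 <- corr_fft(FV2, mask, nv)
  locsd <- sqrt(pmax(s2 - s1^2 / m, 0))
  locsd <- pmax(locsd, cfg$variance_floor * max(locsd))
  denom <- locsd * sqrt(nrg)
  cc <- array(0, dim = nv)
  ok <- denom > 1e-6 * max(denom)
  cc[ok] <- num[ok] / denom[ok]
  pmin(pmax(cc, -1), 1)
}

#' Orientation net for angular scanning
#'
#' Quasi-uniform net over normal directions (`theta` rings every `other_step`
#' degrees, ring populations proportional to `sin(theta)`), combined with
#' in-plane spins every `phi_step` degrees over `360 / sym` (template Cn
#' symmetry reduces the spin range).
#'
#' @param other_step Direction net arc spacing, degrees.
#' @param phi_step Spin step, degrees.
#' @param sym Cn symmetry order of the template.
#' @return Tibble of Euler triplets `phi, theta, psi`.
#' @export
orientation_net <- function(other_step = 15, phi_step = 10, sym = 1L) {
  dirs <- purrr::map_dfr(seq(0, 180, by = other_step), function(th) {
    n_phi <- max(1L, ceiling(360 * sin(deg2rad(th)) / other_step))
    tibble(phi = seq(0, 360, length.out = n_phi + 1)[seq_len(n_phi)],
           theta = th)
  })
  psis <- seq(0, 360 / sym - 1e-9, by = phi_step)
  tidyr::crossing(dirs, psi = psis)
}

#' Scan orientations and templates over a volume
#'
#' For every voxel retains the maximum correlation over all scanned
#' orientations of all templates, then extracts peaks as local correlation
#' maxima with a minimum mutual separation (greedy, highest correlation first,
#' ties broken by lowest linear voxel index).
#'
#' @param vol A [density_volume].
#' @param templates Named list of [density_volume] templates per unit type.
#' @param cfg A [match_config].
#' @return Particle table of peaks (positions 0-based voxels, best Euler
#'   triplet, `cc`, `unit_type` from the winning template).
#' @export
scan_orientations <- function(vol, templates, cfg = match_config()) {
  volf <- band_pass(vol, cfg$bandpass[1], cfg$bandpass[2])
  nv <- dim(volf$grid)
  FV <- stats::fft(volf$grid)
  FV2 <- stats::fft(volf$grid^2)
  best_cc <- array(-Inf, dim = nv)
  best_or <- array(0L, dim = nv)
  best_tp <- array(0L, dim = nv)
  all_orients <- list()
  denom_cache <- list()
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    if (any(dim(tpl$grid) > nv)) stop("template box exceeds volume box",
                                      call. = FALSE)
    tplf <- band_pass(tpl, cfg$bandpass[1], cfg$bandpass[2])
    nt <- dim(tplf$grid)
    rad <- if (is.null(cfg$mask_radius)) (min(nt) / 2 - 1) else
      cfg$mask_radius / vol$voxel_size
    key <- paste(nt[1], signif(rad, 8))
    if (is.null(denom_cache[[key]])) {
      mask <- spherical_mask(nt[1], rad)
      m <- sum(mask)
      s1 <- corr_fft(FV, mask, nv)
      s2 <- corr_fft(FV2, mask, nv)
      locsd <- sqrt(pmax(s2 - s1^2 / m, 0))
      locsd <- pmax(locsd, cfg$variance_floor * max(locsd))
      denom_cache[[key]] <- list(mask = mask, m = m, locsd = locsd)
    }
    ctx <- denom_cache[[key]]
    sym <- attr(tpl, "symmetry") %||% 1L
    net <- orientation_net(cfg$other_step, cfg$phi_step, sym)
    all_orients[[ti]] <- net
    for (oi in seq_len(nrow(net))) {
      R <- rotation_from_euler(net$phi[oi], net$theta[oi], net$psi[oi])
      tgrid <- rotate_grid(tplf$grid, R)
      t0 <- ctx$mask * (tgrid - sum(tgrid * ctx$mask) / ctx$m)
      nrg <- sum(t0^2)
      if (nrg < 1e-12) stop("template is degenerate (all-zero after ",
                            "filtering)", call. = FALSE)
      num <- corr_fft(FV, t0, nv)
      denom <- ctx$locsd * sqrt(nrg)
      cc <- array(0, dim = nv)
      ok <- denom > 1e-6 * max(denom)
      cc[ok] <- pmin(pmax(num[ok] / denom[ok], -1), 1)
      upd <- cc > best_cc
      best_cc[upd] <- cc[upd]
      best_or[upd] <- oi
      best_tp[upd] <- ti
    }
  }
  find_cc_peaks(best_cc, best_or, best_tp, all_orients, names(templates),
                vol$voxel_size, cfg)
}

find_cc_peaks <- function(best_cc, best_or, best_tp, orients, type_names,
                          voxel_size, cfg) {
  d <- dim(best_cc)
  cand <- which(best_cc >= cfg$cc_min)
  if (length(cand) == 0) {
    return(as_particle_table(tibble(
      x = numeric(), y = numeric(), z = numeric(), phi = numeric(),
      theta = numeric(), psi = numeric(), cc = numeric(),
      unit_type = character())))
  }
  cand <- cand[order(-best_cc[cand], cand)]
  sep_vox <- cfg$peak_min_separation / voxel_size
  coords <- arrayInd(cand, d) - 1L
  kept <- integer(0)
  kept_pos <- matrix(numeric(0), ncol = 3)
  for (i in seq_along(cand)) {
    p <- coords[i, ]
    if (nrow(kept_pos) > 0) {
      dd <- sqrt(rowSums((kept_pos - matrix(p, nrow(kept_pos), 3,
                                            byrow = TRUE))^2))
      if (any(dd < sep_vox)) next
    }
    kept <- c(kept, cand[i])
    kept_pos <- rbind(kept_pos, p)
  }
  purrr::map_dfr(seq_along(kept), function(i) {
    li <- kept[i]
    ti <- best_tp[li]
    net <- orients[[ti]]
    o <- net[best_or[li], ]
    tibble(x = kept_pos[i, 1], y = kept_pos[i, 2], z = kept_pos[i, 3],
           phi = o$phi, theta = o$theta, psi = o$psi, cc = best_cc[li],
           unit_type = type_names[ti], network_id = NA_integer_,
           group = NA_integer_, subclass = NA_integer_)
  }) |> as_particle_table()
}

#' Refine peaks locally and sort them into unit types
#'
#' For every peak, each template is locally aligned (small bounded rotation
#' and translation search around the peak's pose) and the peak is assigned
#' the type of the best-correlating template, with its pose and correlation
#' updated. This reproduces the sorting of subvolumes into pentamers and
#' hexamers by additional alignment rounds, and sharpens both the poses and
#' the correlation contrast between genuine lattice units and spurious
#' matching peaks.
#'
#' @param vol A [density_volume] (will be band-pass filtered with `cfg`).
#' @param peaks Particle table of peaks.
#' @param templates Named list of template volumes (equal boxes).
#' @param cfg A [match_config].
#' @param max_shift Translation bound, voxels.
#' @param rot_range,rot_step Rotation search bound/step, degrees.
#' @param wedge Optional [wedge_spec] of the tomogram: when given, each
#'   rotated template is degraded by the same missing wedge before scoring,
#'   so that genuine units and artifacts are compared on equal footing
#'   (wedge compensation belongs to this sorting/averaging stage, not to the
#'   initial scan).
#' @return The peaks table with refined poses, updated `cc` and `unit_type`.
#' @export
refine_peaks <- function(vol, peaks, templates, cfg = match_config(),
                         max_shift = 3, rot_range = 12, rot_step = 6,
                         wedge = NULL) {
  peaks <- as_particle_table(peaks)
  volf <- band_pass(vol, cfg$bandpass[1], cfg$bandpass[2])
  tplsf <- lapply(templates, function(t)
    band_pass(t, cfg$bandpass[1], cfg$bandpass[2]))
  nb <- dim(tplsf[[1]]$grid)[1]
  rad <- if (is.null(cfg$mask_radius)) (nb / 2 - 1) else
    cfg$mask_radius / vol$voxel_size
  mask <- spherical_mask(nb, rad)
  wmask <- if (!is.null(wedge)) wedge_mask(nb, wedge) else NULL
  score <- function(sub, ti, Rc) {
    ref_rot <- rotate_grid(tplsf[[ti]]$grid, Rc)
    if (!is.null(wmask)) {
      ft <- stats::fft(ref_rot)
      ft[!wmask] <- 0
      ref_rot <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
    }
    ncc_shift_search(sub, ref_rot, mask, max_shift)
  }
  gr1 <- small_rotation_grid(rot_range, rot_range)
  gr2 <- small_rotation_grid(rot_step, rot_step)
  for (i in seq_len(nrow(peaks))) {
    ctr <- round(c(peaks$x[i], peaks$y[i], peaks$z[i]))
    sub <- extract_box(volf$grid, ctr, nb)
    if (is.null(sub)) next
    R0 <- rotation_from_euler(peaks$phi[i], peaks$theta[i], peaks$psi[i])
    best <- list(cc = -Inf)
    # stage 1: coarse rotations, all templates (type decision)
    for (ti in seq_along(tplsf)) {
      for (k in seq_len(nrow(gr1))) {
        Rc <- R0 %*% rot_x(gr1$rx[k]) %*%
          rodrigues(c(0, 1, 0), gr1$ry[k]) %*% rot_z(gr1$rz[k])
        r <- score(sub, ti, Rc)
        if (r$cc > best$cc) {
          best <- list(cc = r$cc, shift = r$shift, R = Rc,
                       type = names(tplsf)[ti], ti = ti)
        }
      }
    }
    # stage 2: fine rotations around the winner
    if (is.finite(best$cc)) {
      Rb <- best$R
      for (k in seq_len(nrow(gr2))) {
        Rc <- Rb %*% rot_x(gr2$rx[k]) %*%
          rodrigues(c(0, 1, 0), gr2$ry[k]) %*% rot_z(gr2$rz[k])
        r <- score(sub, best$ti, Rc)
        if (r$cc > best$cc) {
          best <- list(cc = r$cc, shift = r$shift, R = Rc, type = best$type,
                       ti = best$ti)
        }
      }
    }
    if (is.finite(best$cc)) {
      eu <- euler_from_rotation(best$R)
      peaks$x[i] <- ctr[1] + best$shift[1]
      peaks$y[i] <- ctr[2] + best$shift[2]
      peaks$z[i] <- ctr[3] + best$shift[3]
      peaks$phi[i] <- eu[["phi"]]; peaks$theta[i] <- eu[["theta"]]
      peaks$psi[i] <- eu[["psi"]]
      peaks$cc[i] <- best$cc
      peaks$unit_type[i] <- best$type
    }
  }
  peaks
}

#' Render a unit template into its own small volume box
#'
#' Convenience for building matching references from the pseudo-atom
#' templates: the template is rendered at identity pose in the centre of a
#' cube just large enough to hold it.
#'
#' @param tpl A [unit_template].
#' @param voxel_size Angstroms per voxel.
#' @param box Optional box side in voxels (default: fits the template extent).
#' @return A [density_volume] with the template's `symmetry` attribute
#'   attached.
#' @export
render_template <- function(tpl, voxel_size = 4, box = NULL) {
  if (is.null(box)) box <- 2 * ceiling(template_extent(tpl) / voxel_size) + 2
  g <- lattice_graph(
    unit_row(box / 2, box / 2, box / 2, c(0, 0, 0),
             unit_type = attr(tpl, "unit_type")),
    tibble(from = integer(), to = integer()),
    closed = FALSE, voxel_size = voxel_size)
  tpls <- list(tpl); names(tpls) <- attr(tpl, "unit_type")
  out <- render_density(g, box, templates = tpls, voxel_size = voxel_size)
  attr(out, "symmetry") <- attr(tpl, "symmetry")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
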