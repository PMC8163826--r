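test_that("subtomogram extraction centres particles and skips out-of-bounds rows", {
  grid <- array(0, c(32, 32, 32))
  grid[17, 21, 13] <- 1  # 0-based (16, 20, 12)
  vol <- density_volume(grid, 4)
  tb <- as_particle_table(tibble::tibble(
    x = c(16, 1), y = c(20, 1), z = c(12, 1), phi = 0, theta = 0, psi = 0,
    cc = 1, unit_type = "hexamer_C6"))
  expect_warning(st <- extract_subtomograms(vol, tb, 16), "out of bounds")
  expect_length(st$stack, 1)
  expect_equal(nrow(st$table), 1)
  am <- arrayInd(which.max(st$stack[[1]]), c(16, 16, 16)) - 1
  expect_equal(as.vector(am), c(8, 8, 8))
  empty <- extract_subtomograms(vol, tb[0, ], 16)
  expect_length(empty$stack, 0)
})

test_that("duplicate removal is greedy by cc with the stated cutoff", {
  tb <- as_particle_table(tibble::tibble(
    x = c(0, 0.5, 10), y = 0, z = 0, phi = 0, theta = 0, psi = 0,
    cc = c(0.5, 0.9, 0.7), unit_type = "hexamer_C6"))
  out <- remove_duplicates(tb, cutoff = 20, voxel_size = 4)
  # rows 1 and 2 are 2 A apart: the higher-cc row survives
  expect_equal(nrow(out), 2)
  expect_equal(out$cc, c(0.9, 0.7))
  # cc threshold removes strictly below
  expect_equal(nrow(threshold_cc(tb, 0.7)), 2)
  expect_equal(nrow(threshold_cc(tb, 0.95)), 0)
})

test_that("oversampled tube annotations dedupe to the unit count", {
  t <- build_tube(8, 4, 80)
  u <- t$units
  # 4x oversampling: four jittered copies of every annotation
  copies <- purrr::map_dfr(1:4, function(k) {
    uu <- u
    withr::with_seed(k, {
      uu$x <- uu$x + rnorm(nrow(uu), sd = 0.3)
      uu$y <- uu$y + rnorm(nrow(uu), sd = 0.3)
      uu$cc <- runif(nrow(uu), 0.5, 1)
    })
    uu
  })
  out <- remove_duplicates(copies, cutoff = 40, voxel_size = t$voxel_size)
  expect_lte(abs(nrow(out) - nrow(u)), ceiling(0.02 * nrow(u)))
})

test_that("Cn symmetrization is an averaging projection about z", {
  withr::with_seed(50, {
    v <- density_volume(array(rnorm(24^3), c(24, 24, 24)), 4)
  })
  expect_identical(apply_symmetry(v, 1)$grid, v$grid)
  s2 <- apply_symmetry(v, 2)
  s22 <- apply_symmetry(s2, 2)
  # idempotence holds away from the box corners (rotation support)
  inner <- latticectx:::spherical_mask(24, 9) > 0
  expect_equal(s22$grid[inner], s2$grid[inner], tolerance = 1e-6)
  # symmetrized map invariant under a further 360/n rotation
  r <- rotate_grid(s2$grid, latticectx:::rot_z(180))
  expect_gt(cor(r[inner], s2$grid[inner]), 0.98)
})

test_that("wedge-weighted averaging reduces to the plain mean for full coverage", {
  withr::with_seed(51, {
    stack <- lapply(1:3, function(i) array(rnorm(16^3), c(16, 16, 16)))
  })
  full <- array(1, c(16, 16, 16))
  wa <- weighted_average(stack, list(full, full, full), voxel_size = 4)
  plain <- (stack[[1]] + stack[[2]] + stack[[3]]) / 3
  expect_equal(wa$grid, plain, tolerance = 1e-9)
  expect_equal(attr(wa, "coverage"), 1)
  # complementary half-coverage wedges reconstruct the signal exactly
  m1 <- wedge_mask(16, wedge_spec("x", -45, 45))
  m2 <- !m1
  sig <- stack[[1]]
  f <- fft(sig)
  s1 <- Re(fft(f * m1, inverse = TRUE)) / 16^3
  s2v <- Re(fft(f * m2, inverse = TRUE)) / 16^3
  wa2 <- weighted_average(list(s1, s2v), list(m1, m2), voxel_size = 4)
  expect_equal(wa2$grid, sig, tolerance = 1e-9)
  # single subtomogram: itself inside its wedge
  wa3 <- weighted_average(list(s1), list(m1), voxel_size = 4)
  expect_equal(wa3$grid, s1, tolerance = 1e-9)
  expect_lt(attr(wa3, "coverage"), 1)
})

test_that("FSC is exactly 1 for identical maps and within the null band for noise", {
  withr::with_seed(52, {
    a <- density_volume(array(rnorm(32^3), c(32, 32, 32)), 4)
    b <- density_volume(array(rnorm(32^3), c(32, 32, 32)), 4)
  })
  self <- fsc(a, a)
  expect_true(all(abs(self$fsc - 1) < 1e-9))
  r <- resolution_at(self)
  expect_true(attr(r, "nyquist_limited"))
  null <- fsc(a, b)
  band <- 3 / sqrt(null$n_voxels)
  expect_gte(mean(abs(null$fsc) < band), 0.95)
})

test_that("a 20 A band-limited signal crosses FSC 0.143 near the band edge", {
  n <- 64; vs <- 4
  withr::with_seed(53, {
    sig <- array(rnorm(n^3), c(n, n, n))
    k <- latticectx:::fft_freqs(n)
    kx <- array(rep(k, times = n * n), dim = c(n, n, n))
    ky <- aperm(kx, c(2, 1, 3)); kz <- aperm(kx, c(3, 2, 1))
    f <- sqrt(kx^2 + ky^2 + kz^2) / (n * vs)
    F <- fft(sig); F[f > 1 / 20] <- 0
    sig <- Re(fft(F, inverse = TRUE)) / n^3
    sig <- sig / sd(sig)
    h1 <- density_volume(sig + array(rnorm(n^3, sd = 0.15), dim(sig)), vs)
    h2 <- density_volume(sig + array(rnorm(n^3, sd = 0.15), dim(sig)), vs)
  })
  curve <- fsc(h1, h2)
  res <- resolution_at(curve, 0.143)
  expect_gte(res, 18)
  expect_lte(res, 22)
})

test_that("tube averaging recovers the hexamer and fails on shuffled poses", {
  g <- place_in_box(build_tube(6, 3, 80, voxel_size = 8), 40)
  vol <- render_density(g, 40)
  ref0 <- render_template(unit_template("hexamer_C2"), voxel_size = 8,
                          box = 16)
  res <- run_tube_average(vol, g, box = 16, n_rounds = 2, max_shift = 4,
                          rot_range = 3, rot_step = 3, min_cc = 0.4,
                          reference = ref0)
  expect_equal(nrow(res$table), nrow(g$units))
  m <- latticectx:::spherical_mask(16, 5) > 0
  expect_gt(cor(as.vector(res$average$grid[m]), as.vector(ref0$grid[m])),
            0.95)
  expect_s3_class(res$fsc, "fsc_curve")
  # negative control: random poses give a near-featureless average
  tb <- res$table
  withr::with_seed(54, {
    tb$phi <- runif(nrow(tb), 0, 360)
    tb$theta <- runif(nrow(tb), 0, 180)
    tb$psi <- runif(nrow(tb), 0, 360)
    tb$x <- runif(nrow(tb), 12, 28); tb$y <- runif(nrow(tb), 12, 28)
    tb$z <- runif(nrow(tb), 12, 28)
  })
  acc <- array(0, c(16, 16, 16))
  for (i in seq_len(nrow(tb))) {
    sub <- latticectx:::extract_box(vol$grid, round(c(tb$x[i], tb$y[i],
                                                      tb$z[i])), 16)
    R <- rotation_from_euler(tb$phi[i], tb$theta[i], tb$psi[i])
    acc <- acc + rotate_grid(sub, t(R))
  }
  shuffled <- acc / nrow(tb)
  expect_lt(abs(cor(as.vector(shuffled[m]), as.vector(ref0$grid[m]))), 0.3)
})

test_that("noisy tubes resolve more coarsely than noise-free tubes", {
  g <- place_in_box(build_tube(6, 3, 80, voxel_size = 8), 40)
  vol <- render_density(g, 40)
  ref0 <- render_template(unit_template("hexamer_C2"), voxel_size = 8,
                          box = 16)
  clean <- run_tube_average(vol, g, box = 16, n_rounds = 1, max_shift = 4,
                            rot_range = 3, rot_step = 3, min_cc = 0.4,
                            reference = ref0)
  noisy_vol <- add_noise(vol, 0.6 * sd(vol$grid), seed = 6)
  noisy <- run_tube_average(noisy_vol, g, box = 16, n_rounds = 1,
                            max_shift = 4, rot_range = 3, rot_step = 3,
                            min_cc = 0.2, reference = ref0)
  expect_gte(as.numeric(noisy$resolution), as.numeric(clean$resolution))
})
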