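test_that("tube generator produces a regular rolled hexagonal lattice", {
  t <- fix_tube()
  expect_equal(nrow(t$units), 120)
  expect_equal(sum(t$units$unit_type == "pentamer_C5"), 0)
  expect_false(t$closed)
  # brute-force distance scan: all nearest neighbours within 10% of spacing
  pos <- as.matrix(t$units[, c("x", "y", "z")]) * t$voxel_size
  d <- as.matrix(dist(pos)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(nn >= 0.9 * 80 & nn <= 1.1 * 80))
  # every generator edge passes the connectivity criteria
  crit <- connectivity_criteria()
  for (i in seq_len(nrow(t$edges))) {
    pp <- pair_passes(t$units[t$edges$from[i], ], t$units[t$edges$to[i], ],
                      crit, t$voxel_size)
    expect_true(pp$pass)
  }
  # normals point radially outward
  u <- t$units
  for (i in sample(nrow(u), 10)) {
    n <- normal_from_euler(u$phi[i], u$theta[i])
    r <- c(u$x[i], u$y[i], 0); r <- r / sqrt(sum(r^2))
    expect_equal(as.vector(n), r, tolerance = 1e-9)
  }
  expect_error(build_tube(5, 5, 80), "n_around")
  expect_error(build_tube(12, 5, 150), "spacing")
})

test_that("icosahedral generators follow Caspar-Klug counts and adjacency", {
  i1 <- fix_t1()
  expect_equal(sum(i1$units$unit_type == "pentamer_C5"), 12)
  expect_equal(nrow(i1$units), 12)
  expect_true(i1$closed)

  i3 <- fix_t3()
  expect_equal(sum(i3$units$unit_type == "pentamer_C5"), 12)
  expect_equal(sum(i3$units$unit_type == "hexamer_C6"), 20)
  # every hexamer has exactly 3 pentamer neighbours, alternating around its ring
  hex <- which(i3$units$unit_type == "hexamer_C6")
  for (h in hex) {
    nb <- latticectx:::ordered_neighbors(i3, h)
    is_p <- i3$units$unit_type[nb] == "pentamer_C5"
    expect_equal(sum(is_p), 3)
    expect_true(all(diff(which(is_p)) == 2))
  }
  expect_error(build_icosahedron(4), "T = 4")
})

test_that("polyhedron generator: 12 pentamers, determinism, Euler characteristic", {
  for (seed in 1:10) {
    p <- build_polyhedron(42, elongation = runif(1, 0, 0.15), seed = seed)
    expect_equal(sum(p$units$unit_type == "pentamer_C5"), 12)
    expect_true(p$closed)
    # triangulated closed surface: E = 3 (V - 2)  <=>  V - E + F = 2
    expect_equal(nrow(p$edges), 3 * (nrow(p$units) - 2))
  }
  p1 <- build_polyhedron(92, 0.1, seed = 5)
  p2 <- build_polyhedron(92, 0.1, seed = 5)
  expect_identical(p1$units, p2$units)
  expect_error(build_polyhedron(10, 0, 1), "n_units")
  # deterministic generators without RNG
  expect_identical(build_tube(8, 4, 80)$units, build_tube(8, 4, 80)$units)
})

test_that("templates obey their declared Cn symmetry", {
  for (type in c("hexamer_C2", "hexamer_C6", "pentamer_C5")) {
    tpl <- unit_template(type)
    n <- attr(tpl, "symmetry")
    ang <- 2 * pi / n
    Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                 3, 3)
    rot <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(Rz)
    # every rotated pseudo-atom coincides with an original of equal weight
    for (i in seq_len(nrow(tpl))) {
      d <- sqrt(rowSums((as.matrix(tpl[, c("x", "y", "z")]) -
                           matrix(rot[i, ], nrow(tpl), 3, byrow = TRUE))^2))
      j <- which.min(d)
      expect_lt(d[j], 1e-6)
      expect_equal(tpl$weight[j], tpl$weight[i], tolerance = 1e-12)
    }
  }
})

test_that("rendering places density at unit positions and is linear", {
  box <- 32
  g <- lattice_graph(
    tibble::tibble(x = 16, y = 16, z = 16, phi = 0, theta = 0, psi = 0,
                   cc = 1, unit_type = "hexamer_C6", network_id = 1L,
                   group = NA_integer_, subclass = NA_integer_),
    tibble::tibble(from = integer(), to = integer()),
    closed = FALSE, voxel_size = 8)
  v <- render_density(g, box)
  am <- arrayInd(which.max(v$grid), dim(v$grid)) - 1
  expect_equal(as.vector(am), c(16, 16, 16))
  # doubling template weights doubles every voxel
  tpl <- unit_template("hexamer_C6")
  tpl2 <- tpl; tpl2$weight <- 2 * tpl$weight
  attr(tpl2, "symmetry") <- attr(tpl, "symmetry")
  attr(tpl2, "sigma") <- attr(tpl, "sigma")
  v2 <- render_density(g, box, templates = list(hexamer_C6 = tpl2))
  expect_equal(v2$grid, 2 * v$grid, tolerance = 1e-12)
  # overflow is an error listing the extent
  g$units$x <- 2
  expect_error(render_density(g, box), "exceeds box")
})

test_that("missing wedge mask is a projection and noise is seed-reproducible", {
  withr::with_seed(20, {
    v <- density_volume(array(rnorm(16^3), c(16, 16, 16)), 4)
  })
  full <- apply_missing_wedge(v, wedge_spec("x", -90, 90))
  expect_equal(full$grid, v$grid, tolerance = 1e-6)
  w1 <- apply_missing_wedge(v, wedge_spec("x", -60, 60))
  w2 <- apply_missing_wedge(w1, wedge_spec("x", -60, 60))
  expect_equal(w1$grid, w2$grid, tolerance = 1e-9)
  expect_error(wedge_spec("x", 30, 10), "min_angle")
  n1 <- add_noise(v, 0.5, seed = 99)
  n2 <- add_noise(v, 0.5, seed = 99)
  expect_identical(n1$grid, n2$grid)
  expect_false(identical(add_noise(v, 0.5, 1)$grid, n1$grid))
})

test_that("ground-truth tables match rendered poses after boxing", {
  g <- place_in_box(fix_t1(), 96)
  expect_equal(mean(g$units$x), 48, tolerance = 1e-9)
  t <- as_particle_table(g$units)
  expect_equal(nrow(t), 12)
})
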