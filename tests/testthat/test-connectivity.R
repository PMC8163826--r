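flat_unit <- function(x, y = 0, z = 0, phi = 0, theta = 0, psi = 0) {
  tibble::tibble(x = x, y = y, z = z, phi = phi, theta = theta, psi = psi,
                 cc = 1, unit_type = "hexamer_C6", network_id = 1L,
                 group = NA_integer_, subclass = NA_integer_)
}

test_that("pair criteria reject boundary violations with the right labels", {
  crit <- connectivity_criteria()
  vs <- 1
  a <- flat_unit(0)
  expect_false(pair_passes(a, flat_unit(59), crit, vs)$pass)
  expect_match(pair_passes(a, flat_unit(59), crit, vs)$failed, "min_spacing")
  expect_true(pair_passes(a, flat_unit(60), crit, vs)$pass)   # inclusive
  expect_true(pair_passes(a, flat_unit(110), crit, vs)$pass)  # inclusive
  expect_match(pair_passes(a, flat_unit(111), crit, vs)$failed, "max_spacing")
  # normal difference of 50 degrees rejected, 45 accepted
  b50 <- flat_unit(80, theta = 50)
  expect_match(pair_passes(a, b50, crit, vs)$failed, "max_normal_diff")
  # normal tilted 45 deg about the edge direction: normal_diff exactly 45
  # (inclusive), curvature unaffected
  b45 <- flat_unit(80, phi = 0, theta = 45)
  expect_true(pair_passes(a, b45, crit, vs)$pass)
  # curvature beyond +40 (b far below a's tangential plane)
  bless <- flat_unit(50, z = -60)
  expect_match(pair_passes(a, bless, crit, vs)$failed, "max_curvature")
  # an accepting mid-range case
  good <- pair_passes(a, flat_unit(80), crit, vs)
  expect_true(good$pass)
  expect_equal(good$failed, "")
})

test_that("curvature criterion is applied from both units of the pair", {
  crit <- connectivity_criteria()
  # b lies 30 deg below a's plane (curvature +30, fine); seen from b with its
  # normal tilted so that a is far above b's plane -> min_curvature violation
  a <- flat_unit(0)
  d <- 80
  b <- flat_unit(d * cos(-30 * pi / 180), z = d * sin(-30 * pi / 180),
                 phi = 90, theta = 40)
  pp <- pair_passes(a, b, crit, 1)
  gba <- pair_geometry(b, a, 1)
  if (gba$curvature < crit$min_curvature) {
    expect_false(pp$pass)
  } else {
    succeed("configuration not degenerate in this direction")
  }
})

test_that("network construction keeps connected components above size 20", {
  # ground-truth tube: one network of 120
  t <- fix_tube()
  nets <- build_networks(t$units, connectivity_criteria(), t$voxel_size)
  expect_length(nets, 1)
  expect_equal(nrow(nets[[1]]$units), 120)
  expect_equal(unique(nets[[1]]$units$network_id), 1)

  # two T=1 lattices 500 A apart: both components have 12 <= 20 units
  i1 <- fix_t1()
  far <- i1$units
  far$x <- far$x + 500 / i1$voxel_size
  both <- dplyr::bind_rows(i1$units, far)
  expect_length(build_networks(both, connectivity_criteria(), i1$voxel_size),
                0)

  # T=3 lattice: 32 > 20 units retained
  i3 <- fix_t3()
  nets3 <- build_networks(i3$units, connectivity_criteria(), i3$voxel_size)
  expect_length(nets3, 1)
  expect_equal(nrow(nets3[[1]]$units), 32)
})

test_that("size filter is strictly greater-than: 20 discarded, 21 retained", {
  mk_chain <- function(n) {
    purrr::map_dfr(seq_len(n) - 1, function(i) flat_unit(i * 80))
  }
  crit <- connectivity_criteria()
  expect_length(build_networks(mk_chain(20), crit, 1), 0)
  nets <- build_networks(mk_chain(21), crit, 1)
  expect_length(nets, 1)
  expect_equal(nrow(nets[[1]]$units), 21)
})

test_that("recovered edges equal generator edges on gentle ground truth", {
  # tube of radius ~153 A (curvature radius >= 150 A), spacing 80 A
  t <- build_tube(12, 5, 80)
  nets <- build_networks(t$units, connectivity_criteria(), t$voxel_size)
  expect_length(nets, 1)
  rec <- nets[[1]]$edges[, c("from", "to")]
  truth <- t$edges[, c("from", "to")]
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key(rec), key(truth))
})

test_that("pruning removes dangling units and over-coordinated edges", {
  t <- build_tube(8, 4, 80)
  # append a spurious unit dangling off one lattice unit
  sp <- flat_unit(t$units$x[1] + 70 / t$voxel_size, t$units$y[1],
                  t$units$z[1])
  sp$phi <- t$units$phi[1]; sp$theta <- t$units$theta[1]
  aug <- dplyr::bind_rows(t$units, sp)
  nets <- build_networks(aug, connectivity_criteria(), t$voxel_size)
  pruned <- prune_network(nets[[1]])
  expect_lte(nrow(pruned$units), nrow(t$units))
  deg <- tabulate(c(pruned$edges$from, pruned$edges$to), nrow(pruned$units))
  expect_true(all(deg >= 3))
  expect_true(all(deg <= 6))
})
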