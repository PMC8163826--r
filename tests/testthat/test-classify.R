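test_that("position numbering marks partners and shared neighbours", {
  # pentamer partner occupies slot 1
  i3 <- fix_t3()
  ph <- i3$edges[i3$edges$from <= 12 & i3$edges$to > 12, ][1, ]
  np <- number_positions(i3, c(ph$to, ph$from))  # A = hexamer, B = pentamer
  expect_true(1 %in% np$positions_a)
  # shared neighbours: 2' = 6'' and 6' = 2''
  hh <- i3$edges[i3$edges$from > 12 & i3$edges$to > 12, ][1, ]
  np2 <- number_positions(i3, c(hh$from, hh$to))
  expect_equal(np2$slots_a[2], np2$slots_b[6])
  expect_equal(np2$slots_a[6], np2$slots_b[2])
  # tube pair: both position sets empty
  t <- fix_tube()
  e <- t$edges[50, ]
  npt <- number_positions(t, c(e$from, e$to))
  expect_length(npt$positions_a, 0)
  expect_length(npt$positions_b, 0)
})

test_that("canonical lattices classify to their expected groups", {
  # every edge of a T=1 lattice is group 1
  c1 <- classify_edges(fix_t1())
  expect_true(all(c1$group == 1))
  # T=3: hexamer-hexamer pairs are group 2 with two shared pentamers
  c3 <- classify_edges(fix_t3())
  hh <- c3[c3$from > 12 & c3$to > 12, ]
  expect_true(all(hh$group == 2))
  expect_true(all(hh$subclass == 2))
  # tube interior: group 5 with exactly three orientation subclasses
  ct <- classify_edges(fix_tube())
  expect_true(all(ct$group == 5))
  expect_setequal(unique(ct$subclass[ct$subclass > 0]), 1:3)
})

test_that("orientation classes alternate around a hexagon and are rigid-motion invariant", {
  t <- fix_tube()
  deg <- tabulate(c(t$edges$from, t$edges$to), nrow(t$units))
  u <- which(deg == 6)[15]
  nb <- latticectx:::ordered_neighbors(t, u)
  oc <- vapply(nb, function(v) orientation_class(t, c(u, v)), integer(1))
  expect_equal(oc[1:3], oc[4:6])
  expect_setequal(unique(oc), 1:3)
  # rigid rotation of the whole lattice leaves classes unchanged
  R <- rotation_from_euler(25, 40, 10)
  tr <- t
  pos <- as.matrix(t$units[, c("x", "y", "z")]) %*% t(R)
  tr$units$x <- pos[, 1]; tr$units$y <- pos[, 2]; tr$units$z <- pos[, 3]
  for (i in seq_len(nrow(t$units))) {
    Ru <- R %*% rotation_from_euler(t$units$phi[i], t$units$theta[i],
                                    t$units$psi[i])
    e <- euler_from_rotation(Ru)
    tr$units$phi[i] <- e[1]; tr$units$theta[i] <- e[2]; tr$units$psi[i] <- e[3]
  }
  ocr <- vapply(nb, function(v) orientation_class(tr, c(u, v)), integer(1))
  expect_equal(ocr, oc)
})

test_that("local hexamer symmetry detection covers C3, C2 and C1 contexts", {
  i3 <- fix_t3()
  hex <- which(i3$units$unit_type == "hexamer_C6")
  for (h in hex) expect_equal(local_symmetry(i3, h), "C3")
  t <- fix_tube()
  deg <- tabulate(c(t$edges$from, t$edges$to), nrow(t$units))
  expect_equal(local_symmetry(t, which(deg == 6)[1]), "C2_tube")
  # synthetic contexts: single pentamer -> C1; antipodal pair -> C2_pentamer
  g1 <- context_patch(pents_a = 3)
  expect_equal(local_symmetry(g1, 1), "C1")
  g2 <- context_patch(pents_a = c(2, 5))  # slots 2 and 5 are antipodal
  expect_equal(local_symmetry(g2, 1), "C2_pentamer")
  g3 <- context_patch(pents_a = c(2, 4, 6))
  expect_equal(local_symmetry(g3, 1), "C3")
  expect_error(local_symmetry(fix_t1(), 1), "pentamer")
})

test_that("the six context groups are assigned per their definitions", {
  expect_equal(classify_pair(context_patch(partner_pent = TRUE), c(1, 2))$group, 1)
  expect_equal(classify_pair(context_patch(pents_a = 2), c(1, 2))$group, 2)
  expect_equal(classify_pair(context_patch(pents_a = 6), c(1, 2))$group, 2)
  expect_equal(classify_pair(context_patch(pents_a = 4, pents_b = 3),
                             c(1, 2))$group, 3)
  expect_equal(classify_pair(context_patch(pents_a = 4), c(1, 2))$group, 4)
  expect_equal(classify_pair(context_patch(), c(1, 2))$group, 5)
  expect_equal(classify_pair(context_patch(pents_a = c(3, 4)), c(1, 2))$group, 6)
  expect_equal(classify_pair(context_patch(pents_a = c(3, 5)), c(1, 2))$group, 6)
  # two pentamers on one side and one on the other: constrained-first order
  expect_equal(classify_pair(context_patch(pents_a = c(3, 4), pents_b = 4),
                             c(1, 2))$group, 4)
})

test_that("classification is total and swap-consistent on random polyhedra", {
  groups_seen <- integer(0)
  for (seed in 1:8) {
    p <- build_polyhedron(sample(c(42, 92), 1), runif(1, 0, 0.12),
                          seed = seed)
    cls <- classify_edges(p)
    expect_equal(nrow(cls), nrow(p$edges))
    expect_true(all(cls$group %in% 1:6))
    groups_seen <- union(groups_seen, unique(cls$group))
    # swap consistency on a sample of edges
    for (i in sample(nrow(p$edges), 10)) {
      ga <- classify_pair(p, c(p$edges$from[i], p$edges$to[i]))
      gb <- classify_pair(p, c(p$edges$to[i], p$edges$from[i]))
      expect_equal(ga$group, gb$group)
    }
  }
  expect_gte(length(groups_seen), 3)
})

test_that("an exhaustive context sweep yields exactly the six groups", {
  groups <- c(
    classify_pair(context_patch(partner_pent = TRUE), c(1, 2))$group,
    vapply(2:6, function(s)
      classify_pair(context_patch(pents_a = s), c(1, 2))$group, numeric(1)),
    vapply(3:5, function(s)
      classify_pair(context_patch(pents_a = s, pents_b = s), c(1, 2))$group,
      numeric(1)),
    classify_pair(context_patch(pents_a = c(3, 4)), c(1, 2))$group,
    classify_pair(context_patch(pents_a = c(3, 5)), c(1, 2))$group,
    classify_pair(context_patch(pents_a = c(4, 5)), c(1, 2))$group,
    classify_pair(context_patch(), c(1, 2))$group,
    classify_edges(fix_tube())$group,
    classify_edges(fix_t1())$group,
    classify_edges(fix_t3())$group)
  expect_setequal(unique(groups), 1:6)
})

test_that("topology reconciliation restores mistyped units on closed lattices", {
  i3 <- fix_t3()
  bad <- i3
  bad$units$unit_type[1] <- "hexamer_C6"   # a pentamer mistyped
  bad$units$unit_type[13] <- "pentamer_C5" # a hexamer mistyped
  bad$closed <- FALSE
  fixed <- assign_types_by_topology(bad)
  expect_equal(fixed$units$unit_type, i3$units$unit_type)
})
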