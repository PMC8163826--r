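# Shared fixtures, memoised so expensive volumes are built once per run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

fix_tube <- function() memo("tube", function() build_tube(12, 10, 80))
fix_t1 <- function() memo("t1", function() build_icosahedron(1, 80))
fix_t3 <- function() memo("t3", function() build_icosahedron(3, 80))
fix_poly <- function() memo("poly", function()
  build_polyhedron(92, 0.1, seed = 7))

# Small rendered T=3 volume (noise-free) used by alignment tests.
fix_t3_volume <- function() memo("t3vol", function() {
  g <- place_in_box(build_icosahedron(3, 80, voxel_size = 8), 64)
  list(graph = g, volume = render_density(g, 64))
})

random_euler <- function() {
  c(runif(1, 0, 360), runif(1, 1, 179), runif(1, 0, 360))
}

rotation_angle <- function(R1, R2) {
  acos(max(-1, min(1, (sum(diag(t(R1) %*% R2)) - 1) / 2))) * 180 / pi
}

# Independent quaternion-eigenvalue superposition oracle (Horn's method):
# optimal RMSD from the largest eigenvalue of the 4x4 key matrix.
quaternion_rmsd <- function(pa, pb) {
  ca <- colMeans(pa); cb <- colMeans(pb)
  A <- sweep(pa, 2, ca); B <- sweep(pb, 2, cb)
  M <- t(B) %*% A
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sq <- sum(A^2) + sum(B^2) - 2 * lam
  sqrt(max(0, sq) / nrow(pa))
}

# Minimal PDB writer for atom_model-style tibbles (fixed-width ATOM records).
write_pdb_fixture <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, df$atom[i], "ALA", df$chain[i], df$resno[i],
            df$x[i], df$y[i], df$z[i], df$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

random_atom_model <- function(n = 20, chains = "A", seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      chain = rep(chains, length.out = n),
      resno = seq_len(n),
      atom = "CA", element = "C",
      x = rnorm(n, sd = 10), y = rnorm(n, sd = 10), z = rnorm(n, sd = 10))
  })
}

# Flat hexagonal patch around a central unit pair (A, B): pentamers are
# placed at the requested slot numbers of A and B (slot numbering as produced
# by number_positions: slot 1 = partner, slots 2/6 = shared neighbours).
# Slot k of A corresponds to direction -60*(k-1) degrees; mirrored for B.
context_patch <- function(pents_a = integer(0), pents_b = integer(0),
                          partner_pent = FALSE, spacing = 80,
                          voxel_size = 4) {
  s <- spacing / voxel_size
  slot_dir_a <- function(k) -60 * (k - 1)
  slot_dir_b <- function(k) 180 + 60 * (k - 1)
  pos <- list(A = c(0, 0, 0), B = c(s, 0, 0))
  types <- c(A = "hexamer_C6",
             B = if (partner_pent) "pentamer_C5" else "hexamer_C6")
  # a pentamer partner has 5 neighbours in total: skip one of its ring slots
  b_slots <- if (partner_pent) 3:4 else 2:6
  add_unit <- function(p, type) {
    key <- paste(round(p, 4), collapse = ",")
    nm <- names(pos)
    hit <- which(vapply(pos, function(q)
      sqrt(sum((q - p)^2)) < 1e-3, logical(1)))
    if (length(hit) > 0) {
      if (type == "pentamer_C5") types[names(pos)[hit[1]]] <<- type
      return(invisible(NULL))
    }
    id <- paste0("u", length(pos) + 1)
    pos[[id]] <<- p
    types[id] <<- type
  }
  for (k in 2:6) {
    d <- slot_dir_a(k) * pi / 180
    add_unit(c(cos(d), sin(d), 0) * s,
             if (k %in% pents_a) "pentamer_C5" else "hexamer_C6")
  }
  for (k in b_slots) {
    d <- slot_dir_b(k) * pi / 180
    add_unit(pos$B + c(cos(d), sin(d), 0) * s,
             if (k %in% pents_b) "pentamer_C5" else "hexamer_C6")
  }
  nm <- names(pos)
  units <- purrr::map_dfr(nm, function(id) {
    tibble::tibble(x = pos[[id]][1], y = pos[[id]][2], z = pos[[id]][3],
                   phi = 0, theta = 0, psi = 0, cc = 1,
                   unit_type = types[[id]], network_id = 1L,
                   group = NA_integer_, subclass = NA_integer_)
  })
  edges <- latticectx:::edges_from_positions(units, voxel_size,
                                             max_dist = 1.1 * spacing)
  lattice_graph(units, edges, closed = FALSE, voxel_size = voxel_size,
                spacing = spacing)
}
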