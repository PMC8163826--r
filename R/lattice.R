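#' Lattice graph container
#'
#' A `lattice_graph` holds the units of one capsid-like particle (hexamers and
#' pentamers with positions, orientations and scores) together with the
#' validated neighbour edges and their pairwise geometry.
#'
#' @param units Particle table (see [as_particle_table]) with one row per
#'   unit; row order defines `unit_id` 1..n.
#' @param edges Tibble with columns `from`, `to` (unit ids, `from < to`) plus
#'   the [pair_geometry] columns.
#' @param closed Logical; `TRUE` when the surface has no boundary. Closed
#'   lattices must contain exactly 12 pentamers.
#' @param voxel_size Angstroms per voxel for the unit coordinates.
#' @param spacing Nominal lattice spacing in angstroms (generator metadata).
#' @return Object of class `lattice_graph`.
#' @export
lattice_graph <- function(units, edges, closed, voxel_size, spacing = NA_real_) {
  units <- as_particle_table(units)
  n <- nrow(units)
  if (nrow(edges) > 0) {
    if (any(edges$from < 1 | edges$from > n | edges$to < 1 | edges$to > n)) {
      stop("edge endpoints outside unit range", call. = FALSE)
    }
    if (any(edges$from == edges$to)) stop("self-edges are not allowed",
                                          call. = FALSE)
  }
  if (isTRUE(closed)) {
    npent <- sum(units$unit_type == "pentamer_C5")
    if (npent != 12) {
      stop("closed lattice must contain exactly 12 pentamers, found ", npent,
           call. = FALSE)
    }
  }
  structure(list(units = units, edges = as_tibble(edges), closed = closed,
                 voxel_size = voxel_size, spacing = spacing),
            class = "lattice_graph")
}

#' @export
print.lattice_graph <- function(x, ...) {
  cat(sprintf(
    "<lattice_graph> %d units (%d pentamers, %d hexamers), %d edges, %s\n",
    nrow(x$units), sum(x$units$unit_type == "pentamer_C5"),
    sum(x$units$unit_type != "pentamer_C5"), nrow(x$edges),
    if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}

# Edge list from unit positions: all pairs closer than `max_dist` angstroms,
# annotated with pair geometry. Deterministic (ordered by from, to).
edges_from_positions <- function(units, voxel_size, max_dist) {
  pos <- as.matrix(units[, c("x", "y", "z")]) * voxel_size
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d) & d > 1e-6 & d <= max_dist, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(from = integer(), to = integer(), distance = numeric(),
                  tilt = numeric(), twist = numeric(), curvature = numeric(),
                  normal_diff = numeric()))
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  geo <- purrr::map2_dfr(idx[, 1], idx[, 2], function(i, j) {
    pair_geometry(units[i, ], units[j, ], voxel_size)
  })
  dplyr::bind_cols(tibble(from = as.integer(idx[, 1]),
                          to = as.integer(idx[, 2])), geo)
}

# Lock every unit's in-plane orientation to the lattice: the local x axis
# points at the first (lowest-id) neighbour, as the dimeric interfaces of a
# capsid lattice do. Requires edges to be present.
orient_units_to_lattice <- function(units, edges) {
  for (i in seq_len(nrow(units))) {
    nb <- c(edges$to[edges$from == i], edges$from[edges$to == i])
    if (length(nb) == 0) next
    j <- min(nb)
    n <- normal_from_euler(units$phi[i], units$theta[i])
    d <- c(units$x[j] - units$x[i], units$y[j] - units$y[i],
           units$z[j] - units$z[i])
    e <- euler_from_frame(n, x_axis = d)
    units$phi[i] <- e[["phi"]]; units$theta[i] <- e[["theta"]]
    units$psi[i] <- e[["psi"]]
  }
  units
}

unit_row <- function(x, y, z, euler, cc = 1, unit_type, network_id = 1L) {
  tibble(x = x, y = y, z = z,
         phi = euler[[1]], theta = euler[[2]], psi = euler[[3]],
         cc = cc, unit_type = unit_type, network_id = network_id,
         group = NA_integer_, subclass = NA_integer_)
}

#' Build a regular hexamer tube
#'
#' Hexagonal lattice rolled onto a cylinder (axis along z, centred at the
#' origin): `n_around` hexamers per ring, rings axially separated by
#' `spacing * sqrt(3) / 2` with alternating half-step azimuthal offsets, unit
#' normals pointing radially outward and the in-plane x axis along the tube
#' axis. Tube hexamers carry the `hexamer_C2` type.
#'
#' @param n_around Hexamers per ring (>= 6).
#' @param n_rings Number of rings (>= 3).
#' @param spacing Nominal unit spacing in angstroms, within `[60, 110]`.
#' @param voxel_size Angstroms per voxel for the emitted coordinates.
#' @return A [lattice_graph] with `n_around * n_rings` hexamers, no pentamers.
#' @export
build_tube <- function(n_around, n_rings, spacing = 80, voxel_size = 4) {
  if (n_around < 6) stop("n_around must be >= 6 (self-intersecting tube)",
                         call. = FALSE)
  if (n_rings < 3) stop("n_rings must be >= 3", call. = FALSE)
  if (spacing < 60 || spacing > 110) {
    stop("spacing must lie in [60, 110] angstroms", call. = FALSE)
  }
  radius <- n_around * spacing / (2 * pi)
  dz <- spacing * sqrt(3) / 2
  rows <- purrr::map_dfr(seq_len(n_rings) - 1L, function(i) {
    purrr::map_dfr(seq_len(n_around) - 1L, function(j) {
      ang <- 2 * pi * (j + 0.5 * (i %% 2)) / n_around
      p <- c(radius * cos(ang), radius * sin(ang), (i - (n_rings - 1) / 2) * dz)
      n <- c(cos(ang), sin(ang), 0)
      # in-plane x axis circumferential: toward the in-ring neighbour,
      # consistent for every unit of the tube
      e <- euler_from_frame(n, x_axis = c(-sin(ang), cos(ang), 0))
      unit_row(p[1] / voxel_size, p[2] / voxel_size, p[3] / voxel_size,
               e, unit_type = "hexamer_C2")
    })
  })
  edges <- edges_from_positions(rows, voxel_size, max_dist = 1.3 * spacing)
  lattice_graph(rows, edges, closed = FALSE, voxel_size = voxel_size,
                spacing = spacing)
}

# Icosahedron vertex/face geometry (circumradius-normalized vertices).
icosahedron_mesh <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1)
  )
  # faces as vertex index triples (edge length 2 in these coordinates)
  d <- as.matrix(stats::dist(v))
  adj <- d < 2.01 & d > 0.1
  faces <- list()
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    if (adj[i, j] && adj[j, k] && adj[i, k]) faces[[length(faces) + 1]] <- c(i, j, k)
  }
  list(vertices = v, faces = do.call(rbind, faces), edge = 2)
}

#' Build a T=1 or T=3 icosahedral lattice
#'
#' Caspar-Klug placement: T=1 puts the 12 pentamers on the icosahedron
#' vertices; T=3 additionally puts one hexamer at the centre of each of the
#' 20 triangular faces, so that every hexamer is surrounded by the three
#' pentamers of its face. Normals are radial; the lattice is closed.
#'
#' @param T Triangulation number, 1 or 3.
#' @param spacing Nominal nearest-neighbour spacing in angstroms (for T=3 this
#'   is the pentamer-hexamer distance).
#' @param voxel_size Angstroms per voxel.
#' @return A [lattice_graph].
#' @export
build_icosahedron <- function(T = 1, spacing = 80, voxel_size = 4) {
  if (!T %in% c(1, 3)) stop("unsupported triangulation number T = ", T,
                            "; only T = 1 and T = 3 are implemented",
                            call. = FALSE)
  mesh <- icosahedron_mesh()
  if (T == 1) {
    scale <- spacing / mesh$edge
    pos <- mesh$vertices * scale
    types <- rep("pentamer_C5", 12)
  } else {
    # pentamer-hexamer distance = edge / sqrt(3)
    scale <- spacing / (mesh$edge / sqrt(3))
    cents <- t(apply(mesh$faces, 1, function(f) colMeans(mesh$vertices[f, ])))
    pos <- rbind(mesh$vertices, cents) * scale
    types <- c(rep("pentamer_C5", 12), rep("hexamer_C6", 20))
  }
  rows <- purrr::map_dfr(seq_len(nrow(pos)), function(i) {
    n <- pos[i, ] / sqrt(sum(pos[i, ]^2))
    unit_row(pos[i, 1] / voxel_size, pos[i, 2] / voxel_size,
             pos[i, 3] / voxel_size, euler_from_frame(n), unit_type = types[i])
  })
  max_d <- if (T == 1) 1.2 * spacing else 1.15 * spacing
  edges <- edges_from_positions(rows, voxel_size, max_dist = max_d)
  rows <- orient_units_to_lattice(rows, edges)
  edges <- edges_from_positions(rows, voxel_size, max_dist = max_d)
  lattice_graph(rows, edges, closed = TRUE, voxel_size = voxel_size,
                spacing = spacing)
}

# Subdivide the icosahedron at frequency f and project to the unit sphere.
# Returns vertices (rows), triangle faces (index triples) and the 12 indices
# of the original degree-5 vertices.
icosphere <- function(f) {
  mesh <- icosahedron_mesh()
  v0 <- mesh$vertices / sqrt(sum(mesh$vertices[1, ]^2))
  verts <- list()
  keymap <- new.env(parent = emptyenv())
  get_idx <- function(p) {
    key <- paste(sprintf("%.8f", round(p, 8)), collapse = ",")
    if (!is.null(keymap[[key]])) return(keymap[[key]])
    verts[[length(verts) + 1]] <<- p
    keymap[[key]] <- length(verts)
    length(verts)
  }
  pent_idx <- vapply(seq_len(12), function(i) {
    p <- v0[i, ]; get_idx(p / sqrt(sum(p^2)))
  }, integer(1))
  faces <- list()
  for (fi in seq_len(nrow(mesh$faces))) {
    tri <- v0[mesh$faces[fi, ], ]
    # barycentric grid index (i, j), corner order fixed by the face row
    idx_of <- matrix(0L, f + 1, f + 1)
    for (i in 0:f) for (j in 0:(f - i)) {
      p <- ((f - i - j) * tri[1, ] + i * tri[2, ] + j * tri[3, ]) / f
      idx_of[i + 1, j + 1] <- get_idx(p / sqrt(sum(p^2)))
    }
    for (i in 0:(f - 1)) for (j in 0:(f - 1 - i)) {
      faces[[length(faces) + 1]] <-
        c(idx_of[i + 1, j + 1], idx_of[i + 2, j + 1], idx_of[i + 1, j + 2])
      if (j < f - 1 - i) {
        faces[[length(faces) + 1]] <-
          c(idx_of[i + 2, j + 1], idx_of[i + 2, j + 2], idx_of[i + 1, j + 2])
      }
    }
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces),
       pent_idx = pent_idx)
}

# Outward area-weighted vertex normals of a closed triangle mesh.
mesh_vertex_normals <- function(vertices, faces) {
  centre <- colMeans(vertices)
  normals <- matrix(0, nrow(vertices), 3)
  for (fi in seq_len(nrow(faces))) {
    tri <- faces[fi, ]
    a <- vertices[tri[1], ]; b <- vertices[tri[2], ]; c_ <- vertices[tri[3], ]
    fn <- cross3(b - a, c_ - a)
    if (sum(fn * (colMeans(vertices[tri, ]) - centre)) < 0) fn <- -fn
    for (vi in tri) normals[vi, ] <- normals[vi, ] + fn
  }
  normals / sqrt(rowSums(normals^2))
}

#' Build a random closed polyhedral lattice
#'
#' Closed fullerene-type lattice with exactly 12 pentamers: an icosphere
#' subdivision at frequency `f` (yielding `10 f^2 + 2` units, the 12 original
#' icosahedron vertices being the pentamers), randomly oriented, elongated
#' along a random axis and given a small seeded tangential jitter to emulate
#' the pleomorphism of polyhedral capsid-like particles. `n_units` is snapped
#' to the nearest feasible size (12, 42, 92, 162, ...).
#'
#' @param n_units Requested unit count (>= 12); snapped to `10 f^2 + 2`.
#' @param elongation Fractional stretch along the random axis (e.g. 0.1 for
#'   10 percent prolate distortion). Kept small so all neighbour spacings stay
#'   inside the 60-110 angstrom connectivity window.
#' @param seed Integer seed fixing all randomness.
#' @param spacing Nominal mean neighbour spacing in angstroms.
#' @param jitter Tangential position jitter, as a fraction of `spacing`.
#' @param voxel_size Angstroms per voxel.
#' @return A [lattice_graph] with exactly 12 pentamers.
#' @export
build_polyhedron <- function(n_units = 92, elongation = 0.1, seed = 1,
                             spacing = 80, jitter = 0.01, voxel_size = 4) {
  if (n_units < 12) stop("n_units must be >= 12", call. = FALSE)
  f <- max(1L, as.integer(round(sqrt((n_units - 2) / 10))))
  withr::with_seed(seed, {
    sph <- icosphere(f)
    v <- sph$vertices
    # random orientation
    M <- matrix(stats::rnorm(9), 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    v <- v %*% t(Q)
    # prolate stretch along z (in the rotated frame the axis is random)
    v[, 3] <- v[, 3] * (1 + elongation)
    # scale so the mean edge length equals `spacing`
    el <- apply(sph$faces, 1, function(fc) {
      mean(c(sqrt(sum((v[fc[1], ] - v[fc[2], ])^2)),
             sqrt(sum((v[fc[2], ] - v[fc[3], ])^2)),
             sqrt(sum((v[fc[1], ] - v[fc[3], ])^2))))
    })
    v <- v * spacing / mean(el)
    normals <- mesh_vertex_normals(v, sph$faces)
    if (jitter > 0) {
      for (i in seq_len(nrow(v))) {
        t1 <- cross3(normals[i, ], if (abs(normals[i, 3]) < 0.9) c(0, 0, 1)
                     else c(1, 0, 0))
        t1 <- t1 / sqrt(sum(t1^2))
        t2 <- cross3(normals[i, ], t1)
        v[i, ] <- v[i, ] + spacing * jitter *
          (stats::rnorm(1) * t1 + stats::rnorm(1) * t2)
      }
    }
  })
  types <- rep("hexamer_C6", nrow(v))
  types[sph$pent_idx] <- "pentamer_C5"
  rows <- purrr::map_dfr(seq_len(nrow(v)), function(i) {
    unit_row(v[i, 1] / voxel_size, v[i, 2] / voxel_size, v[i, 3] / voxel_size,
             euler_from_frame(normals[i, ]), unit_type = types[i])
  })
  # edges straight from the mesh triangulation
  ep <- rbind(sph$faces[, c(1, 2)], sph$faces[, c(2, 3)], sph$faces[, c(1, 3)])
  ep <- t(apply(ep, 1, sort))
  ep <- unique(ep)
  ep <- ep[order(ep[, 1], ep[, 2]), , drop = FALSE]
  rows <- orient_units_to_lattice(
    rows, tibble(from = as.integer(ep[, 1]), to = as.integer(ep[, 2])))
  geo <- purrr::map2_dfr(ep[, 1], ep[, 2], function(i, j) {
    pair_geometry(rows[i, ], rows[j, ], voxel_size)
  })
  edges <- dplyr::bind_cols(tibble(from = as.integer(ep[, 1]),
                                   to = as.integer(ep[, 2])), geo)
  lattice_graph(rows, edges, closed = TRUE, voxel_size = voxel_size,
                spacing = spacing)
}

#' Recentre a lattice inside a cubic box
#'
#' Translates the unit coordinates so that the lattice centroid sits at the
#' box centre voxel `box / 2`.
#'
#' @param g A [lattice_graph].
#' @param box Box side length in voxels.
#' @return The recentred [lattice_graph].
#' @export
place_in_box <- function(g, box) {
  u <- g$units
  centroid <- c(mean(u$x), mean(u$y), mean(u$z))
  shift <- box / 2 - centroid
  u$x <- u$x + shift[1]; u$y <- u$y + shift[2]; u$z <- u$z + shift[3]
  g$units <- u
  g
}
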