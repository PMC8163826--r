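#' Context-based classification of unit pairs
#'
#' Every pair of adjacent lattice units (a "dimer") is assigned to one of six
#' general groups from the positions of pentamers in its local neighbourhood
#' and, where no pentamer constrains the geometry, from the orientation of
#' the pair with respect to the local tube axis. See [classify_pair] for the
#' group definitions.
#'
#' @name context-classification
NULL

# Neighbour ids of a unit, ordered cyclically around its ring: neighbour
# directions are projected onto the unit's tangential plane and sorted by
# angle, counterclockwise when viewed from outside the lattice (i.e. looking
# along -normal). Fixed global handedness.
ordered_neighbors <- function(g, uid) {
  e <- g$edges
  nb <- c(e$to[e$from == uid], e$from[e$to == uid])
  if (length(nb) == 0) return(integer(0))
  u <- g$units[uid, ]
  R <- rotation_from_euler(u$phi, u$theta, u$psi)
  x <- R[, 1]; y <- R[, 2]
  ang <- vapply(nb, function(v) {
    d <- c(g$units$x[v] - u$x, g$units$y[v] - u$y, g$units$z[v] - u$z)
    atan2(-sum(d * y), sum(d * x))
  }, numeric(1))
  nb[order(ang, nb)]
}

max_degree <- function(unit_type) if (unit_type == "pentamer_C5") 5L else 6L

is_pent <- function(g, ids) g$units$unit_type[ids] == "pentamer_C5"

#' Number the neighbour positions of a unit pair
#'
#' For edge (A, B), A's neighbour slots are numbered 1'..6' with slot 1 = the
#' partner B, proceeding around the ring in the package's fixed handedness;
#' symmetrically for B. The returned position sets are the slots occupied by
#' pentamers (so `1` in `positions_a` means the partner is a pentamer). For
#' shared neighbours the identities 2' = 6'' and 6' = 2'' hold.
#'
#' @param g A [lattice_graph].
#' @param edge Length-2 integer vector of unit ids `c(a, b)`.
#' @return List with `positions_a`, `positions_b` (integer slot sets),
#'   `slots_a`, `slots_b` (neighbour unit ids in slot order).
#' @export
number_positions <- function(g, edge) {
  a <- edge[1]; b <- edge[2]
  out <- lapply(c(a, b), function(uid) {
    partner <- if (uid == a) b else a
    nb <- ordered_neighbors(g, uid)
    kmax <- max_degree(g$units$unit_type[uid])
    if (length(nb) > kmax) {
      stop("unit ", uid, " has ", length(nb), " neighbours, more than its ",
           "type allows (", kmax, ")", call. = FALSE)
    }
    start <- match(partner, nb)
    if (is.na(start)) stop("edge endpoints are not neighbours", call. = FALSE)
    slots <- nb[((seq_along(nb) - 1 + start - 1) %% length(nb)) + 1]
    positions <- which(is_pent(g, slots))
    list(slots = slots, positions = positions)
  })
  list(positions_a = out[[1]]$positions, positions_b = out[[2]]$positions,
       slots_a = out[[1]]$slots, slots_b = out[[2]]$slots)
}

# Estimate the local cylinder axis around a unit from the normals of its
# neighbourhood: on a tube the neighbourhood normals lie in the plane
# perpendicular to the axis, so the axis is the smallest-variance direction
# of the normal cloud. Returns NULL when degenerate (spherical region or too
# few neighbours).
local_axis <- function(g, uid, radius_factor = 2, min_neighbors = 5,
                       degeneracy_ratio = 0.35) {
  u <- g$units
  spacing <- if (is.finite(g$spacing)) g$spacing else
    stats::median(g$edges$distance)
  pos <- as.matrix(u[, c("x", "y", "z")]) * g$voxel_size
  d <- sqrt(rowSums((pos - matrix(pos[uid, ], nrow(pos), 3, byrow = TRUE))^2))
  sel <- which(d <= radius_factor * spacing)
  if (length(sel) < min_neighbors + 1) return(NULL)
  N <- t(vapply(sel, function(i) normal_from_euler(u$phi[i], u$theta[i]),
                numeric(3)))
  C <- stats::cov(N)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[2] < 1e-12 ||
      ev$values[3] / ev$values[2] > degeneracy_ratio) {
    return(NULL)
  }
  ev$vectors[, 3]
}

#' Orientation class of a hexamer pair with respect to the tube geometry
#'
#' The signed in-plane angle between the edge vector and the local cylinder
#' axis, folded to `(-90, 90]` by the lattice's twofold edge symmetry, falls
#' into one of the three hexagonal edge families: class 1 for edges
#' approximately perpendicular to the axis (|angle| >= 60), class 2 for the
#' +30-degree family, class 3 for the -30-degree family. Returns `NA` when no
#' local axis is estimable (spherical neighbourhood).
#'
#' @param g A [lattice_graph].
#' @param edge Length-2 integer vector `c(a, b)`.
#' @return Integer 1, 2, 3 or `NA`.
#' @export
orientation_class <- function(g, edge) {
  axis <- local_axis(g, edge[1])
  if (is.null(axis)) axis <- local_axis(g, edge[2])
  if (is.null(axis)) return(NA_integer_)
  u <- g$units
  a <- edge[1]; b <- edge[2]
  n <- normal_from_euler(u$phi[a], u$theta[a])
  d <- c(u$x[b] - u$x[a], u$y[b] - u$y[a], u$z[b] - u$z[a])
  dt <- d - sum(d * n) * n
  at <- axis - sum(axis * n) * n
  if (sqrt(sum(at^2)) < 1e-9) return(NA_integer_)
  ang <- rad2deg(atan2(sum(cross3(at, dt) * n), sum(at * dt)))
  ang <- ang %% 180
  if (ang > 90) ang <- ang - 180  # fold to (-90, 90]
  if (abs(ang) >= 60) 1L else if (ang >= 0) 2L else 3L
}

#' Classify a unit pair into the six context groups
#'
#' Groups, evaluated in the order 1, 2, 3, 6, 4, 5 with the first match
#' winning (more constrained contexts take precedence):
#' \enumerate{
#'   \item one or both units are pentamers;
#'   \item two hexamers sharing one or two pentamer neighbours
#'     (positions 2/6);
#'   \item two hexamers, each with exactly one pentamer in positions 3-5;
#'   \item (order: evaluated after 6) at least one hexamer has a pentamer in
#'     positions 3-5; subclassed by the tube orientation class;
#'   \item neither hexamer has a pentamer in positions 2-6; three orientation
#'     subclasses;
#'   \item one hexamer has pentamers in two of positions 3'/4'/5' and the
#'     partner has none in 2-6 (orientation neglected).
#' }
#'
#' @param g A [lattice_graph].
#' @param edge Length-2 integer vector `c(a, b)`.
#' @return One-row tibble: `from`, `to`, `group`, `subclass`,
#'   `orientation_class`, `positions_a`, `positions_b` (the last two as
#'   comma-separated strings).
#' @export
classify_pair <- function(g, edge) {
  a <- edge[1]; b <- edge[2]
  np <- number_positions(g, edge)
  pos_a <- np$positions_a; pos_b <- np$positions_b
  pent_a35 <- intersect(pos_a, 3:5); pent_b35 <- intersect(pos_b, 3:5)
  pent_a26 <- intersect(pos_a, 2:6); pent_b26 <- intersect(pos_b, 2:6)
  shared <- intersect(pos_a, c(2L, 6L))
  oc <- NA_integer_
  if (any(is_pent(g, c(a, b)))) {
    group <- 1L
    subclass <- sum(is_pent(g, c(a, b)))
  } else if (length(shared) > 0) {
    group <- 2L
    subclass <- length(shared)
  } else if (length(pent_a35) == 1 && length(pent_b35) == 1) {
    group <- 3L
    s <- sort(c(pent_a35, pent_b35))
    subclass <- (s[1] - 3L) * 3L + (s[2] - 3L) + 1L
  } else if ((length(pent_a35) == 2 && length(pent_b26) == 0) ||
             (length(pent_b35) == 2 && length(pent_a26) == 0)) {
    group <- 6L
    two <- if (length(pent_a35) == 2) pent_a35 else pent_b35
    subclass <- match(paste(sort(two), collapse = ","),
                      c("3,4", "3,5", "4,5"))
  } else if (length(pent_a35) > 0 || length(pent_b35) > 0) {
    group <- 4L
    oc <- orientation_class(g, edge)
    subclass <- if (is.na(oc)) 0L else oc
  } else {
    group <- 5L
    oc <- orientation_class(g, edge)
    subclass <- if (is.na(oc)) 0L else oc
  }
  tibble(from = a, to = b, group = group, subclass = as.integer(subclass),
         orientation_class = oc,
         positions_a = paste(pos_a, collapse = ","),
         positions_b = paste(pos_b, collapse = ","))
}

#' Classify every edge of a lattice
#'
#' @param g A [lattice_graph].
#' @return Tibble with one row per edge: the [classify_pair] columns plus the
#'   edge geometry.
#' @export
classify_edges <- function(g) {
  cls <- purrr::map_dfr(seq_len(nrow(g$edges)), function(i) {
    classify_pair(g, c(g$edges$from[i], g$edges$to[i]))
  })
  dplyr::bind_cols(cls, g$edges[, c("distance", "tilt", "twist", "curvature")])
}

#' Local symmetry of a hexamer from its pentamer arrangement
#'
#' For a hexamer with six neighbours: `C3` when pentamers occupy the three
#' alternating positions, `C2_pentamer` when exactly two pentamers sit at
#' antipodal positions, `C2_tube` when no neighbour is a pentamer (the
#' tube-like twofold context), otherwise `C1`.
#'
#' @param g A [lattice_graph].
#' @param uid Unit id of a hexamer.
#' @return Character scalar.
#' @export
local_symmetry <- function(g, uid) {
  if (is_pent(g, uid)) stop("unit ", uid, " is a pentamer", call. = FALSE)
  nb <- ordered_neighbors(g, uid)
  if (length(nb) != 6) return("C1")
  slots <- which(is_pent(g, nb))
  k <- length(slots)
  if (k == 0) return("C2_tube")
  if (k == 3 && all(diff(slots) == 2)) return("C3")
  if (k == 2 && diff(slots) == 3) return("C2_pentamer")
  "C1"
}

#' Reconcile unit types with lattice topology
#'
#' On a closed capsid lattice the coordination number determines the unit
#' type: pentamers have five ring neighbours, hexamers six. For units whose
#' template-derived type disagrees with an unambiguous interior coordination
#' number, the type is relabelled accordingly; boundary units (which may have
#' missing neighbours) are left untouched. Used by the pipeline after
#' network recovery to make the census robust to template misassignments.
#'
#' @param g A [lattice_graph].
#' @return The lattice with reconciled `unit_type`.
#' @export
assign_types_by_topology <- function(g) {
  has_edge <- function(a, b) {
    any((g$edges$from == a & g$edges$to == b) |
          (g$edges$from == b & g$edges$to == a))
  }
  tp <- g$units$unit_type
  for (uid in seq_len(nrow(g$units))) {
    nb <- ordered_neighbors(g, uid)
    k <- length(nb)
    if (!k %in% c(5L, 6L)) next
    ring_closed <- all(vapply(seq_len(k), function(i) {
      has_edge(nb[i], nb[i %% k + 1])
    }, logical(1)))
    if (!ring_closed) next  # boundary or incomplete ring: keep template type
    if (k == 5L) {
      tp[uid] <- "pentamer_C5"
    } else if (tp[uid] == "pentamer_C5") {
      tp[uid] <- "hexamer_C6"
    }
  }
  g$units$unit_type <- tp
  g
}

#' Local symmetry labels for all hexamers of a lattice
#'
#' @param g A [lattice_graph].
#' @return Tibble `unit_id`, `unit_type`, `symmetry`.
#' @export
unit_symmetries <- function(g) {
  hex <- which(!is_pent(g, seq_len(nrow(g$units))))
  tibble(unit_id = hex,
         unit_type = g$units$unit_type[hex],
         symmetry = vapply(hex, function(u) local_symmetry(g, u),
                           character(1)))
}
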