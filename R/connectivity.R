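#' Connectivity criteria for lattice networks
#'
#' The five pairwise criteria used to accept a neighbour edge between two
#' correlation peaks, and the minimum network size. Defaults: spacing within
#' 60-110 angstroms, curvature within -15..40 degrees (evaluated from both
#' units' tangential planes), normal-vector difference at most 45 degrees,
#' and only networks with strictly more than 20 peaks retained.
#'
#' @param min_spacing,max_spacing Centre distance bounds, angstroms.
#' @param min_curvature,max_curvature Curvature bounds, degrees.
#' @param max_normal_diff Maximum angle between unit normals, degrees.
#' @param min_network_size Networks must contain strictly more than this many
#'   units to be retained.
#' @return A `connectivity_criteria` list.
#' @export
connectivity_criteria <- function(min_spacing = 60, max_spacing = 110,
                                  min_curvature = -15, max_curvature = 40,
                                  max_normal_diff = 45,
                                  min_network_size = 20) {
  if (min_spacing >= max_spacing) stop("min_spacing must be < max_spacing",
                                       call. = FALSE)
  if (min_curvature >= max_curvature) {
    stop("min_curvature must be < max_curvature", call. = FALSE)
  }
  structure(list(min_spacing = min_spacing, max_spacing = max_spacing,
                 min_curvature = min_curvature, max_curvature = max_curvature,
                 max_normal_diff = max_normal_diff,
                 min_network_size = min_network_size),
            class = "connectivity_criteria")
}

#' Evaluate the pair criteria for two units
#'
#' Boundary values are inclusive. The curvature criterion is applied
#' bidirectionally (from each unit's tangential plane; both must pass), which
#' is stricter than a one-sided check but symmetric and deterministic.
#'
#' @param a,b One-row particle-table entries.
#' @param crit A [connectivity_criteria].
#' @param voxel_size Angstroms per voxel.
#' @return One-row tibble: `pass` (logical) and `failed` (comma-separated
#'   labels of violated criteria, empty when passing).
#' @export
pair_passes <- function(a, b, crit = connectivity_criteria(), voxel_size) {
  gab <- pair_geometry(a, b, voxel_size)
  gba <- pair_geometry(b, a, voxel_size)
  failed <- character(0)
  if (gab$distance < crit$min_spacing) failed <- c(failed, "min_spacing")
  if (gab$distance > crit$max_spacing) failed <- c(failed, "max_spacing")
  if (gab$curvature < crit$min_curvature || gba$curvature < crit$min_curvature)
    failed <- c(failed, "min_curvature")
  if (gab$curvature > crit$max_curvature || gba$curvature > crit$max_curvature)
    failed <- c(failed, "max_curvature")
  if (gab$normal_diff > crit$max_normal_diff)
    failed <- c(failed, "max_normal_diff")
  tibble(pass = length(failed) == 0, failed = paste(failed, collapse = ","))
}

#' Prune a recovered lattice network
#'
#' Cleans a network recovered from template matching using lattice-geometry
#' constraints: units with fewer than `min_degree` validated neighbours are
#' removed iteratively (every unit of a capsid lattice interior has at least
#' three), and units exceeding their maximum coordination (6 for hexamers,
#' 5 for pentamers) have their longest edges dropped until consistent.
#'
#' @param g A [lattice_graph].
#' @param min_degree Minimum surviving coordination number.
#' @return The pruned [lattice_graph] (unit ids re-indexed).
#' @export
prune_network <- function(g, min_degree = 3) {
  repeat {
    e <- g$edges
    n <- nrow(g$units)
    # drop excess edges on over-coordinated units (longest distance first)
    repeat {
      deg <- tabulate(c(e$from, e$to), n)
      kmax <- ifelse(g$units$unit_type == "pentamer_C5", 5L, 6L)
      over <- which(deg > kmax)
      if (length(over) == 0) break
      u <- over[1]
      cand <- which(e$from == u | e$to == u)
      e <- e[-cand[which.max(e$distance[cand])], , drop = FALSE]
    }
    deg <- tabulate(c(e$from, e$to), n)
    drop <- which(deg < min_degree)
    if (length(drop) == 0) {
      g$edges <- e
      return(g)
    }
    keep <- setdiff(seq_len(n), drop)
    idx <- match(seq_len(n), keep)
    sel <- e$from %in% keep & e$to %in% keep
    e <- e[sel, , drop = FALSE]
    e$from <- idx[e$from]; e$to <- idx[e$to]
    g <- lattice_graph(g$units[keep, ], e, closed = FALSE,
                       voxel_size = g$voxel_size, spacing = g$spacing)
  }
}

#' Build lattice networks from correlation peaks
#'
#' Forms the graph of all peak pairs passing [pair_passes], decomposes it into
#' connected components (each a candidate capsid-like particle), and retains
#' components with strictly more than `crit$min_network_size` peaks. Retained
#' components are returned as [lattice_graph]s with `network_id` assigned in
#' decreasing size order.
#'
#' @param peaks Particle table of peaks (e.g. from [scan_orientations]).
#' @param crit A [connectivity_criteria].
#' @param voxel_size Angstroms per voxel.
#' @return List of [lattice_graph]s.
#' @export
build_networks <- function(peaks, crit = connectivity_criteria(), voxel_size) {
  peaks <- as_particle_table(peaks)
  n <- nrow(peaks)
  if (n == 0) return(list())
  pos <- as.matrix(peaks[, c("x", "y", "z")]) * voxel_size
  d <- as.matrix(stats::dist(pos))
  cand <- which(upper.tri(d) & d <= crit$max_spacing, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  geo <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    pp <- pair_passes(peaks[i, ], peaks[j, ], crit, voxel_size)
    keep[r] <- pp$pass
    if (pp$pass) geo[[r]] <- pair_geometry(peaks[i, ], peaks[j, ], voxel_size)
  }
  edges_all <- cand[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges_all, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  retained <- which(sizes > crit$min_network_size)
  retained <- retained[order(-sizes[retained],
                             vapply(retained, function(ci)
                               min(which(comp$membership == ci)), numeric(1)))]
  geo_tbl <- dplyr::bind_rows(geo[keep])
  out <- list()
  for (k in seq_along(retained)) {
    ids <- which(comp$membership == retained[k])
    units <- peaks[ids, ]
    units$network_id <- k
    sel <- edges_all[, 1] %in% ids  # components: both endpoints follow
    emap <- match(seq_len(n), ids)
    edges <- tibble(from = emap[edges_all[sel, 1]],
                    to = emap[edges_all[sel, 2]])
    edges <- dplyr::bind_cols(edges, geo_tbl[sel, ])
    out[[k]] <- lattice_graph(units, edges, closed = FALSE,
                              voxel_size = voxel_size)
  }
  out
}
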