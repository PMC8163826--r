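#' Per-class geometry statistics
#'
#' Mean and standard deviation of tilt, twist and distance per classification
#' class (group/subclass). Standard deviations are only computed for classes
#' with at least two members and are floored (see
#' [optimize_class_geometry]) when used as weights.
#'
#' @param classified Output of [classify_edges] (must contain `group`,
#'   `subclass`, `tilt`, `twist`, `distance`).
#' @return Tibble with one row per class.
#' @export
class_geometry_stats <- function(classified) {
  classified |>
    dplyr::group_by(.data$group, .data$subclass) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_tilt = mean(.data$tilt), sd_tilt = stats::sd(.data$tilt),
      mean_twist = mean(.data$twist), sd_twist = stats::sd(.data$twist),
      mean_distance = mean(.data$distance),
      sd_distance = stats::sd(.data$distance),
      .groups = "drop")
}

edge_objective <- function(g, edge_rows, stats, floor_ang, floor_dist) {
  total <- 0
  for (r in seq_len(nrow(edge_rows))) {
    i <- edge_rows$from[r]; j <- edge_rows$to[r]
    geo <- pair_geometry(g$units[i, ], g$units[j, ], g$voxel_size)
    s <- stats[stats$group == edge_rows$group[r] &
                 stats$subclass == edge_rows$subclass[r], ]
    if (nrow(s) == 0) next
    sdt <- max(s$sd_tilt, floor_ang, na.rm = TRUE)
    sdw <- max(s$sd_twist, floor_ang, na.rm = TRUE)
    sdd <- max(s$sd_distance, floor_dist, na.rm = TRUE)
    total <- total +
      ((geo$tilt - s$mean_tilt) / sdt)^2 +
      ((geo$twist - s$mean_twist) / sdw)^2 +
      ((geo$distance - s$mean_distance) / sdd)^2
  }
  total
}

#' Optimize unit poses toward their class-mean geometry
#'
#' Minimizes, by bounded coordinate descent over each unit's position and
#' Euler angles, the sum over all classified edges of the z-scored squared
#' deviations of tilt, twist and distance from their class means. The
#' z-scoring makes angstroms and degrees commensurable; zero or missing
#' standard deviations are floored. The global objective is non-increasing by
#' construction (a candidate step is taken only when it lowers the objective
#' restricted to the unit's incident edges, which equals the global change).
#'
#' @param g A [lattice_graph].
#' @param classified Output of [classify_edges] on `g`.
#' @param stats Optional precomputed [class_geometry_stats].
#' @param n_iter Number of full sweeps; the step sizes are halved each sweep.
#' @param step_pos Initial position step, voxels.
#' @param step_ang Initial angle step, degrees.
#' @param floor_ang,floor_dist Standard-deviation floors (degrees,
#'   angstroms).
#' @return The lattice with optimized poses; the per-sweep objective values
#'   are attached as attribute `objective_trace` (position 1 is the initial
#'   objective).
#' @export
optimize_class_geometry <- function(g, classified, stats = NULL, n_iter = 3,
                                    step_pos = 0.25, step_ang = 1,
                                    floor_ang = 0.5, floor_dist = 0.5) {
  if (is.null(stats)) stats <- class_geometry_stats(classified)
  incident <- lapply(seq_len(nrow(g$units)), function(uid) {
    which(classified$from == uid | classified$to == uid)
  })
  obj_unit <- function(uid) {
    edge_objective(g, classified[incident[[uid]], , drop = FALSE], stats,
                   floor_ang, floor_dist)
  }
  total_obj <- function() {
    edge_objective(g, classified, stats, floor_ang, floor_dist)
  }
  trace <- total_obj()
  params <- c("x", "y", "z", "phi", "theta", "psi")
  sp <- step_pos; sa <- step_ang
  for (it in seq_len(n_iter)) {
    for (uid in seq_len(nrow(g$units))) {
      if (length(incident[[uid]]) == 0) next
      for (par in params) {
        delta <- if (par %in% c("x", "y", "z")) sp else sa
        base <- obj_unit(uid)
        old <- g$units[[par]][uid]
        best_val <- old; best_obj <- base
        for (cand in c(old - delta, old + delta)) {
          g$units[[par]][uid] <- cand
          o <- obj_unit(uid)
          if (o < best_obj - 1e-12) { best_obj <- o; best_val <- cand }
        }
        g$units[[par]][uid] <- best_val
      }
    }
    trace <- c(trace, total_obj())
    sp <- sp / 2; sa <- sa / 2
  }
  attr(g, "objective_trace") <- trace
  g
}

#' Dimer-interface-centred class averages
#'
#' Re-extracts subtomograms centred at the midpoint of each classified unit
#' pair, rotates them into the pair's canonical frame (central unit normal
#' along +z, neighbour direction along +x) and averages them per class.
#' Classes with fewer than `min_members` pairs are skipped with a warning.
#'
#' @param vol A [density_volume] containing the lattice.
#' @param g The [lattice_graph] with (refined) poses.
#' @param classified Output of [classify_edges].
#' @param box Subtomogram box side, voxels.
#' @param min_members Minimum pairs per class.
#' @return Named list (`"group.subclass"`) of [density_volume] class
#'   averages, each with attribute `n_pairs`.
#' @export
interface_refinement <- function(vol, g, classified, box = 32,
                                 min_members = 3) {
  keys <- paste(classified$group, classified$subclass, sep = ".")
  out <- list()
  for (key in unique(keys)) {
    rows <- classified[keys == key, , drop = FALSE]
    if (nrow(rows) < min_members) {
      warning("class ", key, " has ", nrow(rows), " pair(s) (< ",
              min_members, "); skipped", call. = FALSE)
      next
    }
    acc <- array(0, dim = c(box, box, box))
    n_used <- 0
    for (r in seq_len(nrow(rows))) {
      a <- rows$from[r]; b <- rows$to[r]
      u <- g$units
      mid <- round(c(u$x[a] + u$x[b], u$y[a] + u$y[b], u$z[a] + u$z[b]) / 2)
      sub <- extract_box(vol$grid, mid, box)
      if (is.null(sub)) next
      d <- c(u$x[b] - u$x[a], u$y[b] - u$y[a], u$z[b] - u$z[a])
      F0 <- pair_frame(c(u$phi[a], u$theta[a], u$psi[a]), d)
      acc <- acc + rotate_grid(sub, t(F0))
      n_used <- n_used + 1
    }
    if (n_used == 0) next
    avg <- density_volume(acc / n_used, vol$voxel_size)
    attr(avg, "n_pairs") <- n_used
    out[[key]] <- avg
  }
  out
}
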