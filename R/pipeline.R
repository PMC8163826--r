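#' Default pipeline configuration
#'
#' @param kind Lattice kind: `"tube"`, `"t1"`, `"t3"` or `"polyhedron"`.
#' @param seed Global seed; per-stage seeds are derived as `seed + stage`.
#' @param out_dir Output directory.
#' @param ... Overrides for nested fields (see the returned list).
#' @return Named configuration list.
#' @export
pipeline_config <- function(kind = "t3", seed = 1, out_dir = tempfile("run"),
                            ...) {
  cfg <- list(
    kind = kind, seed = seed, out_dir = out_dir,
    spacing = 80, voxel_size = 8, box = 64, noise_sigma = 0.1,
    n_around = 8, n_rings = 4,            # tube parameters
    n_units = 42, elongation = 0.1,       # polyhedron parameters
    # The annotation pipeline scores plain (unwedged) normalized correlation;
    # wedge-aware constrained correlation is out of scope for the matching
    # stage, so pipeline volumes are simulated without a wedge by default.
    # Set e.g. wedge = list(tilt_axis = "x", min_angle = -60, max_angle = 60)
    # to simulate the acquisition wedge anyway.
    wedge = NULL,
    match = list(phi_step = 30, other_step = 20, bandpass = c(425, 30),
                 peak_min_separation = 50, cc_min = 0.45, mask_radius = 36,
                 variance_floor = 0.5),
    refine = list(rot_range = 12, rot_step = 6, max_shift = 3,
                  cc_min = 0.5, use_wedge = TRUE),
    reconcile_topology = TRUE,
    criteria = list(min_spacing = 60, max_spacing = 110, min_curvature = -15,
                    max_curvature = 40, max_normal_diff = 45,
                    min_network_size = 20),
    log_level = "info"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, dots)
}

validate_config <- function(cfg) {
  cr <- cfg$criteria
  if (cr$min_spacing >= cr$max_spacing) {
    stop("invalid configuration: min_spacing must be < max_spacing",
         call. = FALSE)
  }
  if (cr$min_curvature >= cr$max_curvature) {
    stop("invalid configuration: min_curvature must be < max_curvature",
         call. = FALSE)
  }
  if (!cfg$kind %in% c("tube", "t1", "t3", "polyhedron")) {
    stop("invalid configuration: unknown kind ", cfg$kind, call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a lattice volume per configuration
#'
#' @param cfg A [pipeline_config].
#' @return List: `graph` (ground truth, placed in the box), `volume` (noisy
#'   missing-wedge density).
#' @export
simulate_stage <- function(cfg) {
  g <- switch(cfg$kind,
    tube = build_tube(cfg$n_around, cfg$n_rings, cfg$spacing,
                      voxel_size = cfg$voxel_size),
    t1 = build_icosahedron(1, cfg$spacing, voxel_size = cfg$voxel_size),
    t3 = build_icosahedron(3, cfg$spacing, voxel_size = cfg$voxel_size),
    polyhedron = build_polyhedron(cfg$n_units, cfg$elongation,
                                  seed = cfg$seed + 1, spacing = cfg$spacing,
                                  voxel_size = cfg$voxel_size))
  g <- place_in_box(g, cfg$box)
  vol <- render_density(g, cfg$box)
  if (!is.null(cfg$wedge)) {
    w <- cfg$wedge
    vol <- apply_missing_wedge(vol, wedge_spec(w$tilt_axis, w$min_angle,
                                               w$max_angle))
  }
  if (cfg$noise_sigma > 0) vol <- add_noise(vol, cfg$noise_sigma,
                                            seed = cfg$seed + 2)
  list(graph = g, volume = vol)
}

#' Run the annotation pipeline
#'
#' simulate -> render -> template matching -> connectivity networks ->
#' context classification, writing all stage outputs plus a machine-readable
#' summary to `cfg$out_dir`. Fully deterministic for a fixed seed.
#'
#' @param cfg A [pipeline_config] (or a path to a YAML file holding one).
#' @return The summary list, invisibly; outputs on disk in `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- do.call(pipeline_config, yaml::read_yaml(cfg))
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  log_info <- function(...) {
    if (identical(cfg$log_level, "info")) message("[latticectx] ", ...)
  }

  log_info("simulate: kind=", cfg$kind, " spacing=", cfg$spacing,
           "A voxel=", cfg$voxel_size, "A box=", cfg$box)
  sim <- simulate_stage(cfg)
  write_mrc(sim$volume, file.path(cfg$out_dir, "volume.mrc"))
  write_particles(sim$graph$units, file.path(cfg$out_dir, "truth.tsv"))

  mc <- cfg$match
  mcfg <- match_config(phi_step = mc$phi_step, other_step = mc$other_step,
                       bandpass = mc$bandpass,
                       peak_min_separation = mc$peak_min_separation,
                       cc_min = mc$cc_min, mask_radius = mc$mask_radius,
                       variance_floor = mc$variance_floor)
  # common box (and hence identical spherical mask) so that correlation
  # values are comparable across the three templates
  tbox <- 2 * ceiling(max(vapply(default_templates(), template_extent,
                                 numeric(1))) / cfg$voxel_size) + 2
  tpls <- lapply(default_templates(), render_template,
                 voxel_size = cfg$voxel_size, box = tbox)
  log_info("match: direction net ", mc$other_step, " deg, spin step ",
           mc$phi_step, " deg")
  peaks <- scan_orientations(sim$volume, tpls, mcfg)
  write_particles(peaks, file.path(cfg$out_dir, "peaks.tsv"))

  cr <- cfg$criteria
  crit <- connectivity_criteria(cr$min_spacing, cr$max_spacing,
                                cr$min_curvature, cr$max_curvature,
                                cr$max_normal_diff, cr$min_network_size)
  log_info("network: spacing [", cr$min_spacing, ",", cr$max_spacing,
           "] A, curvature [", cr$min_curvature, ",", cr$max_curvature,
           "] deg, normal diff <= ", cr$max_normal_diff,
           " deg, size > ", cr$min_network_size)
  nets <- build_networks(peaks, crit, cfg$voxel_size)

  # refine network members against the templates (wedge-aware), discard
  # non-aligning subvolumes by cc, rebuild and prune the networks, and
  # reconcile unit types with the lattice topology
  rf <- cfg$refine
  wsp <- if (is.null(cfg$wedge)) NULL else
    wedge_spec(cfg$wedge$tilt_axis, cfg$wedge$min_angle,
               cfg$wedge$max_angle)
  log_info("refine: ", sum(vapply(nets, function(n) nrow(n$units),
                                  integer(1))), " network members")
  members <- dplyr::bind_rows(lapply(nets, function(n) n$units))
  nets <- list()
  if (nrow(members) > 0) {
    members <- refine_peaks(sim$volume, members, tpls, mcfg,
                            max_shift = rf$max_shift,
                            rot_range = rf$rot_range, rot_step = rf$rot_step,
                            wedge = if (isTRUE(rf$use_wedge)) wsp else NULL)
    members <- threshold_cc(members, rf$cc_min)
    members <- remove_duplicates(members, mc$peak_min_separation,
                                 cfg$voxel_size)
    nets <- build_networks(members, crit, cfg$voxel_size)
    nets <- lapply(nets, prune_network)
    if (isTRUE(cfg$reconcile_topology)) {
      nets <- lapply(nets, assign_types_by_topology)
    }
  }
  all_units <- dplyr::bind_rows(lapply(nets, function(n) n$units))
  if (nrow(all_units) > 0) {
    write_particles(all_units, file.path(cfg$out_dir, "lattices.tsv"))
  }

  census <- list()
  sym_census <- list()
  for (n in nets) {
    cls <- classify_edges(n)
    census[[length(census) + 1]] <- cls
    sym_census[[length(sym_census) + 1]] <- unit_symmetries(n)
  }
  classified <- dplyr::bind_rows(census)
  if (nrow(classified) > 0) {
    utils::write.table(classified, file.path(cfg$out_dir, "classified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  syms <- dplyr::bind_rows(sym_census)

  summary <- list(
    kind = cfg$kind, seed = cfg$seed,
    truth = list(
      n_units = nrow(sim$graph$units),
      n_pentamers = sum(sim$graph$units$unit_type == "pentamer_C5"),
      n_hexamers = sum(sim$graph$units$unit_type != "pentamer_C5")),
    n_peaks = nrow(peaks),
    n_networks = length(nets),
    network_sizes = vapply(nets, function(n) nrow(n$units), integer(1)),
    recovered_pentamers = if (nrow(all_units)) {
      sum(all_units$unit_type == "pentamer_C5")
    } else 0L,
    recovered_hexamers = if (nrow(all_units)) {
      sum(all_units$unit_type != "pentamer_C5")
    } else 0L,
    group_census = if (nrow(classified)) {
      as.list(table(classified$group))
    } else list(),
    symmetry_census = if (nrow(syms)) as.list(table(syms$symmetry)) else list()
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
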