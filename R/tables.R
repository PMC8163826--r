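#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# Fixed particle-table schema. Positions are 0-based voxel coordinates; angles
# are intrinsic ZXZ Euler angles in degrees; cc is the correlation score.
particle_columns <- c("x", "y", "z", "phi", "theta", "psi", "cc",
                      "unit_type", "network_id", "group", "subclass")

unit_types <- c("hexamer_C2", "hexamer_C6", "pentamer_C5")

#' Construct a particle table
#'
#' A particle table is a tibble with one row per lattice unit (hexamer or
#' pentamer) and the fixed column set
#' `x, y, z, phi, theta, psi, cc, unit_type, network_id, group, subclass`.
#' Positions are 0-based voxel coordinates (the voxel size is carried
#' separately wherever angstrom thresholds apply), angles are degrees.
#' Missing label columns are filled with `NA`.
#'
#' @param df Data frame holding at least `x, y, z, phi, theta, psi, cc,
#'   unit_type`.
#' @return A tibble with the full particle-table schema.
#' @export
as_particle_table <- function(df) {
  df <- as_tibble(df)
  unknown <- setdiff(names(df), particle_columns)
  if (length(unknown) > 0) {
    stop("unknown particle-table column(s): ", paste(unknown, collapse = ", "),
         "; accepted columns are: ", paste(particle_columns, collapse = ", "),
         call. = FALSE)
  }
  required <- c("x", "y", "z", "phi", "theta", "psi", "cc", "unit_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("particle table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$unit_type), unit_types)
  if (length(bad) > 0) {
    stop("unknown unit_type value(s): ", paste(bad, collapse = ", "),
         "; must be one of ", paste(unit_types, collapse = ", "), call. = FALSE)
  }
  for (col in c("network_id", "group", "subclass")) {
    if (!col %in% names(df)) df[[col]] <- NA_integer_
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("x", "y", "z", "phi", "theta", "psi", "cc")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]))) {
      stop("non-finite values in particle-table column `", col, "`",
           call. = FALSE)
    }
  }
  df[particle_columns]
}

#' Read / write particle tables
#'
#' Tab-separated text with a header line. Doubles are serialized with 17
#' significant digits so that `read_particles(write_particles(t))` is exact
#' (bit-level round trip of IEEE doubles).
#'
#' @param table Particle table (see [as_particle_table]).
#' @param path File path.
#' @return `read_particles` returns a particle table; `write_particles`
#'   returns `path` invisibly.
#' @export
write_particles <- function(table, path) {
  table <- as_particle_table(table)
  out <- table
  for (col in c("x", "y", "z", "phi", "theta", "psi", "cc")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  as_particle_table(df)
}

#' Read an atomic coordinate model from PDB
#'
#' Parses ATOM/HETATM records (via bio3d) into a tibble with one row per atom:
#' `chain`, `resno` (1-based residue number), `atom` (atom name), `element`,
#' and `x`, `y`, `z` in angstroms.
#'
#' @param path Path to a PDB file.
#' @return A tibble of class `atom_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  m <- tibble(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    atom = as.character(a$elety),
    element = as.character(a$elesy),
    x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z)
  )
  if (any(!is.finite(c(m$x, m$y, m$z)))) {
    stop("non-finite atom coordinates in ", path, call. = FALSE)
  }
  class(m) <- c("atom_model", class(m))
  m
}

#' Select atoms from a model
#'
#' @param model An `atom_model` tibble (see [read_model]).
#' @param chain Optional chain id(s) to keep.
#' @param resno Optional residue numbers (e.g. a range `10:50`) to keep.
#' @param atom Optional atom name(s) to keep, e.g. `"CA"`.
#' @return The filtered `atom_model`.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, atom = NULL) {
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(atom)) keep <- keep & model$atom %in% atom
  out <- model[keep, , drop = FALSE]
  class(out) <- unique(c("atom_model", class(out)))
  out
}

#' C-alpha coordinates of a model as an n x 3 matrix
#' @param model An `atom_model`.
#' @return Numeric matrix with one row per C-alpha atom.
#' @export
ca_coords <- function(model) {
  ca <- select_atoms(model, atom = "CA")
  if (nrow(ca) == 0) stop("model has no C-alpha atoms", call. = FALSE)
  as.matrix(ca[, c("x", "y", "z")])
}
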