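#' Density volume container
#'
#' A `density_volume` wraps a 3D numeric array together with an isotropic
#' voxel size in angstroms and an (informational) origin offset. The array is
#' stored in x-fastest order, matching the on-disk MRC layout, so
#' `grid[i, j, k]` is the voxel at 0-based position `(i-1, j-1, k-1)`.
#' All physical thresholds elsewhere in the package are expressed in angstroms
#' and converted through `voxel_size` explicitly.
#'
#' @param grid 3D numeric array of density values.
#' @param voxel_size Single positive number, angstroms per voxel (isotropic).
#'   Anisotropic voxel sizes are rejected.
#' @param origin Numeric length-3, angstrom offset of the centre of voxel
#'   (0,0,0). Recorded for provenance only; never used in matching.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L || !is.numeric(grid)) {
    stop("`grid` must be a 3D numeric array", call. = FALSE)
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number of angstroms per voxel; ",
         "anisotropic voxel sizes are not supported", call. = FALSE)
  }
  if (length(origin) != 3L || !is.numeric(origin)) {
    stop("`origin` must be a numeric vector of length 3", call. = FALSE)
  }
  structure(
    list(grid = grid, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "density_volume"
  )
}

#' @export
dim.density_volume <- function(x) dim(x$grid)

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_volume> %d x %d x %d voxels, %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

#' Read an MRC2014 volume
#'
#' Reads mode 0 (int8), 1 (int16) or 2 (float32) MRC files written in
#' little-endian byte order. The voxel size is taken from the header cell
#' dimensions divided by the sampling grid and must be isotropic to 1e-3 A.
#' The header origin is recorded on the returned object but otherwise ignored:
#' volumes are treated as starting at index 0.
#'
#' @param path Path to an MRC file.
#' @return A [density_volume].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  sz <- file.size(path)
  if (sz < 1024) stop("malformed MRC header: file shorter than the 1024-byte header",
                      call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 3, size = 4, endian = "little")  # nxstart..
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # cellb
  readBin(con, "integer", 3, size = 4, endian = "little")  # mapc/mapr/maps
  readBin(con, "numeric", 3, size = 4, endian = "little")  # dmin/dmax/dmean
  readBin(con, "integer", 1, size = 4, endian = "little")  # ispg
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 25, size = 4, endian = "little") # extra
  orig <- readBin(con, "numeric", 3, size = 4, endian = "little")

  if (any(nxyz <= 0L)) stop("malformed MRC header: non-positive nx/ny/nz",
                            call. = FALSE)
  if (!mode %in% c(0L, 1L, 2L)) {
    stop("malformed MRC header: unsupported mode ", mode,
         " (modes 0, 1, 2 supported)", call. = FALSE)
  }
  if (any(mxyz <= 0L)) stop("malformed MRC header: non-positive mx/my/mz",
                            call. = FALSE)
  if (any(cella <= 0)) stop("malformed MRC header: non-positive cell dimensions",
                            call. = FALSE)
  vs <- cella / mxyz
  if (max(vs) - min(vs) > 1e-3) {
    stop("malformed MRC header: anisotropic voxel size ",
         paste(signif(vs, 6), collapse = "/"), call. = FALSE)
  }
  bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L)[[as.character(mode)]]
  ndata <- prod(as.double(nxyz))
  if (sz < 1024 + nsymbt + ndata * bytes) {
    stop("malformed MRC file: truncated data block (expected ",
         1024 + nsymbt + ndata * bytes, " bytes, found ", sz, ")", call. = FALSE)
  }
  seek(con, 1024 + nsymbt)
  data <- if (mode == 2L) {
    readBin(con, "numeric", ndata, size = 4, endian = "little")
  } else {
    readBin(con, "integer", ndata, size = bytes, signed = TRUE,
            endian = "little")
  }
  grid <- array(as.numeric(data), dim = nxyz)
  density_volume(grid, voxel_size = mean(vs), origin = orig)
}

#' Write a density volume as MRC2014 (mode 2, float32)
#'
#' @param vol A [density_volume].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  d <- dim(vol$grid)
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wint(d)                                # nx ny nz
  wint(2L)                               # mode 2: float32
  wint(c(0L, 0L, 0L))                    # nxstart
  wint(d)                                # mx my mz
  wflt(d * vol$voxel_size)               # cella
  wflt(c(90, 90, 90))                    # cellb
  wint(c(1L, 2L, 3L))                    # mapc mapr maps
  wflt(c(min(vol$grid), max(vol$grid), mean(vol$grid)))
  wint(c(1L, 0L))                        # ispg, nsymbt
  wint(integer(25))                      # extra
  wflt(vol$origin)                       # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wflt(stats::sd(vol$grid))
  wint(0L)                               # nlabl
  writeBin(raw(800), con)                # labels
  writeBin(as.numeric(vol$grid), con, size = 4, endian = "little")
  invisible(path)
}
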