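# Cryo-EM volumes: a minimal MRC/CCP4 (2014 dialect) reader/writer and the
# sigma-scaling used to express map values in standard deviations above the
# mean, the unit in which contour thresholds are quoted.

#' Construct a density map
#'
#' @param grid 3-D numeric array; the first index runs fastest along x.
#' @param voxel_size Angstrom per voxel, length-3 (or scalar, recycled).
#' @param origin World-frame position (Angstrom) of the center of voxel
#'   (1, 1, 1).
#' @return A \code{density_map} object with full-grid mean/sd statistics.
#' @export
density_map <- function(grid, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) {
    abort("voxel sizes must be positive", class = "ionpore_geometry_error")
  }
  m <- mean(grid)
  # population RMS deviation, the convention in which map thresholds are
  # quoted (an {0,2} grid scales to {-1,+1})
  s <- sqrt(mean((grid - m)^2))
  structure(
    list(grid = grid, voxel_size = voxel_size, origin = as.numeric(origin),
         mean = m, sd = s, sigma_scaled = FALSE,
         raw_mean = m, raw_sd = s),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<density_map %dx%dx%d, voxel %.3f A, origin (%.1f, %.1f, %.1f), %s>\n",
    d[1], d[2], d[3], x$voxel_size[1], x$origin[1], x$origin[2], x$origin[3],
    if (x$sigma_scaled) "sigma-scaled" else
      sprintf("raw (mean %.3g, sd %.3g)", x$mean, x$sd)))
  invisible(x)
}

#' Scale a map to sigma units
#'
#' Subtracts the full-grid mean and divides by the full-grid standard
#' deviation (the EMDB visualization convention), so a voxel value of 12 reads
#' as "12 sigma". Idempotent: an already-scaled map is returned unchanged.
#' Original statistics are retained in \code{raw_mean}/\code{raw_sd} so peak
#' amplitudes can be mapped back to raw units.
#'
#' @param map A \code{density_map}.
#' @return A sigma-scaled \code{density_map}.
#' @export
sigma_scale <- function(map) {
  stopifnot(inherits(map, "density_map"))
  if (isTRUE(map$sigma_scaled)) return(map)
  if (!is.finite(map$sd) || map$sd <= 0) {
    abort("map has zero variance; sigma scaling is undefined",
          class = "ionpore_degenerate_map")
  }
  out <- map
  out$grid <- (map$grid - map$mean) / map$sd
  out$raw_mean <- map$mean
  out$raw_sd <- map$sd
  out$mean <- 0
  out$sd <- 1
  out$sigma_scaled <- TRUE
  out
}

#' World coordinates of voxel indices
#'
#' @param map A \code{density_map}.
#' @param ijk Integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of Angstrom coordinates of voxel centers.
#' @export
voxel_to_world <- function(map, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk - 1, 2, map$voxel_size, "*"), 2, map$origin, "+")
}

# ---- MRC/CCP4 2014 I/O -----------------------------------------------------
# Header: 56 4-byte words + 800 bytes of labels = 1024 bytes, little-endian.
# Supported modes: 0 (int8), 1 (int16), 2 (float32). Axis order is normalized
# on read so the stored grid always runs x fastest (MAPC,MAPR,MAPS = 1,2,3).

#' Read an MRC/CCP4 volume
#'
#' The world origin follows the convention used when quoting deposited maps:
#' the ORIGIN header record if any component is nonzero, otherwise
#' NXSTART * voxel size. Only orthogonal cells are supported.
#'
#' @param path Path to an .mrc/.map file.
#' @return A \code{density_map}.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("map file not found: ", path), class = "ionpore_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg_nsym <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  invisible(readBin(con, "integer", n = 25, size = 4, endian = "little"))
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 4))          # "MAP "
  invisible(readBin(con, "raw", n = 4))          # machine stamp
  invisible(readBin(con, "numeric", n = 1, size = 4, endian = "little"))  # RMS
  invisible(readBin(con, "integer", n = 1, size = 4, endian = "little"))  # NLABL
  invisible(readBin(con, "raw", n = 800))
  nx <- ints1[1]; ny <- ints1[2]; nz <- ints1[3]; mode <- ints1[4]
  nstart <- ints1[5:7]
  mxyz <- ints1[8:10]
  if (any(abs(cellb - 90) > 1e-3)) {
    abort("non-orthogonal cells are not supported",
          class = "ionpore_unsupported_geometry")
  }
  if (!mode %in% c(0L, 1L, 2L)) {
    abort(paste0("unsupported MRC mode ", mode, " (need 0, 1 or 2)"),
          class = "ionpore_unsupported_mode")
  }
  if (ispg_nsym[2] != 0) {
    invisible(readBin(con, "raw", n = ispg_nsym[2]))  # skip symmetry records
  }
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little")
  )
  if (length(vals) != n) {
    abort("truncated MRC data block", class = "ionpore_format_error")
  }
  grid <- array(vals, dim = c(nx, ny, nz))
  # normalize axis order to x-fastest
  if (!all(mapcrs == c(1L, 2L, 3L))) {
    if (!setequal(mapcrs, 1:3)) {
      abort("MAPC/MAPR/MAPS must be a permutation of 1,2,3",
            class = "ionpore_unsupported_geometry")
    }
    grid <- aperm(grid, order(mapcrs))
    nstart <- nstart[order(mapcrs)]
  }
  mxyz[mxyz <= 0] <- dim(grid)[mxyz <= 0]
  voxel <- cella / mxyz
  voxel[!is.finite(voxel) | voxel <= 0] <- 1
  origin <- if (any(orig != 0)) orig else nstart * voxel
  density_map(grid, voxel_size = voxel, origin = origin)
}

#' Write a density map as MRC/CCP4 (mode 2)
#'
#' The world origin is stored in the ORIGIN header record; NXSTART is zero.
#'
#' @param map A \code{density_map}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # NX NY NZ
  wi(2L)                                  # MODE float32
  wi(c(0L, 0L, 0L))                       # NXSTART
  wi(d)                                   # MX MY MZ
  wf(d * map$voxel_size)                  # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(1:3)                                 # MAPC MAPR MAPS
  wf(c(min(map$grid), max(map$grid), mean(map$grid)))
  wi(c(1L, 0L))                           # ISPG, NSYMBT
  wi(rep(0L, 25))                         # EXTRA
  wf(map$origin)                          # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.vector(map$grid)))             # RMS
  wi(0L)                                  # NLABL
  writeBin(raw(800), con)
  writeBin(as.vector(map$grid), con, size = 4, endian = "little")
  invisible(path)
}
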