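# Density map container and MRC/CCP4 I/O.
#
# A `density_map` stores the voxel grid as a numeric 3-D array with
# dim = (nx, ny, nz), x varying fastest (R column-major order), together
# with a physical origin and voxel spacing in Angstrom.  Files with
# permuted internal axis order (mapc/mapr/maps != 1,2,3) are
# canonicalized to this x,y,z convention on read.

#' Construct a density map
#'
#' A `density_map` is a 3-D scalar density grid with a physical frame:
#' `data[i, j, k]` is the density at Cartesian position
#' `origin + (i-1, j-1, k-1) * voxel_size` (Angstrom).
#'
#' @param data Numeric 3-D array, axis order x, y, z.
#' @param voxel_size Numeric length-3 (or scalar) voxel spacing in
#'   Angstrom per voxel; all components must be positive.
#' @param origin Numeric length-3 physical position of voxel (1,1,1), in
#'   Angstrom.
#' @param label Free-text label stored in the MRC header on write.
#' @return An object of class `density_map`.
#' @examples
#' m <- density_map(array(runif(8^3), c(8, 8, 8)), voxel_size = 1.0)
#' dim(m$data)
#' @export
density_map <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                        label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("`data` must have positive dimensions")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive finite values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 label = as.character(label)[1L]),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size: %.4g x %.4g x %.4g A\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin:     (%.4g, %.4g, %.4g) A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density:    min %.4g, max %.4g, mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Test for density map objects
#' @param x Object to test.
#' @return `TRUE` if `x` is a `density_map`.
#' @export
is_density_map <- function(x) inherits(x, "density_map")

.assert_map <- function(map) {
  if (!is_density_map(map)) stop("expected a `density_map` object")
  invisible(map)
}

# ---------------------------------------------------------------------------
# MRC2014 header layout (1024 bytes, 56 words + 800 bytes of labels).
# Only the fields this package uses are interpreted; the rest round-trip
# as zeros.  Mode 2 (float32) is written; modes 0, 1, 2 are read.

#' Read an MRC/CCP4 density map
#'
#' Reads a map file and canonicalizes it to the package's fixed axis
#' convention (data array indexed x, y, z with x fastest), honoring the
#' header's `mapc`/`mapr`/`maps` axis-order fields.  The physical origin
#' is taken from the MRC2014 `origin` record when non-zero, otherwise
#' from the `nxstart`/`nystart`/`nzstart` offsets times the voxel size.
#'
#' @param path Path to an MRC/CCP4 file (modes 0, 1 and 2 supported).
#' @return A [density_map].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("cannot read map: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nc <- hdr_i[1]; nr <- hdr_i[2]; ns <- hdr_i[3]; mode <- hdr_i[4]
  nstart <- hdr_i[5:7]
  m_grid <- hdr_i[8:10]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little")  # cellb
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little")  # dmin/dmax/dmean
  readBin(con, "integer", n = 2L, size = 4L, endian = "little")  # ispg, nsymbt
  readBin(con, "raw", n = 4L * 25L)                               # extra words 25-49
  orig <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  map_id <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "raw", n = 4L)                                     # machst
  readBin(con, "numeric", n = 1L, size = 4L, endian = "little")   # rms
  nlabl <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  labels <- readBin(con, "raw", n = 800L)

  if (any(c(nc, nr, ns) <= 0L))
    stop("malformed MRC header in ", path, ": non-positive dimensions")
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode, " in ", path,
         " (field `mode`; modes 0, 1, 2 supported)")
  if (!identical(sort(mapcrs), 1:3))
    stop("malformed MRC header in ", path, ": mapc/mapr/maps = ",
         paste(mapcrs, collapse = ","))

  n_vox <- as.numeric(nc) * nr * ns
  raw_data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n_vox, size = 1L,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n_vox, size = 2L,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = n_vox, size = 4L, endian = "little"))
  if (length(raw_data) != n_vox)
    stop("truncated MRC data block in ", path)
  arr <- array(raw_data, dim = c(nc, nr, ns))

  # file axes (col, row, section) carry Cartesian axes mapcrs; permute so
  # result dimension d is the file dimension holding Cartesian axis d
  perm <- match(1:3, mapcrs)
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)

  m_grid_xyz <- pmax(m_grid, 1L)
  voxel <- ifelse(cella > 0, cella / m_grid_xyz, 1.0)
  nstart_xyz <- nstart[perm]
  origin <- if (any(orig != 0)) as.numeric(orig) else nstart_xyz * voxel

  lab <- ""
  if (nlabl >= 1L && nlabl <= 10L) {
    first <- labels[1:80]
    lab <- trimws(rawToChar(first[first != as.raw(0)]))
  }
  density_map(arr, voxel_size = voxel, origin = origin, label = lab)
}

#' Write a density map to an MRC file
#'
#' Writes a standard MRC2014 file in mode 2 (32-bit float), axis order
#' x, y, z (`mapc,mapr,maps = 1,2,3`), with the origin stored in the
#' MRC2014 origin record.
#'
#' @param map A [density_map].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path) {
  .assert_map(map)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write map: ", path,
                                           " (", conditionMessage(e), ")"))
  on.exit(close(con))
  d <- dim(map$data)
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nstart
  wi(d)                      # mx my mz
  wf(d * map$voxel_size)     # cella
  wf(c(90, 90, 90))          # cellb
  wi(1:3)                    # mapc mapr maps
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(c(1L, 0L))              # ispg, nsymbt
  writeBin(raw(4L * 25L), con)
  wf(map$origin)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(sd(as.vector(map$data)))
  has_label <- nzchar(map$label)
  wi(if (has_label) 1L else 0L)
  labels <- raw(800L)
  if (has_label) {
    lab_raw <- charToRaw(formatC(substr(map$label, 1L, 80L), width = -80L))
    labels[seq_along(lab_raw)] <- lab_raw
  }
  writeBin(labels, con)
  wf(as.vector(map$data))
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Resample a density map to a uniform grid spacing
#'
#' Trilinear interpolation onto a new grid with the given uniform
#' spacing.  The new grid starts at the input origin and covers the full
#' physical extent of the input (to within one voxel).  Interpolation
#' points outside the input grid evaluate to 0, matching the
#' zero-padding used downstream by the cube pipeline.
#'
#' @param map A [density_map].
#' @param target_spacing Output voxel spacing in Angstrom (default 1.0).
#' @return A [density_map] with `voxel_size = rep(target_spacing, 3)`.
#' @export
resample_to_unit_grid <- function(map, target_spacing = 1.0) {
  .assert_map(map)
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be a single positive number")
  d <- dim(map$data)
  if (all(abs(map$voxel_size - target_spacing) < 1e-12)) return(map)

  extent <- (d - 1L) * map$voxel_size            # physical span from origin
  nd <- pmax(as.integer(floor(extent / target_spacing + 1e-9)) + 1L, 1L)

  # fractional input-grid coordinates (0-based) of each output voxel
  gx <- (seq_len(nd[1]) - 1) * target_spacing / map$voxel_size[1]
  gy <- (seq_len(nd[2]) - 1) * target_spacing / map$voxel_size[2]
  gz <- (seq_len(nd[3]) - 1) * target_spacing / map$voxel_size[3]
  out <- .trilinear_grid(map$data, gx, gy, gz)
  density_map(out, voxel_size = rep(target_spacing, 3L), origin = map$origin,
              label = map$label)
}

# Trilinear interpolation of `arr` at the tensor grid gx x gy x gz of
# fractional 0-based coordinates; points outside [0, n-1] evaluate to 0.
.trilinear_grid <- function(arr, gx, gy, gz) {
  d <- dim(arr)
  clampf <- function(g, n) {
    inside <- g >= -1e-12 & g <= (n - 1) + 1e-12
    i0 <- floor(g)
    i0[i0 > n - 2] <- n - 2     # snap points on/past the last node
    i0[i0 < 0] <- 0             # outside points are masked to 0 below
    f <- g - i0
    list(i0 = i0, f = f, inside = inside)
  }
  # degenerate single-plane axes: treat as constant along that axis
  if (any(d < 2L)) {
    arr2 <- array(0, pmax(d, 2L))
    arr2[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    if (d[1] < 2L) arr2[2, , ] <- arr2[1, , ]
    if (d[2] < 2L) arr2[, 2, ] <- arr2[, 1, ]
    if (d[3] < 2L) arr2[, , 2] <- arr2[, , 1]
    arr <- arr2
    d <- dim(arr)
  }
  cx <- clampf(gx, d[1]); cy <- clampf(gy, d[2]); cz <- clampf(gz, d[3])
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  ix <- rep(cx$i0, times = ny * nz)
  fx <- rep(cx$f, times = ny * nz)
  iy <- rep(rep(cy$i0, each = nx), times = nz)
  fy <- rep(rep(cy$f, each = nx), times = nz)
  iz <- rep(cz$i0, each = nx * ny)
  fz <- rep(cz$f, each = nx * ny)
  inside <- rep(cx$inside, times = ny * nz) &
    rep(rep(cy$inside, each = nx), times = nz) &
    rep(cz$inside, each = nx * ny)

  at <- function(dx, dy, dz)
    arr[cbind(ix + dx + 1, iy + dy + 1, iz + dz + 1)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(0, 0, 0) +
       fx * (1 - fy) * (1 - fz) * at(1, 0, 0) +
       (1 - fx) * fy * (1 - fz) * at(0, 1, 0) +
       fx * fy * (1 - fz) * at(1, 1, 0) +
       (1 - fx) * (1 - fy) * fz * at(0, 0, 1) +
       fx * (1 - fy) * fz * at(1, 0, 1) +
       (1 - fx) * fy * fz * at(0, 1, 1) +
       fx * fy * fz * at(1, 1, 1)
  v[!inside] <- 0
  array(v, c(nx, ny, nz))
}

#' Min-max normalize a density map to [0, 1]
#'
#' Negative densities are clamped to 0 first; the map is then rescaled
#' voxel-wise as `(d - min) / (max - min)` so the output spans exactly
#' `[0, 1]`.  Statistics are computed over the whole map (not per cube).
#'
#' @param map A [density_map].
#' @return A normalized [density_map].
#' @export
normalize_density <- function(map) {
  .assert_map(map)
  d <- map$data
  d[d < 0] <- 0
  lo <- min(d); hi <- max(d)
  if (hi <= lo)
    stop("degenerate map: constant density after clamping negatives, ",
         "cannot normalize")
  map$data <- (d - lo) / (hi - lo)
  map
}
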