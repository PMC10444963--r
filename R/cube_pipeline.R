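# Sliding-cube decomposition of maps, valid-pair filtering, and
# overlap-averaged reconstruction.  At the enforced 1 Angstrom spacing a
# 25-voxel cube is the canonical 25^3 A^3 chunk; cubes slide with a
# stride of 4 voxels and the map is zero-padded upward so every original
# voxel is covered.

#' Build the sliding-cube grid for a map shape
#'
#' Along each axis the cube corner offsets run `0, stride, ...` up to
#' the smallest multiple of `stride` that is `>= N - cube_size` (N being
#' the padded length), and the map is zero-padded to
#' `max_offset + cube_size` so every original voxel is covered.  Offsets
#' are ordered lexicographically, first axis most significant.
#'
#' @param shape Integer length-3 original map shape (voxels).
#' @param cube_size Cube edge length in voxels (default 25).
#' @param stride Cube translation step in voxels (default 4).
#' @param voxel_size,origin Physical frame carried through to
#'   [merge_cubes()].
#' @return A list of class `cube_grid` with fields `cube_size`,
#'   `stride`, `offsets` (n x 3 integer matrix, 0-based corner
#'   positions), `padded_shape`, `original_shape`, `voxel_size`,
#'   `origin`.
#' @export
cube_grid <- function(shape, cube_size = 25L, stride = 4L,
                      voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  cube_size <- as.integer(cube_size)
  stride <- as.integer(stride)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (cube_size < 1L) stop("`cube_size` must be positive")
  if (stride < 1L || stride > cube_size)
    stop("`stride` must satisfy 0 < stride <= cube_size")
  ax_offsets <- function(n) {
    max_off <- if (n <= cube_size) 0L else
      stride * as.integer(ceiling((n - cube_size) / stride))
    seq.int(0L, max_off, by = stride)
  }
  ox <- ax_offsets(shape[1]); oy <- ax_offsets(shape[2])
  oz <- ax_offsets(shape[3])
  padded <- c(max(ox) + cube_size, max(oy) + cube_size, max(oz) + cube_size)
  # lexicographic: x most significant, z fastest
  off <- as.matrix(expand.grid(z = oz, y = oy, x = ox))[, c("x", "y", "z"),
                                                        drop = FALSE]
  dimnames(off) <- NULL
  structure(list(cube_size = cube_size, stride = stride,
                 offsets = off, padded_shape = as.integer(padded),
                 original_shape = shape,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "cube_grid")
}

#' @export
print.cube_grid <- function(x, ...) {
  cat(sprintf("<cube_grid> %d cubes of %d^3 voxels, stride %d\n",
              nrow(x$offsets), x$cube_size, x$stride))
  cat(sprintf("  original shape %s, padded to %s\n",
              paste(x$original_shape, collapse = "x"),
              paste(x$padded_shape, collapse = "x")))
  invisible(x)
}

.pad_to <- function(arr, shape) {
  if (all(dim(arr) == shape)) return(arr)
  out <- array(0, shape)
  d <- dim(arr)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out
}

#' Extract sliding cubes from a density map
#'
#' @param map A [density_map], expected to be normalized to `[0, 1]` and
#'   resampled to 1 Angstrom spacing for the canonical pipeline (not
#'   enforced here).
#' @param cube_size Cube edge in voxels (default 25).
#' @param stride Stride in voxels (default 4).
#' @return A list with `grid` (a [cube_grid]) and `cubes` (a list of
#'   `cube_size^3` arrays, one per grid offset, in grid order).
#' @export
extract_cubes <- function(map, cube_size = 25L, stride = 4L) {
  .assert_map(map)
  grid <- cube_grid(dim(map$data), cube_size, stride,
                    voxel_size = map$voxel_size, origin = map$origin)
  padded <- .pad_to(map$data, grid$padded_shape)
  cs <- grid$cube_size
  cubes <- lapply(seq_len(nrow(grid$offsets)), function(i) {
    o <- grid$offsets[i, ]
    padded[o[1] + seq_len(cs), o[2] + seq_len(cs), o[3] + seq_len(cs)]
  })
  list(grid = grid, cubes = cubes)
}

#' Extract matched experimental/simulated cube pairs
#'
#' Cubes are extracted at identical offsets from both maps; a pair is
#' kept iff neither cube is all zeros.
#'
#' @param exp,sim Two [density_map]s on the same grid frame (same shape,
#'   voxel size and origin).
#' @param cube_size,stride As in [extract_cubes()].
#' @return A list with `grid` and `pairs`; each pair is a list with
#'   `exp_cube`, `sim_cube` and `offset` (0-based integer 3-vector).
#' @export
make_pairs <- function(exp, sim, cube_size = 25L, stride = 4L) {
  .assert_map(exp); .assert_map(sim)
  if (!all(dim(exp$data) == dim(sim$data)))
    stop("map shape mismatch: exp ", paste(dim(exp$data), collapse = "x"),
         " vs sim ", paste(dim(sim$data), collapse = "x"))
  if (any(abs(exp$voxel_size - sim$voxel_size) > 1e-6) ||
      any(abs(exp$origin - sim$origin) > 1e-6))
    stop("maps are not on the same grid frame (voxel size / origin differ)")
  ce <- extract_cubes(exp, cube_size, stride)
  cs <- extract_cubes(sim, cube_size, stride)
  keep <- vapply(seq_along(ce$cubes), function(i)
    any(ce$cubes[[i]] != 0) && any(cs$cubes[[i]] != 0), logical(1))
  pairs <- lapply(which(keep), function(i)
    list(exp_cube = ce$cubes[[i]], sim_cube = cs$cubes[[i]],
         offset = ce$grid$offsets[i, ]))
  list(grid = ce$grid, pairs = pairs)
}

#' Merge cubes back into a full map with overlap averaging
#'
#' Each voxel receives the arithmetic mean of all cubes covering it; the
#' padded border is then cropped back to the original shape.
#'
#' @param grid A [cube_grid].
#' @param cubes List of `cube_size^3` arrays, one per grid offset, in
#'   grid order.
#' @return A [density_map] with the grid's original shape and frame.
#' @export
merge_cubes <- function(grid, cubes) {
  if (!inherits(grid, "cube_grid")) stop("expected a `cube_grid`")
  if (length(cubes) != nrow(grid$offsets))
    stop("got ", length(cubes), " cubes for ", nrow(grid$offsets),
         " grid offsets")
  cs <- grid$cube_size
  acc <- array(0, grid$padded_shape)
  cnt <- array(0, grid$padded_shape)
  for (i in seq_along(cubes)) {
    cube <- cubes[[i]]
    if (!all(dim(cube) == cs)) stop("cube ", i, " has wrong shape")
    o <- grid$offsets[i, ]
    ix <- o[1] + seq_len(cs); iy <- o[2] + seq_len(cs)
    iz <- o[3] + seq_len(cs)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + cube
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  merged <- acc / cnt
  d <- grid$original_shape
  density_map(merged[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                     drop = FALSE],
              voxel_size = grid$voxel_size, origin = grid$origin)
}
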