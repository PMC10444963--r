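test_that("MRC write/read round-trips data, header and origin", {
  m <- rand_map(c(10, 12, 14), seed = 11, voxel = 1.2, origin = c(1.5, -2, 3))
  m$label <- "round trip"
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  m2 <- read_map(p)
  expect_lt(max(abs(m2$data - m$data)), 1e-6)   # float32 storage
  expect_equal(m2$voxel_size, c(1.2, 1.2, 1.2), tolerance = 1e-6)
  expect_equal(m2$origin, c(1.5, -2, 3), tolerance = 1e-6)
  expect_equal(m2$label, "round trip")

  z <- density_map(array(0, c(8, 8, 8)))
  pz <- withr::local_tempfile(fileext = ".mrc")
  write_map(z, pz)
  expect_equal(file.size(pz), 1024 + 4 * 8^3)   # header + mode-2 data
  expect_equal(read_map(pz)$data, z$data)

  n <- normalize_density(rand_map(c(6, 6, 6), seed = 12, lo = -1, hi = 2))
  pn <- withr::local_tempfile(fileext = ".mrc")
  write_map(n, pn)
  rn <- read_map(pn)
  expect_lt(abs(min(rn$data)), 1e-6)
  expect_lt(abs(max(rn$data) - 1), 1e-6)
})

test_that("read_map canonicalizes permuted axis order", {
  m <- rand_map(c(5, 6, 7), seed = 21)
  # hand-write a file whose fastest axis is Cartesian y (mapcrs = 2,3,1)
  write_permuted <- function(map, path, mapcrs) {
    perm_store <- mapcrs            # file dim i holds Cartesian axis mapcrs[i]
    raw_arr <- aperm(map$data, perm_store)
    con <- file(path, "wb"); on.exit(close(con))
    wi <- function(v) writeBin(as.integer(v), con, size = 4L,
                               endian = "little")
    wf <- function(v) writeBin(as.numeric(v), con, size = 4L,
                               endian = "little")
    d <- dim(raw_arr)
    wi(d); wi(2L); wi(c(0L, 0L, 0L))
    wi(dim(map$data))                       # mx,my,mz follow Cartesian axes
    wf(dim(map$data) * map$voxel_size); wf(c(90, 90, 90))
    wi(mapcrs)
    wf(c(min(map$data), max(map$data), mean(map$data)))
    wi(c(1L, 0L)); writeBin(raw(100L), con)
    wf(map$origin)
    writeChar("MAP ", con, nchars = 4L, eos = NULL)
    writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
    wf(0); wi(0L); writeBin(raw(800L), con)
    wf(as.vector(raw_arr))
  }
  p1 <- withr::local_tempfile(fileext = ".mrc")
  p2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p1)
  write_permuted(m, p2, c(2L, 3L, 1L))
  a <- read_map(p1); b <- read_map(p2)
  expect_equal(dim(b$data), dim(m$data))
  expect_lt(max(abs(a$data - b$data)), 1e-6)
})

test_that("read_map rejects unreadable or malformed files", {
  expect_error(read_map(file.path(tempdir(), "nope.mrc")), "no such file")
  p <- withr::local_tempfile(fileext = ".mrc")
  m <- rand_map(c(4, 4, 4), seed = 1)
  write_map(m, p)
  # corrupt the mode field (bytes 13-16) to an unsupported value
  con <- file(p, "r+b"); seek(con, 12, rw = "write")
  writeBin(99L, con, size = 4L, endian = "little"); close(con)
  expect_error(read_map(p), "mode")
})

test_that("resampling is the identity at the input spacing", {
  m <- rand_map(c(7, 8, 9), seed = 31)
  expect_identical(resample_to_unit_grid(m, 1.0)$data, m$data)
})

test_that("resampling reproduces affine fields exactly", {
  # trilinear interpolation is exact on trilinear (here: affine) fields
  d <- c(6, 7, 8)
  co <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  f <- function(x, y, z) 0.3 * x - 1.2 * y + 2.5 * z + 4
  m <- density_map(array(f(co$x * 2, co$y * 2, co$z * 2), d),
                   voxel_size = 2.0)
  r <- resample_to_unit_grid(m, 0.8)
  dr <- dim(r$data)
  cr <- expand.grid(x = 0:(dr[1] - 1), y = 0:(dr[2] - 1), z = 0:(dr[3] - 1))
  expect_lt(max(abs(r$data - array(f(cr$x * 0.8, cr$y * 0.8, cr$z * 0.8),
                                   dr))), 1e-9)
})

test_that("upsampling recovers original values at original grid points", {
  m <- rand_map(c(5, 5, 5), seed = 41, voxel = 2.0)
  r <- resample_to_unit_grid(m, 1.0)
  expect_lt(max(abs(r$data[seq(1, 9, 2), seq(1, 9, 2), seq(1, 9, 2)] -
                    m$data)), 1e-9)
})

test_that("resampling agrees with the brute-force trilinear oracle", {
  for (seed in c(51, 52)) {
    m <- rand_map(c(6, 5, 7), seed = seed, voxel = 1.7)
    r <- resample_to_unit_grid(m, 1.0)
    dr <- dim(r$data)
    pts <- expand.grid(i = seq_len(dr[1]), j = seq_len(dr[2]),
                       k = seq_len(dr[3]))
    sel <- seq(1, nrow(pts), by = 7)  # spot-check a lattice subset
    for (s in sel) {
      p <- unname(unlist(pts[s, ]) - 1) * 1.0 / 1.7
      expect_equal(r$data[pts$i[s], pts$j[s], pts$k[s]],
                   unname(bf_trilinear_point(m$data, p)), tolerance = 1e-9)
    }
  }
})

test_that("normalize_density clamps, rescales and is idempotent", {
  m <- density_map(array(c(-1, 0, 2, rep(0.5, 5)), c(2, 2, 2)))
  n <- normalize_density(m)
  expect_equal(sort(unique(as.vector(n$data))), c(0, 0.25, 1))
  expect_equal(min(n$data), 0)
  expect_equal(max(n$data), 1)
  n2 <- normalize_density(n)
  expect_lt(max(abs(n2$data - n$data)), 1e-9)

  expect_error(normalize_density(density_map(array(0, c(3, 3, 3)))),
               "degenerate")
  expect_error(normalize_density(density_map(array(-2, c(3, 3, 3)))),
               "degenerate")
  expect_error(normalize_density(density_map(array(7, c(3, 3, 3)))),
               "degenerate")
})

test_that("density_map validates its inputs", {
  expect_error(density_map(1:10), "3-D array")
  expect_error(density_map(array(0, c(2, 2, 2)), voxel_size = c(1, -1, 1)),
               "positive")
  expect_error(density_map(array(0, c(2, 2, 2)), origin = c(1, NA, 0)),
               "finite")
})
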