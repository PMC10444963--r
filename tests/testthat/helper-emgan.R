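# Shared helpers: small network configs, random-map builders, and the
# independent brute-force oracles used throughout the suite.

small_gen_cfg <- function(blocks = 1L, channels = 4L, dropout = 0.25)
  generator_config(n_resnet_blocks = blocks, channels = channels,
                   dropout_p = dropout)

small_disc_cfg <- function(layers = 4L, channels = 4L)
  discriminator_config(n_conv_layers = layers, base_channels = channels,
                       group_norm_group_size = 4L)

rand_map <- function(shape, seed, voxel = 1, origin = c(0, 0, 0),
                     lo = 0, hi = 1) {
  set.seed(seed)
  density_map(array(runif(prod(shape), lo, hi), shape),
              voxel_size = voxel, origin = origin)
}

# sparse map: mostly zero with a few random positive blobs
sparse_map <- function(shape, seed, n_blobs = 3L) {
  set.seed(seed)
  arr <- array(0, shape)
  for (b in seq_len(n_blobs)) {
    c0 <- sapply(shape, function(n) sample(seq_len(n), 1))
    w <- sample(2:4, 1)
    ix <- lapply(1:3, function(a)
      max(1, c0[a] - w):min(shape[a], c0[a] + w))
    arr[ix[[1]], ix[[2]], ix[[3]]] <-
      runif(length(ix[[1]]) * length(ix[[2]]) * length(ix[[3]]))
  }
  density_map(arr)
}

# --- independent oracles ---------------------------------------------------

# trilinear interpolation of arr (0-based grid) at one fractional point
bf_trilinear_point <- function(arr, p) {
  d <- dim(arr)
  if (any(p < 0) || any(p > d - 1)) return(0)
  i0 <- pmin(pmax(floor(p), 0), d - 2)
  f <- p - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
    v <- v + wgt * arr[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  v
}

# covering cube offsets along one axis: grow until the last cube
# covers the final original voxel
bf_axis_offsets <- function(n, cube, stride) {
  offs <- 0L
  while (tail(offs, 1) + cube < n) offs <- c(offs, tail(offs, 1) + stride)
  offs
}

# overlap-average merge by direct accumulation
bf_merge <- function(offsets, cubes, cube, padded, original) {
  acc <- array(0, padded)
  cnt <- array(0, padded)
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    ix <- o[1] + seq_len(cube); iy <- o[2] + seq_len(cube)
    iz <- o[3] + seq_len(cube)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + cubes[[i]]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  (acc / cnt)[seq_len(original[1]), seq_len(original[2]),
              seq_len(original[3])]
}

# Pearson correlation written out longhand
bf_pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# per-residue masked correlation by scanning every voxel
bf_rscc <- function(map, ref, model, radius) {
  d <- dim(map$data)
  key <- paste(model$chain, model$resi, model$icode)
  out <- list()
  for (rk in unique(key)) {
    sel <- which(key == rk)
    vox <- c()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      pos <- map$origin + (c(i, j, k) - 1) * map$voxel_size
      for (a in sel) {
        dd <- pos - c(model$x[a], model$y[a], model$z[a])
        if (sum(dd^2) <= radius^2) {
          vox <- c(vox, i + (j - 1) * d[1] + (k - 1) * d[1] * d[2])
          break
        }
      }
    }
    vox <- unique(vox)
    if (length(vox) < 2) next
    mv <- map$data[vox]; rv <- ref$data[vox]
    if (sd(mv) == 0 || sd(rv) == 0) next
    out[[rk]] <- bf_pearson(mv, rv)
  }
  out
}
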