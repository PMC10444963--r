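# Internal neural-network layer primitives with hand-written backward
# passes.  Feature maps are numeric arrays dim = (nx, ny, nz, channels);
# convolutions dispatch to the compiled im2col kernel.  All dropout
# randomness is drawn from R's RNG stream so a single set.seed() makes
# training fully reproducible.

.EPS_NORM <- 1e-5

.conv_fw <- function(x, w, b, stride = 1L, pad = NULL) {
  k <- dim(w)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  conv3d_fw(x, w, b, as.integer(stride), as.integer(pad))
}

.conv_bw <- function(x, w, gout, stride = 1L, pad = NULL) {
  k <- dim(w)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  conv3d_bw(x, w, gout, as.integer(stride), as.integer(pad))
}

# PReLU with one learnable slope per layer
.prelu_fw <- function(x, a) {
  neg <- x < 0
  y <- x
  y[neg] <- a * x[neg]
  list(y = y, neg = neg, x = x)
}

.prelu_bw <- function(dy, cache, a) {
  dx <- dy
  dx[cache$neg] <- a * dy[cache$neg]
  da <- sum(dy[cache$neg] * cache$x[cache$neg])
  list(dx = dx, da = da)
}

# Instance normalization with learnable per-channel affine (gamma,
# beta): per-channel standardization over spatial voxels of a single
# sample, then y = gamma * xhat + beta.  The affine scale is what lets
# a residual block's contribution start at zero (zero-init-residual)
# without the normalization blowing the branch back up to unit
# variance.
.instnorm_fw <- function(x, gamma, beta) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  M <- x; dim(M) <- c(nvox, d[4])
  mu <- colMeans(M)
  xc <- sweep(M, 2L, mu)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + .EPS_NORM)
  xhat <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, dims = d)
}

.instnorm_bw <- function(dy, cache, gamma) {
  d <- cache$dims
  nvox <- prod(d[1:3])
  G <- dy; dim(G) <- c(nvox, d[4])
  dgamma <- colSums(G * cache$xhat)
  dbeta <- colSums(G)
  Gh <- sweep(G, 2L, gamma, `*`)          # gradient w.r.t. xhat
  m1 <- colMeans(Gh)
  m2 <- colMeans(Gh * cache$xhat)
  dx <- sweep(Gh, 2L, m1) - sweep(cache$xhat, 2L, m2, `*`)
  dx <- sweep(dx, 2L, cache$istd, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Group normalization over (spatial x channel-group) of one sample,
# group size capped at (and forced to divide) the channel count.
.gn_group_size <- function(channels, gsize) {
  gs <- min(gsize, channels)
  while (channels %% gs != 0L) gs <- gs - 1L
  gs
}

.groupnorm_fw <- function(x, gsize) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  C <- d[4]
  gs <- .gn_group_size(C, gsize)
  M <- x; dim(M) <- c(nvox, C)
  xhat <- M
  istd <- numeric(C %/% gs)
  groups <- split(seq_len(C), rep(seq_len(C %/% gs), each = gs))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    vals <- M[, idx, drop = FALSE]
    mu <- mean(vals)
    v <- mean((vals - mu)^2)
    istd[g] <- 1 / sqrt(v + .EPS_NORM)
    xhat[, idx] <- (vals - mu) * istd[g]
  }
  y <- xhat
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, groups = groups, dims = d)
}

.groupnorm_bw <- function(dy, cache) {
  d <- cache$dims
  nvox <- prod(d[1:3])
  G <- dy; dim(G) <- c(nvox, d[4])
  dx <- G
  for (g in seq_along(cache$groups)) {
    idx <- cache$groups[[g]]
    gg <- G[, idx, drop = FALSE]
    xh <- cache$xhat[, idx, drop = FALSE]
    m1 <- mean(gg)
    m2 <- mean(gg * xh)
    dx[, idx] <- cache$istd[g] * (gg - m1 - xh * m2)
  }
  dim(dx) <- d
  dx
}

# Inverted dropout; identity when not training or p == 0.
.dropout_fw <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

.dropout_bw <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# ---------------------------------------------------------------------------
# Parameter-tree utilities: parameters are nested named lists whose
# leaves are numeric arrays/scalars; gradients and Adam moments mirror
# the structure.

.tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) .tree_map(f, t)) else f(tree)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

.tree_zero <- function(tree) .tree_map(function(x) x * 0, tree)

.tree_scale <- function(tree, s) .tree_map(function(x) x * s, tree)

.tree_add <- function(a, b) .tree_map2(`+`, a, b)

.tree_finite <- function(tree) {
  ok <- TRUE
  walk <- function(t) {
    if (is.list(t)) lapply(t, walk)
    else if (any(!is.finite(t))) ok <<- FALSE
    invisible(NULL)
  }
  walk(tree)
  ok
}

# Adam optimizer state and update (beta1 = 0.9, beta2 = 0.999)
.adam_init <- function(params)
  list(m = .tree_zero(params), v = .tree_zero(params), t = 0L)

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
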