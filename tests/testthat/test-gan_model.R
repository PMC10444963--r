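test_that("config constructors validate their fields", {
  expect_error(generator_config(kernel_size = 4), "odd")
  expect_error(generator_config(dropout_p = 1), "dropout")
  expect_error(discriminator_config(n_conv_layers = 0), ">= 1")
  expect_equal(discriminator_channels(discriminator_config()),
               c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L, 512L, 512L))
  expect_equal(discriminator_channels(small_disc_cfg(5, 8)),
               c(8L, 8L, 16L, 16L, 32L))
})

test_that("generator preserves shape, range and is deterministic", {
  P <- gan_init(small_gen_cfg(2, 4), small_disc_cfg(), seed = 7)
  for (n in c(9, 13)) {
    cube <- array(runif(n^3), c(n, n, n))
    out <- generator_forward(cube, P)
    expect_equal(dim(out), dim(cube))
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
    out2 <- generator_forward(cube, P)
    expect_identical(out, out2)   # inference has no randomness
  }
  expect_error(generator_forward(matrix(0, 3, 3), P), "3-D")
})

test_that("zeroed projection conv forces a constant 0.5 output", {
  P <- gan_init(small_gen_cfg(1, 4), small_disc_cfg(), seed = 8)
  P$gen$w_out[] <- 0
  P$gen$b_out <- 0
  out <- generator_forward(array(runif(7^3), c(7, 7, 7)), P)
  expect_true(all(out == 0.5))    # tanh(0) = 0 -> (0+1)/2
})

test_that("a block-free generator still preserves shape", {
  P <- gan_init(small_gen_cfg(0, 3), small_disc_cfg(), seed = 9)
  cube <- array(runif(8^3), c(8, 8, 8))
  out <- generator_forward(cube, P)
  expect_equal(dim(out), dim(cube))
})

test_that("discriminator returns a valid, deterministic probability", {
  P <- gan_init(small_gen_cfg(1, 3), small_disc_cfg(4, 4), seed = 10)
  cube <- array(runif(11^3), c(11, 11, 11))
  p <- discriminator_forward(cube, P)
  expect_gte(p, 0); expect_lte(p, 1)
  expect_identical(p, discriminator_forward(cube, P))
  # softmax normalization: both class probabilities sum to one
  full <- emgan3d:::.disc_fw(cube, P$disc, P$disc_cfg, training = FALSE)
  expect_equal(sum(full$p), 1, tolerance = 1e-6)
})

test_that("loss functions match direct arithmetic", {
  a <- array(1, c(3, 3, 3)); b <- array(0, c(3, 3, 3))
  expect_equal(content_loss(a, a), 0)
  expect_equal(content_loss(a, b), 1)
  set.seed(11)
  x <- array(runif(27), c(3, 3, 3)); y <- array(runif(27), c(3, 3, 3))
  bf <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    bf <- bf + (x[i, j, k] - y[i, j, k])^2
  expect_equal(content_loss(x, y), bf / 27, tolerance = 1e-9)
  expect_equal(content_loss(x, y, reduction = "sum"), bf, tolerance = 1e-9)
  expect_error(content_loss(a, array(0, c(2, 2, 2))), "mismatch")

  expect_equal(adversarial_loss(1), -1)
  expect_equal(adversarial_loss(0), 0)
  expect_equal(adversarial_loss(0.37), -0.37)
  expect_error(adversarial_loss(1.2), "probability")

  expect_equal(generator_loss(0.5, -0.8, 1e-3), 0.4992)
  expect_equal(generator_loss(0.5, -0.8, 0), 0.5)
  expect_equal(generator_loss(0, -1, 1e-3), -0.001)
  expect_error(generator_loss(-0.1, 0, 1e-3), "non-negative")

  expect_equal(discriminator_loss(1, 0), 0)
  expect_equal(discriminator_loss(0, 1), 2)
  expect_equal(discriminator_loss(0.6, 0.3), 0.7)
  expect_error(discriminator_loss(1.5, 0), "\\[0, 1\\]")
})

test_that("analytic gradients match finite differences", {
  # the whole training loop rests on these hand-written backward passes
  gcfg <- small_gen_cfg(1, 3, dropout = 0)
  dcfg <- small_disc_cfg(3, 3)
  P <- gan_init(gcfg, dcfg, seed = 12)
  cube <- array(runif(5^3), c(5, 5, 5))
  R <- array(rnorm(5^3), c(5, 5, 5))
  fw <- emgan3d:::.gen_fw(cube, P$gen, gcfg, training = FALSE)
  bwd <- emgan3d:::.gen_bw(R, fw$cache, P$gen)
  num_grad <- function(setter, getter, eps = 1e-6) {
    v <- getter()
    v[1] <- v[1] + eps; setter(v)
    fp <- sum(emgan3d:::.gen_fw(cube, P$gen, gcfg, FALSE)$out * R)
    v[1] <- v[1] - 2 * eps; setter(v)
    fm <- sum(emgan3d:::.gen_fw(cube, P$gen, gcfg, FALSE)$out * R)
    v[1] <- v[1] + eps; setter(v)
    (fp - fm) / (2 * eps)
  }
  checks <- list(
    list(g = bwd$grads$w_in[1],
         set = function(v) P$gen$w_in <<- v, get = function() P$gen$w_in),
    list(g = bwd$grads$blocks[[1]]$w1[1],
         set = function(v) P$gen$blocks[[1]]$w1 <<- v,
         get = function() P$gen$blocks[[1]]$w1),
    list(g = bwd$grads$blocks[[1]]$w2[1],
         set = function(v) P$gen$blocks[[1]]$w2 <<- v,
         get = function() P$gen$blocks[[1]]$w2),
    list(g = bwd$grads$a_in,
         set = function(v) P$gen$a_in <<- v, get = function() P$gen$a_in),
    list(g = bwd$grads$w_out[1],
         set = function(v) P$gen$w_out <<- v, get = function() P$gen$w_out))
  for (ck in checks)
    expect_equal(num_grad(ck$set, ck$get), ck$g, tolerance = 1e-5)

  # discriminator: d p_real / d theta and d p_real / d input
  dfw <- emgan3d:::.disc_fw(cube, P$disc, dcfg, training = FALSE)
  dbw <- emgan3d:::.disc_bw(1, dfw$cache, P$disc)
  ng2 <- function(setter, getter, eps = 1e-6) {
    v <- getter()
    v[1] <- v[1] + eps; setter(v)
    fp <- emgan3d:::.disc_fw(cube, P$disc, dcfg, FALSE)$p[1]
    v[1] <- v[1] - 2 * eps; setter(v)
    fm <- emgan3d:::.disc_fw(cube, P$disc, dcfg, FALSE)$p[1]
    v[1] <- v[1] + eps; setter(v)
    (fp - fm) / (2 * eps)
  }
  expect_equal(ng2(function(v) P$disc$layers[[1]]$w <<- v,
                   function() P$disc$layers[[1]]$w),
               dbw$grads$layers[[1]]$w[1], tolerance = 1e-5)
  expect_equal(ng2(function(v) P$disc$head_w <<- v,
                   function() P$disc$head_w),
               dbw$grads$head_w[1], tolerance = 1e-5)
  eps <- 1e-6
  c2 <- cube; c2[2, 3, 4] <- cube[2, 3, 4] + eps
  fp <- emgan3d:::.disc_fw(c2, P$disc, dcfg, FALSE)$p[1]
  c2[2, 3, 4] <- cube[2, 3, 4] - eps
  fm <- emgan3d:::.disc_fw(c2, P$disc, dcfg, FALSE)$p[1]
  expect_equal((fp - fm) / (2 * eps), dbw$dx[2, 3, 4, 1], tolerance = 1e-5)
})

test_that("checkpoints round-trip parameters and metadata", {
  P <- gan_init(small_gen_cfg(1, 3), small_disc_cfg(3, 3), seed = 13)
  p <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(P, p, epoch = 4L, seed = 13L)
  P2 <- load_checkpoint(p)
  expect_equal(P2$gen, P$gen)
  expect_equal(attr(P2, "epoch"), 4L)
  cube <- array(runif(7^3), c(7, 7, 7))
  expect_identical(generator_forward(cube, P), generator_forward(cube, P2))
  bad <- withr::local_tempfile()
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
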