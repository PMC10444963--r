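# Alternating adversarial training over cube-pair datasets.  Per batch
# the generator takes one Adam step against the content + adversarial
# objective, then the discriminator takes one Adam step on the same
# batch's (simulated, generated) cubes.  Everything stochastic (weight
# init, shuffling, dropout) flows from the single seed in the training
# config, so runs are exactly reproducible.

#' Training configuration
#'
#' Defaults follow the reference training setup: learning rate 0.001
#' for both networks, batch size 16, 100 epochs, Adam (beta1 = 0.9,
#' beta2 = 0.999), adversarial weight 1e-3.
#'
#' @param lr_generator,lr_discriminator Adam learning rates.
#' @param batch_size Cubes per optimization step.
#' @param epochs Number of passes over the training pairs.
#' @param adversarial_weight Weight lambda of the adversarial term.
#' @param seed Integer seed driving all randomness.
#' @param max_steps Optional cap on total generator steps (for
#'   desk-scale runs); `NULL` trains all epochs.
#' @param freeze_discriminator Skip all discriminator updates (with
#'   `adversarial_weight = 0` this is plain supervised regression).
#' @param loss_mode `"linear"` uses the printed linear losses
#'   (adversarial `-D(G(Exp))`, discriminator `(1 - D(x)) + D(G(Exp))`);
#'   `"log"` switches to the standard log-loss GAN objectives.
#' @param content_reduction `"mean"` (mean squared error, default) or
#'   `"sum"` over voxels.
#' @param validate_every Epoch interval for validation passes
#'   (default 1).
#' @param checkpoint_every Epoch interval for writing checkpoints into
#'   `checkpoint_dir` (0 = never).
#' @param checkpoint_dir Directory for periodic checkpoints.
#' @return A list of class `training_config`.
#' @export
training_config <- function(lr_generator = 0.001, lr_discriminator = 0.001,
                            batch_size = 16L, epochs = 100L,
                            adversarial_weight = 1e-3, seed = 1L,
                            max_steps = NULL, freeze_discriminator = FALSE,
                            loss_mode = c("linear", "log"),
                            content_reduction = c("mean", "sum"),
                            validate_every = 1L, checkpoint_every = 0L,
                            checkpoint_dir = NULL) {
  loss_mode <- match.arg(loss_mode)
  content_reduction <- match.arg(content_reduction)
  if (lr_generator <= 0 || lr_discriminator <= 0)
    stop("learning rates must be positive")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (adversarial_weight < 0) stop("`adversarial_weight` must be >= 0")
  structure(list(lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 adversarial_weight = adversarial_weight,
                 seed = as.integer(seed),
                 max_steps = if (is.null(max_steps)) NULL else
                   as.integer(max_steps),
                 freeze_discriminator = isTRUE(freeze_discriminator),
                 loss_mode = loss_mode,
                 content_reduction = content_reduction,
                 validate_every = as.integer(validate_every),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir),
            class = "training_config")
}

#' Split cube pairs into training and validation sets at the map level
#'
#' No cube from one source map ever appears in both partitions.
#'
#' @param pair_groups Named list: one element per source map, each a
#'   list of cube pairs (as produced by [make_pairs()]`$pairs`).
#' @param validation_maps Number of maps held out for validation.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A list with `train` and `validation` (flat lists of pairs)
#'   and `train_maps` / `validation_map_names` name vectors.
#' @export
split_by_map <- function(pair_groups, validation_maps, seed = 1L) {
  if (is.null(names(pair_groups)) || any(!nzchar(names(pair_groups))))
    stop("`pair_groups` must be a named list (one element per map)")
  n_maps <- length(pair_groups)
  if (n_maps < 2L) stop("need at least 2 source maps to split")
  if (validation_maps < 1L || validation_maps >= n_maps)
    stop("`validation_maps` must be in [1, number of maps - 1]")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  val_names <- sample(names(pair_groups), validation_maps)
  tr_names <- setdiff(names(pair_groups), val_names)
  list(train = do.call(c, unname(pair_groups[tr_names])),
       validation = do.call(c, unname(pair_groups[val_names])),
       train_maps = tr_names, validation_map_names = val_names)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# per-voxel gradient of the content loss w.r.t. the generated cube
.content_grad <- function(gen_cube, sim_cube, reduction) {
  g <- 2 * (gen_cube - sim_cube)
  if (reduction == "mean") g / length(gen_cube) else g
}

#' Train the GAN on cube pairs
#'
#' @param pairs List of cube pairs (`exp_cube`, `sim_cube`), e.g. from
#'   [make_pairs()] or [split_by_map()].
#' @param cfg A [training_config].
#' @param gen_cfg,disc_cfg Network configurations; ignored when a warm
#'   start `params` is given.
#' @param val_pairs Optional validation pairs for per-epoch validation.
#' @param params Optional `gan_params` to continue training from.
#' @param verbose Print one line per epoch.
#' @return A list with `params` (trained `gan_params`) and `history`
#'   (data frame: epoch, gen_loss, content_loss, adversarial_loss,
#'   disc_loss, val_cc, val_content).
#' @export
train_gan <- function(pairs, cfg = training_config(),
                      gen_cfg = generator_config(),
                      disc_cfg = discriminator_config(),
                      val_pairs = NULL, params = NULL, verbose = FALSE) {
  if (length(pairs) == 0L) stop("empty training set")
  if (!inherits(cfg, "training_config")) stop("expected `training_config`")
  set.seed(cfg$seed)
  if (is.null(params))
    params <- gan_init(gen_cfg, disc_cfg,
                       adversarial_weight = cfg$adversarial_weight)
  gen_cfg <- params$gen_cfg
  disc_cfg <- params$disc_cfg
  lambda <- cfg$adversarial_weight
  use_disc <- !cfg$freeze_discriminator
  eps <- 1e-8

  opt_g <- .adam_init(params$gen)
  opt_d <- if (use_disc) .adam_init(params$disc) else NULL

  n <- length(pairs)
  hist <- list()
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    ep <- c(gen = 0, content = 0, adv = 0, disc = 0)
    n_batches <- 0L
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      bn <- length(idx)

      # --- generator step -------------------------------------------------
      ggrads <- NULL
      gen_outs <- vector("list", bn)
      b_content <- 0; b_adv <- 0
      for (j in seq_len(bn)) {
        pr <- pairs[[idx[j]]]
        fw <- .gen_fw(pr$exp_cube, params$gen, gen_cfg, training = TRUE)
        gen_outs[[j]] <- fw$out
        cl <- content_loss(pr$sim_cube, fw$out,
                           reduction = cfg$content_reduction)
        dout <- .content_grad(fw$out, pr$sim_cube, cfg$content_reduction)
        adv <- 0
        if (use_disc && lambda > 0) {
          dfw <- .disc_fw(fw$out, params$disc, disc_cfg, training = TRUE)
          p_real <- dfw$p[1]
          if (cfg$loss_mode == "linear") {
            adv <- -p_real
            dLdp <- -lambda
          } else {
            adv <- -log(p_real + eps)
            dLdp <- -lambda / (p_real + eps)
          }
          dbk <- .disc_bw(dLdp, dfw$cache, params$disc)
          dout <- dout + array(dbk$dx, dim(dout))
        }
        bwd <- .gen_bw(dout, fw$cache, params$gen)
        ggrads <- if (is.null(ggrads)) bwd$grads else
          .tree_add(ggrads, bwd$grads)
        b_content <- b_content + cl
        b_adv <- b_adv + adv
      }
      ggrads <- .tree_scale(ggrads, 1 / bn)
      b_content <- b_content / bn
      b_adv <- b_adv / bn
      b_gen <- b_content + lambda * b_adv
      if (!is.finite(b_gen) || !.tree_finite(ggrads))
        stop(sprintf("non-finite generator loss/gradient at epoch %d batch %d",
                     epoch, bi))
      st <- .adam_step(params$gen, ggrads, opt_g, cfg$lr_generator)
      params$gen <- st$params
      opt_g <- st$state

      # --- discriminator step --------------------------------------------
      b_disc <- NA_real_
      if (use_disc) {
        dgrads <- NULL
        b_disc <- 0
        for (j in seq_len(bn)) {
          pr <- pairs[[idx[j]]]
          # real (simulated) branch
          fr <- .disc_fw(pr$sim_cube, params$disc, disc_cfg, training = TRUE)
          # generated branch, detached sample from the pre-update generator
          ff <- .disc_fw(gen_outs[[j]], params$disc, disc_cfg,
                         training = TRUE)
          if (cfg$loss_mode == "linear") {
            loss_d <- (1 - fr$p[1]) + ff$p[1]
            g_real <- .disc_bw(-1, fr$cache, params$disc)$grads
            g_fake <- .disc_bw(1, ff$cache, params$disc)$grads
          } else {
            loss_d <- -log(fr$p[1] + eps) - log(1 - ff$p[1] + eps)
            g_real <- .disc_bw(-1 / (fr$p[1] + eps), fr$cache,
                               params$disc)$grads
            g_fake <- .disc_bw(1 / (1 - ff$p[1] + eps), ff$cache,
                               params$disc)$grads
          }
          gsum <- .tree_add(g_real, g_fake)
          dgrads <- if (is.null(dgrads)) gsum else .tree_add(dgrads, gsum)
          b_disc <- b_disc + loss_d
        }
        dgrads <- .tree_scale(dgrads, 1 / bn)
        b_disc <- b_disc / bn
        if (!is.finite(b_disc) || !.tree_finite(dgrads))
          stop(sprintf(
            "non-finite discriminator loss/gradient at epoch %d batch %d",
            epoch, bi))
        st <- .adam_step(params$disc, dgrads, opt_d, cfg$lr_discriminator)
        params$disc <- st$params
        opt_d <- st$state
      }

      ep <- ep + c(b_gen, b_content, b_adv,
                   if (is.na(b_disc)) 0 else b_disc)
      n_batches <- n_batches + 1L
      step <- step + 1L
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) {
        done <- TRUE
        break
      }
    }
    ep <- ep / n_batches
    val_cc <- NA_real_; val_content <- NA_real_
    if (!is.null(val_pairs) && length(val_pairs) > 0 &&
        (epoch %% max(cfg$validate_every, 1L) == 0L || done ||
         epoch == cfg$epochs)) {
      v <- validate_gan(params, val_pairs)
      val_cc <- v$mean_cc
      val_content <- v$mean_content
    }
    hist[[length(hist) + 1L]] <-
      data.frame(epoch = epoch, gen_loss = ep[1], content_loss = ep[2],
                 adversarial_loss = ep[3],
                 disc_loss = if (use_disc) ep[4] else NA_real_,
                 val_cc = val_cc, val_content = val_content)
    if (verbose)
      message(sprintf(
        "epoch %3d | gen %.5f content %.5f adv %.5f disc %s val_cc %s",
        epoch, ep[1], ep[2], ep[3],
        if (use_disc) sprintf("%.4f", ep[4]) else "-",
        if (is.na(val_cc)) "-" else sprintf("%.4f", val_cc)))
    if (cfg$checkpoint_every > 0L && !is.null(cfg$checkpoint_dir) &&
        epoch %% cfg$checkpoint_every == 0L) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(params,
                      file.path(cfg$checkpoint_dir,
                                sprintf("epoch_%04d.ckpt", epoch)),
                      epoch = epoch, seed = cfg$seed)
    }
    if (done) break
  }
  list(params = params, history = do.call(rbind, hist))
}

#' Validate a generator on held-out cube pairs
#'
#' Runs the generator in inference mode (no dropout) and reports the
#' mean Pearson cross-correlation between generated and simulated cubes
#' and the mean content loss.  Cubes for which the correlation is
#' undefined (constant generated or target cube) are skipped.
#'
#' @param params A `gan_params` object.
#' @param pairs Non-empty list of cube pairs.
#' @return A list with `mean_cc`, `mean_content` and `n`.
#' @export
validate_gan <- function(params, pairs) {
  if (length(pairs) == 0L) stop("empty validation set")
  ccs <- numeric(0)
  cls <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    out <- generator_forward(pr$exp_cube, params, training = FALSE)
    cls[i] <- content_loss(pr$sim_cube, out)
    cc <- tryCatch(cross_correlation(out, pr$sim_cube),
                   error = function(e) NA_real_)
    if (!is.na(cc)) ccs <- c(ccs, cc)
  }
  list(mean_cc = if (length(ccs)) mean(ccs) else NA_real_,
       mean_content = mean(cls), n = length(pairs))
}

#' Save a parameter checkpoint
#'
#' Checkpoints are RDS containers holding the parameter trees, both
#' network configurations, the adversarial weight and provenance
#' metadata (epoch, seed, package version).
#'
#' @param params A `gan_params` object.
#' @param path Output file path.
#' @param epoch,seed Optional provenance metadata.
#' @param history Optional training history to embed.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(params, path, epoch = NA_integer_,
                            seed = NA_integer_, history = NULL) {
  if (!inherits(params, "gan_params")) stop("expected `gan_params`")
  saveRDS(list(format = "emgan3d-checkpoint-v1", params = params,
               epoch = epoch, seed = seed, history = history,
               package_version = as.character(utils::packageVersion("emgan3d"))),
          path)
  invisible(path)
}

#' Load a parameter checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The `gan_params` object, with metadata in attributes
#'   `epoch`, `seed` and `history`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "emgan3d-checkpoint-v1") ||
      !inherits(obj$params, "gan_params"))
    stop("not an emgan3d checkpoint: ", path)
  params <- obj$params
  attr(params, "epoch") <- obj$epoch
  attr(params, "seed") <- obj$seed
  attr(params, "history") <- obj$history
  params
}

#' Desk-scale learning-rate search harness
#'
#' Trains one small model per candidate learning rate (same rate for
#' generator and discriminator) and reports the final validation
#' cross-correlation.  Mirrors a grid search over
#' `{0.01, 0.001, 0.005, 0.0001}`; not run by default anywhere.
#'
#' @param pairs,val_pairs Training and validation cube pairs.
#' @param learning_rates Candidate rates.
#' @param cfg Base [training_config]; its learning rates are overridden.
#' @param gen_cfg,disc_cfg Network configurations.
#' @return A data frame with one row per learning rate.
#' @export
lr_search <- function(pairs, val_pairs,
                      learning_rates = c(0.01, 0.001, 0.005, 0.0001),
                      cfg = training_config(), gen_cfg = generator_config(),
                      disc_cfg = discriminator_config()) {
  rows <- lapply(learning_rates, function(lr) {
    cfg$lr_generator <- lr
    cfg$lr_discriminator <- lr
    fit <- train_gan(pairs, cfg, gen_cfg, disc_cfg, val_pairs = val_pairs)
    last <- fit$history[nrow(fit$history), ]
    data.frame(learning_rate = lr, val_cc = last$val_cc,
               val_content = last$val_content,
               final_gen_loss = last$gen_loss)
  })
  do.call(rbind, rows)
}
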