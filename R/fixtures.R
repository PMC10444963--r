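# Synthetic toy protein-like structures and paired low/high-resolution
# simulated maps.  These stand in for the experimental/simulated map
# corpus: the "experimental" member of a pair is a lower-resolution
# simulation with additive Gaussian voxel noise, re-normalized -- same
# underlying structure, degraded detail -- on the identical grid frame
# as the high-resolution target.

#' Specification of a synthetic fixture dataset
#'
#' @param n_structures Number of toy structures (default 20).
#' @param residues_range Inclusive range of per-structure residue
#'   counts, sampled uniformly (default 30--80).
#' @param motif_mix Named fractions for helix/strand/coil; must sum
#'   to 1 (default 0.4/0.3/0.3).
#' @param low_resolution Resolution of the degraded input map in
#'   Angstrom (default 5.0).
#' @param high_resolution Resolution of the target map in Angstrom
#'   (default 2.0); must be better (smaller) than `low_resolution`.
#' @param noise_sd SD of Gaussian voxel noise added to the normalized
#'   low-resolution map (default 0.05).
#' @param voxel_spacing Grid spacing in Angstrom (default 1.0).
#' @param cube_size,stride Cube-pipeline parameters (defaults 25, 4).
#' @param seed Integer master seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_structures = 20L, residues_range = c(30L, 80L),
                         motif_mix = c(helix = 0.4, strand = 0.3,
                                       coil = 0.3),
                         low_resolution = 5.0, high_resolution = 2.0,
                         noise_sd = 0.05, voxel_spacing = 1.0,
                         cube_size = 25L, stride = 4L, seed = 1L) {
  if (n_structures < 1L) stop("`n_structures` must be >= 1")
  if (length(residues_range) != 2L || residues_range[1] < 2L ||
      residues_range[2] < residues_range[1])
    stop("`residues_range` must be an increasing pair >= 2")
  if (abs(sum(motif_mix) - 1) > 1e-9) stop("`motif_mix` must sum to 1")
  if (!all(names(motif_mix) %in% c("helix", "strand", "coil")))
    stop("`motif_mix` names must be helix/strand/coil")
  if (low_resolution <= high_resolution)
    stop("`low_resolution` must be worse (larger) than `high_resolution`")
  if (high_resolution <= 0) stop("resolutions must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(n_structures = as.integer(n_structures),
                 residues_range = as.integer(residues_range),
                 motif_mix = motif_mix,
                 low_resolution = low_resolution,
                 high_resolution = high_resolution,
                 noise_sd = noise_sd, voxel_spacing = voxel_spacing,
                 cube_size = as.integer(cube_size),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a toy protein-like structure
#'
#' Backbone-like point chains with ideal geometry: helices rise 1.5
#' Angstrom per residue turning 100 degrees about the axis at radius
#' 2.3; strands rise 3.3 per residue with an alternating lateral
#' offset; coils are self-avoiding random walks with 3.8 Angstrom steps
#' (non-consecutive residues kept >= 2 Angstrom apart).  Each residue
#' carries one "CA" atom plus 1--3 pseudo-sidechain atoms.
#'
#' @param kind `"helix"`, `"strand"`, `"coil"` or `"mixed"` (random
#'   segments of the three).
#' @param n_residues Number of residues (>= 2).
#' @param seed Integer seed; identical seeds give identical
#'   coordinates.
#' @return An [atom_model] with one chain `"A"`.
#' @export
make_toy_structure <- function(kind = c("helix", "strand", "coil", "mixed"),
                               n_residues, seed = 1L) {
  kind <- match.arg(kind)
  if (n_residues < 2L) stop("`n_residues` must be >= 2")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  ca <- switch(kind,
    helix = .helix_trace(n_residues),
    strand = .strand_trace(n_residues),
    coil = .coil_trace(n_residues),
    mixed = .mixed_trace(n_residues))
  # pseudo-sidechain atoms: 1-3 per residue, 1.5 A bonds in random
  # directions away from the backbone
  rows <- list()
  for (i in seq_len(n_residues)) {
    rows[[length(rows) + 1L]] <-
      c(ca[i, ], i, 1)  # CA marker
    n_side <- sample(1:3, 1L)
    for (s in seq_len(n_side)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      rows[[length(rows) + 1L]] <- c(ca[i, ] + 1.5 * u, i, 0)
    }
  }
  m <- do.call(rbind, rows)
  is_ca <- m[, 5] == 1
  atom_model(element = ifelse(is_ca, "C", "C"),
             chain = "A", resi = m[, 4],
             resname = switch(kind, helix = "ALA", strand = "VAL",
                              coil = "GLY", mixed = "ALA"),
             x = m[, 1], y = m[, 2], z = m[, 3],
             atom_name = ifelse(is_ca, "CA", "CB"))
}

.helix_trace <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  i <- seq_len(n) - 1
  ang <- i * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), i * rise)
}

.strand_trace <- function(n, rise = 3.3, lateral = 0.9) {
  i <- seq_len(n) - 1
  cbind(lateral * (-1)^i, rep(0, n), i * rise)
}

.coil_trace <- function(n, step = 3.8, min_sep = 2.0) {
  pts <- matrix(0, n, 3)
  for (i in 2:n) {
    placed <- FALSE
    for (attempt in 1:200) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- pts[i - 1, ] + step * u
      prev <- pts[seq_len(max(i - 2, 1)), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (all(d2 >= min_sep^2)) {
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("self-avoiding walk failed after 200 attempts")
  }
  pts
}

.mixed_trace <- function(n) {
  pts <- NULL
  left <- n
  while (left > 0) {
    seg <- min(left, sample(5:15, 1L))
    kind <- sample(c("helix", "strand", "coil"), 1L)
    tr <- switch(kind, helix = .helix_trace(seg),
                 strand = .strand_trace(seg), coil = .coil_trace(max(seg, 2)))
    tr <- tr[seq_len(seg), , drop = FALSE]
    # random rotation, then translate to continue from the last point
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    tr <- tr %*% R
    if (!is.null(pts)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      shift <- pts[nrow(pts), ] + 3.8 * u - tr[1, ]
      tr <- sweep(tr, 2, shift, `+`)
    }
    pts <- rbind(pts, tr)
    left <- left - seg
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Build a paired low/high-resolution training map pair
#'
#' The high-resolution member is a simulation at
#' `spec$high_resolution`; the low-resolution member is a simulation of
#' the same model at `spec$low_resolution` on the identical grid, plus
#' seeded Gaussian voxel noise (`spec$noise_sd`), re-normalized to
#' `[0, 1]`.
#'
#' @param model An [atom_model].
#' @param spec A [fixture_spec].
#' @param seed Seed for the noise draw (default `spec$seed`).
#' @return A list with `low` and `high` [density_map]s on the same
#'   frame.
#' @export
make_training_pair <- function(model, spec, seed = spec$seed) {
  if (!inherits(spec, "fixture_spec")) stop("expected a `fixture_spec`")
  high_cfg <- simulation_config(spec$high_resolution,
                                voxel_spacing = spec$voxel_spacing)
  low_cfg <- simulation_config(spec$low_resolution,
                               voxel_spacing = spec$voxel_spacing)
  high <- simulate_map(model, high_cfg)
  low <- simulate_map(model, low_cfg, grid = high)
  if (spec$noise_sd > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
    low$data <- low$data + rnorm(length(low$data), sd = spec$noise_sd)
    low <- normalize_density(low)
  }
  list(low = low, high = high)
}

#' Generate a full synthetic fixture dataset
#'
#' Draws `spec$n_structures` independent toy structures (kinds sampled
#' from `spec$motif_mix`, residue counts from `spec$residues_range`),
#' builds their map pairs and extracts valid cube pairs.  Fully
#' deterministic under `spec$seed`.
#'
#' @param spec A [fixture_spec].
#' @return A list with `structures` (each: `model`, `low`, `high`,
#'   `pairs`, `kind`, `n_residues`, `seed`) and `manifest` (data frame
#'   with per-structure metadata and cube counts).
#' @export
make_fixture_dataset <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) stop("expected a `fixture_spec`")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  kinds <- sample(names(spec$motif_mix), spec$n_structures, replace = TRUE,
                  prob = spec$motif_mix)
  res_vals <- seq(spec$residues_range[1], spec$residues_range[2])
  n_res <- res_vals[sample.int(length(res_vals), spec$n_structures,
                               replace = TRUE)]
  seeds <- sample.int(.Machine$integer.max %/% 2L, spec$n_structures)
  structures <- vector("list", spec$n_structures)
  for (i in seq_len(spec$n_structures)) {
    model <- make_toy_structure(kinds[i], n_res[i], seed = seeds[i])
    pair <- make_training_pair(model, spec, seed = seeds[i] + 1L)
    mp <- make_pairs(pair$low, pair$high, spec$cube_size, spec$stride)
    structures[[i]] <- list(model = model, low = pair$low,
                            high = pair$high, pairs = mp$pairs,
                            grid = mp$grid, kind = kinds[i],
                            n_residues = n_res[i], seed = seeds[i])
  }
  names(structures) <- sprintf("toy%03d", seq_len(spec$n_structures))
  manifest <- data.frame(name = names(structures), kind = kinds,
                         n_residues = n_res, seed = seeds,
                         n_cubes = vapply(structures,
                                          function(s) length(s$pairs),
                                          integer(1)),
                         stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  list(structures = structures, manifest = manifest, spec = spec)
}

#' Flatten a fixture dataset into per-map cube-pair groups
#'
#' Convenience for [split_by_map()].
#'
#' @param dataset Result of [make_fixture_dataset()].
#' @return Named list of cube-pair lists, one element per structure.
#' @export
fixture_pair_groups <- function(dataset) {
  lapply(dataset$structures, function(s) s$pairs)
}
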