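# Map-change metrics: cube-level cross-correlation, map-level
# improvement fractions, and a per-residue real-space correlation
# (RSCC-like) profile computed against a model-derived reference map.

#' Cross-correlation between two density arrays
#'
#' With `about_mean = TRUE` (default) this is the Pearson correlation
#' over voxels; with `about_mean = FALSE` it is the about-zero form
#' `sum(a*b) / (||a|| * ||b||)`.
#'
#' @param a,b Equal-shaped numeric arrays.
#' @param about_mean Subtract means first (default `TRUE`).
#' @return A scalar in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b, about_mean = TRUE) {
  if (!all(dim(a) == dim(b)) || length(a) != length(b))
    stop("`a` and `b` must have identical shape")
  a <- as.numeric(a); b <- as.numeric(b)
  if (about_mean) {
    a <- a - mean(a); b <- b - mean(b)
    na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
    if (na == 0 || nb == 0)
      stop("undefined correlation: constant input with about_mean = TRUE")
    sum(a * b) / (na * nb)
  } else {
    na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
    if (na == 0 || nb == 0)
      stop("undefined correlation: zero-norm input with about_mean = FALSE")
    sum(a * b) / (na * nb)
  }
}

#' Cube-level improvement of a modified map
#'
#' Decomposes all three maps with the same sliding-cube grid, keeps the
#' valid cubes (neither the experimental nor the simulated cube all
#' zeros), and compares `CC(mod, sim)` against `CC(exp, sim)` per cube.
#' Cubes where either correlation is undefined (constant arrays) are
#' skipped and counted in `n_skipped`.
#'
#' @param exp,mod,sim Three [density_map]s on a shared grid frame.
#' @param cube_size,stride Cube grid parameters (defaults 25 and 4).
#' @param about_mean Correlation convention, see [cross_correlation()].
#' @return A list with `fraction_improved` (CC improved or equal),
#'   `mean_cc_exp_sim`, `mean_cc_mod_sim`, `n_cubes`, `n_skipped`.
#' @export
cubewise_improvement <- function(exp, mod, sim, cube_size = 25L,
                                 stride = 4L, about_mean = TRUE) {
  .assert_map(exp); .assert_map(mod); .assert_map(sim)
  shapes <- list(dim(exp$data), dim(mod$data), dim(sim$data))
  if (!all(vapply(shapes, function(s) all(s == shapes[[1]]), logical(1))))
    stop("frame mismatch: shapes ",
         paste(vapply(shapes, paste, "", collapse = "x"), collapse = " / "))
  ce <- extract_cubes(exp, cube_size, stride)
  cm <- extract_cubes(mod, cube_size, stride)
  cs <- extract_cubes(sim, cube_size, stride)
  cc_e <- cc_m <- numeric(0)
  n_skip <- 0L
  for (i in seq_along(ce$cubes)) {
    if (!any(ce$cubes[[i]] != 0) || !any(cs$cubes[[i]] != 0)) next
    ei <- tryCatch(cross_correlation(ce$cubes[[i]], cs$cubes[[i]],
                                     about_mean), error = function(e) NA)
    mi <- tryCatch(cross_correlation(cm$cubes[[i]], cs$cubes[[i]],
                                     about_mean), error = function(e) NA)
    if (is.na(ei) || is.na(mi)) { n_skip <- n_skip + 1L; next }
    cc_e <- c(cc_e, ei); cc_m <- c(cc_m, mi)
  }
  if (length(cc_e) == 0L) stop("no scorable cubes")
  list(fraction_improved = mean(cc_m >= cc_e - 1e-12),
       mean_cc_exp_sim = mean(cc_e),
       mean_cc_mod_sim = mean(cc_m),
       n_cubes = length(cc_e), n_skipped = n_skip)
}

#' Per-residue real-space correlation profile
#'
#' Computes an RSCC-like score: a reference map is simulated from the
#' model on the input map's own grid (via [simulate_map()] at
#' `sim_cfg$resolution`), and for every residue the Pearson correlation
#' between map and reference is taken over the voxels within
#' `mask_radius` of any of that residue's atoms.  Residues whose mask
#' is empty (or constant density) are skipped with a warning.
#'
#' @param map A [density_map].
#' @param model An [atom_model].
#' @param sim_cfg A [simulation_config] for the reference map.
#' @param mask_radius Mask radius around atoms in Angstrom
#'   (default 2.5).
#' @return A data frame of class `rscc_profile` with columns `chain`,
#'   `resi`, `icode`, `resname`, `rscc`, `n_voxels`, plus attribute
#'   `mean_rscc`.
#' @export
rscc_per_residue <- function(map, model, sim_cfg, mask_radius = 2.5) {
  .assert_map(map)
  if (!is_atom_model(model)) stop("expected an `atom_model`")
  ref <- simulate_map(model, sim_cfg, grid = map)
  d <- dim(map$data)
  key <- paste(model$chain, model$resi, model$icode, sep = "\r")
  res_keys <- unique(key)
  rows <- list()
  skipped <- character(0)
  for (rk in res_keys) {
    sel <- which(key == rk)
    vox <- .mask_voxels(model[sel, , drop = FALSE], map, mask_radius)
    if (length(vox) < 2L) {
      skipped <- c(skipped, rk)
      next
    }
    mv <- map$data[vox]; rv <- ref$data[vox]
    if (sd(mv) == 0 || sd(rv) == 0) {
      skipped <- c(skipped, rk)
      next
    }
    r <- sum((mv - mean(mv)) * (rv - mean(rv))) /
      (sqrt(sum((mv - mean(mv))^2)) * sqrt(sum((rv - mean(rv))^2)))
    a1 <- sel[1]
    rows[[length(rows) + 1L]] <-
      data.frame(chain = model$chain[a1], resi = model$resi[a1],
                 icode = model$icode[a1], resname = model$resname[a1],
                 rscc = r, n_voxels = length(vox),
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("empty density mask for every residue: model outside the map?")
  if (length(skipped) > 0L)
    warning(length(skipped), " residue(s) skipped (empty or constant mask)")
  out <- do.call(rbind, rows)
  class(out) <- c("rscc_profile", "data.frame")
  attr(out, "mean_rscc") <- mean(out$rscc)
  out
}

# linear voxel indices of the map within `radius` of any atom in `sub`
.mask_voxels <- function(sub, map, radius) {
  d <- dim(map$data)
  vox <- map$voxel_size
  org <- map$origin
  idx <- integer(0)
  for (a in seq_len(nrow(sub))) {
    p <- c(sub$x[a], sub$y[a], sub$z[a])
    lo <- pmax(as.integer(ceiling((p - radius - org) / vox)) + 1L, 1L)
    hi <- pmin(as.integer(floor((p + radius - org) / vox)) + 1L, d)
    if (any(lo > hi)) next
    xs <- org[1] + (seq(lo[1], hi[1]) - 1) * vox[1] - p[1]
    ys <- org[2] + (seq(lo[2], hi[2]) - 1) * vox[2] - p[2]
    zs <- org[3] + (seq(lo[3], hi[3]) - 1) * vox[3] - p[3]
    r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
    sel <- which(r2 <= radius^2)
    if (length(sel) == 0L) next
    ar <- arrayInd(sel, dim(r2))
    lin <- (lo[1] - 1L + ar[, 1]) +
      (lo[2] - 2L + ar[, 2]) * d[1] +
      (lo[3] - 2L + ar[, 3]) * d[1] * d[2]
    idx <- c(idx, lin)
  }
  unique(idx)
}

#' Compare two RSCC profiles residue by residue
#'
#' Aligns profiles by (chain, residue index, insertion code) and
#' reports per-residue deltas and summary statistics.
#'
#' @param profile_a Baseline profile (e.g. experimental map).
#' @param profile_b Comparison profile (e.g. modified map).
#' @return A list with `deltas` (data frame with `delta_rscc`),
#'   `fraction_improved` (delta >= 0), `mean_before`, `mean_after`.
#' @export
improvement_report <- function(profile_a, profile_b) {
  ka <- paste(profile_a$chain, profile_a$resi, profile_a$icode, sep = "\r")
  kb <- paste(profile_b$chain, profile_b$resi, profile_b$icode, sep = "\r")
  if (!setequal(ka, kb)) {
    miss <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("residue key mismatch between profiles: ",
         paste(gsub("\r", "/", utils::head(miss, 10L)), collapse = ", "))
  }
  ord <- match(ka, kb)
  deltas <- data.frame(chain = profile_a$chain, resi = profile_a$resi,
                       icode = profile_a$icode,
                       resname = profile_a$resname,
                       rscc_before = profile_a$rscc,
                       rscc_after = profile_b$rscc[ord],
                       stringsAsFactors = FALSE)
  deltas$delta_rscc <- deltas$rscc_after - deltas$rscc_before
  list(deltas = deltas,
       fraction_improved = mean(deltas$delta_rscc >= -1e-12),
       mean_before = mean(deltas$rscc_before),
       mean_after = mean(deltas$rscc_after))
}

#' Write an RSCC profile as TSV or JSON
#'
#' @param profile An `rscc_profile` from [rscc_per_residue()].
#' @param path Output path; format chosen by extension (`.json` for
#'   JSON, anything else TSV).
#' @return Invisibly, `path`.
#' @export
write_rscc_profile <- function(profile, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(mean_rscc = attr(profile, "mean_rscc"),
           residues = as.data.frame(profile)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(profile), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
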