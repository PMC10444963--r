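# End-to-end map enhancement: resample -> normalize -> cubes ->
# generator -> overlap-averaged merge.

#' Enhance a density map with a trained generator
#'
#' Pipeline: [resample_to_unit_grid()] (target spacing
#' `target_spacing`), [normalize_density()], [extract_cubes()],
#' [generator_forward()] per cube in inference mode, and
#' [merge_cubes()] with overlap averaging.  Deterministic for a fixed
#' checkpoint.
#'
#' @param map Input [density_map] (experimental map).
#' @param params A `gan_params` object or a checkpoint path.
#' @param cube_size Cube edge in voxels (default 25).
#' @param stride Inference stride in voxels (default 4; a denser stride
#'   is allowed, overlaps are averaged).
#' @param target_spacing Grid spacing the map is resampled to before
#'   cubing (default 1.0 Angstrom).
#' @return The modified [density_map] (values in `[0, 1]`, same frame
#'   as the normalized resampled input).
#' @export
enhance_map <- function(map, params, cube_size = 25L, stride = 4L,
                        target_spacing = 1.0) {
  .assert_map(map)
  if (is.character(params)) params <- load_checkpoint(params)
  if (!inherits(params, "gan_params")) stop("expected `gan_params`")
  prep <- normalize_density(resample_to_unit_grid(map, target_spacing))
  ex <- extract_cubes(prep, cube_size, stride)
  out_cubes <- lapply(ex$cubes, function(cb)
    generator_forward(cb, params, training = FALSE))
  out <- merge_cubes(ex$grid, out_cubes)
  out$label <- "emgan3d enhanced"
  out
}
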