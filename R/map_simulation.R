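# Simulated density maps from atomic models (the pdb2vol role): each
# atom contributes an isotropic Gaussian whose FWHM equals the nominal
# resolution, truncated at a fixed number of sigma.

#' Construct an atomic model
#'
#' An `atom_model` is an ordered table of atoms with element symbol,
#' chain id, residue index, insertion code, residue name, Cartesian
#' position (Angstrom) and a positive per-atom weight.
#'
#' @param element Character vector of element symbols.
#' @param chain Character vector of chain identifiers.
#' @param resi Integer vector of residue sequence numbers.
#' @param resname Character vector of residue names.
#' @param x,y,z Numeric coordinate vectors in Angstrom.
#' @param icode Insertion codes (default `""`).
#' @param weight Positive per-atom weights (default 1.0).
#' @param atom_name Atom names (default the element symbol).
#' @return A data frame of class `atom_model`.
#' @export
atom_model <- function(element, chain, resi, resname, x, y, z,
                       icode = "", weight = 1.0, atom_name = element) {
  n <- length(x)
  df <- data.frame(element = toupper(as.character(element)),
                   chain = as.character(chain),
                   resi = as.integer(resi),
                   icode = rep_len(as.character(icode), n),
                   resname = as.character(resname),
                   atom_name = rep_len(as.character(atom_name), n),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   weight = rep_len(as.numeric(weight), n),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("atom model must contain at least one atom")
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("all atom positions must be finite")
  if (any(!is.finite(df$weight) | df$weight <= 0))
    stop("all atom weights must be positive")
  class(df) <- c("atom_model", "data.frame")
  df
}

#' Test for atom model objects
#' @param x Object to test.
#' @return `TRUE` if `x` is an `atom_model`.
#' @export
is_atom_model <- function(x) inherits(x, "atom_model")

# small element -> atomic number table for the Z weighting scheme
.atomic_numbers <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                     MG = 12, `NA` = 11, K = 19, CA = 20, FE = 26, ZN = 30,
                     MN = 25, CL = 17, CU = 29, SE = 34)

#' Read an atomic model from a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records.  Alternate locations
#' keep the highest-occupancy conformer per atom; insertion codes are
#' honored as part of the residue key; waters (`HOH`/`WAT`/`DOD`) are
#' excluded by default.
#'
#' @param path Path to a PDB file.
#' @param include_het Keep `HETATM` records (default `TRUE`).
#' @param exclude_waters Drop water residues (default `TRUE`).
#' @return An [atom_model].
#' @export
read_pdb <- function(path, include_het = TRUE, exclude_waters = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (include_het & rec == "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path)
  fx <- function(a, b) substr(lines, a, b)
  name <- trimws(fx(13, 16))
  altloc <- fx(17, 17)
  resname <- trimws(fx(18, 20))
  chain <- fx(22, 22)
  resi <- suppressWarnings(as.integer(fx(23, 26)))
  icode <- trimws(fx(27, 27))
  x <- as.numeric(fx(31, 38)); y <- as.numeric(fx(39, 46))
  z <- as.numeric(fx(47, 54))
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1.0
  elem <- toupper(trimws(fx(77, 78)))
  # fall back to the first letter of the atom name when the element
  # column is absent (old-style files)
  elem[elem == ""] <- toupper(substr(gsub("^[0-9]", "", name[elem == ""]), 1, 1))
  bad <- is.na(x) | is.na(y) | is.na(z) | is.na(resi)
  if (any(bad)) stop("malformed coordinate records in ", path)
  df <- data.frame(element = elem, chain = chain, resi = resi, icode = icode,
                   resname = resname, atom_name = name,
                   x = x, y = y, z = z, altloc = altloc, occ = occ,
                   stringsAsFactors = FALSE)
  if (exclude_waters) df <- df[!df$resname %in% c("HOH", "WAT", "DOD"), ]
  if (nrow(df) == 0L) stop("no atoms left after filtering in ", path)
  # altloc: keep highest occupancy per (chain, resi, icode, atom name)
  if (any(df$altloc != " ")) {
    key <- paste(df$chain, df$resi, df$icode, df$atom_name, sep = "\r")
    ord <- order(key, -df$occ)
    df <- df[ord, ][!duplicated(key[ord]), ]
    df <- df[order(as.integer(rownames(df))), ]
  }
  atom_model(df$element, df$chain, df$resi, df$resname, df$x, df$y, df$z,
             icode = df$icode, atom_name = df$atom_name)
}

#' Write an atomic model as a PDB file
#'
#' Minimal PDB writer used mainly to export synthetic toy structures.
#'
#' @param model An [atom_model].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  if (!is_atom_model(model)) stop("expected an `atom_model`")
  n <- nrow(model)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n) %% 100000L,
    substr(sprintf(" %-3s", model$atom_name), 1, 4), " ",
    substr(model$resname, 1, 3), substr(model$chain, 1, 1),
    model$resi %% 10000L, substr(paste0(model$icode, " "), 1, 1),
    model$x, model$y, model$z, 1.0, 0.0, substr(model$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Configuration for map simulation
#'
#' @param resolution Nominal resolution in Angstrom; the Gaussian kernel
#'   FWHM equals this value, i.e. `sigma = resolution / (2*sqrt(2*ln 2))`.
#' @param voxel_spacing Grid spacing in Angstrom (default 1.0).
#' @param padding Padding around the model bounding box in Angstrom
#'   (default 5.0).
#' @param kernel_truncation Kernel cutoff in multiples of sigma
#'   (default 3.0, minimum 2).
#' @param weight_scheme `"unit"` (all atoms weight 1) or
#'   `"atomic-number"` (weight = element Z).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(resolution, voxel_spacing = 1.0, padding = 5.0,
                              kernel_truncation = 3.0,
                              weight_scheme = c("unit", "atomic-number")) {
  weight_scheme <- match.arg(weight_scheme)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number")
  if (voxel_spacing <= 0) stop("`voxel_spacing` must be positive")
  if (padding < 0) stop("`padding` must be non-negative")
  if (kernel_truncation < 2) stop("`kernel_truncation` must be >= 2")
  structure(list(resolution = resolution, voxel_spacing = voxel_spacing,
                 padding = padding, kernel_truncation = kernel_truncation,
                 weight_scheme = weight_scheme),
            class = "simulation_config")
}

#' Simulate a density map from an atomic model
#'
#' Each atom contributes an isotropic 3-D Gaussian of weight `w`
#' centered at its position, with `sigma = resolution / (2*sqrt(2*ln2))`
#' (kernel FWHM = nominal resolution), truncated at
#' `kernel_truncation * sigma`.  Contributions are summed on a grid
#' covering the model bounding box plus `padding`, then min-max
#' normalized to `[0, 1]` (unless `normalize = FALSE`).
#'
#' @param model An [atom_model].
#' @param cfg A [simulation_config].
#' @param grid Optional [density_map] whose frame (dims, spacing,
#'   origin) the simulation should use instead of the model bounding
#'   box; used to score a model against an existing map.
#' @param normalize Min-max normalize the result (default `TRUE`).
#' @return A [density_map].
#' @export
simulate_map <- function(model, cfg, grid = NULL, normalize = TRUE) {
  if (!is_atom_model(model)) stop("expected an `atom_model`")
  if (!inherits(cfg, "simulation_config"))
    stop("expected a `simulation_config`")
  sigma <- cfg$resolution / (2 * sqrt(2 * log(2)))
  cut <- cfg$kernel_truncation * sigma
  w <- if (cfg$weight_scheme == "unit") rep(1, nrow(model)) else {
    z <- .atomic_numbers[model$element]
    z[is.na(z)] <- 6  # unknown elements behave like carbon
    as.numeric(z)
  }

  if (is.null(grid)) {
    h <- cfg$voxel_spacing
    lo <- c(min(model$x), min(model$y), min(model$z)) - cfg$padding
    hi <- c(max(model$x), max(model$y), max(model$z)) + cfg$padding
    nd <- as.integer(ceiling((hi - lo) / h)) + 1L
    origin <- lo
    vox <- rep(h, 3)
  } else {
    .assert_map(grid)
    nd <- dim(grid$data)
    origin <- grid$origin
    vox <- grid$voxel_size
  }

  acc <- array(0, nd)
  inv2s2 <- 1 / (2 * sigma^2)
  for (a in seq_len(nrow(model))) {
    p <- c(model$x[a], model$y[a], model$z[a])
    i_lo <- pmax(as.integer(ceiling((p - cut - origin) / vox)) + 1L, 1L)
    i_hi <- pmin(as.integer(floor((p + cut - origin) / vox)) + 1L, nd)
    if (any(i_lo > i_hi)) next
    xs <- origin[1] + (seq(i_lo[1], i_hi[1]) - 1) * vox[1] - p[1]
    ys <- origin[2] + (seq(i_lo[2], i_hi[2]) - 1) * vox[2] - p[2]
    zs <- origin[3] + (seq(i_lo[3], i_hi[3]) - 1) * vox[3] - p[3]
    gx <- exp(-xs^2 * inv2s2); gy <- exp(-ys^2 * inv2s2)
    gz <- exp(-zs^2 * inv2s2)
    blk <- outer(outer(gx, gy), gz)
    # zero beyond the spherical truncation radius
    r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
    blk[r2 > cut^2] <- 0
    acc[i_lo[1]:i_hi[1], i_lo[2]:i_hi[2], i_lo[3]:i_hi[3]] <-
      acc[i_lo[1]:i_hi[1], i_lo[2]:i_hi[2], i_lo[3]:i_hi[3]] + w[a] * blk
  }
  out <- density_map(acc, voxel_size = vox, origin = origin,
                     label = sprintf("simulated at %.2f A", cfg$resolution))
  if (normalize) out <- normalize_density(out)
  out
}

#' Target simulated-map resolution for an experimental map
#'
#' Maps an experimental resolution to the resolution at which the
#' high-resolution simulated target map is generated: 1.8 Angstrom for
#' experimental maps in `[3.0, 3.5)` and 3.0 Angstrom for `[3.5, 6.0]`.
#' The 3.5 boundary is assigned to the 3.0-Angstrom branch.  Inputs
#' outside `[3.0, 6.0]` produce a warning and use the nearest branch.
#'
#' @param experimental_resolution Resolution of the experimental map in
#'   Angstrom; must be positive.
#' @return Target simulation resolution in Angstrom (1.8 or 3.0).
#' @examples
#' target_resolution_for(3.2)  # 1.8
#' target_resolution_for(4.4)  # 3.0
#' @export
target_resolution_for <- function(experimental_resolution) {
  r <- experimental_resolution
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`experimental_resolution` must be a single positive number")
  if (r < 3.0 || r > 6.0)
    warning("experimental resolution ", r,
            " A is outside the supported range [3.0, 6.0]")
  if (r < 3.5) 1.8 else 3.0
}
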