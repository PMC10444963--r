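test_that("PDB write/read round-trips a toy model", {
  m <- make_toy_structure("helix", 8, seed = 5)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, p)
  m2 <- read_pdb(p)
  expect_equal(nrow(m2), nrow(m))
  expect_lt(max(abs(m2$x - m$x)), 1e-3)  # %8.3f columns
  expect_lt(max(abs(m2$z - m$z)), 1e-3)
  expect_equal(m2$resi, m$resi)
  expect_equal(m2$chain, m$chain)
})

test_that("read_pdb handles altlocs, waters and HETATM", {
  fmt <- paste0("%-6s%5d %-4s%1s%3s %1s%4d%1s   ",
                "%8.3f%8.3f%8.3f%6.2f%6.2f          %2s")
  lines <- c(
    sprintf(fmt, "ATOM", 1L, " CA", "A", "ALA", "A", 1L, " ",
            1, 0, 0, 0.40, 10, " C"),
    sprintf(fmt, "ATOM", 2L, " CA", "B", "ALA", "A", 1L, " ",
            2, 0, 0, 0.60, 10, " C"),
    sprintf(fmt, "HETATM", 3L, "MG", " ", " MG", "A", 2L, " ",
            5, 5, 5, 1.00, 10, "MG"),
    sprintf(fmt, "HETATM", 4L, " O", " ", "HOH", "A", 3L, " ",
            9, 9, 9, 1.00, 10, " O"),
    "END")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, p)
  m <- read_pdb(p)
  expect_equal(nrow(m), 2L)               # water dropped, altloc B kept
  expect_equal(m$x[m$resi == 1], 2.0)     # highest occupancy wins
  expect_equal(m$element[m$resi == 2], "MG")
  m_now <- read_pdb(p, include_het = FALSE)
  expect_equal(nrow(m_now), 1L)
})

test_that("single-atom map peaks at the atom and is symmetric", {
  # atom exactly on a grid node: bounding box [0,0,0], padding 5 A
  m <- atom_model("C", "A", 1, "ALA", 0, 0, 0)
  cfg <- simulation_config(resolution = 1.5 * 2 * sqrt(2 * log(2)),
                           voxel_spacing = 1.0, padding = 5.0)
  dm <- simulate_map(m, cfg, normalize = FALSE)
  peak <- which(dm$data == max(dm$data), arr.ind = TRUE)
  ctr <- as.integer(-dm$origin) + 1L      # voxel at physical (0,0,0)
  expect_equal(unname(peak[1, ]), ctr)
  # spherical symmetry under axis permutations about the peak
  expect_equal(dm$data[ctr[1] + 1, ctr[2], ctr[3]],
               dm$data[ctr[1], ctr[2] + 1, ctr[3]], tolerance = 1e-12)
  expect_equal(dm$data[ctr[1], ctr[2] + 1, ctr[3]],
               dm$data[ctr[1], ctr[2], ctr[3] + 1], tolerance = 1e-12)
  # closed-form Gaussian falloff at 1 voxel, sigma = 1.5 A
  expect_equal(dm$data[ctr[1] + 1, ctr[2], ctr[3]] /
                 dm$data[ctr[1], ctr[2], ctr[3]],
               exp(-1 / (2 * 1.5^2)), tolerance = 1e-9)
})

test_that("well-separated atoms give equal local maxima", {
  cfg <- simulation_config(resolution = 2.0, padding = 4.0)
  sigma <- 2.0 / (2 * sqrt(2 * log(2)))
  # far beyond the truncation radius, and integer so both atoms sit
  # exactly on grid nodes (origin and spacing are integral)
  gap <- ceiling(2 * cfg$kernel_truncation * sigma * 4)
  m <- atom_model(c("C", "C"), "A", c(1, 2), "ALA",
                  x = c(0, gap), y = c(0, 0), z = c(0, 0))
  dm <- simulate_map(m, cfg, normalize = FALSE)
  half <- dim(dm$data)[1] %/% 2
  peak1 <- max(dm$data[seq_len(half), , ])
  peak2 <- max(dm$data[(half + 1):dim(dm$data)[1], , ])
  expect_lt(abs(peak1 - peak2) / peak1, 1e-6)
})

test_that("total unnormalized density matches the analytic kernel mass", {
  m <- make_toy_structure("strand", 5, seed = 9)
  res <- 1.5 * 2 * sqrt(2 * log(2))      # sigma = 1.5 A
  cfg <- simulation_config(res, voxel_spacing = 1.0, padding = 6.0)
  dm <- simulate_map(m, cfg, normalize = FALSE)
  sigma <- 1.5
  # mass of one truncated kernel: (2 pi s^2)^{3/2} * P(chi2_3 <= t^2)
  mass1 <- (2 * pi * sigma^2)^1.5 * stats::pchisq(cfg$kernel_truncation^2, 3)
  expect_lt(abs(sum(dm$data) - nrow(m) * mass1) / (nrow(m) * mass1), 0.01)
})

test_that("same-resolution simulations correlate exactly, gaps degrade", {
  m <- make_toy_structure("helix", 15, seed = 13)
  sim <- function(res) simulate_map(m, simulation_config(res))
  s2a <- sim(2.0); s2b <- sim(2.0)
  expect_equal(cross_correlation(s2a$data, s2b$data), 1.0)
  s4 <- simulate_map(m, simulation_config(4.0), grid = s2a)
  s6 <- simulate_map(m, simulation_config(6.0), grid = s2a)
  cc24 <- cross_correlation(s2a$data, s4$data)
  cc26 <- cross_correlation(s2a$data, s6$data)
  expect_gt(1, cc24)
  expect_gt(cc24, cc26)
})

test_that("target resolution rule maps experimental to simulated", {
  expect_equal(target_resolution_for(3.2), 1.8)
  expect_equal(target_resolution_for(4.4), 3.0)
  expect_equal(target_resolution_for(3.0), 1.8)   # lower boundary
  expect_equal(target_resolution_for(3.5), 3.0)   # tie-break to 3.0 branch
  expect_equal(target_resolution_for(6.0), 3.0)
  expect_warning(v <- target_resolution_for(6.5), "outside")
  expect_equal(v, 3.0)
  expect_error(target_resolution_for(-1), "positive")
})

test_that("atomic-number weighting scales contributions", {
  mC <- atom_model("C", "A", 1, "ALA", 0, 0, 0)
  mO <- atom_model("O", "A", 1, "ALA", 0, 0, 0)
  cfg <- simulation_config(2.0, weight_scheme = "atomic-number")
  dC <- simulate_map(mC, cfg, normalize = FALSE)
  dO <- simulate_map(mO, cfg, normalize = FALSE)
  expect_equal(max(dO$data) / max(dC$data), 8 / 6, tolerance = 1e-9)
})

test_that("simulate_map validates input", {
  expect_error(simulation_config(-1), "positive")
  expect_error(simulation_config(2, kernel_truncation = 1), ">= 2")
  expect_error(simulate_map(list(), simulation_config(2)), "atom_model")
})
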