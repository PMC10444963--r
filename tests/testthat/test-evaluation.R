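test_that("cross_correlation basics and brute-force agreement", {
  set.seed(61)
  a <- array(runif(27), c(3, 3, 3))
  expect_equal(cross_correlation(a, a), 1.0)
  expect_equal(cross_correlation(a, -a), -1.0)
  b <- array(runif(27), c(3, 3, 3))
  expect_equal(cross_correlation(a, b), bf_pearson(a, b),
               tolerance = 1e-12)
  # about-zero variant
  expect_equal(cross_correlation(a, b, about_mean = FALSE),
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)), tolerance = 1e-12)
  expect_error(cross_correlation(array(1, c(2, 2, 2)), a[1:2, 1:2, 1:2]),
               "constant")
  expect_error(cross_correlation(array(0, c(3, 3, 3)), b,
                                 about_mean = FALSE), "zero-norm")
  expect_error(cross_correlation(a, b[1:2, 1:2, 1:2, drop = FALSE]),
               "shape")
})

test_that("cross_correlation is symmetric, bounded and invariant", {
  set.seed(62)
  for (i in 1:5) {
    a <- array(rnorm(64), c(4, 4, 4)); b <- array(rnorm(64), c(4, 4, 4))
    cc <- cross_correlation(a, b)
    expect_lte(abs(cc), 1 + 1e-12)
    expect_equal(cc, cross_correlation(b, a), tolerance = 1e-12)
    expect_equal(cc, cross_correlation(2.5 * a, b), tolerance = 1e-12)
    expect_equal(cc, cross_correlation(a + 3, b), tolerance = 1e-12)
  }
})

test_that("cubewise_improvement handles the boundary cases", {
  e <- rand_map(c(29, 25, 25), seed = 63, lo = 0.05)
  s <- rand_map(c(29, 25, 25), seed = 64, lo = 0.05)
  r1 <- cubewise_improvement(e, s, s)     # mod == sim
  expect_equal(r1$fraction_improved, 1.0)
  expect_equal(r1$mean_cc_mod_sim, 1.0, tolerance = 1e-12)
  r2 <- cubewise_improvement(e, e, s)     # mod == exp: exact ties only
  expect_equal(r2$fraction_improved, 1.0)
  expect_equal(r2$mean_cc_mod_sim, r2$mean_cc_exp_sim, tolerance = 1e-12)
  expect_error(cubewise_improvement(e, s, rand_map(c(25, 25, 25), 1)),
               "frame")
})

test_that("cubewise_improvement equals a brute-force per-cube loop", {
  e <- rand_map(c(33, 33, 33), seed = 65)
  m <- rand_map(c(33, 33, 33), seed = 66)
  s <- rand_map(c(33, 33, 33), seed = 67)
  r <- cubewise_improvement(e, m, s)
  ee <- extract_cubes(e); mm <- extract_cubes(m); ss <- extract_cubes(s)
  cce <- ccm <- c()
  for (i in seq_along(ee$cubes)) {
    if (!any(ee$cubes[[i]] != 0) || !any(ss$cubes[[i]] != 0)) next
    cce <- c(cce, bf_pearson(ee$cubes[[i]], ss$cubes[[i]]))
    ccm <- c(ccm, bf_pearson(mm$cubes[[i]], ss$cubes[[i]]))
  }
  expect_equal(r$n_cubes, length(cce))
  expect_equal(r$mean_cc_exp_sim, mean(cce), tolerance = 1e-6)
  expect_equal(r$mean_cc_mod_sim, mean(ccm), tolerance = 1e-6)
  expect_equal(r$fraction_improved, mean(ccm >= cce - 1e-12))
})

test_that("RSCC is 1 against a map simulated from the same model", {
  model <- make_toy_structure("helix", 10, seed = 71)
  cfg <- simulation_config(2.5)
  sim <- simulate_map(model, cfg)
  prof <- rscc_per_residue(sim, model, cfg)
  expect_equal(nrow(prof), 10L)
  expect_true(all(abs(prof$rscc - 1) < 1e-9))
  expect_equal(attr(prof, "mean_rscc"), 1, tolerance = 1e-9)
})

test_that("seeded noise strictly lowers mean RSCC", {
  model <- make_toy_structure("strand", 8, seed = 72)
  cfg <- simulation_config(2.5)
  sim <- simulate_map(model, cfg)
  noisy <- sim
  set.seed(73)
  noisy$data <- noisy$data + rnorm(length(noisy$data), sd = 0.2)
  noisy <- normalize_density(noisy)
  prof_clean <- rscc_per_residue(sim, model, cfg)
  prof_noisy <- rscc_per_residue(noisy, model, cfg)
  expect_lt(attr(prof_noisy, "mean_rscc"), attr(prof_clean, "mean_rscc"))
})

test_that("RSCC matches the brute-force masked-correlation loop", {
  model <- atom_model(c("C", "C", "C"), "A", c(1, 1, 2), "ALA",
                      x = c(3, 4.2, 6.5), y = c(3, 3.5, 4), z = c(3, 3, 5))
  cfg <- simulation_config(3.0, padding = 3.0)
  mp <- rand_map(c(11, 10, 11), seed = 74)
  ref <- simulate_map(model, cfg, grid = mp)
  prof <- rscc_per_residue(mp, model, cfg, mask_radius = 2.5)
  bf <- bf_rscc(mp, ref, model, 2.5)
  expect_equal(nrow(prof), length(bf))
  for (i in seq_len(nrow(prof))) {
    key <- paste(prof$chain[i], prof$resi[i], prof$icode[i])
    expect_equal(prof$rscc[i], bf[[key]], tolerance = 1e-6)
  }
})

test_that("improvement_report aligns by residue and summarizes deltas", {
  model <- make_toy_structure("helix", 6, seed = 75)
  cfg <- simulation_config(2.5)
  sim <- simulate_map(model, cfg)
  a <- rscc_per_residue(sim, model, cfg)
  same <- improvement_report(a, a)
  expect_true(all(same$deltas$delta_rscc == 0))
  expect_equal(same$fraction_improved, 1.0)

  b <- a
  b$rscc <- a$rscc - 0.2
  rep2 <- improvement_report(b, a)  # a is 0.2 above b everywhere
  expect_equal(rep2$fraction_improved, 1.0)
  expect_equal(rep2$mean_after - rep2$mean_before, 0.2, tolerance = 1e-12)

  shuffled <- a[rev(seq_len(nrow(a))), ]
  rep3 <- improvement_report(shuffled, a)
  expect_equal(rep3$mean_before, rep3$mean_after, tolerance = 1e-12)

  bad <- a[-1, ]
  expect_error(improvement_report(bad, a), "mismatch")
})

test_that("RSCC profiles serialize to TSV and JSON", {
  model <- make_toy_structure("helix", 5, seed = 76)
  cfg <- simulation_config(2.5)
  prof <- rscc_per_residue(simulate_map(model, cfg), model, cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_rscc_profile(prof, tsv)
  write_rscc_profile(prof, js)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(prof))
  expect_equal(back$rscc, prof$rscc, tolerance = 1e-9)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$mean_rscc, attr(prof, "mean_rscc"), tolerance = 1e-9)
})
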