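test_that("cell tessellation: topology, determinism, expression spread", {
  # single cell: periphery band is a closed ring (one band component, and the
  # complement splits into inside + outside)
  cfg1 <- simulation_config(population_state(), n_cells = 1, image_size = 128)
  cells1 <- generate_cells(cfg1)
  band <- EBImage::Image(cells1$periphery * 1)
  expect_equal(max(EBImage::bwlabel(band)), 1)
  expect_gte(max(EBImage::bwlabel(EBImage::Image((!cells1$periphery) * 1))), 1)

  cfg <- simulation_config(population_state(), n_cells = 6, seed = 9L)
  cells <- generate_cells(cfg)
  expect_equal(sort(unique(as.vector(cells$labels))), 1:6)
  # band is 2-4 px wide: it contains the label boundaries and stays thin
  expect_lt(mean(cells$periphery), 0.35)
  # determinism
  cells2 <- generate_cells(cfg)
  expect_identical(cells$labels, cells2$labels)
  expect_identical(cells$expression, cells2$expression)
  # degenerate variability: all cells share one expression level
  cfg0 <- simulation_config(population_state(), expression_cv = 0, seed = 3L)
  expect_equal(length(unique(generate_cells(cfg0)$cell_expression)), 1L)
  # log-normal spread has roughly the configured mean
  cfgv <- simulation_config(population_state(), n_cells = 40,
                            image_size = 256, expression_cv = 0.3, seed = 5L)
  expect_equal(mean(generate_cells(cfgv)$cell_expression), 15,
               tolerance = 0.15)
  # field too small for the requested cell count
  expect_error(generate_cells(
    simulation_config(population_state(), n_cells = 200, image_size = 64)),
    "too small")
})

test_that("rendering: noiseless exactness, blank fields, determinism", {
  p <- fret_params()
  st <- population_state("NcCg", "WT")
  cfg <- noiseless_config(st, p, seed = 4L)
  acq <- render_acquisition(cfg)
  expect_identical(acq$donor_488, acq$truth$expected$donor_488)
  expect_identical(acq$fret_488, acq$truth$expected$fret_488)
  expect_identical(acq$acceptor_552, acq$truth$expected$acceptor_552)
  expect_true(all(acq$donor_488 >= 0))

  # stored efficiency map equals the closed-form mean efficiency on signal
  mix <- species_mixture(st, p)
  on <- acq$truth$expression > 0
  expect_true(all(acq$truth$efficiency[on] == mean_efficiency(mix)))
  expect_true(all(acq$truth$efficiency[!on] == 0))

  # donor-only construct, no bleed: FRET and acceptor channels at noise floor
  p0 <- fret_params(beta_bleed = 0, alpha_direct = 0)
  donor_only <- population_state("TwoInOne", "WT", p_gfp = 1)
  acq0 <- render_acquisition(tiny_config(donor_only, p0, seed = 8L))
  expect_lt(mean(acq0$fret_488), 1.2 * mean(abs(
    acq0$fret_488[acq0$truth$expression == 0])))
  expect_equal(acq0$truth$expected$fret_488,
               matrix(0, 64, 64))
  expect_equal(acq0$truth$expected$acceptor_552, matrix(0, 64, 64))

  # determinism of the full acquisition
  a1 <- render_acquisition(tiny_config(st, p, seed = 77L))
  a2 <- render_acquisition(tiny_config(st, p, seed = 77L))
  expect_identical(a1$donor_488, a2$donor_488)
  expect_identical(a1$fret_488, a2$fret_488)
  a3 <- render_acquisition(tiny_config(st, p, seed = 78L))
  expect_false(identical(a1$donor_488, a3$donor_488))
})

test_that("shot noise is Poisson-like: Fano factor near 1 at fixed expectation", {
  st <- population_state("NcCg", "WT")
  # expression_cv = 0 gives a single periphery intensity level, so pooling
  # seeded replicates yields many pixels at one fixed expectation
  px <- unlist(lapply(1:3, function(s) {
    cfg <- simulation_config(st, fret_params(), image_size = 256, n_cells = 8,
                             expression_cv = 0, noise_read_sd = 0,
                             shot_noise = TRUE, seed = 11L + s)
    acq <- render_acquisition(cfg)
    lam <- acq$truth$expected$donor_488
    acq$donor_488[abs(lam - max(lam)) < 1e-9]
  }))
  expect_gt(length(px), 1e4)
  fano <- stats::var(px) / mean(px)
  expect_gt(fano, 0.9)
  expect_lt(fano, 1.1)
})

test_that("bleach series: donor rises in the mask by the closed-form amount", {
  p <- single_path_params(0.2, beta = 0, alpha = 0)
  st <- single_path_state(0.2)

  # noiseless complete bleach: exactly +25% inside the mask, 0% in control
  cfg <- noiseless_config(st, p, bleach_completeness = 1, seed = 2L)
  ser <- render_bleach_series(cfg)
  res_mask <- bleach_percent_increase(ser, method = "mask")
  expect_equal(res_mask$summary$percent_increase, 25, tolerance = 1e-9)
  expect_equal(res_mask$summary$control_percent_increase, 0, tolerance = 1e-9)
  res_prof <- bleach_percent_increase(ser, method = "profile")
  expect_equal(res_prof$summary$percent_increase, 25, tolerance = 1e-9)


  # no-FRET population: post equals pre in expectation
  p0 <- single_path_params(0)
  ser0 <- render_bleach_series(noiseless_config(single_path_state(0), p0,
                                                seed = 2L))
  expect_identical(ser0$truth$expected_post, ser0$truth$expected_pre)

  # masks are disjoint; stacks have the protocol scan counts
  expect_false(any(ser$bleach_mask & ser$control_mask))
  expect_length(ser$pre_stack, 5)
  expect_length(ser$post_stack, 5)

  # determinism
  s1 <- render_bleach_series(tiny_config(st, p, seed = 31L))
  s2 <- render_bleach_series(tiny_config(st, p, seed = 31L))
  expect_identical(s1$pre_stack, s2$pre_stack)
  expect_identical(s1$post_stack, s2$post_stack)
})

test_that("control region is statistically flat across seeded replicates", {
  p <- fret_params()
  st <- population_state("NcCg", "WT")
  deltas <- vapply(1:20, function(s) {
    ser <- render_bleach_series(simulation_config(st, p, seed = 400L + s))
    res <- bleach_percent_increase(ser, method = "mask")
    res$summary$control_percent_increase
  }, 0)
  # mean control change within 3 SE of zero, and within 2 percentage points
  expect_lt(abs(mean(deltas)), 3 * stats::sd(deltas) / sqrt(length(deltas)))
  expect_lt(abs(mean(deltas)), 2)
})
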