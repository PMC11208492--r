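test_that("partition_dye follows Nernst weighting below saturation", {
  # equal potentials, load far below saturation: equal density per area,
  # rim fraction set purely by the membrane-area weights
  p <- partition_dye(0.001, -120, -120, k_sat = 100,
                     area_cm = 2, area_ibm = 1)
  expect_equal(p$cm_density, p$ibm_density, tolerance = 1e-4)
  expect_equal(p$f, 1 / 3, tolerance = 1e-4)
  # 60 mV difference at 310 K: Nernst preference exp(60 / 26.73) = 9.44
  rt_f <- 1000 * 8.31446 * 310 / 96485.33
  expect_equal(rt_f, 26.73, tolerance = 0.005)
  p <- partition_dye(1e-6, -180, -120, k_sat = 1e9,
                     area_cm = 1, area_ibm = 1)
  expect_equal(p$cm_amount / p$ibm_amount, exp(60 / rt_f), tolerance = 1e-6)
  expect_equal(exp(60 / rt_f), 9.44, tolerance = 0.005 * 9.44)
  expect_error(partition_dye(-1, -150, -120, 10), "dye_total")
  expect_error(partition_dye(1, 10, -120, 10), "<= 0 mV")
  expect_error(partition_dye(1, -150, -120, 0), "k_sat")
})

test_that("rim fraction rises with load once cristae saturate", {
  loads <- exp(seq(log(0.1), log(200), length.out = 25))
  fs <- vapply(loads, function(D)
    partition_dye(D, -150, -120, k_sat = 40)$f, numeric(1))
  expect_true(all(diff(fs) > 0))
  # unsaturated limit: f approaches the Nernst-area floor from above
  expect_lt(fs[1], 0.2)
  expect_gt(fs[25], 0.7)
})

test_that("rendering conserves dye and is deterministic under a seed", {
  sc <- synthetic_scene(noise = FALSE)
  fr <- render_frame(sc)
  expect_equal(sum(fr$frame$object), sc$dye_total * sc$gain,
               tolerance = 1e-3)
  expect_equal(sum(fr$frame$reference), sc$ref_total * sc$gain,
               tolerance = 1e-3)
  scn <- synthetic_scene(noise = TRUE, seed = 77)
  f1 <- render_frame(scn)
  f2 <- render_frame(scn)
  expect_identical(f1$frame$object, f2$frame$object)
  expect_identical(f1$frame$reference, f2$frame$reference)
  f3 <- render_frame(scn, seed = 78)
  expect_false(identical(f1$frame$object, f3$frame$object))
})

test_that("a vanishing PSF returns the rasterized density map", {
  sc <- synthetic_scene(noise = FALSE, psf_fwhm_nm = 1e-9)
  fr <- render_frame(sc)$frame
  sc_blur <- synthetic_scene(noise = FALSE, psf_fwhm_nm = 120)
  fb <- render_frame(sc_blur)$frame
  # no blur: cristae slab contrast along the axis survives; blurred: gone
  expect_gt(max(fr$object), 2 * max(fb$object))
  expect_equal(sum(fr$object), sum(fb$object), tolerance = 1e-6)
})

test_that("object channel contrast follows the rim fraction", {
  f0 <- render_frame(synthetic_scene(noise = FALSE, rim_fraction = 0))
  f9 <- render_frame(synthetic_scene(noise = FALSE, rim_fraction = 0.9))
  masks <- reference_masks(f0$frame$reference)
  i0 <- ibm_association_index(f0$frame$object, masks)$index
  i9 <- ibm_association_index(f9$frame$object, masks)$index
  expect_lt(i0, i9)
})

test_that("null protocol gives flat truth and a flat measured index", {
  sc <- synthetic_scene(seed = 21)
  sim <- simulate_timelapse(sc, protocol_null(n_frames = 5, dt = 10))
  expect_equal(nrow(sim$truth), 5)
  expect_equal(length(unique(sim$truth$f)), 1)
  expect_equal(sim$truth$n_objects, rep(3, 5))
  tr <- compute_traces(sim$timelapse)
  expect_lt(stats::sd(tr$ibm_index) / mean(tr$ibm_index), 0.02)
})

test_that("histamine protocol drops the rim fraction after the stimulus", {
  sc <- synthetic_scene(seed = 5, noise = FALSE)
  sim <- simulate_timelapse(sc, protocol_histamine(n_frames = 8, dt = 10,
                                                   t_stim = 20))
  pre <- sim$truth$f[sim$truth$t < 20]
  post <- tail(sim$truth$f, 3)
  expect_true(all(post < min(pre)))
  tr <- compute_traces(sim$timelapse)
  expect_lt(tail(tr$ibm_index, 1), tr$ibm_index[1])
})

test_that("programmed fissions appear in the truth log with bookkeeping", {
  sc <- synthetic_scene(seed = 11, noise = FALSE)
  fiss <- list(list(t = 40, mito = 1, s_frac = 0.5, dim_frac = 0.4),
               list(t = 60, mito = 2, s_frac = 0.4, dim_frac = 0.4),
               list(t = 80, mito = 3, s_frac = 0.6, dim_frac = 0.4))
  sim <- simulate_timelapse(sc, protocol_histamine(n_frames = 10, dt = 10,
                                                   t_stim = 20,
                                                   fissions = fiss))
  expect_equal(nrow(sim$events), 3)
  expect_equal(tail(sim$truth$n_objects, 1), 3 + 3)
  expect_error(
    simulate_timelapse(sc, protocol_histamine(
      n_frames = 5, dt = 10,
      fissions = list(list(t = 500, mito = 1, s_frac = 0.5)))),
    "outside the simulated interval")
})

test_that("identical seeds give identical simulated stacks", {
  sc <- synthetic_scene(seed = 33)
  p <- protocol_histamine(n_frames = 4, dt = 10)
  s1 <- simulate_timelapse(sc, p)
  s2 <- simulate_timelapse(sc, p)
  for (k in seq_along(s1$timelapse$frames))
    expect_identical(s1$timelapse$frames[[k]]$object,
                     s2$timelapse$frames[[k]]$object)
  expect_identical(s1$truth, s2$truth)
})
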