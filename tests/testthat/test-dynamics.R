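test_that("compute_traces returns one complete row per frame", {
  sc <- synthetic_scene(seed = 17)
  sim <- simulate_timelapse(sc, protocol_null(n_frames = 4, dt = 10))
  tr <- compute_traces(sim$timelapse, atp = rep(1, 4))
  expect_equal(nrow(tr), 4)
  expect_true(all(c("t", "ibm_index", "delta_fwhm_px", "total_ref",
                    "total_obj", "c", "mean_area_um2", "mean_ar",
                    "mean_ff", "atp_proxy") %in% names(tr)))
  expect_true(all(is.finite(tr$ibm_index)))
  # determinism
  tr2 <- compute_traces(sim$timelapse, atp = rep(1, 4))
  expect_identical(tr$ibm_index, tr2$ibm_index)
})

test_that("ATP traces on a different clock are aligned by interpolation", {
  sc <- synthetic_scene(seed = 17)
  sim <- simulate_timelapse(sc, protocol_null(n_frames = 4, dt = 10))
  atp <- data.frame(t_seconds = c(-5, 15, 35), value = c(0, 2, 4))
  tr <- compute_traces(sim$timelapse, atp = atp)
  expect_equal(tr$atp_proxy, c(0.5, 1.5, 2.5, 3.5))
})

test_that("single-frame failures leave the other frames intact", {
  sc <- synthetic_scene(seed = 17)
  sim <- simulate_timelapse(sc, protocol_null(n_frames = 3, dt = 10))
  # corrupt one frame so the reference has no Otsu foreground
  sim$timelapse$frames[[2]]$reference <- matrix(5, 96, 96)
  sim$timelapse$frames[[2]]$object <- matrix(5, 96, 96)
  tr <- compute_traces(sim$timelapse)
  expect_true(is.na(tr$ibm_index[2]))
  expect_true(all(is.finite(tr$ibm_index[c(1, 3)])))
  expect_match(paste(attr(tr, "notes"), collapse = "; "), "frame 2")
})

test_that("normalize_delta subtracts or divides by the baseline", {
  x <- c(10, 10, 15, 20)
  add <- normalize_delta(x, baseline = 1:2)
  expect_equal(as.numeric(add), c(0, 0, 5, 10))
  frac <- normalize_delta(x, baseline = 1:2, mode = "fractional")
  expect_equal(as.numeric(frac), c(0, 0, 0.5, 1))
  expect_equal(as.numeric(normalize_delta(rep(3, 5), baseline = 1:3)),
               rep(0, 5))
  expect_error(normalize_delta(x, baseline = 1), "at least 2")
})

test_that("linear_fit recovers exact lines and rejects degenerate input", {
  x <- 1:10
  fit <- linear_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  for (a in c(-3, 0.5)) {
    f <- linear_fit(x, a * x - 2)
    expect_equal(f$slope, a, tolerance = 1e-10)
    expect_equal(f$r_squared, 1, tolerance = 1e-10)
  }
  expect_error(linear_fit(rep(1, 5), 1:5), "zero variance in x")
  expect_error(linear_fit(1:5, rep(2, 5)), "zero variance in y")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("r_squared is invariant under affine rescaling of either trace", {
  set.seed(12)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50, 0, 0.5)
  r0 <- linear_fit(x, y)$r_squared
  expect_equal(linear_fit(3 * x - 5, y)$r_squared, r0, tolerance = 1e-12)
  expect_equal(linear_fit(x, -2 * y + 11)$r_squared, r0, tolerance = 1e-12)
})

test_that("independent traces give near-zero r_squared", {
  set.seed(99)
  x <- rnorm(100); y <- rnorm(100)
  fit <- linear_fit(x, y)
  expect_lt(fit$r_squared, 0.05)
  expect_gt(fit$p_slope, 0.01)
})

test_that("detect_fission finds programmed splits and nothing else", {
  sc <- synthetic_scene(seed = 11, noise = FALSE)
  fiss <- list(list(t = 40, mito = 1, s_frac = 0.5, dim_frac = 0.4),
               list(t = 60, mito = 2, s_frac = 0.4, dim_frac = 0.4),
               list(t = 80, mito = 3, s_frac = 0.6, dim_frac = 0.4))
  sim <- simulate_timelapse(sc, protocol_histamine(n_frames = 10, dt = 10,
                                                   t_stim = 20,
                                                   fissions = fiss))
  labs <- lapply(sim$timelapse$frames, function(fr)
    label_particles(binarize(subtract_background(fr$reference))))
  objs <- lapply(sim$timelapse$frames, function(fr) fr$object)
  ev <- detect_fission(labs, objs)
  m <- match_events(ev, sim$events)
  expect_equal(m$tp, 3); expect_equal(m$fp, 0); expect_equal(m$fn, 0)
  # local pre-split dimming within 10 percentage points of programmed 40%
  expect_true(all(abs(ev$local_drop - 0.4) <= 0.10))
  # static scene: no events
  simn <- simulate_timelapse(sc, protocol_null(n_frames = 4, dt = 10))
  labs0 <- lapply(simn$timelapse$frames, function(fr)
    label_particles(binarize(subtract_background(fr$reference))))
  ev0 <- detect_fission(labs0, lapply(simn$timelapse$frames, `[[`, "object"))
  expect_equal(nrow(ev0), 0)
})
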