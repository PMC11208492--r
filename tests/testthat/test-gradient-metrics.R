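test_that("reference_masks matches brute-force morphology on a disk", {
  img <- disk_mask(10) * 1000
  masks <- reference_masks(img, erode_iters = 1, dilate_iters = 2)
  whole <- img > 500
  expect_identical(masks$whole, img > otsu_threshold(img))
  expect_identical(masks$core, brute_erode(whole, 1))
  expect_identical(masks$rim, brute_dilate(whole, 2) & !brute_erode(whole, 1))
  # hollow structure: rim is an annulus, disjoint from the core
  expect_false(any(masks$rim & masks$core))
  expect_true(all(masks$core[masks$core] %in% masks$whole[masks$core]))
})

test_that("masks are invariant under positive scaling of the reference", {
  sc <- synthetic_scene(seed = 2)
  img <- render_frame(sc)$frame$reference
  m1 <- reference_masks(img)
  m3 <- reference_masks(img * 3)
  expect_identical(m1$whole, m3$whole)
  expect_identical(m1$core, m3$core)
  expect_identical(m1$rim, m3$rim)
})

test_that("degenerate references fail loudly", {
  expect_error(reference_masks(matrix(0, 10, 10)), "constant image")
  thin <- matrix(0, 12, 12); thin[6, 3:10] <- 1000  # 1 px wide line
  expect_error(reference_masks(thin, erode_iters = 1), "thinner than")
})

test_that("ibm_association_index handles the canonical mask cases", {
  img <- disk_mask(10) * 1000
  masks <- reference_masks(img)
  # all signal in the core -> index 0
  core_only <- matrix(0, nrow(img), ncol(img)); core_only[masks$core] <- 100
  expect_equal(ibm_association_index(core_only, masks)$index, 0)
  # uniform over rim and core -> index 1
  unif <- matrix(0, nrow(img), ncol(img))
  unif[masks$core | masks$rim] <- 100
  expect_equal(ibm_association_index(unif, masks)$index, 1)
  # zero core mean -> explicit error, not infinity
  rim_only <- matrix(0, nrow(img), ncol(img)); rim_only[masks$rim] <- 5
  expect_error(ibm_association_index(rim_only, masks), "core mean")
})

test_that("index is scale invariant and rotation/translation equivariant", {
  sc <- synthetic_scene(seed = 4)
  fr <- render_frame(sc)$frame
  masks <- reference_masks(fr$reference)
  i0 <- ibm_association_index(fr$object, masks)$index
  expect_equal(ibm_association_index(fr$object * 7.3, masks)$index, i0)
  # joint 90-degree rotation of both channels
  rot <- function(m) t(m)[, nrow(m):1]
  masks_r <- reference_masks(rot(fr$reference))
  expect_equal(ibm_association_index(rot(fr$object), masks_r)$index, i0,
               tolerance = 1e-10)
})

test_that("cross_profile reproduces analytic sections", {
  # ideal vertical tube: width averaging must equal the single-line profile
  img <- matrix(0, 40, 40)
  for (cc in 1:40) img[, cc] <- exp(-(cc - 20)^2 / 8)
  fr <- two_channel_frame(img, img, pixel_size = 32)
  wide <- cross_profile(fr, rbind(c(20, 5), c(20, 35)), width = 12)
  thin <- cross_profile(fr, rbind(c(20, 5), c(20, 35)), width = 1)
  expect_equal(wide$values_ref, thin$values_ref, tolerance = 1e-9)
  # central section of an isotropic Gaussian is Gaussian with the same sigma
  r <- row(matrix(0, 41, 41)) - 21; c <- col(matrix(0, 41, 41)) - 21
  g <- exp(-(r^2 + c^2) / (2 * 4))
  fr <- two_channel_frame(g, g, pixel_size = 32)
  # spacing 1 samples pixel centers exactly; finer spacings interpolate
  # linearly between them, which slightly inflates the second moment
  prof <- cross_profile(fr, rbind(c(21, 5), c(21, 37)), width = 1,
                        spacing = 1)
  w <- prof$values_ref / sum(prof$values_ref)
  mu <- sum(prof$positions_px * w)
  sigma_hat <- sqrt(sum((prof$positions_px - mu)^2 * w))
  expect_equal(sigma_hat, 2, tolerance = 0.01)
  # reversing the endpoints reverses the profile, FWHM unchanged
  rev_prof <- cross_profile(fr, rbind(c(21, 37), c(21, 5)), width = 1,
                            spacing = 1)
  expect_equal(rev_prof$values_ref, rev(prof$values_ref), tolerance = 1e-9)
  expect_equal(fwhm_subpixel(rev_prof$positions_px, rev_prof$values_ref)$fwhm,
               fwhm_subpixel(prof$positions_px, prof$values_ref)$fwhm,
               tolerance = 1e-9)
  expect_error(cross_profile(fr, rbind(c(-3, 5), c(21, 37))), "outside")
  expect_error(cross_profile(fr, rbind(c(21, 5), c(21, 7))), "shorter")
})

test_that("fwhm_subpixel is exact on triangles, 1% on Gaussians", {
  # triangle: linear interpolation is exact on piecewise-linear data
  r <- fwhm_subpixel(0:10, c(0, 2, 4, 6, 8, 10, 8, 6, 4, 2, 0))
  expect_equal(r$fwhm, 5.0)
  expect_equal(unname(r$crossings), c(2.5, 7.5))
  # sampled Gaussians, sigma >= 1.5 px at <= 1 px spacing
  for (sigma in c(1.5, 2, 3)) for (sp in c(1, 0.5)) {
    p <- gaussian_profile(sigma, spacing = sp)
    expect_equal(fwhm_subpixel(p$x, p$y)$fwhm, 2 * sqrt(2 * log(2)) * sigma,
                 tolerance = 0.01)
  }
  expect_error(fwhm_subpixel(0:5, 0:5), "maximum at profile end")
  expect_error(fwhm_subpixel(0:6, c(0, 5, 1, 0.5, 1, 5, 0)),
               "separated maxima")
  # plateau sitting exactly at half-max: midpoint rule with a warning
  expect_warning(  # both flanks warn: plateau on each side of the peak
    expect_warning(r <- fwhm_subpixel(0:4, c(5, 5, 10, 5, 5), baseline = 0),
                   "plateau"),
    "plateau")
  expect_equal(unname(r$fwhm), 3)
})

test_that("delta_fwhm subtracts channels with a switchable sign", {
  p2 <- gaussian_profile(2, spacing = 0.5)
  p1 <- gaussian_profile(1, spacing = 0.5)
  prof <- structure(list(positions_px = p2$x, positions_nm = p2$x * 32,
                         values_ref = p2$y, values_obj = p2$y,
                         width = 1, pixel_size = 32),
                    class = "line_profile")
  expect_equal(delta_fwhm(prof)$delta, 0)
  prof$values_obj <- p1$y
  d <- delta_fwhm(prof)
  expect_equal(d$delta, -2 * sqrt(2 * log(2)), tolerance = 0.01)
  expect_equal(delta_fwhm(prof, sign = "mtg_minus_tmrm")$delta, -d$delta)
  expect_equal(d$delta_nm, d$delta * 32)
  # channel errors are tagged with the channel
  prof$values_obj <- seq_along(p2$x) * 1.0
  expect_error(delta_fwhm(prof), "object channel")
})

test_that("both metrics increase strictly with the true rim fraction", {
  fs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  res <- vapply(fs, function(f) {
    fr <- render_frame(synthetic_scene(noise = FALSE, rim_fraction = f))$frame
    masks <- reference_masks(fr$reference)
    idx <- ibm_association_index(fr$object, masks)$index
    eps <- auto_profiles(fr, masks)
    deltas <- vapply(eps, function(e)
      delta_fwhm(cross_profile(fr, e, width = 10))$delta, numeric(1))
    c(idx, mean(deltas))
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) > 0))
})
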