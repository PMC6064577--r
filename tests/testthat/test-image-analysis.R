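# Build a photograph-like object directly from a DN matrix.
dn_photo <- function(dn, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dn), ncol(dn))
  storage.mode(dn) <- "integer"
  structure(list(dn = dn, mask = mask, exposure = 0, blur_sigma = 0,
                 cfg = camera_config()), class = "photograph")
}

test_that("histograms count exactly and demand a non-empty mask", {
  dn <- matrix(200L, 10, 10)
  h <- greyness_histogram(dn_photo(dn))
  expect_equal(h$counts[201], 100)
  expect_equal(sum(h$counts), h$total)

  two <- matrix(c(0L, 255L), 10, 10)
  h2 <- greyness_histogram(dn_photo(two))
  expect_equal(h2$counts[c(1, 256)], c(50, 50))
  expect_equal(sum(h2$counts > 0), 2)

  expect_error(greyness_histogram(dn_photo(dn, matrix(FALSE, 10, 10))),
               "empty")
})

test_that("gap-fraction curve is exact, monotone and bounded", {
  dn <- matrix(0L, 10, 10)
  dn[1:4, ] <- 255L  # 40% bright
  h <- greyness_histogram(dn_photo(dn))
  expect_equal(gap_fraction_at_threshold(h, 0), 1.0)
  expect_equal(gap_fraction_at_threshold(h, 128), 0.40)
  expect_equal(gap_fraction_at_threshold(h, 255), 0.40)
  curve <- gap_fraction_curve(h)
  expect_true(all(diff(curve$gap_fraction) <= 0))
  expect_error(gap_fraction_at_threshold(h, 256), "0..255")

  # random histograms stay monotone
  set.seed(42)
  for (rep in 1:20) {
    dn <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    cv <- gap_fraction_curve(greyness_histogram(dn_photo(dn)))
    expect_true(all(diff(cv$gap_fraction) <= 0))
  }
})

test_that("grey-pixel bounds recover a constructed bridge between humps", {
  # humps at DN 10 and 245, flat low bridge carrying 12% of the mass
  counts <- rep(0, 256)
  counts[10 + 1] <- 5000
  counts[245 + 1] <- 3200
  bridge <- 13:242
  counts[bridge + 1] <- ceiling(0.12 * 10000 / length(bridge))
  total <- sum(counts)
  h <- structure(list(dn = 0:255, counts = counts, total = total),
                 class = "greyness_histogram")
  g <- grey_pixel_bounds(h)
  expect_lte(g$t_low, min(bridge))
  expect_gte(g$t_high, max(bridge))
  bridge_mass <- sum(counts[bridge + 1]) / total
  expect_equal(g$grey_fraction, bridge_mass, tolerance = 0.01)

  # a two-delta histogram has no grey pixels
  counts2 <- rep(0, 256)
  counts2[c(1, 256)] <- 500
  h2 <- structure(list(dn = 0:255, counts = counts2, total = 1000),
                  class = "greyness_histogram")
  expect_equal(grey_pixel_bounds(h2)$grey_fraction, 0)

  # explicit bounds override detection
  g3 <- grey_pixel_bounds(h, t_low = 12, t_high = 243)
  expect_equal(g3$grey_fraction, bridge_mass, tolerance = 1e-12)
})

test_that("grey fraction vanishes without borders and grows with blur", {
  # all-sky and all-canopy scenes have no sky-canopy border, hence no grey
  for (occ_val in c(0, 1)) {
    sc <- scene_from_occupancy(matrix(occ_val, 32, 32))
    ph <- simulate_photograph(sc, 0, camera_config())
    expect_equal(grey_pixel_bounds(greyness_histogram(ph))$grey_fraction, 0)
  }
  sc <- render_canopy(canopy_spec(5, gf_designed = 0.25),
                      pixel_scale = 0.047, supersample = 8, extent_mm = 30)
  f <- sapply(c(0.7, 1.5, 2.5), function(s) {
    ph <- simulate_photograph(sc, 0, camera_config(blur_sigma = s))
    grey_pixel_bounds(greyness_histogram(ph))$grey_fraction
  })
  expect_true(all(diff(f) > 0))
})

test_that("binarization agrees with the histogram route and is bounded", {
  set.seed(7)
  dn <- matrix(sample(0:255, 900, replace = TRUE), 30, 30)
  ph <- dn_photo(dn)
  h <- greyness_histogram(ph)
  for (thr in c(0, 31, 128, 255)) {
    bin <- binarize(ph, thr)
    expect_equal(gap_fraction(bin), gap_fraction_at_threshold(h, thr))
  }
  expect_true(all(binarize(ph, 0)$sky))
  b255 <- binarize(ph, 255)
  expect_equal(sum(b255$sky), sum(dn == 255L))
  expect_error(binarize(ph, 256), "0..255")
})

test_that("misclassification categories partition the mask", {
  sc <- render_canopy(canopy_spec(2.5, gf_designed = 0.25),
                      pixel_scale = 0.1, supersample = 4, extent_mm = 15)
  ph <- simulate_photograph(sc, 0, camera_config())
  ref <- binarize(ph, matched_threshold(ph))
  # reference judged against itself: nothing misclassified
  mis0 <- misclassification_map(ref, ph$labels, ref)
  expect_equal(misclassified_count(mis0), 0)
  # a mismatched threshold misclassifies some pixels, and the four
  # categories exactly cover the mask
  bin <- binarize(ph, threshold_for_stop(camera_threshold_model(ph$cfg), -2))
  mis <- misclassification_map(bin, ph$labels, ref)
  expect_gt(misclassified_count(mis), 0)
  expect_equal(sum(mis$counts), sum(ph$mask))
  expect_error(
    misclassification_map(bin, ph$labels[1:5, 1:5], ref),
    "geometry"
  )
})

test_that("Sobel MPZ matches a brute-force convolution oracle", {
  sobel_brute <- function(m) {
    kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # columns of Gx
    ky <- t(kx)
    nr <- nrow(m)
    nc <- ncol(m)
    edge <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        gx <- 0
        gy <- 0
        for (di in -1:1) {
          for (dj in -1:1) {
            v <- m[min(max(i + di, 1), nr), min(max(j + dj, 1), nc)]
            gx <- gx + kx[di + 2, dj + 2] * v
            gy <- gy + ky[di + 2, dj + 2] * v
          }
        }
        edge[i, j] <- (gx^2 + gy^2) > 0
      }
    }
    edge
  }
  set.seed(99)
  for (rep in 1:200) {
    m <- matrix(stats::runif(256) < 0.5, 16, 16)
    bin <- structure(list(sky = m, mask = matrix(TRUE, 16, 16),
                          threshold = 128), class = "binary_map")
    res <- mpz_sobel(bin)
    expect_identical(res$edge_mask, sobel_brute(m * 1))
  }
})

test_that("Sobel MPZ flags the two columns flanking a step and none elsewhere", {
  m <- matrix(FALSE, 16, 16)
  m[, 9:16] <- TRUE
  bin <- structure(list(sky = m, mask = matrix(TRUE, 16, 16),
                        threshold = 128), class = "binary_map")
  res <- mpz_sobel(bin)
  expect_true(all(res$edge_mask[, 8:9]))
  expect_false(any(res$edge_mask[, c(1:7, 10:16)]))
  expect_equal(res$mpz_fraction, 2 / 16)

  uniform <- structure(list(sky = matrix(TRUE, 8, 8),
                            mask = matrix(TRUE, 8, 8), threshold = 0),
                       class = "binary_map")
  expect_equal(mpz_sobel(uniform)$mpz_fraction, 0)
})

test_that("MPZ fraction is linear in border length across the suite", {
  suite <- generate_canopy_suite()
  d <- do.call(rbind, lapply(suite, function(s) {
    sc <- render_canopy(s, pixel_scale = 0.1, supersample = 4,
                        extent_mm = 45)
    ph <- simulate_photograph(sc, 0, camera_config(blur_sigma = 0))
    bin <- binarize(ph, matched_threshold(ph))
    data.frame(B = s$scb_per_area, mpz = mpz_sobel(bin)$mpz_fraction)
  }))
  fit <- stats::lm(mpz ~ B, d)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(abs(stats::coef(fit)[1]), 0.01)  # near-zero intercept
})

test_that("edge response distance recovers the Gaussian blur scale", {
  # an unblurred step transitions within a pixel
  ph0 <- simulate_photograph(step_scene(32), 0,
                             camera_config(gamma = 1, blur_sigma = 0))
  expect_lte(edge_response_distance(ph0)$rise_distance, 1)

  # Gaussian blur: 10-90% distance = 2 qnorm(0.9) sigma, and doubling the
  # blur doubles the distance
  cfg3 <- camera_config(sky_dn_at_reference = 200, gamma = 1, blur_sigma = 3)
  d3 <- edge_response_distance(simulate_photograph(step_scene(96), 0, cfg3))
  expect_equal(d3$rise_distance, 2 * qnorm(0.9) * 3, tolerance = 0.02)
  expect_equal(d3$sharpness, 1 / d3$rise_distance)
  cfg6 <- camera_config(sky_dn_at_reference = 200, gamma = 1, blur_sigma = 6)
  d6 <- edge_response_distance(simulate_photograph(step_scene(96), 0, cfg6))
  expect_equal(d6$rise_distance / d3$rise_distance, 2, tolerance = 0.03)

  expect_error(edge_response_distance(matrix(5, 8, 8)), "amplitude")
})
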