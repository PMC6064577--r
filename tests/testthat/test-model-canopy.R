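test_that("geometry formulas invert each other and match hand values", {
  expect_equal(separation_width(0.25, 2.5), 2.5)
  expect_equal(round_half_up(separation_width(0.05, 2.5)), 8.68)
  expect_equal(designed_gap_fraction(2.5, 2.5), 0.25)
  expect_equal(designed_gap_fraction(5, 0), 1.0)
  expect_equal(round_half_up(designed_gap_fraction(5, 10.81)), 0.10)
  expect_equal(scb_length_per_area(2.5, 2.5), 0.40)
  expect_equal(round_half_up(scb_length_per_area(20, 8.28)), 0.10)

  # round trip over a grid of gap fractions and side lengths
  for (g in c(0.01, 0.05, 0.3, 0.75, 0.99)) {
    for (L in c(0.5, 2.5, 20)) {
      W <- separation_width(g, L)
      expect_equal(designed_gap_fraction(L, W), g, tolerance = 1e-12)
      # B = 4 GF / L identically
      expect_equal(scb_length_per_area(L, W), 4 * g / L, tolerance = 1e-12)
    }
  }
  # no separation at full openness
  expect_lt(separation_width(1 - 1e-12, 2.5), 1e-10)

  expect_error(separation_width(0, 2.5), "between 0 and 1")
  expect_error(separation_width(1, 2.5), "between 0 and 1")
  expect_error(designed_gap_fraction(-1, 2), "positive")
  expect_error(scb_length_per_area(2, -1), "non-negative")
})

test_that("canopy scaling preserves gap fraction and rescales border length", {
  spec <- canopy_spec(2.5, gf_designed = 0.25)
  half <- scale_canopy(spec, 0.5)
  expect_equal(half$gf_designed, 0.25)
  expect_equal(half$scb_per_area, 0.80)  # halving scale doubles B
  dbl <- scale_canopy(spec, 2)
  expect_equal(dbl$scb_per_area, spec$scb_per_area / 2)
  expect_equal(dbl$gf_designed, spec$gf_designed)
  same <- scale_canopy(spec, 1)
  expect_equal(same$side_length, spec$side_length)
  expect_equal(same$separation, spec$separation)
  expect_error(scale_canopy(spec, 0), "positive")
})

test_that("the design suite holds exactly the 17 published canopies", {
  suite <- generate_canopy_suite()
  expect_length(suite, 17)
  tab <- canopy_suite_table(suite)
  pub <- published_design()
  key <- function(g, L) paste(g, L)
  expect_setequal(key(tab$gf_designed, tab$side_length_mm),
                  key(pub$gf, pub$L))
  # the dropped cell is absent
  expect_false(key(0.75, 2.5) %in% key(tab$gf_designed, tab$side_length_mm))
  # every cell reproduces the printed W and B at 2-decimal rounding
  m <- match(key(tab$gf_designed, tab$side_length_mm), key(pub$gf, pub$L))
  expect_equal(round_half_up(tab$separation_mm), pub$W[m])
  expect_equal(round_half_up(tab$scb_per_area), pub$B[m])
})

test_that("rendered scenes carry exact occupancy-based ground truth", {
  spec <- canopy_spec(2.5, gf_designed = 0.25)
  sc <- render_canopy(spec, pixel_scale = 0.25, supersample = 8,
                      extent_mm = 20)
  expect_equal(mean(sc$occupancy), sc$true_gap_fraction, tolerance = 1e-12)
  expect_true(all(sc$occupancy >= 0 & sc$occupancy <= 1))
  # labels match occupancy exactly
  expect_true(all((sc$labels == 2L) == (sc$occupancy == 1)))
  expect_true(all((sc$labels == 0L) == (sc$occupancy == 0)))
  # whole-period region: rasterised gap fraction converges to the designed
  # value, within twice the mixed-pixel share
  grey_share <- mean(sc$labels == 1L)
  expect_lte(abs(sc$true_gap_fraction - spec$gf_designed), 2 * grey_share)
  # finer rasters converge
  err <- sapply(c(0.5, 0.25, 0.125), function(ps) {
    abs(render_canopy(spec, ps, 4, 20)$true_gap_fraction - 0.25)
  })
  expect_lt(err[3], 0.01)
  expect_lte(err[3], err[1] + 1e-12)
})

test_that("aligned integer geometry with supersample 1 renders a binary scene", {
  # L and W are whole multiples of the pixel scale and the half-bar offset
  # is too, so every pixel is purely sky or canopy
  spec <- canopy_spec(2, separation = 2)
  sc <- render_canopy(spec, pixel_scale = 1, supersample = 1, extent_mm = 16)
  expect_true(all(sc$occupancy %in% c(0, 1)))
  expect_equal(sum(sc$labels == 1L), 0)
})

test_that("mixed-pixel count of a rendered scene tracks the border length", {
  # brute-force check on one small render: the one-pixel border band around
  # openings covers ~ B * pixel_scale * (band width) of the raster
  spec <- canopy_spec(4.14, gf_designed = 0.5)
  ps <- 0.1
  sc <- render_canopy(spec, pixel_scale = ps, supersample = 8,
                      extent_mm = 20)
  grey_frac <- mean(sc$labels == 1L)
  # borders cut through one-to-two pixel columns each (sub-pixel phases,
  # less the crossings the supersampler resolves as pure), so the grey
  # fraction sits within a band around B * pixel_scale
  expect_gt(grey_frac, 0.5 * spec$scb_per_area * ps)
  expect_lt(grey_frac, 2.5 * spec$scb_per_area * ps)
})

test_that("render guards: tiny extents warn, zero rasters error", {
  spec <- canopy_spec(10, gf_designed = 0.25)  # period 20 mm
  expect_warning(render_canopy(spec, 0.5, 2, extent_mm = 10),
                 "smaller than one pattern period")
  expect_error(render_canopy(spec, 1e6, 2, extent_mm = 20), "zero size")
  expect_error(render_canopy(spec, -1), "positive")
})

test_that("scene_from_occupancy wraps a field with consistent truth", {
  occ <- matrix(c(0, 0.5, 1, 1), 2, 2)
  sc <- scene_from_occupancy(occ, pixel_scale = 2)
  expect_s3_class(sc, "scene_raster")
  expect_equal(sc$true_gap_fraction, mean(occ))
  expect_equal(sc$labels, matrix(c(0L, 1L, 2L, 2L), 2, 2))
})
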