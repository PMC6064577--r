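#' Separation width for a designed gap fraction
#'
#' For a grid model canopy made of square openings of side `L` separated by
#' opaque bars of width `W`, the designed gap fraction is
#' `GF_d = L^2 / (L + W)^2`.  Inverting for `W` gives
#' `W = L / sqrt(GF_d) - L`.
#'
#' @param gf_designed Designed gap fraction, strictly between 0 and 1.
#' @param side_length Side length `L` of the square openings (mm), > 0.
#' @return Separation width `W` in mm.
#' @examples
#' separation_width(0.25, 2.5)  # 2.5
#' @export
separation_width <- function(gf_designed, side_length) {
  if (any(!is.finite(gf_designed)) || any(gf_designed <= 0) ||
      any(gf_designed >= 1)) {
    stop("`gf_designed` must lie strictly between 0 and 1")
  }
  if (any(!is.finite(side_length)) || any(side_length <= 0)) {
    stop("`side_length` must be positive")
  }
  side_length / sqrt(gf_designed) - side_length
}

#' Designed gap fraction of a grid canopy
#'
#' @param side_length Side length `L` of the square openings (mm), > 0.
#' @param separation Separation width `W` between openings (mm), >= 0.
#' @return Gap fraction `L^2 / (L + W)^2` in (0, 1].
#' @examples
#' designed_gap_fraction(2.5, 2.5)  # 0.25
#' @export
designed_gap_fraction <- function(side_length, separation) {
  if (any(!is.finite(side_length)) || any(side_length <= 0)) {
    stop("`side_length` must be positive")
  }
  if (any(!is.finite(separation)) || any(separation < 0)) {
    stop("`separation` must be non-negative")
  }
  side_length^2 / (side_length + separation)^2
}

#' Sky-canopy border length per unit area
#'
#' Each pattern period `(L + W)^2` contains one square opening whose
#' perimeter `4 L` is sky-canopy border, so the border length per unit
#' canopy area is `B = 4 L / (L + W)^2` (mm per mm^2).  Identically,
#' `B = 4 GF_d / L`.
#'
#' @inheritParams designed_gap_fraction
#' @return Border length per unit area (mm mm^-2).
#' @examples
#' scb_length_per_area(2.5, 2.5)  # 0.40
#' @export
scb_length_per_area <- function(side_length, separation) {
  if (any(!is.finite(side_length)) || any(side_length <= 0)) {
    stop("`side_length` must be positive")
  }
  if (any(!is.finite(separation)) || any(separation < 0)) {
    stop("`separation` must be non-negative")
  }
  4 * side_length / (side_length + separation)^2
}

#' Construct a model-canopy specification
#'
#' A `canopy_spec` describes one grid model canopy: square openings of side
#' `L` (mm) on an opaque sheet, separated by bars of width `W` (mm).  Either
#' `separation` or `gf_designed` must be supplied; the other is derived.
#'
#' @param side_length Side length `L` of square openings (mm).
#' @param separation Separation width `W` (mm), or `NULL` to derive it from
#'   `gf_designed`.
#' @param gf_designed Designed gap fraction, or `NULL` to derive it from
#'   `separation`.
#' @param sheet_width,sheet_height Physical sheet extent (mm).  Default
#'   200 x 210 mm.
#' @param id Optional identifier string.
#' @return An object of class `canopy_spec` with fields `side_length`,
#'   `separation`, `gf_designed`, `scb_per_area`, `sheet_width`,
#'   `sheet_height`, `id`.
#' @examples
#' canopy_spec(2.5, gf_designed = 0.25)
#' @export
canopy_spec <- function(side_length, separation = NULL, gf_designed = NULL,
                        sheet_width = 200, sheet_height = 210, id = NULL) {
  if (is.null(separation) && is.null(gf_designed)) {
    stop("supply either `separation` or `gf_designed`")
  }
  if (is.null(separation)) {
    separation <- separation_width(gf_designed, side_length)
  }
  gf <- designed_gap_fraction(side_length, separation)
  if (!is.null(gf_designed) && abs(gf - gf_designed) > 1e-9) {
    stop("`separation` and `gf_designed` are inconsistent")
  }
  if (is.null(id)) {
    id <- sprintf("gf%s_L%s", format(round(gf, 4)), format(side_length))
  }
  structure(
    list(
      side_length = side_length,
      separation = separation,
      gf_designed = gf,
      scb_per_area = scb_length_per_area(side_length, separation),
      sheet_width = sheet_width,
      sheet_height = sheet_height,
      id = id
    ),
    class = "canopy_spec"
  )
}

#' @export
print.canopy_spec <- function(x, ...) {
  cat(sprintf(
    "canopy_spec %s: L = %.2f mm, W = %.2f mm, GF_d = %.3f, B = %.3f mm/mm^2\n",
    x$id, x$side_length, x$separation, x$gf_designed, x$scb_per_area
  ))
  invisible(x)
}

#' Rescale a model canopy
#'
#' Scaling all lengths by `c` (equivalently, changing the camera-to-canopy
#' distance by `1/c`) leaves the gap fraction unchanged and divides the
#' border length per unit area by `c`: halving the scale doubles the border
#' length packed into a unit of image area.
#'
#' @param spec A [canopy_spec()].
#' @param factor Positive length scale factor.
#' @return A new `canopy_spec`.
#' @export
scale_canopy <- function(spec, factor) {
  stopifnot(inherits(spec, "canopy_spec"))
  if (!is.finite(factor) || factor <= 0) stop("`factor` must be positive")
  canopy_spec(
    side_length = spec$side_length * factor,
    separation = spec$separation * factor,
    sheet_width = spec$sheet_width * factor,
    sheet_height = spec$sheet_height * factor,
    id = if (factor == 1) spec$id else sprintf("%s_x%g", spec$id, factor)
  )
}

#' The 17-canopy design suite
#'
#' The full factorial of designed gap fraction {0.05, 0.10, 0.25, 0.50,
#' 0.75} by opening side length {2.5, 5, 10, 20} mm, minus the three
#' combinations whose separation width would be impractically large or small
#' to fabricate (gap fractions 0.05 and 0.10 with 20 mm openings, and 0.75
#' with 2.5 mm openings), giving 17 model canopies.
#'
#' @param gap_fractions,side_lengths Design levels; defaults give the
#'   standard 17-canopy suite.
#' @param drop Data frame of (gf_designed, side_length) combinations to
#'   omit; defaults to the three unfabricated cells.
#' @return A list of [canopy_spec()] objects.
#' @examples
#' length(generate_canopy_suite())  # 17
#' @export
generate_canopy_suite <- function(gap_fractions = c(0.05, 0.10, 0.25, 0.50, 0.75),
                                  side_lengths = c(2.5, 5, 10, 20),
                                  drop = data.frame(
                                    gf_designed = c(0.05, 0.10, 0.75),
                                    side_length = c(20, 20, 2.5)
                                  )) {
  grid <- expand.grid(
    side_length = side_lengths, gf_designed = gap_fractions,
    KEEP.OUT.ATTRS = FALSE
  )
  keep <- !(paste(grid$gf_designed, grid$side_length) %in%
              paste(drop$gf_designed, drop$side_length))
  grid <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    canopy_spec(grid$side_length[i], gf_designed = grid$gf_designed[i])
  })
}

#' Tabulate a canopy suite
#'
#' @param suite List of [canopy_spec()] objects.
#' @return A data.frame with columns `id`, `gf_designed`, `side_length_mm`,
#'   `separation_mm`, `scb_per_area`.
#' @export
canopy_suite_table <- function(suite = generate_canopy_suite()) {
  data.frame(
    id = vapply(suite, `[[`, character(1), "id"),
    gf_designed = vapply(suite, `[[`, numeric(1), "gf_designed"),
    side_length_mm = vapply(suite, `[[`, numeric(1), "side_length"),
    separation_mm = vapply(suite, `[[`, numeric(1), "separation"),
    scb_per_area = vapply(suite, `[[`, numeric(1), "scb_per_area"),
    stringsAsFactors = FALSE
  )
}

# Fraction of each pixel along one axis covered by openings, by area-averaging
# `supersample` sub-positions per pixel.  The opening pattern is separable:
# a point at position x (mm) lies over an opening iff
# ((x + offset) mod P) < L.  The offset places the raster edge mid-bar so
# that no sky-canopy border coincides with the image boundary (where blur
# padding would erase it).
axis_gap_fraction <- function(n_px, pixel_scale, period, side_length,
                              supersample, offset = 0) {
  ss <- supersample
  sub <- (rep(seq_len(n_px) - 1L, each = ss) +
            (rep.int(seq_len(ss), n_px) - 0.5) / ss) * pixel_scale
  in_gap <- ((sub + offset) %% period) < side_length
  colMeans(matrix(in_gap, nrow = ss))
}

#' Render a model canopy to a raster scene
#'
#' Rasterises the square-opening pattern onto a pixel grid.  Per-pixel sky
#' occupancy in \[0, 1\] is computed by area-averaging a `supersample` x
#' `supersample` binary sub-grid (the pattern is separable, so the average
#' factorises by axis).  The analysis region is an integer number of pattern
#' periods so that the continuous-space gap fraction of the region equals
#' the designed gap fraction exactly.  The pattern is positioned with half a
#' separation bar at the raster edge, so every sky-canopy border lies in the
#' raster interior (a border on the boundary would lose its mixed-pixel zone
#' to the blur padding) and the border length per unit area within the
#' region is exactly `B`.
#'
#' @param spec A [canopy_spec()].
#' @param pixel_scale mm per pixel, > 0.
#' @param supersample Sub-samples per pixel axis, >= 1.  Default 8 bounds
#'   the per-axis occupancy quantisation to 1/8 (1/64 per pixel).
#' @param extent_mm Target extent of the rendered region (mm); the actual
#'   region is the largest integer number of periods not exceeding it
#'   (at least one period, with a warning if a single period overflows the
#'   target).  Defaults to the sheet extent.
#' @return An object of class `scene_raster`: list with `occupancy` (matrix,
#'   rows = y), `labels` (integer matrix: 0 canopy, 1 grey, 2 sky),
#'   `pixel_scale`, `true_gap_fraction` (mean occupancy of the raster),
#'   `gf_designed`, `true_border_length` (analytic B, mm mm^-2), `spec`.
#' @examples
#' sc <- render_canopy(canopy_spec(2.5, gf_designed = 0.25),
#'                     pixel_scale = 0.25, extent_mm = 20)
#' mean(sc$occupancy)
#' @export
render_canopy <- function(spec, pixel_scale = 0.1, supersample = 8,
                          extent_mm = NULL) {
  stopifnot(inherits(spec, "canopy_spec"))
  if (!is.finite(pixel_scale) || pixel_scale <= 0) {
    stop("`pixel_scale` must be positive")
  }
  supersample <- as.integer(supersample)
  if (is.na(supersample) || supersample < 1L) {
    stop("`supersample` must be a positive integer")
  }
  if (is.null(extent_mm)) {
    extent_mm <- min(spec$sheet_width, spec$sheet_height)
  }
  if (!is.finite(extent_mm) || extent_mm <= 0) {
    stop("`extent_mm` must be positive")
  }
  period <- spec$side_length + spec$separation
  n_periods <- floor(extent_mm / period)
  if (n_periods < 1) {
    warning("requested extent is smaller than one pattern period; ",
            "rendering a single period")
    n_periods <- 1
  }
  extent <- n_periods * period
  n_px <- round(extent / pixel_scale)
  if (n_px < 1) stop("raster has zero size; decrease `pixel_scale`")

  fx <- axis_gap_fraction(n_px, pixel_scale, period, spec$side_length,
                          supersample, offset = spec$separation / 2)
  occupancy <- outer(fx, fx)  # rows = y, cols = x; pattern is symmetric
  labels <- matrix(1L, n_px, n_px)
  labels[occupancy == 0] <- 0L
  labels[occupancy == 1] <- 2L

  structure(
    list(
      occupancy = occupancy,
      labels = labels,
      pixel_scale = pixel_scale,
      true_gap_fraction = mean(occupancy),
      gf_designed = spec$gf_designed,
      true_border_length = spec$scb_per_area,
      spec = spec
    ),
    class = "scene_raster"
  )
}

#' @export
print.scene_raster <- function(x, ...) {
  cat(sprintf(
    "scene_raster: %d x %d px at %.3g mm/px, gap fraction %.4f (designed %.4f)\n",
    nrow(x$occupancy), ncol(x$occupancy), x$pixel_scale,
    x$true_gap_fraction, x$gf_designed
  ))
  invisible(x)
}

#' Build a scene from an arbitrary occupancy field
#'
#' Wraps a per-pixel sky-occupancy matrix (values in \[0, 1\]) as a
#' `scene_raster`, deriving labels and the raster gap fraction.  Useful for
#' custom fixtures such as straight-edge targets.
#'
#' @param occupancy Numeric matrix with values in \[0, 1\].
#' @param pixel_scale mm per pixel.
#' @param border_length Known border length per unit area (mm mm^-2), if
#'   any.
#' @param id Identifier for provenance.
#' @return A `scene_raster`.
#' @export
scene_from_occupancy <- function(occupancy, pixel_scale = 1,
                                 border_length = NA_real_, id = "custom") {
  stopifnot(is.matrix(occupancy), all(occupancy >= 0 & occupancy <= 1))
  labels <- matrix(1L, nrow(occupancy), ncol(occupancy))
  labels[occupancy == 0] <- 0L
  labels[occupancy == 1] <- 2L
  structure(
    list(
      occupancy = occupancy,
      labels = labels,
      pixel_scale = pixel_scale,
      true_gap_fraction = mean(occupancy),
      gf_designed = NA_real_,
      true_border_length = border_length,
      spec = list(id = id)
    ),
    class = "scene_raster"
  )
}

#' Scene label constants
#'
#' Integer codes used in `scene_raster$labels`: canopy pixels (occupancy 0)
#' are 0, mixed "grey" pixels (0 < occupancy < 1) are 1, sky pixels
#' (occupancy 1) are 2.
#' @format Named integer vector.
#' @export
SCENE_LABELS <- c(canopy = 0L, grey = 1L, sky = 2L)
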