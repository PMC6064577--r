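#' Camera configuration for the photograph simulator
#'
#' The simulator uses a minimal monotone radiometric model.  Scene radiance
#' is expressed relative to the unobscured sky: a pixel with sky occupancy
#' `o` has linear radiance `o + (1 - o) * canopy_radiance_ratio`.  Radiance
#' is blurred (optical blur precedes the sensor), scaled by `2^X` for an
#' exposure manipulation of `X` stops, passed through a gamma tone curve and
#' quantised to an 8-bit digital number (DN):
#' `DN = clip(round(sky_dn_at_reference * (radiance * 2^X)^(1/gamma)), 0, 255)`.
#'
#' @param sky_dn_at_reference DN of unobscured sky at exposure manipulation
#'   0 (reference exposure metered on the sky).  Default 60, which keeps the
#'   sky below saturation up to about +4.6 stop so the full -3..+5 stop
#'   study range stays informative; saturation ("blooming") still occurs at
#'   the top of the range.
#' @param canopy_radiance_ratio Fraction of sky radiance emitted by opaque
#'   canopy elements (default 0.01).
#' @param gamma Tone-curve exponent (default 2.2).
#' @param blur_sigma Gaussian optical blur scale in pixels (default 0.7, giving a mixed-pixel zone a few pixels wide as in a near-focused photograph).
#' @param mask_diameter Diameter (px) of the circular analysis region of the
#'   photograph (the image circle of a fisheye frame), or `NULL` (default)
#'   for a full-frame analysis region, which keeps the geometric ground
#'   truth of whole-period synthetic scenes exact.  See
#'   [apply_circular_mask()].
#' @param threshold_radiance Sky-relative radiance whose DN defines the
#'   camera's matched (stop-equivalent) threshold; see
#'   [camera_threshold_model()].  Default 0.45, slightly below the 50/50
#'   sky-canopy mixture so that a threshold one stop high still lies below
#'   the pure-sky tone (only mixed pixels are misclassified at one stop of
#'   mismatch, matching the behaviour of calibrated cameras whose optimal
#'   threshold sits below the canopy-sky midpoint).
#' @param noise_sd Optional Gaussian DN noise standard deviation (default 0,
#'   the deterministic model).
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(sky_dn_at_reference = 60,
                          canopy_radiance_ratio = 0.01,
                          gamma = 2.2,
                          blur_sigma = 0.7,
                          mask_diameter = NULL,
                          threshold_radiance = 0.45,
                          noise_sd = 0) {
  stopifnot(
    sky_dn_at_reference > 0, sky_dn_at_reference <= 255,
    canopy_radiance_ratio >= 0, canopy_radiance_ratio < 1,
    gamma > 0, blur_sigma >= 0, noise_sd >= 0,
    threshold_radiance > 0, threshold_radiance < 1
  )
  structure(
    list(
      sky_dn_at_reference = sky_dn_at_reference,
      canopy_radiance_ratio = canopy_radiance_ratio,
      gamma = gamma,
      blur_sigma = blur_sigma,
      mask_diameter = mask_diameter,
      threshold_radiance = threshold_radiance,
      noise_sd = noise_sd
    ),
    class = "camera_config"
  )
}

# Continuous (unclipped, unrounded) DN of a sky-relative radiance at
# exposure manipulation `stops`.
dn_continuous <- function(radiance, stops, cfg) {
  cfg$sky_dn_at_reference * (radiance * 2^stops)^(1 / cfg$gamma)
}

clip_dn <- function(dn) pmin(pmax(dn, 0), 255)

#' Simulate the acquisition of a photograph
#'
#' Renders a [render_canopy()] scene through the radiometric model of
#' [camera_config()]: linear radiance from occupancy, Gaussian optical blur,
#' exposure scaling by `2^stops`, gamma tone mapping, rounding and clipping
#' to 8-bit.  DN is monotonically non-decreasing in `stops` for every pixel;
#' clipping at 255 reproduces the saturation ("blooming") regime at high
#' exposure.
#'
#' @param scene A `scene_raster`.
#' @param stops Exposure manipulation X in stops relative to the reference
#'   exposure.
#' @param cfg A [camera_config()].
#' @return An object of class `photograph`: list with `dn` (integer matrix),
#'   `mask` (logical matrix), `exposure` (X), `blur_sigma`, `cfg`, and
#'   ground-truth provenance `labels`, `gap_fraction_true` (mean occupancy
#'   within the mask), `scb_per_area`, `pixel_scale`, `canopy_id`.
#' @export
simulate_photograph <- function(scene, stops, cfg = camera_config()) {
  stopifnot(inherits(scene, "scene_raster"), is.finite(stops))
  occ <- scene$occupancy
  radiance <- occ + (1 - occ) * cfg$canopy_radiance_ratio
  if (cfg$blur_sigma > 0) {
    radiance <- gaussian_blur(radiance, cfg$blur_sigma)
  }
  dn <- clip_dn(round(dn_continuous(radiance, stops, cfg)))
  if (cfg$noise_sd > 0) {
    dn <- clip_dn(round(dn + stats::rnorm(length(dn), 0, cfg$noise_sd)))
  }
   storage.mode(dn) <- "integer"

  mask <- if (is.null(cfg$mask_diameter)) {
    # full rectangular frame: over whole pattern periods the geometric
    # ground truth (gap fraction, border length per area) is then exact
    matrix(TRUE, nrow(dn), ncol(dn))
  } else {
    circular_mask(dim(dn), cfg$mask_diameter)
  }

  structure(
    list(
      dn = dn,
      mask = mask,
      exposure = stops,
      blur_sigma = cfg$blur_sigma,
      cfg = cfg,
      labels = scene$labels,
      occupancy = scene$occupancy,
      gap_fraction_true = mean(scene$occupancy[mask]),
      scb_per_area = scene$true_border_length,
      gf_designed = scene$gf_designed,
      pixel_scale = scene$pixel_scale,
      canopy_id = scene$spec$id
    ),
    class = "photograph"
  )
}

#' @export
print.photograph <- function(x, ...) {
  cat(sprintf(
    "photograph %s: %d x %d px, X = %+g stop, blur sigma %.2g px, %d masked px\n",
    x$canopy_id %||% "?", nrow(x$dn), ncol(x$dn), x$exposure, x$blur_sigma,
    sum(x$mask)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Logical mask of pixels whose centres lie within `diameter / 2` of the
# image centre.
circular_mask <- function(dims, diameter) {
  if (!is.finite(diameter) || diameter <= 0) {
    stop("`diameter` must be positive")
  }
  nr <- dims[1]
  nc <- dims[2]
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  dy <- (seq_len(nr) - cy)^2
  dx <- (seq_len(nc) - cx)^2
  outer(dy, dx, `+`) <= (diameter / 2)^2
}

#' Restrict a photograph to a circular analysis region
#'
#' Replaces the photograph's analysis mask by the set of pixels whose
#' centres lie within `diameter / 2` of the image centre, and updates the
#' masked ground-truth gap fraction accordingly.
#'
#' @param photo A `photograph`.
#' @param diameter Mask diameter in pixels; values larger than the image are
#'   capped at the full frame.
#' @return The photograph with the new mask.
#' @export
apply_circular_mask <- function(photo, diameter) {
  stopifnot(inherits(photo, "photograph"))
  diameter <- min(diameter, sqrt(sum(dim(photo$dn)^2)))  # cap: full frame
  photo$mask <- circular_mask(dim(photo$dn), diameter)
  if (!is.null(photo$occupancy)) {
    # ground truth follows the analysis region for synthetic photographs
    photo$gap_fraction_true <- mean(photo$occupancy[photo$mask])
  }
  photo
}
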