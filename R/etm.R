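#' Logistic exposure/optimal-threshold calibration
#'
#' Calibration constants of the logistic model linking exposure manipulation
#' `X` (stops) to the optimal 8-bit threshold `Y`:
#' `Y = a / (1 + exp((-X + x0) / s))`.
#' The defaults are the published calibration of the source camera
#' (`a = 260.542`, `x0 = 1.422`, `s = 1.160`); real-valued thresholds are
#' mapped to integers by `floor` and clamped to 0..255 (the asymptote
#' exceeds the DN range).
#'
#' @param a Asymptote (DN).
#' @param x0 Midpoint (stop).
#' @param s Scale (stop).
#' @param rounding `"floor"` (default) or `"round"`.
#' @return Object of class `etm_params`.
#' @export
etm_params <- function(a = 260.542, x0 = 1.422, s = 1.160,
                       rounding = c("floor", "round")) {
  stopifnot(a > 0, s > 0)
  structure(
    list(a = a, x0 = x0, s = s, rounding = match.arg(rounding)),
    class = "etm_params"
  )
}

round_threshold <- function(y, params) {
  y <- switch(params$rounding, floor = floor(y), round = round(y))
  as.integer(pmin(pmax(y, 0), 255))
}

#' Optimal threshold for an exposure manipulation
#'
#' Evaluates the logistic calibration at `X` stops and maps the result to an
#' integer DN.  With the default constants, `optimal_threshold(+2) = 162`
#' and `optimal_threshold(-1) = 28`.
#'
#' @param X Exposure manipulation in stops (vectorised).
#' @param params An [etm_params()].
#' @return Integer threshold DN(s) in 0..255.
#' @export
optimal_threshold <- function(X, params = etm_params()) {
  stopifnot(all(is.finite(X)))
  y <- params$a / (1 + exp((-X + params$x0) / params$s))
  round_threshold(y, params)
}

#' Thresholding manipulation of a threshold value
#'
#' Inverts the logistic calibration: the thresholding manipulation of a
#' threshold DN `t` is the stop value whose optimal threshold equals `t`,
#' `S_t = x0 - s * log(a / t - 1)`.
#'
#' @param threshold Threshold DN(s), each in (0, a).
#' @param params An [etm_params()].
#' @return Thresholding manipulation(s) in stops.
#' @export
thresholding_manipulation <- function(threshold, params = etm_params()) {
  if (any(threshold <= 0 | threshold >= params$a)) {
    stop("threshold must lie strictly between 0 and the asymptote")
  }
  params$x0 - params$s * log(params$a / threshold - 1)
}

#' Exposure-thresholding-mismatch extent
#'
#' The ETM extent is the thresholding manipulation subtracted from the
#' exposure manipulation, `M = X - S_t`.  Zero means matched (correct)
#' analysis; positive values overestimate the gap fraction, negative values
#' underestimate it.
#'
#' @param X Exposure manipulation (stop).
#' @param S_t Thresholding manipulation (stop).
#' @return ETM extent in stops.
#' @export
etm_extent <- function(X, S_t) {
  stopifnot(all(is.finite(X)), all(is.finite(S_t)))
  X - S_t
}

#' Gap-fraction estimation inaccuracy
#'
#' @param gf_photo Photographed (estimated) gap fraction.
#' @param gf_ref Reference (correct) gap fraction.
#' @return Signed inaccuracy `gf_photo - gf_ref` in \[-1, 1\].
#' @export
inaccuracy <- function(gf_photo, gf_ref) {
  stopifnot(all(gf_photo >= 0 & gf_photo <= 1),
            all(gf_ref >= 0 & gf_ref <= 1))
  gf_photo - gf_ref
}

#' Threshold models: stop to DN
#'
#' A threshold model converts a thresholding manipulation in stops to an
#' integer threshold DN.  Two models are provided:
#' `logistic_threshold_model()` wraps the published [etm_params()]
#' calibration of the source camera, and `camera_threshold_model()` derives
#' the curve of the package's own simulator from its [camera_config()]: the
#' optimal threshold for exposure `S` is the DN the camera assigns to the
#' radiance `threshold_radiance` (a sky-canopy mixture slightly below the
#' midpoint) at exposure `S`.
#'
#' @param params An [etm_params()].
#' @return An object with class `threshold_model`.
#' @export
logistic_threshold_model <- function(params = etm_params()) {
  structure(list(kind = "logistic", params = params),
            class = c("logistic_threshold_model", "threshold_model"))
}

#' @rdname logistic_threshold_model
#' @param cfg A [camera_config()].
#' @export
camera_threshold_model <- function(cfg) {
  stopifnot(inherits(cfg, "camera_config"))
  structure(list(kind = "camera", cfg = cfg),
            class = c("camera_threshold_model", "threshold_model"))
}

#' Threshold DN for a thresholding manipulation
#'
#' @param model A threshold model.
#' @param S_t Thresholding manipulation in stops (vectorised).
#' @return Integer threshold DN(s).
#' @export
threshold_for_stop <- function(model, S_t) UseMethod("threshold_for_stop")

#' @export
threshold_for_stop.logistic_threshold_model <- function(model, S_t) {
  optimal_threshold(S_t, model$params)
}

#' @export
threshold_for_stop.camera_threshold_model <- function(model, S_t) {
  cfg <- model$cfg
  y <- dn_continuous(cfg$threshold_radiance, S_t, cfg)
  as.integer(pmin(pmax(floor(y), 0), 255))
}

#' Matched threshold of a synthetic photograph
#'
#' The integer threshold whose gap fraction is closest to the photograph's
#' ground-truth gap fraction; ties resolve to the lower DN.  Used to define
#' the zero-mismatch reference classification for synthetic scenes.
#'
#' @param photo A `photograph` with ground truth.
#' @param hist Optional precomputed [greyness_histogram()].
#' @return Integer threshold DN.
#' @export
matched_threshold <- function(photo, hist = NULL) {
  stopifnot(inherits(photo, "photograph"))
  if (is.null(photo$gap_fraction_true)) stop("photograph has no ground truth")
  if (is.null(hist)) hist <- greyness_histogram(photo)
  gf <- gap_fraction_at_threshold(hist, 0:255)
  which.min(abs(gf - photo$gap_fraction_true)) - 1L
}

#' Analyse a photograph under a thresholding manipulation
#'
#' Applies the threshold corresponding to `S_t` stops, computes the gap
#' fraction, the ETM extent `M = X - S_t`, the inaccuracy against the
#' reference gap fraction, and the grey-pixel summary.
#'
#' @param photo A `photograph` with a recorded exposure manipulation.
#' @param S_t Thresholding manipulation in stops.
#' @param model Threshold model; defaults to the simulator's own
#'   [camera_threshold_model()] for synthetic photographs.
#' @param gf_ref Reference gap fraction; defaults to the photograph's
#'   ground truth.
#' @param hist Optional precomputed [greyness_histogram()].
#' @param grey Optional precomputed [grey_pixel_bounds()].
#' @param mpz_fraction Optional MPZ fraction to carry along in the record.
#' @return A one-row data.frame (analysis record) with columns `canopy_id`,
#'   `gf_designed`, `scb_per_area`, `exposure`, `threshold_stop`,
#'   `etm_extent`, `threshold_dn`, `gf_est`, `gf_true`, `inaccuracy`,
#'   `grey_fraction`, `t_low`, `t_high`, `mpz_fraction`.
#' @export
analyze_with_etm <- function(photo, S_t, model = NULL, gf_ref = NULL,
                             hist = NULL, grey = NULL, mpz_fraction = NA_real_) {
  stopifnot(inherits(photo, "photograph"), is.finite(S_t))
  if (is.null(model)) model <- camera_threshold_model(photo$cfg)
  if (is.null(gf_ref)) gf_ref <- photo$gap_fraction_true
  if (is.null(gf_ref)) stop("no reference gap fraction available")
  if (is.null(hist)) hist <- greyness_histogram(photo)
  if (is.null(grey)) grey <- grey_pixel_bounds(hist)
  thr <- threshold_for_stop(model, S_t)
  gf_est <- gap_fraction_at_threshold(hist, thr)
  data.frame(
    canopy_id = photo$canopy_id %||% NA_character_,
    gf_designed = photo$gf_designed %||% NA_real_,
    scb_per_area = photo$scb_per_area %||% NA_real_,
    exposure = photo$exposure,
    threshold_stop = S_t,
    etm_extent = etm_extent(photo$exposure, S_t),
    threshold_dn = thr,
    gf_est = gf_est,
    gf_true = gf_ref,
    inaccuracy = inaccuracy(gf_est, gf_ref),
    grey_fraction = grey$grey_fraction,
    t_low = grey$t_low,
    t_high = grey$t_high,
    mpz_fraction = mpz_fraction,
    stringsAsFactors = FALSE
  )
}
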