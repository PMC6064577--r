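#' Greyness histogram of a photograph
#'
#' Exact pixel counts per digital number (0..255) inside the analysis mask.
#'
#' @param photo A `photograph`, or an integer DN matrix.
#' @param mask Logical matrix; defaults to the photograph's mask (full frame
#'   for a bare matrix).
#' @return Object of class `greyness_histogram`: list with `dn` (0:255),
#'   `counts` (256 integers) and `total`.
#' @export
greyness_histogram <- function(photo, mask = NULL) {
  if (inherits(photo, "photograph")) {
    dn <- photo$dn
    if (is.null(mask)) mask <- photo$mask
  } else {
    dn <- photo
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dn), ncol(dn))
  vals <- dn[mask]
  if (length(vals) == 0) stop("empty analysis mask")
  if (any(vals < 0 | vals > 255)) stop("DN values outside 0..255")
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  structure(
    list(dn = 0:255, counts = counts, total = length(vals)),
    class = "greyness_histogram"
  )
}

#' @export
print.greyness_histogram <- function(x, ...) {
  nz <- range(which(x$counts > 0)) - 1L
  cat(sprintf("greyness_histogram: %d px, DN range %d..%d\n",
              x$total, nz[1], nz[2]))
  invisible(x)
}

#' Gap fraction at a threshold
#'
#' The gap fraction for threshold `i` is the fraction of masked pixels with
#' digital number greater than or equal to `i`.  Non-increasing in `i`.
#'
#' @param hist A [greyness_histogram()].
#' @param i Threshold DN (may be a vector), each in 0..255.
#' @return Gap fraction(s) in \[0, 1\].
#' @export
gap_fraction_at_threshold <- function(hist, i) {
  stopifnot(inherits(hist, "greyness_histogram"))
  if (any(i < 0 | i > 255)) stop("threshold outside 0..255")
  tail_ge <- rev(cumsum(rev(hist$counts)))  # tail_ge[d+1] = #\{DN >= d\}
  tail_ge[as.integer(i) + 1L] / hist$total
}

#' Gap-fraction curve over all thresholds
#'
#' @param hist A [greyness_histogram()].
#' @return data.frame with columns `dn` and `gap_fraction`.
#' @export
gap_fraction_curve <- function(hist) {
  data.frame(dn = 0:255, gap_fraction = gap_fraction_at_threshold(hist, 0:255))
}

# Centred moving average with window truncation at the ends.
smooth_counts <- function(counts, window) {
  half <- (window - 1L) %/% 2L
  n <- length(counts)
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Grey-pixel bounds and fraction from a greyness histogram
#'
#' Locates the canopy hump (dark) and sky hump (bright) of the histogram and
#' the "sharp turns" where each hump ends: scanning from a hump's peak
#' towards the other hump, the hump ends at the last DN before the smoothed
#' count first falls below `alpha` times the hump's peak.  `t_low` is the
#' top of the canopy hump and `t_high` the bottom of the sky hump; grey
#' pixels are those with `t_low < DN < t_high` (open interval, so the bound
#' DNs belong to canopy/sky).  If only one hump is detected (overexposure or
#' a canopy too fine to leave pure pixels), its identity is decided by where
#' the remaining histogram mass lies -- grey pixels trail below a sky hump
#' and above a canopy hump -- and the missing bound collapses to the
#' histogram edge (0 or 255).
#'
#' @param hist A [greyness_histogram()].
#' @param alpha Peak fraction defining the end of a hump (default 0.05).
#' @param window Smoothing window in DN bins.  The default 1 (no smoothing)
#'   suits noise-free counts, where the pure-sky and pure-canopy humps are
#'   near-spikes that smoothing would flatten into the grey bridge; widen it
#'   for noisy sensors.
#' @param t_low,t_high Optional explicit bounds overriding detection.
#' @return Object of class `grey_pixel_summary`: list with `t_low`,
#'   `t_high`, `grey_fraction`, `canopy_peak`, `sky_peak` (NA when not
#'   detected).
#' @export
grey_pixel_bounds <- function(hist, alpha = 0.05, window = 1,
                              t_low = NULL, t_high = NULL) {
  stopifnot(inherits(hist, "greyness_histogram"))
  s <- smooth_counts(hist$counts, window)
  canopy_peak <- NA_integer_
  sky_peak <- NA_integer_

  if (is.null(t_low) || is.null(t_high)) {
    p1 <- which.max(s)  # 1-based index; DN = p1 - 1
    # second hump: the highest smoothed count on either side of p1 that is
    # separated from p1 by a valley falling below alpha * its own height
    find_second <- function(idx) {
      if (length(idx) == 0) return(NULL)
      best <- idx[which.max(s[idx])]
      valley <- min(s[seq(min(best, p1), max(best, p1))])
      if (s[best] > 0 && valley < alpha * s[best]) best else NULL
    }
    left <- find_second(seq_len(p1 - 1L))
    right <- find_second(if (p1 < 256L) seq(p1 + 1L, 256L) else integer(0))
    p2 <- if (is.null(left) && is.null(right)) {
      NULL
    } else if (is.null(left)) {
      right
    } else if (is.null(right)) {
      left
    } else if (s[left] >= s[right]) left else right

    if (is.null(p2)) {
      # single hump: grey mass trails below a sky hump / above a canopy
      # hump, so assign identity by where the off-peak mass sits
      mass_below <- if (p1 > 1L) sum(s[seq_len(p1 - 1L)]) else 0
      mass_above <- if (p1 < 256L) sum(s[seq(p1 + 1L, 256L)]) else 0
      if (mass_below >= mass_above) {
        sky_peak <- p1 - 1L
      } else {
        canopy_peak <- p1 - 1L
      }
    } else {
      canopy_peak <- min(p1, p2) - 1L
      sky_peak <- max(p1, p2) - 1L
    }

    hump_end <- function(peak_dn, direction) {
      # last DN (scanning in `direction`) before smoothed count < alpha*peak
      peak_val <- s[peak_dn + 1L]
      d <- peak_dn
      while (d + direction >= 0L && d + direction <= 255L &&
             s[d + direction + 1L] >= alpha * peak_val) {
        d <- d + direction
      }
      d
    }
    if (is.null(t_low)) {
      t_low <- if (is.na(canopy_peak)) 0L else hump_end(canopy_peak, 1L)
    }
    if (is.null(t_high)) {
      t_high <- if (is.na(sky_peak)) 255L else hump_end(sky_peak, -1L)
    }
  }
  t_low <- as.integer(t_low)
  t_high <- as.integer(t_high)
  if (t_low > t_high) {
    # humps merged or bounds crossed: no resolvable grey band
    t_low <- t_high <- as.integer(round((t_low + t_high) / 2))
  }
  grey <- if (t_high - t_low >= 2L) {
    sum(hist$counts[(t_low + 2L):t_high]) / hist$total  # DN in (t_low, t_high)
  } else {
    0
  }
  structure(
    list(t_low = t_low, t_high = t_high, grey_fraction = grey,
         canopy_peak = canopy_peak, sky_peak = sky_peak),
    class = "grey_pixel_summary"
  )
}

#' @export
print.grey_pixel_summary <- function(x, ...) {
  cat(sprintf(
    "grey pixels: bounds (%d, %d), fraction %.4f\n",
    x$t_low, x$t_high, x$grey_fraction
  ))
  invisible(x)
}

#' Binarize a photograph
#'
#' Pixels with DN greater than or equal to the threshold are classified as
#' sky, the rest as canopy; the gap fraction of the resulting map equals
#' [gap_fraction_at_threshold()] at the same threshold by construction.
#'
#' @param photo A `photograph` or integer DN matrix.
#' @param threshold Threshold DN in 0..255.
#' @param mask Optional logical mask (defaults to the photograph's).
#' @return Object of class `binary_map`: list with `sky` (logical matrix),
#'   `mask`, `threshold`.
#' @export
binarize <- function(photo, threshold, mask = NULL) {
  if (threshold < 0 || threshold > 255) stop("threshold outside 0..255")
  if (inherits(photo, "photograph")) {
    dn <- photo$dn
    if (is.null(mask)) mask <- photo$mask
  } else {
    dn <- photo
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dn), ncol(dn))
  structure(
    list(sky = dn >= threshold, mask = mask, threshold = threshold),
    class = "binary_map"
  )
}

#' Gap fraction of a binary map
#'
#' @param bin A [binarize()] result.
#' @return Fraction of masked pixels classified as sky.
#' @export
gap_fraction <- function(bin) {
  stopifnot(inherits(bin, "binary_map"))
  mean(bin$sky[bin$mask])
}

#' Misclassification map against ground truth
#'
#' Classifies every masked pixel of a binary map into four categories:
#' correctly classified sky (white), correctly classified canopy (black),
#' misclassified as sky (red) and misclassified as canopy (blue).  Pure sky
#' and canopy pixels are judged against their ground-truth labels; mixed
#' ("grey") pixels have no true binary class and are judged against a
#' reference classification obtained with matched exposure and thresholding.
#'
#' @param bin A [binarize()] result.
#' @param labels Integer label matrix ([SCENE_LABELS] codes).
#' @param reference A [binarize()] result at matched (zero-mismatch)
#'   thresholding, used to judge grey pixels.
#' @return Object of class `misclassification_map`: list with `category`
#'   (integer matrix: 1 correct sky, 2 correct canopy, 3 false sky,
#'   4 false canopy, NA outside mask) and `counts` (named vector).
#' @export
misclassification_map <- function(bin, labels, reference) {
  stopifnot(inherits(bin, "binary_map"), inherits(reference, "binary_map"))
  if (!all(dim(bin$sky) == dim(labels)) ||
      !all(dim(bin$sky) == dim(reference$sky))) {
    stop("geometry mismatch between map, labels and reference")
  }
  truth_sky <- reference$sky
  truth_sky[labels == SCENE_LABELS[["sky"]]] <- TRUE
  truth_sky[labels == SCENE_LABELS[["canopy"]]] <- FALSE

  category <- matrix(NA_integer_, nrow(labels), ncol(labels))
  m <- bin$mask
  category[m & bin$sky & truth_sky] <- 1L
  category[m & !bin$sky & !truth_sky] <- 2L
  category[m & bin$sky & !truth_sky] <- 3L
  category[m & !bin$sky & truth_sky] <- 4L
  counts <- c(
    correct_sky = sum(category == 1L, na.rm = TRUE),
    correct_canopy = sum(category == 2L, na.rm = TRUE),
    false_sky = sum(category == 3L, na.rm = TRUE),
    false_canopy = sum(category == 4L, na.rm = TRUE)
  )
  structure(
    list(category = category, counts = counts, masked = sum(m)),
    class = "misclassification_map"
  )
}

#' @export
print.misclassification_map <- function(x, ...) {
  cat("misclassification map (pixels):\n")
  print(x$counts)
  invisible(x)
}

#' Misclassified pixel count
#'
#' @param mis A [misclassification_map()].
#' @return Number of masked pixels classified differently from truth.
#' @export
misclassified_count <- function(mis) {
  unname(mis$counts[["false_sky"]] + mis$counts[["false_canopy"]])
}

#' Write a misclassification map as an RGB image
#'
#' Colour code: correct sky white, correct canopy black, misclassified as
#' sky red, misclassified as canopy blue; pixels outside the mask mid-grey.
#'
#' @param mis A [misclassification_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_misclassification_png <- function(mis, path) {
  cat_rgb <- rbind(
    c(0.5, 0.5, 0.5),  # outside mask
    c(1, 1, 1),        # correct sky
    c(0, 0, 0),        # correct canopy
    c(1, 0, 0),        # false sky
    c(0, 0, 1)         # false canopy
  )
  idx <- mis$category
  idx[is.na(idx)] <- 0L
  arr <- array(0, c(nrow(idx), ncol(idx), 3))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(cat_rgb[idx + 1L, ch], nrow(idx), ncol(idx))
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Mixed-pixel-zone measurement by Sobel edge detection
#'
#' Applies the standard 3x3 Sobel operator to a correctly thresholded binary
#' map (0/1) with replicate border padding, in the manner of ImageJ's "Find
#' edges".  Any pixel with non-zero gradient magnitude is an edge (MPZ)
#' pixel; on a hard binary edge this marks the pixels on both flanks, a
#' two-pixel-wide zone.  The MPZ fraction (edge pixels / masked pixels)
#' approximates the sky-canopy border length per unit area.
#'
#' @param bin A [binarize()] result.
#' @return Object of class `mpz_result`: list with `edge_mask` (logical
#'   matrix) and `mpz_fraction`.
#' @export
mpz_sobel <- function(bin) {
  stopifnot(inherits(bin, "binary_map"))
  g <- sobel_magnitude(bin$sky * 1)
  edge <- g > 1e-9
  structure(
    list(edge_mask = edge, mpz_fraction = mean(edge[bin$mask])),
    class = "mpz_result"
  )
}

#' 10-90% edge-response distance and sharpness
#'
#' Averages the DN profile perpendicular to a straight vertical or
#' horizontal edge and measures the distance between the linearly
#' interpolated 10% and 90% crossings of the low-to-high amplitude.  The
#' reciprocal is the image sharpness used in the grey-fraction model
#' `F = B/S + G`.  For a step edge blurred with a Gaussian of scale
#' `sigma` px (linear tone curve), the expected distance is
#' `2 * qnorm(0.9) * sigma ~= 2.5631 * sigma`.
#'
#' @param photo A `photograph` or numeric matrix containing a straight edge.
#' @param orientation `"vertical"` (edge parallel to image rows' columns;
#'   profile taken across columns) or `"horizontal"`.
#' @return Object of class `sharpness_estimate`: list with `rise_distance`
#'   (px) and `sharpness` (1/px).
#' @export
edge_response_distance <- function(photo, orientation = c("vertical",
                                                          "horizontal")) {
  orientation <- match.arg(orientation)
  m <- if (inherits(photo, "photograph")) photo$dn else photo
  profile <- if (orientation == "vertical") colMeans(m) else rowMeans(m)
  lo <- min(profile)
  hi <- max(profile)
  if (hi - lo <= 0) stop("edge has zero amplitude")
  if (which.min(profile) > which.max(profile)) profile <- rev(profile)
  level <- function(q) {
    y <- lo + q * (hi - lo)
    above <- which(profile >= y)
    i <- above[1]
    if (i == 1L) return(1)
    # linear interpolation between the bracketing samples
    (i - 1) + (y - profile[i - 1]) / (profile[i] - profile[i - 1])
  }
  x10 <- level(0.10)
  x90 <- level(0.90)
  d <- x90 - x10
  if (!is.finite(d) || d <= 0) stop("no monotone 10-90% crossing found")
  structure(
    list(rise_distance = d, sharpness = 1 / d),
    class = "sharpness_estimate"
  )
}
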