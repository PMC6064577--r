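#' Least-squares slope through the origin
#'
#' @param x,y Numeric vectors of equal length.
#' @return The zero-intercept least-squares slope `sum(x*y) / sum(x^2)`.
#' @examples
#' zero_intercept_slope(c(1, 2), c(2, 4))  # 2
#' @export
zero_intercept_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  sxx <- sum(x^2)
  if (sxx == 0) stop("all x are zero; slope undefined")
  sum(x * y) / sxx
}

#' Homogeneity-of-slopes F-test for zero-intercept regressions
#'
#' Tests whether `k` groups of (x, y) observations share a common
#' zero-intercept regression slope.  The total sum of squares (SST) is the
#' residual sum of squares about the grand zero-intercept line fitted to the
#' pooled data; the within-group sum of squares (SSW) is the residual sum of
#' squares about the group-specific lines; the between-group sum of squares
#' is obtained by subtraction, SSB = SST - SSW (clipped at zero against
#' floating-point cancellation).  With DFB = k - 1 and DFW = n - k,
#' `F = (SSB/DFB) / (SSW/DFW)` and the p-value is the upper tail of the
#' F(DFB, DFW) distribution.
#'
#' @param x,y Numeric vectors of observations.
#' @param group Grouping vector (coerced to factor), at least two groups.
#' @return Object of class `slope_ftest`: list with `n`, `k`, `slopes`
#'   (named per-group), `grand_slope`, `SST`, `SSW`, `SSB`, `DFB`, `DFW`,
#'   `F_value`, `p_value`.
#' @examples
#' x <- c(1, 2, 1, 2); y <- c(1, 2.2, 2, 3.8)
#' g <- c("a", "a", "b", "b")
#' slope_homogeneity_ftest(x, y, g)$F_value  # 220.5
#' @export
slope_homogeneity_ftest <- function(x, y, group) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  group <- factor(group)
  k <- nlevels(group)
  n <- length(x)
  if (k < 2) stop("at least two groups are required")
  if (n - k < 1) stop("no within-group degrees of freedom")
  if (any(tabulate(group) == 0)) stop("every group must be non-empty")

  grand <- zero_intercept_slope(x, y)
  SST <- sum((y - grand * x)^2)
  slopes <- vapply(levels(group), function(g) {
    i <- group == g
    zero_intercept_slope(x[i], y[i])
  }, numeric(1))
  SSW <- sum((y - slopes[as.integer(group)] * x)^2)
  SSB <- max(SST - SSW, 0)
  DFB <- k - 1L
  DFW <- n - k
  if (SSW == 0) {
    F_value <- if (SSB == 0) 0 else Inf
    p_value <- if (SSB == 0) 1 else 0
  } else {
    F_value <- (SSB / DFB) / (SSW / DFW)
    p_value <- stats::pf(F_value, DFB, DFW, lower.tail = FALSE)
  }
  structure(
    list(n = n, k = k, slopes = slopes, grand_slope = grand,
         SST = SST, SSW = SSW, SSB = SSB, DFB = DFB, DFW = DFW,
         F_value = F_value, p_value = p_value),
    class = "slope_ftest"
  )
}

#' @export
print.slope_ftest <- function(x, ...) {
  cat(sprintf(
    "Zero-intercept slope homogeneity: F(%d, %d) = %.4g, p = %.4g\n",
    x$DFB, x$DFW, x$F_value, x$p_value
  ))
  cat("group slopes:", paste(sprintf("%s = %.4g", names(x$slopes), x$slopes),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Fit the grey-fraction model F = B/S + G
#'
#' Ordinary least squares of the grey-pixel fraction on the sky-canopy
#' border length per unit area across canopies.  The slope is interpreted as
#' the reciprocal of image sharpness (the effective mixed-pixel-zone width,
#' in image-plane length units per pixel) and the intercept as the fraction
#' of grey pixels arising from sources other than sky-canopy borders.
#'
#' @param scb Border length per unit area `B` (x).
#' @param grey_fraction Grey-pixel fraction `F` (y).
#' @return Object of class `grey_fraction_fit`: list with `inv_sharpness`
#'   (slope), `sharpness` (its reciprocal), `G` (intercept), `r2`, `fit`
#'   (the underlying `lm`).
#' @export
fit_grey_fraction_model <- function(scb, grey_fraction) {
  stopifnot(length(scb) == length(grey_fraction), length(scb) >= 3)
  if (length(unique(scb)) < 2) stop("degenerate design: B does not vary")
  fit <- stats::lm(grey_fraction ~ scb)
  co <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((grey_fraction - mean(grey_fraction))^2)
  structure(
    list(
      inv_sharpness = unname(co[2]),
      sharpness = 1 / unname(co[2]),
      G = unname(co[1]),
      r2 = if (tss > 0) 1 - rss / tss else 1,
      fit = fit
    ),
    class = "grey_fraction_fit"
  )
}

#' @export
print.grey_fraction_fit <- function(x, ...) {
  cat(sprintf(
    "grey-fraction model: F = %.4g * B + %.4g (r^2 = %.4f); sharpness S = %.4g\n",
    x$inv_sharpness, x$G, x$r2, x$sharpness
  ))
  invisible(x)
}

#' Fit the inaccuracy model I = M * F
#'
#' For each level of the ETM extent `M`, fits a zero-intercept regression of
#' the inaccuracy `I` on the grey-pixel fraction `F` across canopies, and
#' additionally fits the pooled zero-intercept regression of `I` on the
#' product `M * F`.
#'
#' @param records A data.frame with columns `etm_extent`, `grey_fraction`
#'   and `inaccuracy` (as produced by [analyze_with_etm()] or
#'   [run_experiment()]).
#' @return Object of class `inaccuracy_fit`: list with `slopes` (data.frame
#'   of `etm_extent`, `slope`, `n`), `slope_ratios` (consecutive ratios) and
#'   `pooled_slope` (of `I` on `M * F`).
#' @export
fit_inaccuracy_model <- function(records) {
  need <- c("etm_extent", "grey_fraction", "inaccuracy")
  stopifnot(all(need %in% names(records)))
  levels_m <- sort(unique(records$etm_extent))
  if (length(levels_m) < 2) stop("need records at two or more ETM extents")
  slopes <- do.call(rbind, lapply(levels_m, function(m) {
    r <- records[records$etm_extent == m, ]
    data.frame(
      etm_extent = m,
      slope = zero_intercept_slope(r$grey_fraction, r$inaccuracy),
      n = nrow(r)
    )
  }))
  ratios <- if (nrow(slopes) > 1) {
    slopes$slope[-1] / slopes$slope[-nrow(slopes)]
  } else {
    numeric(0)
  }
  pooled <- zero_intercept_slope(records$etm_extent * records$grey_fraction,
                                 records$inaccuracy)
  structure(
    list(slopes = slopes, slope_ratios = ratios, pooled_slope = pooled),
    class = "inaccuracy_fit"
  )
}

#' @export
print.inaccuracy_fit <- function(x, ...) {
  cat("per-ETM zero-intercept slopes of I on F:\n")
  print(x$slopes, row.names = FALSE)
  cat(sprintf("pooled slope of I on M*F: %.4g\n", x$pooled_slope))
  invisible(x)
}
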