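# sRGB transfer functions on [0,1] scale
srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}
srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Mean ROI and background color of an RGB raster
#'
#' Channel-wise arithmetic means over two rectangles of an image, the
#' measurement ROI and a background ROI of the same kind taken outside the
#' specimen.
#'
#' @param image Numeric array `height x width x 3` (any intensity scale).
#' @param roi,bg_roi Rectangles as `c(row0, col0, row1, col1)` (inclusive,
#'   1-based), fully inside the image.
#' @return A list with `roi_rgb` and `bg_rgb`, each a length-3 numeric.
#' @export
extract_roi_color <- function(image, roi, bg_roi) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  mean_rect <- function(r) {
    if (r[1] < 1 || r[2] < 1 || r[3] > dim(image)[1] ||
          r[4] > dim(image)[2] || r[1] > r[3] || r[2] > r[4]) {
      stop("ROI out of image bounds", call. = FALSE)
    }
    apply(image[r[1]:r[3], r[2]:r[4], , drop = FALSE], 3, mean)
  }
  list(roi_rgb = mean_rect(roi), bg_rgb = mean_rect(bg_roi))
}

#' Background-shift a color series
#'
#' Per experiment (grouped by `condition`), computes the mean of all
#' background RGB values and shifts every record's ROI and background colors
#' additively so its background lands exactly on that target. The roi - bg
#' difference of every record is preserved channel-wise, and the mean of the
#' shifted backgrounds equals the mean of the originals.
#'
#' @param series A `color_series` tibble (columns `roi_r/g/b`, `bg_r/g/b`,
#'   `condition`).
#' @return The shifted `color_series` (background columns all equal to the
#'   per-experiment target).
#' @export
background_shift <- function(series) {
  stopifnot(all(c("roi_r", "roi_g", "roi_b", "bg_r", "bg_g", "bg_b")
                %in% names(series)))
  singles <- dplyr::count(series, .data$condition) |>
    dplyr::filter(.data$n == 1)
  if (nrow(singles)) {
    message("background_shift: ", nrow(singles),
            " single-record experiment(s); target is the record's own bg")
  }
  out <- series |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(
      roi_r = .data$roi_r + mean(.data$bg_r) - .data$bg_r,
      roi_g = .data$roi_g + mean(.data$bg_g) - .data$bg_g,
      roi_b = .data$roi_b + mean(.data$bg_b) - .data$bg_b,
      bg_r = mean(.data$bg_r), bg_g = mean(.data$bg_g),
      bg_b = mean(.data$bg_b)) |>
    dplyr::ungroup()
  class(out) <- class(series)
  attributes(out)$truth <- attr(series, "truth")
  out
}

#' Convert sRGB to hue-chroma-luminance
#'
#' HCL here is the polar form of CIE L*u*v* under D65 (the dialect used by
#' base R and farver): gamma-decoded sRGB to XYZ to L*u*v*, with
#' `C = sqrt(u^2 + v^2)` and `H = atan2(v, u)` in degrees mod 360.
#' Out-of-range components (e.g. produced by background shifting) are
#' clamped to \[0, 255\] and counted; near-achromatic colors (C below
#' 0.05, the resolution of the conversion on the gray axis) get `H = 0` by
#' convention and an `achromatic` flag so downstream statistics can exclude
#' them.
#'
#' @param rgb Numeric matrix (n x 3) or length-3 vector of sRGB components
#'   on the 0-255 scale.
#' @return A tibble: `luminance` (L*), `chroma`, `hue` (degrees in
#'   \[0, 360)), `achromatic`; attribute `n_clamped` counts clamped
#'   components.
#' @export
rgb_to_hcl <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  stopifnot(ncol(rgb) == 3)
  n_clamped <- sum(rgb < 0 | rgb > 255)
  if (n_clamped > 0) {
    message("rgb_to_hcl: clamped ", n_clamped, " component(s) to [0, 255]")
    rgb <- pmin(pmax(rgb, 0), 255)
  }
  hcl <- farver::convert_colour(rgb, from = "rgb", to = "hcl")
  # the gray axis lands at C ~ 1e-2 (finite-precision conversion), so the
  # achromatic guard uses a small chroma threshold rather than exact zero
  achrom <- hcl[, "c"] < 0.05
  hue <- unname(hcl[, "h"] %% 360)
  hue[achrom] <- 0
  tibble::tibble(luminance = unname(hcl[, "l"]),
                 chroma = unname(hcl[, "c"]), hue = hue,
                 achromatic = unname(achrom)) |>
    structure(n_clamped = n_clamped)
}

#' Shift hue by 180 degrees
#'
#' Moves the circular 0/360 wrap point out of an indicator's color range so
#' hues can be averaged and fit linearly. Self-inverse.
#'
#' @param h Hue in degrees.
#' @return `(h + 180) mod 360`.
#' @export
hue_shift <- function(h) (h + 180) %% 360

#' Hue records of a color series
#'
#' Convenience wrapper: background-shifts a color series, converts ROI
#' colors to HCL, and applies the 180-degree hue shift.
#'
#' @param series A `color_series` tibble.
#' @param shift Apply [background_shift()] first (default `TRUE`).
#' @return A tibble of hue records: `animal`, `time`, `condition`,
#'   `luminance`, `chroma`, `hue_shifted`, `achromatic`.
#' @export
hue_records <- function(series, shift = TRUE) {
  if (shift) series <- background_shift(series)
  hcl <- rgb_to_hcl(as.matrix(series[, c("roi_r", "roi_g", "roi_b")]))
  tibble::tibble(animal = series$animal, time = series$time,
                 condition = series$condition,
                 luminance = hcl$luminance, chroma = hcl$chroma,
                 hue_shifted = hue_shift(hcl$hue),
                 achromatic = hcl$achromatic)
}

#' Polynomial hue-chroma and hue-luminance fits
#'
#' Ordinary-least-squares polynomial fits (degree 4 by default) of shifted
#' hue on chroma and on luminance, with R squared for each. A tight fit
#' indicates that hue alone captures the indicator's color state. A
#' constant-hue input has no variance to explain; its R squared is reported
#' as 1 with a zero-variance note.
#'
#' @param records Hue records (from [hue_records()]); needs at least
#'   `degree + 2` rows.
#' @param degree Polynomial degree.
#' @return An object of class `hue_fit`: list with `fits` (named list of
#'   `lm` objects), `degree`, and `r_squared` (named numeric).
#' @export
fit_hue_polynomials <- function(records, degree = 4L) {
  if (nrow(records) < degree + 2) {
    stop("need at least degree + 2 records", call. = FALSE)
  }
  fit_one <- function(pred) {
    df <- data.frame(y = records$hue_shifted, x = records[[pred]])
    stats::lm(y ~ poly(x, degree, raw = TRUE), data = df)
  }
  fits <- list(chroma = fit_one("chroma"), luminance = fit_one("luminance"))
  r2 <- vapply(fits, function(f) {
    tss <- sum((records$hue_shifted - mean(records$hue_shifted))^2)
    if (tss == 0) return(1)   # zero-variance convention
    1 - sum(stats::residuals(f)^2) / tss
  }, numeric(1))
  structure(list(fits = fits, degree = degree, r_squared = r2,
                 zero_variance = stats::var(records$hue_shifted) == 0),
            class = "hue_fit")
}

#' @export
print.hue_fit <- function(x, ...) {
  cat("<hue_fit> degree ", x$degree, "; R^2 chroma = ",
      sprintf("%.4f", x$r_squared[["chroma"]]), ", luminance = ",
      sprintf("%.4f", x$r_squared[["luminance"]]),
      if (x$zero_variance) " (zero-variance hue)", "\n", sep = "")
  invisible(x)
}

#' Across-animal hue time series with confidence intervals
#'
#' Per timepoint, the across-animal mean of shifted hue with a two-sided
#' t-based 95% confidence interval (plain linear means are valid because the
#' 180-degree shift moves the wrap point outside the data range). Timepoints
#' with a single animal get the point estimate and `NA` bounds.
#'
#' @param records Hue records (from [hue_records()]).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: time, n, mean_hue, ci_lo, ci_hi.
#' @export
hue_timeseries <- function(records, conf_level = 0.95) {
  records |>
    dplyr::group_by(time = .data$time) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_hue = mean(.data$hue_shifted),
                     sd_hue = stats::sd(.data$hue_shifted)) |>
    dplyr::mutate(
      half = stats::qt(1 - (1 - conf_level) / 2, df = .data$n - 1) *
        .data$sd_hue / sqrt(.data$n),
      ci_lo = .data$mean_hue - .data$half,
      ci_hi = .data$mean_hue + .data$half) |>
    dplyr::select(dplyr::all_of(c("time", "n", "mean_hue", "ci_lo",
                                  "ci_hi")))
}

#' Monotone hue-to-pH calibration
#'
#' Builds a monotone interpolation from known-pH standards measured under
#' the same imaging conditions (a hyman-filtered cubic spline on the
#' standards' shifted hue). Intended for recovery analyses on synthetic
#' series; no calibration curve is asserted for real indicators.
#'
#' @param standards Data frame with columns `ph` and `hue_shifted`
#'   (strictly monotone hue along pH).
#' @return A function mapping shifted hue to pH (clamped to the standard
#'   range).
#' @export
calibrate_hue_ph <- function(standards) {
  stopifnot(all(c("ph", "hue_shifted") %in% names(standards)))
  o <- order(standards$hue_shifted)
  h <- standards$hue_shifted[o]
  p <- standards$ph[o]
  if (any(diff(h) <= 0)) stop("standard hues must be strictly monotone",
                              call. = FALSE)
  f <- stats::splinefun(h, p, method = "hyman")
  function(hue) f(pmin(pmax(hue, min(h)), max(h)))
}

#' Fit an exponential pH relaxation
#'
#' Nonlinear least squares for `ph(t) = ph_home + (ph0 - ph_home) *
#' exp(-t / tau)`, the first-order return to homeostatic pH after an acute
#' challenge.
#'
#' @param time,ph Numeric vectors of observations.
#' @return A tibble with one row: ph0, ph_home, tau.
#' @export
fit_ph_relaxation <- function(time, ph) {
  stopifnot(length(time) == length(ph), length(time) >= 4)
  start <- list(ph_home = ph[which.max(time)], ph0 = ph[which.min(time)],
                tau = max(diff(range(time)) / 4, 1e-3))
  fit <- if (requireNamespace("minpack.lm", quietly = TRUE)) {
    minpack.lm::nlsLM(ph ~ ph_home + (ph0 - ph_home) * exp(-time / tau),
                      start = start)
  } else {
    stats::nls(ph ~ ph_home + (ph0 - ph_home) * exp(-time / tau),
               start = start)
  }
  co <- stats::coef(fit)
  tibble::tibble(ph0 = co[["ph0"]], ph_home = co[["ph_home"]],
                 tau = co[["tau"]])
}

#' Known-pH indicator standards
#'
#' Simulates the hue of indicator solutions at fixed known pH values under
#' the same optics as [simulate_ph_series()] (noise-free), for use with
#' [calibrate_hue_ph()] or [fit_hue_relaxation()].
#'
#' @param phs Numeric vector of standard pH values.
#' @param pKa,acid_rgb,base_rgb,bg_offset Indicator and imaging parameters;
#'   match the series being calibrated.
#' @return A tibble with columns `ph` and `hue_shifted`.
#' @export
ph_standards <- function(phs, pKa = 8.0,
                         acid_rgb = c(250, 220, 60),
                         base_rgb = c(235, 60, 150),
                         bg_offset = c(8, 10, 6)) {
  hue <- vapply(phs, function(p) {
    s <- simulate_ph_series(ph0 = p, ph_home = p, tau = 1, timepoints = 0,
                            pKa = pKa, acid_rgb = acid_rgb,
                            base_rgb = base_rgb, bg_offset = bg_offset,
                            noise_sd = 0, n_animals = 1L, seed = 1L)
    # single noise-free records: the usual shift/clamp notes are expected
    suppressMessages(hue_records(s, shift = TRUE)$hue_shifted)
  }, numeric(1))
  tibble::tibble(ph = phs, hue_shifted = hue)
}

#' Fit a pH relaxation to a hue trace through a calibration curve
#'
#' Estimates the relaxation time of a pH transient directly from indicator
#' hue: the standards define a monotone hue-of-pH curve, and nonlinear least
#' squares fits `hue(t) = g(ph_home + (ph0 - ph_home) exp(-t / tau))` to the
#' observed shifted hues. Fitting in hue space keeps the information in the
#' indicator's takeoff time, which a pointwise hue-to-pH inversion loses
#' where the indicator saturates.
#'
#' @param records Hue records (from [hue_records()]) with columns `time` and
#'   `hue_shifted`.
#' @param standards Output of [ph_standards()] (or a data frame with `ph`
#'   and `hue_shifted`).
#' @param start,lower,upper Start values and box bounds for
#'   `(ph_home, ph0, tau)`.
#' @return A tibble with one row: ph0, ph_home, tau.
#' @export
fit_hue_relaxation <- function(records, standards,
                               start = list(ph_home = 7.4, ph0 = 4.5,
                                            tau = 4),
                               lower = c(5, 2, 0.5),
                               upper = c(10, 7, 30)) {
  o <- order(standards$ph)
  hue_of_ph <- stats::splinefun(standards$ph[o], standards$hue_shifted[o],
                                method = "monoH.FC")
  df <- data.frame(hue = records$hue_shifted, tt = records$time)
  fit <- if (requireNamespace("minpack.lm", quietly = TRUE)) {
    minpack.lm::nlsLM(
      hue ~ hue_of_ph(ph_home + (ph0 - ph_home) * exp(-tt / tau)),
      data = df, start = start, lower = lower, upper = upper)
  } else {
    stats::nls(hue ~ hue_of_ph(ph_home + (ph0 - ph_home) * exp(-tt / tau)),
               data = df, start = start, algorithm = "port",
               lower = lower, upper = upper)
  }
  co <- stats::coef(fit)
  tibble::tibble(ph0 = co[["ph0"]], ph_home = co[["ph_home"]],
                 tau = co[["tau"]])
}

#' Background-subtracted ratiometric pH readout
#'
#' The 405 nm / 488 nm excitation ratio of a ratiometric pH reporter after
#' channel-wise background subtraction:
#' `(f405 - bg405) / (f488 - bg488)`. Cells whose background-subtracted
#' denominator is not positive are excluded (`NA` with a warning). Invariant
#' to a common detector gain applied to both channels and their backgrounds.
#'
#' @param f405,f488 ROI mean fluorescence at 405 and 488 nm excitation.
#' @param bg405,bg488 Background means per channel.
#' @return Numeric ratio(s); `NA` where the denominator is non-positive.
#' @export
phluorin_ratio <- function(f405, f488, bg405, bg488) {
  num <- f405 - bg405
  den <- f488 - bg488
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with non-positive background-subtracted ",
            "488 signal excluded", call. = FALSE)
  }
  ifelse(bad, NA_real_, num / den)
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated density - area * mean background fluorescence`.
#'
#' @param integrated_density Sum of pixel intensities over the ROI.
#' @param area ROI area in pixels (> 0).
#' @param mean_bg Mean background fluorescence.
#' @return CTCF value(s).
#' @export
ctcf <- function(integrated_density, area, mean_bg) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  integrated_density - area * mean_bg
}
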