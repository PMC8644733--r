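# Gradient profiles: photograph -> scalar signal image -> values sampled
# along the bisector chord -> profile on the normalized concave->convex
# [0,1] axis -> per-group mean +/- SD summaries.

#' Intensity profile on the normalized concave-to-convex axis
#'
#' @param positions Strictly increasing grid on `[0, 1]` with endpoints 0
#'   and 1.
#' @param values Non-negative signal values (arbitrary units), one per
#'   position.
#' @param seedling_id,genotype,day,treatment Metadata labels.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, values, seedling_id = "",
                              genotype = NA_character_, day = NA,
                              treatment = NA_character_) {
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) < 2L || length(positions) != length(values)) {
    abort_validation("positions and values must have equal length >= 2")
  }
  if (any(!is.finite(positions)) || any(!is.finite(values))) {
    abort_validation("positions and values must be finite")
  }
  if (abs(positions[1]) > 1e-12 || abs(positions[length(positions)] - 1) > 1e-12) {
    abort_validation("positions must span [0, 1] with endpoints 0 and 1")
  }
  if (any(diff(positions) <= 0)) {
    abort_validation("positions must be strictly increasing")
  }
  if (any(values < 0)) {
    abort_validation("values must be non-negative")
  }
  structure(list(positions = positions, values = values,
                 seedling_id = seedling_id,
                 metadata = list(genotype = genotype, day = day,
                                 treatment = treatment)),
            class = "intensity_profile")
}

#' Convert a photograph to a scalar staining-signal image
#'
#' RGB images are reduced to luminance with the fixed weights
#' (0.299, 0.587, 0.114) of the classic RGB-to-gray conversion, rounded to
#' the nearest integer gray level. With `polarity = "stain_dark"` (dark blue
#' staining on a bright background, the usual GUS photograph) the gray level
#' is inverted, `signal = max_value - luminance`, so that heavier staining
#' always means larger signal; `"stain_bright"` keeps the gray level as is
#' (appropriate for images already encoding signal as brightness, such as
#' the synthetic renders). Output is in native units on `[0, max_value]`,
#' never rescaled.
#'
#' @param image Numeric matrix (grayscale) or height x width x 3 (or 4,
#'   alpha ignored) array (RGB), values on `[0, max_value]`.
#' @param polarity `"stain_dark"` or `"stain_bright"`.
#' @param max_value Maximum representable value (255 for 8-bit images).
#' @return Numeric matrix of signal values.
#' @export
to_signal <- function(image, polarity = c("stain_dark", "stain_bright"),
                      max_value = 255) {
  polarity <- match.arg(polarity)
  check_number(max_value, "max_value", min = 1)
  if (is.matrix(image)) {
    lum <- round(image)
  } else if (is.array(image) && length(dim(image)) == 3L &&
             dim(image)[3] %in% c(3L, 4L)) {
    lum <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] +
                   0.114 * image[, , 3])
  } else {
    abort_validation(
      "image must be a grayscale matrix or an RGB(A) array with 3 or 4 channels")
  }
  if (polarity == "stain_dark") max_value - lum else lum
}

#' Sample the signal along a chord
#'
#' Values are read by bilinear interpolation at equal arc-length steps from
#' the concave to the convex endpoint inclusive; the first position is 0 and
#' the last equals the chord length (`step` is the target spacing, the
#' actual spacing is `length / (n - 1) <= step`).
#'
#' @param image Numeric signal matrix.
#' @param chord A [bisector_chord()].
#' @param step Target sampling step in px (> 0).
#' @return A data frame of class `raw_profile` with columns `position_px`
#'   and `value`.
#' @export
sample_chord <- function(image, chord, step = 0.5) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_validation("image must be a numeric matrix")
  }
  check_number(step, "step", min = 0, strict_min = TRUE)
  p0 <- as_point(chord$concave_point, "concave_point")
  p1 <- as_point(chord$convex_point, "convex_point")
  len <- vnorm(p1 - p0)
  n <- max(2L, as.integer(ceiling(len / step)) + 1L)
  tt <- seq(0, len, length.out = n)
  dirn <- (p1 - p0) / len
  vals <- bilinear_sample(image, p0[1] + tt * dirn[1], p0[2] + tt * dirn[2])
  structure(data.frame(position_px = tt, value = vals),
            class = c("raw_profile", "data.frame"))
}

#' Normalize a raw chord profile onto the [0, 1] axis
#'
#' Positions are mapped affinely from `[0, chord length]` onto `[0, 1]`
#' (0 = concave, 1 = convex) — hook diameters differ between seedlings, so
#' profiles are only comparable on this normalized axis — and values are
#' linearly interpolated onto a uniform grid of `n_points` positions.
#' Endpoint values are preserved exactly; applying the operation to an
#' already-normalized profile on the same grid is the identity.
#'
#' @param raw A `raw_profile` from [sample_chord()] (or any data frame with
#'   columns `position_px`/`position` and `value`).
#' @param n_points Number of output grid points (>= 2), default 101.
#' @param seedling_id,genotype,day,treatment Metadata for the profile.
#' @return An [intensity_profile()].
#' @export
normalize_resample <- function(raw, n_points = 101, seedling_id = "",
                               genotype = NA_character_, day = NA,
                               treatment = NA_character_) {
  pos <- raw$position_px %||% raw$position
  val <- raw$value
  if (is.null(pos) || is.null(val) || length(pos) < 2L) {
    abort_validation("raw profile needs >= 2 samples with positions and values")
  }
  check_number(n_points, "n_points", min = 2)
  n_points <- as.integer(n_points)
  span <- pos[length(pos)] - pos[1]
  if (span <= 0) abort_validation("raw profile positions must increase")
  s_in <- (pos - pos[1]) / span
  grid <- seq(0, 1, length.out = n_points)
  out <- approx(s_in, val, xout = grid, ties = "ordered")$y
  out[1] <- val[1]
  out[n_points] <- val[length(val)]
  intensity_profile(grid, pmax(out, 0), seedling_id = seedling_id,
                    genotype = genotype, day = day, treatment = treatment)
}

#' Pointwise mean and SD of an ensemble of profiles
#'
#' All profiles must share the same position grid; the summary is the
#' pointwise arithmetic mean and sample standard deviation (denominator
#' n - 1; SD defined as 0 when n = 1), the form in which per-genotype
#' staining patterns are reported as mean +/- SD curves.
#'
#' @param profiles List of [intensity_profile()] objects on a common grid.
#' @return An object of class `ensemble_summary`: list with `positions`,
#'   `mean_values`, `sd_values`, `n`.
#' @export
ensemble_mean_sd <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 1L) {
    abort_validation("profiles must be a non-empty list of intensity_profile")
  }
  grid <- profiles[[1]]$positions
  for (p in profiles) {
    if (!inherits(p, "intensity_profile")) {
      abort_validation("profiles must all be intensity_profile objects")
    }
    if (length(p$positions) != length(grid) ||
        any(abs(p$positions - grid) > 1e-12)) {
      abort_validation("all profiles must share an identical position grid")
    }
  }
  m <- vapply(profiles, function(p) p$values, numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  n <- length(profiles)
  mu <- rowMeans(m)
  sdv <- if (n == 1L) rep(0, length(grid)) else apply(m, 1, sd)
  structure(list(positions = grid, mean_values = mu, sd_values = sdv, n = n),
            class = "ensemble_summary")
}

#' Read a seedling photograph as a numeric image
#'
#' Reads PNG or TIFF, returning values scaled to `[0, max_value]` native
#' units (a grayscale matrix or an RGB array, as stored).
#'
#' @param path PNG or TIFF file.
#' @param max_value Full-scale value of the stored image (255 for 8-bit).
#' @return Numeric matrix or array.
#' @export
read_seedling_image <- function(path, max_value = 255) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort_validation(sprintf("unsupported image format: '%s'", ext))
  )
  img * max_value
}

#' Write a grayscale signal image
#'
#' @param image Numeric matrix on `[0, max_value]`.
#' @param path Output path (`.png`, `.tif`/`.tiff`).
#' @param max_value Full-scale value (255 for 8-bit output, 65535 for
#'   16-bit PNG).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, max_value = 255) {
  scaled <- pmin(pmax(image / max_value, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path,
                        dpi = NULL),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16L),
    abort_validation(sprintf("unsupported image format: '%s'", ext))
  )
  invisible(path)
}

#' Write profiles or an ensemble summary as CSV
#'
#' Profiles are written long-form with columns
#' `seedling_id, genotype, day, treatment, s, value`; ensemble summaries
#' with columns `s, mean, sd, n`.
#'
#' @param x List of [intensity_profile()] or an `ensemble_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(x, path) {
  df <- if (inherits(x, "ensemble_summary")) {
    data.frame(s = x$positions, mean = x$mean_values, sd = x$sd_values,
               n = x$n)
  } else {
    do.call(rbind, lapply(x, function(p) {
      data.frame(seedling_id = p$seedling_id,
                 genotype = p$metadata$genotype, day = p$metadata$day,
                 treatment = p$metadata$treatment,
                 s = p$positions, value = p$values,
                 stringsAsFactors = FALSE)
    }))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "Intensity profile '%s': %d points on [0,1], values %.1f .. %.1f\n",
    x$seedling_id, length(x$positions), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "Ensemble summary: n = %d profiles, %d grid points, mean %.1f .. %.1f\n",
    x$n, length(x$positions), min(x$mean_values), max(x$mean_values)))
  invisible(x)
}

#' Plot an ensemble mean +/- SD staining curve
#'
#' Convenience base-graphics plot of the per-position mean with an SD
#' ribbon, on the normalized concave (0) to convex (1) axis.
#'
#' @param summary An `ensemble_summary`.
#' @param main Plot title.
#' @param col Curve color.
#' @return Invisibly, `summary`.
#' @export
plot_ensemble_summary <- function(summary, main = "Staining along the hook",
                                  col = "steelblue4") {
  s <- summary$positions
  lo <- summary$mean_values - summary$sd_values
  hi <- summary$mean_values + summary$sd_values
  plot(NA, xlim = c(0, 1), ylim = range(c(lo, hi)),
       xlab = "normalized position (0 = concave, 1 = convex)",
       ylab = "signal (arbitrary units)", main = main)
  graphics::polygon(c(s, rev(s)), c(lo, rev(hi)), border = NA,
                    col = grDevices::adjustcolor(col, alpha.f = 0.3))
  graphics::lines(s, summary$mean_values, col = col, lwd = 2)
  invisible(summary)
}
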