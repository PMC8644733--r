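# Hook geometry: hook angle from landmarks, the bisector ray at the hook
# vertex, and detection of the concave-to-convex tissue chord along it.

#' Seedling landmark annotations
#'
#' Landmarks describing one seedling's hook geometry, in `(row, col)` image
#' coordinates (0-based, pixel centers at integers): the hypocotyl axis as
#' two points ordered proximal -> distal (towards the hook), the cotyledon
#' line ("the imaginary line between the cotyledons") as two points ordered
#' hook side -> tip side, and the hook vertex, the interior corner of the
#' hook on the concave tissue edge.
#'
#' @param hypocotyl_axis 2x2 matrix (rows = points, cols = row/col).
#' @param cotyledon_line 2x2 matrix, same layout.
#' @param hook_vertex Length-2 `(row, col)` point.
#' @return An object of class `seedling_landmarks`.
#' @export
seedling_landmarks <- function(hypocotyl_axis, cotyledon_line, hook_vertex) {
  as_line <- function(x, name) {
    x <- matrix(as.numeric(unlist(x)), ncol = 2, byrow = !is.matrix(x))
    if (is.matrix(x) && nrow(x) != 2L) {
      abort_validation(sprintf("%s must be two (row, col) points", name))
    }
    if (any(!is.finite(x))) {
      abort_validation(sprintf("%s contains non-finite coordinates", name))
    }
    if (vnorm(x[2, ] - x[1, ]) < 1) {
      abort_validation(sprintf(
        "%s: the two points must be at least 1 px apart", name))
    }
    dimnames(x) <- NULL
    x
  }
  lm <- structure(list(
    hypocotyl_axis = as_line(hypocotyl_axis, "hypocotyl_axis"),
    cotyledon_line = as_line(cotyledon_line, "cotyledon_line"),
    hook_vertex = as_point(hook_vertex, "hook_vertex")
  ), class = "seedling_landmarks")
  lm
}

landmark_directions <- function(landmarks) {
  list(
    d_h = unit(landmarks$hypocotyl_axis[2, ] - landmarks$hypocotyl_axis[1, ]),
    d_c = unit(landmarks$cotyledon_line[2, ] - landmarks$cotyledon_line[1, ])
  )
}

#' Hook angle from landmarks
#'
#' The angle between the oriented hypocotyl direction (proximal -> distal)
#' and the oriented cotyledon direction (hook side -> tip side), in degrees
#' in `[0, 180]`. Convention: 180 = fully closed hook (cotyledon line
#' antiparallel to the hypocotyl), 0 = fully open (seedling straight). The
#' angle is invariant under translation, rotation and uniform scaling of the
#' landmarks.
#'
#' @param landmarks A [seedling_landmarks()].
#' @return Hook angle in degrees.
#' @export
hook_angle <- function(landmarks) {
  if (!inherits(landmarks, "seedling_landmarks")) {
    landmarks <- do.call(seedling_landmarks, landmarks)
  }
  d <- landmark_directions(landmarks)
  cosang <- max(-1, min(1, sum(d$d_h * d$d_c)))
  acos(cosang) * 180 / pi
}

#' Bisector ray of the hook angle
#'
#' The ray along which the staining gradient is read: it starts at the hook
#' vertex (on the concave tissue edge), lies on the bisector line of the
#' vertex angle between the hypocotyl and the cotyledon line, and points
#' away from the concave interior, across the tissue towards the convex
#' edge. Its direction is the unit vector along
#' `unit(hypocotyl direction) - unit(cotyledon direction)`; for a closed
#' hook (angle near 180) this is simply the hypocotyl direction, piercing
#' the top of the bend.
#'
#' Undefined for a fully open hook (angle 0), where the two directions
#' coincide and the difference vanishes.
#'
#' @param landmarks A [seedling_landmarks()].
#' @return A list of class `bisector_ray` with `origin` (the hook vertex)
#'   and unit `direction`, both `(row, col)`.
#' @export
bisector_ray <- function(landmarks) {
  if (!inherits(landmarks, "seedling_landmarks")) {
    landmarks <- do.call(seedling_landmarks, landmarks)
  }
  d <- landmark_directions(landmarks)
  diff <- d$d_h - d$d_c
  if (vnorm(diff) < 1e-9) {
    abort_degenerate(
      "bisector undefined: hook angle is 0 (hypocotyl and cotyledon directions coincide)")
  }
  structure(list(origin = landmarks$hook_vertex, direction = unit(diff)),
            class = "bisector_ray")
}

#' Bisector chord between the concave and convex tissue edges
#'
#' @param concave_point,convex_point `(row, col)` chord endpoints.
#' @return An object of class `bisector_chord` with `concave_point`,
#'   `convex_point` and `length` (their Euclidean distance, px).
#' @export
bisector_chord <- function(concave_point, convex_point) {
  concave_point <- as_point(concave_point, "concave_point")
  convex_point <- as_point(convex_point, "convex_point")
  len <- vnorm(convex_point - concave_point)
  if (len <= 0) {
    abort_validation("concave_point and convex_point must be distinct")
  }
  structure(list(concave_point = concave_point, convex_point = convex_point,
                 length = len), class = "bisector_chord")
}

#' Locate the tissue chord along the bisector ray
#'
#' Walks the bisector ray from its origin, sampling the signal image by
#' bilinear interpolation at fixed arc-length steps, and returns the chord
#' spanning the first contiguous run of tissue samples: the concave endpoint
#' is where the signal first rises above the threshold (the ray origin
#' itself when it already lies on tissue) and the convex endpoint is where
#' the same run falls back below it. Both endpoints are refined to sub-pixel
#' precision by linear interpolation of the threshold crossing between
#' adjacent samples.
#'
#' `background_threshold = "auto"` uses the midpoint between the minimum and
#' maximum sampled value along the ray, appropriate for images with a clear
#' two-level background/tissue separation; for strongly graded tissue pass
#' an explicit threshold between the background level and the dimmest
#' tissue value.
#'
#' @param image Numeric matrix: the signal image (larger = more staining).
#' @param ray A [bisector_ray()] (or list with `origin`, `direction`).
#' @param background_threshold `"auto"` or a signal value.
#' @param step Sampling step along the ray, px.
#' @return A [bisector_chord()].
#' @export
tissue_chord <- function(image, ray, background_threshold = "auto",
                         step = 0.5) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_validation("image must be a numeric matrix")
  }
  check_number(step, "step", min = 0, strict_min = TRUE)
  origin <- as_point(ray$origin, "ray$origin")
  dirn <- unit(as_point(ray$direction, "ray$direction"))
  nr <- nrow(image)
  nc <- ncol(image)
  if (origin[1] < 0 || origin[1] > nr - 1 || origin[2] < 0 ||
      origin[2] > nc - 1) {
    abort_oob("ray origin lies outside the image")
  }
  # largest t keeping origin + t*dirn inside [0, nr-1] x [0, nc-1]
  tmax <- Inf
  for (k in 1:2) {
    lim <- c(nr - 1, nc - 1)[k]
    if (dirn[k] > 0) tmax <- min(tmax, (lim - origin[k]) / dirn[k])
    if (dirn[k] < 0) tmax <- min(tmax, (0 - origin[k]) / dirn[k])
  }
  tt <- seq(0, tmax, by = step)
  pts_r <- origin[1] + tt * dirn[1]
  pts_c <- origin[2] + tt * dirn[2]
  vals <- bilinear_sample(image, pts_r, pts_c)
  thr <- if (identical(background_threshold, "auto")) {
    (min(vals) + max(vals)) / 2
  } else {
    check_number(background_threshold, "background_threshold")
  }
  above <- vals >= thr
  i1 <- which(above)[1]
  if (is.na(i1)) {
    abort_no_tissue("no tissue found along the bisector ray")
  }
  run_end <- which(!above & seq_along(above) > i1)
  i2 <- if (length(run_end)) run_end[1] - 1L else length(above)
  if (i2 == length(above)) {
    abort_oob("tissue chord exits the image along the bisector ray")
  }
  # Sub-pixel edge refinement at the local half-maximum: the true tissue
  # boundary sits where the signal crosses the midpoint between the nearby
  # tissue plateau and the nearby background, not where it crosses the
  # detection threshold (which may sit anywhere on the edge ramp).
  reach <- max(1L, as.integer(round(2 / step)))
  refine <- function(i_edge, outward) {
    idx_in <- if (outward > 0) max(i1, i_edge - reach) else min(i2, i_edge + reach)
    idx_out <- if (outward > 0) min(length(tt), i_edge + reach) else max(1L, i_edge - reach)
    level <- (vals[idx_in] + vals[idx_out]) / 2
    ids <- if (outward > 0) idx_in:idx_out else idx_out:idx_in
    v <- vals[ids]
    if (outward < 0) v <- rev(v)  # orient inside -> outside
    cross <- which(v[-1] < level & v[-length(v)] >= level)
    if (!length(cross)) return(tt[i_edge])
    k <- cross[1]
    ii <- if (outward > 0) ids[k] else rev(ids)[k]
    jj <- if (outward > 0) ii + 1L else ii - 1L
    tt[ii] + (level - vals[ii]) / (vals[jj] - vals[ii]) * (tt[jj] - tt[ii])
  }
  t_concave <- if (i1 == 1L) tt[1] else refine(i1, outward = -1)
  t_convex <- refine(i2, outward = 1)
  if (t_convex <= t_concave) {
    abort_no_tissue("tissue run along the bisector ray is degenerate")
  }
  bisector_chord(origin + t_concave * dirn, origin + t_convex * dirn)
}

#' Read or write landmarks as JSON
#'
#' JSON sidecar format: object with keys `hypocotyl_axis`, `cotyledon_line`
#' (each a list of two `[row, col]` pairs) and `hook_vertex` (one
#' `[row, col]` pair).
#'
#' @param path File path.
#' @return `read_landmarks()` returns a [seedling_landmarks()];
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  seedling_landmarks(obj$hypocotyl_axis, obj$cotyledon_line, obj$hook_vertex)
}

#' @rdname read_landmarks
#' @param landmarks A [seedling_landmarks()].
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- list(
    hypocotyl_axis = unname(landmarks$hypocotyl_axis),
    cotyledon_line = unname(landmarks$cotyledon_line),
    hook_vertex = unname(landmarks$hook_vertex)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @export
print.seedling_landmarks <- function(x, ...) {
  cat("Seedling landmarks (row, col):\n")
  cat(sprintf("  hypocotyl: (%.1f, %.1f) -> (%.1f, %.1f)\n",
              x$hypocotyl_axis[1, 1], x$hypocotyl_axis[1, 2],
              x$hypocotyl_axis[2, 1], x$hypocotyl_axis[2, 2]))
  cat(sprintf("  cotyledon: (%.1f, %.1f) -> (%.1f, %.1f)\n",
              x$cotyledon_line[1, 1], x$cotyledon_line[1, 2],
              x$cotyledon_line[2, 1], x$cotyledon_line[2, 2]))
  cat(sprintf("  hook vertex: (%.1f, %.1f); hook angle: %.1f deg\n",
              x$hook_vertex[1], x$hook_vertex[2], hook_angle(x)))
  invisible(x)
}

#' @export
print.bisector_chord <- function(x, ...) {
  cat(sprintf(
    "Bisector chord: concave (%.2f, %.2f) -> convex (%.2f, %.2f), %.2f px\n",
    x$concave_point[1], x$concave_point[2],
    x$convex_point[1], x$convex_point[2], x$length))
  invisible(x)
}
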