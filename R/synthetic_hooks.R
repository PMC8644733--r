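# Synthetic seedling generator: hook images, staining profiles and angle
# tables with analytic ground truth.
#
# The seedling is drawn as a straight hypocotyl joined to a circular arc of
# interior angle `hook_angle_true` (the hook) plus a short cotyledon stub
# tangent to the arc end. An arc makes both the hook angle and the bisector
# chord analytically known: the bisector of the hook angle is the radial line
# through the arc midpoint, so the true chord runs from the inner (concave)
# to the outer (convex) arc edge and has length 2 * tissue_half_width.

#' Specify a synthetic hook image
#'
#' Parameters of the synthetic seedling generator. The staining model across
#' each tissue cross-section at relative depth `u` in `[0, 1]` (0 = concave
#' edge, 1 = convex edge) is `B + S0 * exp(-lambda * u)`, i.e. a baseline
#' plus an exponential decay from the concave towards the convex side, the
#' simplest monotone family with a closed-form cumulative (see
#' [analytic_ardi()]). Synthetic images use the "already inverted" signal
#' convention: larger pixel value = more staining.
#'
#' @param image_width,image_height Image size in pixels.
#' @param hook_angle_true True hook angle in degrees, in `[0, 180]`
#'   (180 = fully closed hook, 0 = fully open).
#' @param tissue_half_width Half-width of the tissue in pixels (>= 2).
#' @param gradient_decay Decay rate `lambda` (>= 0) of the cross-section
#'   staining gradient.
#' @param gradient_baseline Baseline signal `B` (>= 0), in signal units.
#' @param gradient_amplitude Amplitude `S0` (>= 0) of the decaying component.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian pixel
#'   noise, in signal units.
#' @param background_level Signal value of non-tissue pixels.
#' @param seed Integer seed making the rendered noise reproducible, or `NULL`.
#' @param hook_radius Midline radius of the hook arc in pixels; default
#'   `3 * tissue_half_width`.
#' @param hypocotyl_length,cotyledon_length Lengths in pixels of the straight
#'   hypocotyl segment and of the cotyledon stub.
#' @param max_value Maximum representable signal value (255 for 8-bit,
#'   65535 for 16-bit).
#' @param supersample Integer anti-aliasing factor: the seedling is rasterised
#'   on a `supersample`-times finer grid and block-averaged, so edge pixels
#'   carry partial-coverage values and the tissue boundary is localisable to
#'   sub-pixel precision.
#'
#' @return An object of class `hook_spec` (a validated list).
#' @seealso [render_hook_image()], [analytic_ardi()]
#' @export
hook_spec <- function(image_width = 256, image_height = 256,
                      hook_angle_true = 160, tissue_half_width = 16,
                      gradient_decay = 3, gradient_baseline = 60,
                      gradient_amplitude = 160, noise_sd = 0,
                      background_level = 10, seed = NULL,
                      hook_radius = 3 * tissue_half_width,
                      hypocotyl_length = round(0.3 * image_height),
                      cotyledon_length = 2.5 * tissue_half_width,
                      max_value = 255, supersample = 2) {
  spec <- structure(list(
    image_width = image_width, image_height = image_height,
    hook_angle_true = hook_angle_true, tissue_half_width = tissue_half_width,
    gradient_decay = gradient_decay, gradient_baseline = gradient_baseline,
    gradient_amplitude = gradient_amplitude, noise_sd = noise_sd,
    background_level = background_level, seed = seed,
    hook_radius = hook_radius, hypocotyl_length = hypocotyl_length,
    cotyledon_length = cotyledon_length, max_value = max_value,
    supersample = supersample
  ), class = "hook_spec")
  validate_hook_spec(spec)
  spec
}

validate_hook_spec <- function(spec) {
  check_number(spec$image_width, "image_width", min = 16)
  check_number(spec$image_height, "image_height", min = 16)
  check_number(spec$hook_angle_true, "hook_angle_true", min = 0, max = 180)
  check_number(spec$tissue_half_width, "tissue_half_width", min = 2)
  check_number(spec$gradient_decay, "gradient_decay", min = 0)
  check_number(spec$gradient_baseline, "gradient_baseline", min = 0)
  check_number(spec$gradient_amplitude, "gradient_amplitude", min = 0)
  check_number(spec$noise_sd, "noise_sd", min = 0)
  check_number(spec$background_level, "background_level", min = 0)
  check_number(spec$hook_radius, "hook_radius", min = spec$tissue_half_width,
               strict_min = TRUE)
  check_number(spec$hypocotyl_length, "hypocotyl_length", min = 1)
  check_number(spec$cotyledon_length, "cotyledon_length", min = 1)
  check_number(spec$max_value, "max_value", min = 1)
  check_number(spec$supersample, "supersample", min = 1, max = 8)
  # the drawn seedling (all primitive endpoints + tissue margin) must fit
  g <- hook_geometry_model(spec)
  pts <- rbind(g$p_base, g$p0, g$p1, g$p2, g$ctr + (g$R + g$w) * g$u_out,
               c(g$ctr[1] - g$R, g$ctr[2]), c(g$ctr[1], g$ctr[2] + g$R))
  m <- g$w + 1
  if (min(pts[, 1]) < m - 1 || max(pts[, 1]) > spec$image_height - m ||
      min(pts[, 2]) < m - 1 || max(pts[, 2]) > spec$image_width - m) {
    abort_validation(
      "image_width/image_height too small to contain the drawn seedling")
  }
  invisible(spec)
}

# Analytic geometry shared by the rasteriser, the landmarks and the truth.
# Row/col frame, 0-based. The hypocotyl points "up" (decreasing row); the arc
# turns rightwards (towards increasing column) through the interior angle.
hook_geometry_model <- function(spec) {
  theta <- spec$hook_angle_true
  w <- spec$tissue_half_width
  R <- spec$hook_radius
  col0 <- round(0.25 * spec$image_width)
  row0 <- round(0.6 * spec$image_height)
  p0 <- c(row0, col0)                          # arc start = hypocotyl top
  p_base <- c(row0 + spec$hypocotyl_length, col0)
  ctr <- c(row0, col0 + R)                     # arc center
  rad <- theta * pi / 180
  psi0 <- 270            # radial angle (deg) of arc start relative to center
  psi1 <- 270 - theta    # radial angle of arc end
  dir_at <- function(psi_deg) c(cos(psi_deg * pi / 180), sin(psi_deg * pi / 180))
  p1 <- ctr + R * dir_at(psi1)                 # arc end = cotyledon base
  d_h <- c(-1, 0)                              # hypocotyl proximal -> distal
  d_c <- c(-cos(rad), sin(rad))                # cotyledon base -> tip
  p2 <- p1 + spec$cotyledon_length * d_c
  u_out <- dir_at(270 - theta / 2)             # outward radial, arc midpoint
  vertex <- ctr + (R - w) * u_out              # concave tissue edge
  convex <- ctr + (R + w) * u_out
  list(p_base = p_base, p0 = p0, p1 = p1, p2 = p2, ctr = ctr,
       psi0 = psi0, psi1 = psi1, d_h = d_h, d_c = d_c,
       u_out = u_out, vertex = vertex, convex = convex,
       theta = theta, w = w, R = R)
}

#' Render a synthetic seedling hook image with ground truth
#'
#' Draws the seedling described by a [hook_spec()] and returns the grayscale
#' image together with the analytic ground truth (true hook angle, true ARDI,
#' true integrated intensity on the normalized axis, true bisector chord
#' endpoints) and the seedling landmarks consistent with the drawn geometry.
#'
#' Within the hook arc the signal across each tissue cross-section at
#' relative depth `u` (0 = concave edge, 1 = convex edge) is
#' `B + S0 * exp(-lambda * u)`; the same cross-section rule is continued
#' along the straight hypocotyl and cotyledon segments with the concave side
#' facing the arc center. Non-tissue pixels take `background_level`.
#' Zero-mean Gaussian noise of sd `noise_sd` is added to the whole image and
#' values are clipped to `[0, max_value]`.
#'
#' Randomness: the only random draw is the noise field, consumed as one
#' `rnorm(width * height)` vector filled into the image in column-major
#' order; identical specs (including `seed`) give identical images.
#'
#' @param spec A [hook_spec()].
#' @return A list of class `hook_render` with elements `image` (numeric
#'   matrix, rows x cols), `truth` (list: `hook_angle_true`, `ardi_true`,
#'   `area_true`, `chord_endpoints_true`), `landmarks`
#'   (a [seedling_landmarks()]), `tissue_coverage` (fraction of each pixel
#'   covered by tissue) and `spec`.
#' @export
render_hook_image <- function(spec) {
  if (!inherits(spec, "hook_spec")) spec <- do.call(hook_spec, spec)
  validate_hook_spec(spec)
  g <- hook_geometry_model(spec)
  H <- spec$image_height
  W <- spec$image_width
  ss <- as.integer(round(spec$supersample))
  hf <- H * ss
  wf <- W * ss
  # fine-grid pixel centers, expressed in coarse 0-based coordinates
  rr <- matrix((seq_len(hf) - 0.5) / ss - 0.5, nrow = hf, ncol = wf)
  cc <- matrix((seq_len(wf) - 0.5) / ss - 0.5, nrow = hf, ncol = wf,
               byrow = TRUE)

  w <- g$w
  R <- g$R
  # arc membership and depth
  dr <- rr - g$ctr[1]
  dc <- cc - g$ctr[2]
  d <- sqrt(dr^2 + dc^2)
  psi <- (atan2(dc, dr) * 180 / pi) %% 360
  in_arc <- d >= (R - w) & d <= (R + w) & psi >= g$psi1 & psi <= g$psi0
  u_arc <- (d - (R - w)) / (2 * w)
  # hypocotyl membership: vertical strip below the arc start
  off_h <- cc - g$p0[2]
  in_hyp <- abs(off_h) <= w & rr >= g$p0[1] & rr <= g$p_base[1]
  u_hyp <- (w - off_h) / (2 * w)
  # cotyledon stub: straight segment tangent to the arc end
  n1 <- c(cos(g$psi1 * pi / 180), sin(g$psi1 * pi / 180))
  vr <- rr - g$p1[1]
  vc <- cc - g$p1[2]
  t_c <- vr * g$d_c[1] + vc * g$d_c[2]
  p_c <- vr * n1[1] + vc * n1[2]
  in_cot <- t_c >= 0 & t_c <= spec$cotyledon_length & abs(p_c) <= w
  u_cot <- (p_c + w) / (2 * w)

  tissue <- in_arc | in_hyp | in_cot
  u <- ifelse(in_arc, u_arc, ifelse(in_hyp, u_hyp, u_cot))
  val <- matrix(spec$background_level, nrow = hf, ncol = wf)
  val[tissue] <- spec$gradient_baseline +
    spec$gradient_amplitude * exp(-spec$gradient_decay * u[tissue])

  downsample <- function(x) {
    if (ss == 1L) return(x)
    # average ss x ss blocks
    x <- matrix(colMeans(matrix(x, nrow = ss)), nrow = H, ncol = wf)
    t(matrix(colMeans(matrix(t(x), nrow = ss)), nrow = W, ncol = H))
  }
  img <- downsample(val)
  coverage <- downsample(tissue * 1.0)

  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(rnorm(H * W, 0, spec$noise_sd), nrow = H))
    img <- img + noise
  }
  img <- pmin(pmax(img, 0), spec$max_value)

  landmarks <- seedling_landmarks(
    hypocotyl_axis = rbind(g$p_base, g$p0),
    cotyledon_line = rbind(g$p1, g$p2),
    hook_vertex = g$vertex
  )
  total_signal <- spec$gradient_baseline + spec$gradient_amplitude
  truth <- list(
    hook_angle_true = spec$hook_angle_true,
    ardi_true = if (total_signal > 0) {
      analytic_ardi(spec$gradient_decay, spec$gradient_baseline,
                    spec$gradient_amplitude)
    } else NA_real_,
    area_true = profile_area_true(spec$gradient_decay, spec$gradient_baseline,
                                  spec$gradient_amplitude),
    chord_endpoints_true = list(concave = g$vertex, convex = g$convex)
  )
  structure(list(image = img, truth = truth, landmarks = landmarks,
                 tissue_coverage = coverage, spec = spec),
            class = "hook_render")
}

# Integral of B + S0*exp(-lambda*s) over s in [0,1].
profile_area_true <- function(lambda, B, S0) {
  if (lambda == 0) B + S0 else B + S0 * (1 - exp(-lambda)) / lambda
}

#' Analytic ARDI of a baseline-plus-exponential staining profile
#'
#' For the profile `g(s) = B + S0 * exp(-lambda * s)` on the normalized
#' concave-to-convex axis `s` in `[0, 1]`, returns the unique `s*` at which
#' the cumulative integral reaches half of the total: the closed-form
#' counterpart of the measured Auxin Response Distribution Index. The root
#' is located to an absolute tolerance below 1e-9.
#'
#' @param gradient_decay Decay rate `lambda` (>= 0).
#' @param gradient_baseline Baseline `B` (>= 0).
#' @param gradient_amplitude Amplitude `S0` (>= 0); `B + S0` must be > 0.
#' @return The half-mass position, a number in `[0, 1]`; 0.5 for a uniform
#'   profile, < 0.5 when signal is concentrated on the concave side.
#' @examples
#' analytic_ardi(0, 0, 1)   # uniform -> 0.5
#' analytic_ardi(2, 0, 1)   # concave-shifted -> 0.283
#' @export
analytic_ardi <- function(gradient_decay, gradient_baseline = 0,
                          gradient_amplitude = 1) {
  lambda <- check_number(gradient_decay, "gradient_decay", min = 0)
  B <- check_number(gradient_baseline, "gradient_baseline", min = 0)
  S0 <- check_number(gradient_amplitude, "gradient_amplitude", min = 0)
  if (B + S0 <= 0) {
    abort_degenerate("degenerate profile: gradient_baseline and gradient_amplitude are both zero")
  }
  if (lambda == 0 || S0 == 0) return(0.5)
  cum <- function(s) B * s + S0 * (1 - exp(-lambda * s)) / lambda
  half <- cum(1) / 2
  stats::uniroot(function(s) cum(s) - half, c(0, 1), tol = 1e-12)$root
}

#' Simulate an ensemble of staining profiles with known truth
#'
#' Draws `n` independent baseline-plus-exponential profiles whose parameters
#' are sampled from per-parameter normal distributions (truncated at zero),
#' with additive Gaussian measurement noise on the profile values, emulating
#' a per-genotype ensemble of bisector-chord measurements.
#'
#' Randomness: for each profile in turn, draws are consumed in the order
#' decay, baseline, amplitude, then the `n_points` noise values, so a fixed
#' `seed` gives bitwise-identical output across runs.
#'
#' @param n Number of profiles (>= 1).
#' @param mean_decay,sd_decay Mean and sd of the decay rate `lambda`.
#' @param mean_baseline,sd_baseline Mean and sd of the baseline `B`.
#' @param mean_amplitude,sd_amplitude Mean and sd of the amplitude `S0`.
#' @param noise_sd Sd of the additive value noise (signal units).
#' @param n_points Number of grid points of each profile.
#' @param seed Integer seed or `NULL`.
#' @param id_prefix Prefix of generated seedling ids.
#' @param genotype,day,treatment Metadata attached to every profile.
#' @return A list with `profiles` (list of [intensity_profile()]) and
#'   `truth` (list of per-profile parameter lists, each including its
#'   analytic `ardi_true` and `area_true`).
#' @export
simulate_profile_ensemble <- function(n, mean_decay = 3, sd_decay = 0,
                                      mean_baseline = 60, sd_baseline = 0,
                                      mean_amplitude = 160, sd_amplitude = 0,
                                      noise_sd = 8, n_points = 101,
                                      seed = NULL, id_prefix = "sim",
                                      genotype = "synthetic", day = 2,
                                      treatment = "none") {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort_validation("n must be >= 1")
  }
  n <- as.integer(n)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(n_points, "n_points", min = 2)
  s <- seq(0, 1, length.out = n_points)
  with_seed(seed, {
    profiles <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      lambda <- max(0, rnorm(1, mean_decay, sd_decay))
      B <- max(0, rnorm(1, mean_baseline, sd_baseline))
      S0 <- max(0, rnorm(1, mean_amplitude, sd_amplitude))
      values <- B + S0 * exp(-lambda * s)
      if (noise_sd > 0) values <- values + rnorm(n_points, 0, noise_sd)
      values <- pmax(values, 0)
      id <- sprintf("%s%03d", id_prefix, i)
      profiles[[i]] <- intensity_profile(s, values, seedling_id = id,
                                         genotype = genotype, day = day,
                                         treatment = treatment)
      truth[[i]] <- list(
        seedling_id = id, gradient_decay = lambda, gradient_baseline = B,
        gradient_amplitude = S0,
        ardi_true = if (B + S0 > 0) analytic_ardi(lambda, B, S0) else NA_real_,
        area_true = profile_area_true(lambda, B, S0)
      )
    }
    list(profiles = profiles, truth = truth)
  })
}

#' Simulate a hook-angle measurement table
#'
#' Generates per-seedling hook-angle records with genotype x day x
#' concentration group structure and Gaussian measurement noise, clipped to
#' the valid `[0, 180]` degree range — the synthetic counterpart of a manual
#' hook-angle measurement campaign.
#'
#' Randomness: groups are processed in the row order of `group_means`, with
#' `n_per_group` draws each; a fixed `seed` gives identical tables.
#'
#' @param group_means Data frame with columns `genotype`, `concentration_uM`,
#'   `mean_angle` (degrees in `[0, 180]`) and optionally `day`.
#' @param noise_sd Measurement noise sd in degrees (>= 0).
#' @param n_per_group Seedlings per group (>= 2; downstream ANOVA needs
#'   at least two observations per group).
#' @param seed Integer seed or `NULL`.
#' @return A data frame with columns `seedling_id`, `genotype`, `day`,
#'   `concentration_uM`, `angle_deg`.
#' @export
simulate_angle_table <- function(group_means, noise_sd = 5, n_per_group = 30,
                                 seed = NULL) {
  if (!is.data.frame(group_means) ||
      !all(c("genotype", "concentration_uM", "mean_angle") %in%
             names(group_means))) {
    abort_validation(
      "group_means must have columns genotype, concentration_uM, mean_angle")
  }
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 2) {
    abort_validation("n_per_group must be >= 2")
  }
  n_per_group <- as.integer(n_per_group)
  check_number(noise_sd, "noise_sd", min = 0)
  if (any(group_means$mean_angle < 0 | group_means$mean_angle > 180)) {
    abort_validation("mean_angle values must lie in [0, 180] degrees")
  }
  if (any(group_means$concentration_uM < 0)) {
    abort_validation("concentration_uM values must be >= 0")
  }
  if (is.null(group_means$day)) group_means$day <- 2
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(group_means)), function(i) {
      gm <- group_means[i, ]
      ang <- rnorm(n_per_group, gm$mean_angle, noise_sd)
      ang <- pmin(pmax(ang, 0), 180)
      data.frame(
        seedling_id = sprintf("%s_d%s_c%g_%02d", gm$genotype, gm$day,
                              gm$concentration_uM, seq_len(n_per_group)),
        genotype = gm$genotype, day = gm$day,
        concentration_uM = gm$concentration_uM, angle_deg = ang,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
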