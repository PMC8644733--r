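# Batch orchestration: simulate fixture directories, quantify a directory of
# images + landmarks + metadata into profiles/summaries/statistics CSVs, and
# run dose-response analyses on angle tables.

#' Registered synthetic scenarios
#'
#' Named parameter sets for [run_simulate()]. All share the default
#' rendering geometry and 8-bit signal range and differ in the staining
#' gradient: `wt_like` (steep concave-shifted gradient, decay 3),
#' `hyl1_like` (flattened gradient, decay 0.3), `flat_gradient` (no decay,
#' ARDI exactly 0.5) and `concave_shifted` (extreme decay 6). The noise sd
#' is 5% of the gradient amplitude.
#'
#' @return Named list of scenario parameter lists.
#' @export
hook_scenarios <- function() {
  base <- list(image_width = 256, image_height = 256, tissue_half_width = 16,
               gradient_baseline = 60, gradient_amplitude = 160,
               background_level = 10, noise_sd = 8, max_value = 255)
  list(
    wt_like = utils::modifyList(base, list(gradient_decay = 3)),
    hyl1_like = utils::modifyList(base, list(gradient_decay = 0.3)),
    flat_gradient = utils::modifyList(base, list(gradient_decay = 0)),
    concave_shifted = utils::modifyList(base, list(gradient_decay = 6))
  )
}

# Chord-detection threshold recorded with simulated fixtures: midpoint
# between the background and the baseline signal, below the dimmest tissue.
scenario_threshold <- function(params) {
  (params$background_level + params$gradient_baseline) / 2
}

#' Simulate a fixture directory of seedling images
#'
#' Renders `n` synthetic seedlings for a registered scenario into a
#' directory layout that [run_quantify()] accepts unchanged:
#' `images/<id>.png`, `landmarks/<id>.json`, `truth/<id>.json`,
#' `metadata.csv` and `config.json` (recording polarity `"stain_bright"`,
#' the chord threshold and the seed). Hook angles are drawn uniformly on
#' `angle_range` per seedling; each seedling's noise seed derives
#' deterministically from `seed`.
#'
#' @param out_dir Output directory (created; must be empty or absent).
#' @param scenario Scenario name, see [hook_scenarios()].
#' @param n Seedlings to render.
#' @param seed Integer seed.
#' @param angle_range Range (degrees) of the uniform hook-angle draw.
#' @param genotype Genotype label in the metadata (defaults to the
#'   scenario name).
#' @param day Day label in the metadata.
#' @param noise_sd Override of the scenario noise sd (e.g. 0 for
#'   noise-free closure tests), or `NULL` to keep it.
#' @return Invisibly, a list with `metadata`, `truth` (per-seedling list)
#'   and `config`.
#' @export
run_simulate <- function(out_dir, scenario = "wt_like", n = 30, seed = 1,
                         angle_range = c(120, 170), genotype = scenario,
                         day = 2, noise_sd = NULL) {
  scen <- hook_scenarios()
  if (!scenario %in% names(scen)) {
    abort_validation(sprintf("unknown scenario '%s'; registered: %s",
                             scenario, paste(names(scen), collapse = ", ")))
  }
  params <- scen[[scenario]]
  if (!is.null(noise_sd)) params$noise_sd <- noise_sd
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    abort_validation(sprintf("out_dir '%s' exists and is not empty", out_dir))
  }
  for (d in c("", "images", "landmarks", "truth")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  angles <- with_seed(seed, stats::runif(n, angle_range[1], angle_range[2]))
  meta <- list()
  truths <- list()
  for (i in seq_len(n)) {
    id <- sprintf("%s_%03d", scenario, i)
    spec_args <- utils::modifyList(params, list(
      hook_angle_true = angles[i],
      seed = (as.integer(seed) %% 100000L) * 10000L + i))
    rend <- render_hook_image(do.call(hook_spec, spec_args))
    write_gray_image(rend$image, file.path(out_dir, "images",
                                           paste0(id, ".png")),
                     max_value = params$max_value)
    write_landmarks(rend$landmarks,
                    file.path(out_dir, "landmarks", paste0(id, ".json")))
    tr <- rend$truth
    tr$chord_endpoints_true <- lapply(tr$chord_endpoints_true, unname)
    jsonlite::write_json(tr, file.path(out_dir, "truth",
                                       paste0(id, ".json")),
                         digits = NA, auto_unbox = TRUE)
    truths[[id]] <- rend$truth
    meta[[i]] <- data.frame(seedling_id = id, genotype = genotype,
                            day = day, treatment = "none",
                            stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  config <- list(scenario = scenario, n = n, seed = seed,
                 polarity = "stain_bright",
                 background_threshold = scenario_threshold(params),
                 max_value = params$max_value, parameters = params)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metadata = metadata, truth = truths, config = config))
}

#' Quantify a directory of seedling images
#'
#' End-to-end batch run: for every row of the metadata table, reads the
#' image and its landmark sidecar, converts the photograph to a staining
#' signal ([to_signal()]), locates the bisector tissue chord
#' ([bisector_ray()], [tissue_chord()]), samples and normalizes the profile
#' ([sample_chord()], [normalize_resample()]), and summarises it by total
#' integrated intensity and ARDI. Per-genotype ensemble mean/SD curves are
#' computed per day, and ARDI and area are compared across genotypes
#' within each day by one-way ANOVA + Tukey when at least two genotypes
#' have two or more seedlings.
#'
#' Seedlings that fail (missing landmarks, no tissue found, ...) are
#' recorded in the returned `errors` and the run continues; `status` is
#' `"ok"`, `"partial"` or `"failed"`.
#'
#' @param input_dir Directory with `images/`, `landmarks/`, `metadata.csv`
#'   (as written by [run_simulate()]).
#' @param out_dir Output directory for CSVs and the run log (created).
#' @param polarity `"stain_dark"` (stained photographs) or
#'   `"stain_bright"` (signal-encoded images, e.g. synthetic renders).
#' @param background_threshold Chord detection threshold, or `"auto"`.
#' @param n_points Profile grid size.
#' @param step Chord sampling step, px.
#' @param alpha Significance level of the comparisons.
#' @param max_value Full-scale image value.
#' @return Invisibly, a list with `summaries`, `profiles`, `ensembles`,
#'   `comparisons`, `errors`, `status`, `log`.
#' @export
run_quantify <- function(input_dir, out_dir,
                         polarity = c("stain_dark", "stain_bright"),
                         background_threshold = "auto", n_points = 101,
                         step = 0.5, alpha = 0.05, max_value = 255) {
  polarity <- match.arg(polarity)
  check_number(n_points, "n_points", min = 2)
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    abort_validation(sprintf("no metadata.csv under '%s'", input_dir))
  }
  metadata <- read.csv(meta_path, stringsAsFactors = FALSE)
  if (!nrow(metadata)) abort_validation("metadata.csv has no rows")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  profiles <- list()
  summaries <- list()
  errors <- list()
  for (i in seq_len(nrow(metadata))) {
    row <- metadata[i, ]
    id <- row$seedling_id
    res <- tryCatch({
      img_path <- file.path(input_dir, "images", paste0(id, ".png"))
      if (!file.exists(img_path)) {
        img_path <- file.path(input_dir, "images", paste0(id, ".tif"))
      }
      lm_path <- file.path(input_dir, "landmarks", paste0(id, ".json"))
      if (!file.exists(img_path)) stop("image file not found")
      if (!file.exists(lm_path)) stop("landmark file not found")
      img <- read_seedling_image(img_path, max_value = max_value)
      signal <- to_signal(img, polarity = polarity, max_value = max_value)
      lm <- read_landmarks(lm_path)
      chord <- tissue_chord(signal, bisector_ray(lm),
                            background_threshold = background_threshold,
                            step = step)
      raw <- sample_chord(signal, chord, step = step)
      prof <- normalize_resample(raw, n_points = n_points, seedling_id = id,
                                 genotype = row$genotype, day = row$day,
                                 treatment = row$treatment %||% NA_character_)
      list(profile = prof, summary = gradient_summary(prof),
           angle = hook_angle(lm))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
    } else {
      res$summary$hook_angle_deg <- res$angle
      profiles[[id]] <- res$profile
      summaries[[id]] <- res$summary
    }
  }
  if (!length(summaries)) {
    abort_validation("no seedling could be quantified; see errors")
  }
  summaries <- do.call(rbind, summaries)

  # per genotype x day ensembles
  ensembles <- list()
  ens_rows <- list()
  for (d in sort(unique(summaries$day))) {
    for (g in sort(unique(summaries$genotype[summaries$day == d]))) {
      ids <- summaries$seedling_id[summaries$day == d &
                                     summaries$genotype == g]
      es <- ensemble_mean_sd(profiles[ids])
      ensembles[[paste(g, d, sep = "_d")]] <- es
      ens_rows[[length(ens_rows) + 1L]] <- data.frame(
        genotype = g, day = d, s = es$positions, mean = es$mean_values,
        sd = es$sd_values, n = es$n, stringsAsFactors = FALSE)
    }
  }
  ensemble_df <- do.call(rbind, ens_rows)

  # ARDI and area contrasts across genotypes, per day
  comparisons <- list()
  for (d in sort(unique(summaries$day))) {
    sub <- summaries[summaries$day == d, ]
    ok <- names(which(table(sub$genotype) >= 2))
    sub <- sub[sub$genotype %in% ok, ]
    if (length(ok) >= 2) {
      comparisons[[paste0("ardi_day", d)]] <-
        one_way_anova_tukey(sub$ardi, sub$genotype, alpha = alpha)
      comparisons[[paste0("area_day", d)]] <-
        one_way_anova_tukey(sub$area, sub$genotype, alpha = alpha)
    }
  }

  write.csv(summaries, file.path(out_dir, "summaries.csv"),
            row.names = FALSE)
  write_profiles_csv(profiles, file.path(out_dir, "profiles.csv"))
  write.csv(ensemble_df, file.path(out_dir, "ensembles.csv"),
            row.names = FALSE)
  for (nm in names(comparisons)) {
    write_comparison_csv(comparisons[[nm]],
                         file.path(out_dir, paste0("comparison_", nm, ".csv")))
  }
  status <- if (length(errors)) "partial" else "ok"
  log <- list(
    package_version = as.character(utils::packageVersion("hookquant")),
    input_dir = input_dir, polarity = polarity,
    background_threshold = background_threshold, n_points = n_points,
    step = step, alpha = alpha, max_value = max_value,
    n_quantified = nrow(summaries), n_failed = length(errors),
    errors = errors, status = status)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summaries = summaries, profiles = profiles,
                 ensembles = ensembles, comparisons = comparisons,
                 errors = errors, status = status, log = log))
}

#' Dose-response analysis of an angle table
#'
#' Computes per-genotype, per-day dose-response slopes between two
#' concentrations ([dose_response_slope()]), minimum effective
#' concentrations against the mock group
#' ([minimum_effective_concentration()]) and, per day, a two-way
#' genotype x concentration ANOVA with Tukey post-test; writes
#' `slopes.csv`, `mec.csv` and `comparison_day<d>.csv` under `out_dir`.
#'
#' @param table Angle table data frame or CSV path
#'   (see [read_angle_table()]).
#' @param c_low,c_high Slope endpoint concentrations (µM, > 0).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param alpha Significance level.
#' @return Invisibly, a list with `slopes`, `mec`, `comparisons`.
#' @export
run_dose_response <- function(table, c_low = 0.005, c_high = 0.05,
                              out_dir = NULL, alpha = 0.05) {
  if (is.character(table)) table <- read_angle_table(table)
  validate_angle_table(table)
  slopes <- dose_response_slope(table, c_low, c_high)
  # sensitivity readout needs a mock (concentration 0) group; skip otherwise
  mec <- if (any(table$concentration_uM == 0)) {
    minimum_effective_concentration(table, alpha = alpha)
  } else NULL
  comparisons <- list()
  for (d in sort(unique(table$day))) {
    sub <- table[table$day == d, ]
    comparisons[[paste0("day", d)]] <- two_way_anova_tukey(
      sub$angle_deg, sub$genotype, factor(sub$concentration_uM),
      alpha = alpha)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(slopes, file.path(out_dir, "slopes.csv"), row.names = FALSE)
    if (!is.null(mec)) {
      write.csv(mec, file.path(out_dir, "mec.csv"), row.names = FALSE)
    }
    for (nm in names(comparisons)) {
      write_comparison_csv(comparisons[[nm]],
                           file.path(out_dir,
                                     paste0("comparison_", nm, ".csv")))
    }
  }
  invisible(list(slopes = slopes, mec = mec, comparisons = comparisons))
}
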