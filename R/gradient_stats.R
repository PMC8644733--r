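# Summary statistics and group comparisons: total integrated intensity,
# ARDI, one-way/two-way ANOVA with Tukey HSD post-tests and compact letter
# displays, and dose-response slopes on a log10 concentration axis.

#' Total integrated staining intensity of a profile
#'
#' Trapezoidal integral of the signal over the normalized position axis
#' `s` in `[0, 1]` — the "total area" under the staining curve. Linear in
#' the values and non-negative.
#'
#' @param profile An [intensity_profile()].
#' @return The integral, in signal units (positions are dimensionless).
#' @export
integrated_intensity <- function(profile) {
  if (!inherits(profile, "intensity_profile")) {
    abort_validation("profile must be an intensity_profile")
  }
  pracma::trapz(profile$positions, profile$values)
}

#' Auxin Response Distribution Index (ARDI) of a profile
#'
#' The relative position `s*` on the concave (0) to convex (1) axis at
#' which the cumulative trapezoidal integral of the signal reaches half of
#' the total: 0.5 for uniform staining, below 0.5 when signal concentrates
#' on the concave side. The crossing is the smallest such `s*`, located by
#' linear interpolation of the cumulative within the bracketing grid
#' interval; plateaus at exactly half mass resolve to their leftmost point.
#' Scale-invariant: multiplying all values by a positive constant leaves
#' the index unchanged.
#'
#' @param profile An [intensity_profile()].
#' @return The half-mass position, a number in `[0, 1]`.
#' @export
ardi <- function(profile) {
  if (!inherits(profile, "intensity_profile")) {
    abort_validation("profile must be an intensity_profile")
  }
  p <- profile$positions
  v <- profile$values
  seg <- diff(p) * (head(v, -1) + tail(v, -1)) / 2
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) {
    abort_degenerate("degenerate profile: total integrated intensity is zero")
  }
  half <- total / 2
  i <- which(cum >= half)[1]
  if (i == 1L) return(p[1])
  if (cum[i] == cum[i - 1]) return(p[i - 1])
  p[i - 1] + (half - cum[i - 1]) / (cum[i] - cum[i - 1]) * (p[i] - p[i - 1])
}

#' Per-seedling gradient summary
#'
#' @param profile An [intensity_profile()].
#' @return A one-row data frame: `seedling_id`, `genotype`, `day`,
#'   `treatment`, `area`, `ardi`.
#' @export
gradient_summary <- function(profile) {
  data.frame(seedling_id = profile$seedling_id,
             genotype = profile$metadata$genotype,
             day = profile$metadata$day,
             treatment = profile$metadata$treatment,
             area = integrated_intensity(profile),
             ardi = ardi(profile),
             stringsAsFactors = FALSE)
}

# ---- Tukey HSD machinery -------------------------------------------------

# Pairwise Tukey(-Kramer) HSD p-values from group means/sizes and the
# residual mean square, via the studentized-range distribution.
tukey_pairs <- function(means, ns, mse, df_resid) {
  k <- length(means)
  labs <- names(means)
  pairs <- t(utils::combn(k, 2))
  diff <- means[pairs[, 1]] - means[pairs[, 2]]
  se <- sqrt(mse / 2 * (1 / ns[pairs[, 1]] + 1 / ns[pairs[, 2]]))
  q <- abs(diff) / se
  # zero residual variance: identical means are not different, distinct ones
  # are separated with certainty
  q[se == 0] <- ifelse(abs(diff[se == 0]) > 0, Inf, 0)
  p <- ptukey(q, nmeans = k, df = df_resid, lower.tail = FALSE)
  data.frame(group1 = labs[pairs[, 1]], group2 = labs[pairs[, 2]],
             diff = unname(diff), q = unname(q), p_adj = unname(p),
             stringsAsFactors = FALSE)
}

# Compact letter display by insert-and-absorb: start from one class holding
# every group; for each significantly different pair split every class
# containing both; absorb classes that become subsets of others. Groups
# sharing a letter are never significantly different, and every
# non-significant pair shares at least one letter.
compact_letter_display <- function(levels, pairs, alpha) {
  k <- length(levels)
  classes <- list(rep(TRUE, k))
  sig <- pairs[!is.na(pairs$p_adj) & pairs$p_adj < alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    i <- match(sig$group1[r], levels)
    j <- match(sig$group2[r], levels)
    new_classes <- list()
    for (cl in classes) {
      if (cl[i] && cl[j]) {
        a <- cl; a[i] <- FALSE
        b <- cl; b[j] <- FALSE
        new_classes <- c(new_classes, list(a), list(b))
      } else {
        new_classes <- c(new_classes, list(cl))
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_classes))
    for (a in seq_along(new_classes)) {
      for (b in seq_along(new_classes)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_classes[[a]] <= new_classes[[b]]) &&
            !identical(new_classes[[a]], new_classes[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    classes <- new_classes[keep]
    # drop duplicated classes
    classes <- classes[!duplicated(vapply(classes, paste, "", collapse = ""))]
  }
  ord <- order(vapply(classes, function(cl) which(cl)[1], 1L))
  classes <- classes[ord]
  letters_out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(classes, `[`, TRUE, i))], collapse = "")
  }, "")
  setNames(letters_out, levels)
}

comparison_result <- function(groups, pairs, alpha, anova_table, method) {
  structure(list(groups = groups, pairs = pairs, alpha = alpha,
                 anova_table = anova_table, method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (alpha = %g)\n", x$method, x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post-test and letter display
#'
#' Standard fixed-effects one-way ANOVA F-test followed by Tukey's HSD
#' pairwise comparisons computed from the studentized-range distribution
#' (Tukey-Kramer standard errors when group sizes differ), plus a compact
#' letter display at level `alpha`: groups sharing a letter are not
#' significantly different.
#'
#' @param values Numeric response vector.
#' @param group Grouping factor (or vector coercible to one), >= 2 levels
#'   with >= 2 observations each.
#' @param alpha Significance level, default 0.05.
#' @return A `comparison_result`: `groups` (level, n, mean, sd, letters),
#'   `pairs` (pairwise differences and adjusted p-values), `anova_table`,
#'   `alpha`, `method`.
#' @export
one_way_anova_tukey <- function(values, group, alpha = 0.05) {
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  group <- factor(group)
  values <- as.numeric(values)
  if (length(values) != length(group)) {
    abort_validation("values and group must have equal length")
  }
  ns <- table(group)
  if (nlevels(group) < 2L) abort_validation("need at least 2 groups")
  if (any(ns < 2L)) {
    abort_validation(sprintf(
      "every group needs >= 2 observations (group '%s' has %d)",
      names(ns)[which(ns < 2)[1]], min(ns)))
  }
  fit <- aov(values ~ group)
  at <- anova(fit)
  mse <- at$`Mean Sq`[2]
  dfr <- at$Df[2]
  means <- tapply(values, group, mean)
  sds <- tapply(values, group, sd)
  pairs <- tukey_pairs(means, as.numeric(ns), mse, dfr)
  letters_out <- compact_letter_display(levels(group), pairs, alpha)
  groups <- data.frame(group = levels(group), n = as.integer(ns),
                       mean = as.numeric(means), sd = as.numeric(sds),
                       letters = unname(letters_out),
                       stringsAsFactors = FALSE)
  comparison_result(groups, pairs, alpha, at,
                    "One-way ANOVA with Tukey HSD post-test")
}

#' Two-way ANOVA with interaction and Tukey HSD on cell means
#'
#' Fixed-effects two-way ANOVA with interaction on a balanced design
#' (every factor-level combination must hold the same number, >= 2, of
#' observations; balance removes the Type-I/II/III sums-of-squares
#' ambiguity). Tukey's HSD compares all cell means, with a compact letter
#' display over the cells.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (e.g. genotype and treatment).
#' @param alpha Significance level.
#' @return A `comparison_result` whose `groups` rows are the
#'   `factor_a:factor_b` cells and whose `anova_table` holds both main
#'   effects, the interaction and residuals.
#' @export
two_way_anova_tukey <- function(values, factor_a, factor_b, alpha = 0.05) {
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  values <- as.numeric(values)
  if (length(values) != length(fa) || length(values) != length(fb)) {
    abort_validation("values, factor_a and factor_b must have equal length")
  }
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    abort_validation("both factors need >= 2 levels")
  }
  cells <- table(fa, fb)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1, ]
    abort_validation(sprintf("empty design cell: %s x %s",
                             rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  if (length(unique(as.vector(cells))) != 1L || any(cells < 2L)) {
    bad <- which(cells != max(cells) | cells < 2L, arr.ind = TRUE)[1, ]
    abort_validation(sprintf(
      "balanced design with >= 2 observations per cell required; cell %s x %s has %d",
      rownames(cells)[bad[1]], colnames(cells)[bad[2]],
      cells[bad[1], bad[2]]))
  }
  fit <- aov(values ~ fa * fb)
  at <- anova(fit)
  rownames(at) <- c("factor_a", "factor_b", "interaction", "residuals")
  mse <- at$`Mean Sq`[4]
  dfr <- at$Df[4]
  cell <- interaction(fa, fb, sep = ":", lex.order = TRUE)
  means <- tapply(values, cell, mean)
  sds <- tapply(values, cell, sd)
  ns <- table(cell)
  pairs <- tukey_pairs(means, as.numeric(ns), mse, dfr)
  letters_out <- compact_letter_display(levels(cell), pairs, alpha)
  groups <- data.frame(group = levels(cell), n = as.integer(ns),
                       mean = as.numeric(means), sd = as.numeric(sds),
                       letters = unname(letters_out),
                       stringsAsFactors = FALSE)
  comparison_result(groups, pairs, alpha, at,
                    "Two-way ANOVA (interaction) with Tukey HSD on cell means")
}

# ---- Dose-response -------------------------------------------------------

validate_angle_table <- function(table) {
  req <- c("genotype", "day", "concentration_uM", "angle_deg")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    abort_validation(paste0("angle table must have columns ",
                            paste(req, collapse = ", ")))
  }
  if (any(!is.finite(table$angle_deg)) ||
      any(table$angle_deg < 0 | table$angle_deg > 180)) {
    abort_validation("angle_deg values must be finite and in [0, 180]")
  }
  if (any(table$concentration_uM < 0)) {
    abort_validation("concentration_uM values must be >= 0")
  }
  invisible(table)
}

#' Read a hook-angle table from CSV
#'
#' Required header: `seedling_id, genotype, day, concentration_uM,
#' angle_deg` (angles in degrees within `[0, 180]`; concentration 0 denotes
#' the mock treatment).
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_angle_table <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  if (!"seedling_id" %in% names(tb)) {
    abort_validation("angle table must have a seedling_id column")
  }
  validate_angle_table(tb)
  tb
}

#' Dose-response slope between two concentrations
#'
#' Per-genotype slope of the mean hook angle between two inhibitor
#' concentrations on a log10 axis:
#' `(mean angle at c_high - mean angle at c_low) / log10(c_high / c_low)`,
#' in degrees per decade of concentration. A more negative slope means a
#' stronger response (hook closure lost faster per tenfold dose increase).
#' The mock treatment (concentration 0) cannot appear as an endpoint: zero
#' has no logarithm, so sensitivity to the mock is assessed separately via
#' [minimum_effective_concentration()].
#'
#' @param table Angle table (see [read_angle_table()]).
#' @param c_low,c_high The two concentrations (µM, both > 0).
#' @param day Day to analyse (single value present in the table), or `NULL`
#'   to compute slopes for every day in the table.
#' @return Data frame: `genotype`, `day`, `slope_deg_per_decade`,
#'   `mean_low`, `mean_high`, `n_low`, `n_high`.
#' @export
dose_response_slope <- function(table, c_low, c_high, day = NULL) {
  validate_angle_table(table)
  check_number(c_low, "c_low", min = 0, strict_min = TRUE)
  check_number(c_high, "c_high", min = 0, strict_min = TRUE)
  if (c_high == c_low) abort_validation("c_low and c_high must differ")
  days <- if (is.null(day)) sort(unique(table$day)) else day
  out <- list()
  for (d in days) {
    sub <- table[table$day == d, ]
    if (!nrow(sub)) abort_missing_cell(sprintf("no rows for day %s", d))
    for (g in sort(unique(sub$genotype))) {
      lo <- sub$angle_deg[sub$genotype == g & sub$concentration_uM == c_low]
      hi <- sub$angle_deg[sub$genotype == g & sub$concentration_uM == c_high]
      if (!length(lo) || !length(hi)) {
        abort_missing_cell(sprintf(
          "genotype '%s', day %s: missing concentration %g or %g uM",
          g, d, c_low, c_high))
      }
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, day = d,
        slope_deg_per_decade = (mean(hi) - mean(lo)) /
          (log10(c_high) - log10(c_low)),
        mean_low = mean(lo), mean_high = mean(hi),
        n_low = length(lo), n_high = length(hi),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Minimum effective concentration per genotype
#'
#' The smallest tested concentration whose hook-angle distribution differs
#' from the mock (concentration 0) group by the one-way ANOVA + Tukey HSD
#' procedure at level `alpha`, computed per genotype (and per day when the
#' table spans several). Reports `NA` (label `"none"`) when no
#' concentration differs — the readout of whether a genotype's
#' *sensitivity* to the inhibitor, as opposed to its response strength,
#' is altered.
#'
#' @param table Angle table with a concentration-0 mock group per genotype.
#' @param alpha Significance level.
#' @param day Day to analyse, or `NULL` for all days.
#' @return Data frame: `genotype`, `day`, `mec_uM` (numeric, `NA` if none),
#'   `mec_label`.
#' @export
minimum_effective_concentration <- function(table, alpha = 0.05, day = NULL) {
  validate_angle_table(table)
  days <- if (is.null(day)) sort(unique(table$day)) else day
  out <- list()
  for (d in days) {
    sub <- table[table$day == d, ]
    for (g in sort(unique(sub$genotype))) {
      gs <- sub[sub$genotype == g, ]
      concs <- sort(unique(gs$concentration_uM))
      if (!0 %in% concs) {
        abort_validation(sprintf(
          "genotype '%s', day %s: no mock (concentration 0) group", g, d))
      }
      if (length(concs) < 2L) {
        abort_validation(sprintf(
          "genotype '%s', day %s: need at least one nonzero concentration",
          g, d))
      }
      cmp <- one_way_anova_tukey(gs$angle_deg,
                                 factor(gs$concentration_uM), alpha = alpha)
      mock_lab <- as.character(0)
      vs_mock <- cmp$pairs[cmp$pairs$group1 == mock_lab |
                             cmp$pairs$group2 == mock_lab, ]
      other <- ifelse(vs_mock$group1 == mock_lab, vs_mock$group2,
                      vs_mock$group1)
      sig <- as.numeric(other)[vs_mock$p_adj < alpha]
      mec <- if (length(sig)) min(sig) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, day = d, mec_uM = mec,
        mec_label = if (is.na(mec)) "none" else format(mec),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a comparison result as CSV
#'
#' Writes the per-group table (level, n, mean, sd, letters) with the
#' pairwise p-values appended as a second block.
#'
#' @param x A `comparison_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(x, path) {
  g <- x$groups
  g$block <- "groups"
  p <- data.frame(group = paste(x$pairs$group1, x$pairs$group2, sep = " vs "),
                  n = NA_integer_, mean = x$pairs$diff, sd = NA_real_,
                  letters = sprintf("p=%.6g", x$pairs$p_adj),
                  block = "pairs", stringsAsFactors = FALSE)
  write.csv(rbind(g, p), path, row.names = FALSE)
  invisible(path)
}
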