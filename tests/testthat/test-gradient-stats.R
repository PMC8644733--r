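# Integrated intensity, ARDI, ANOVA/Tukey machinery and dose-response.

test_that("integrated_intensity matches closed forms and is linear", {
  s101 <- seq(0, 1, length.out = 101)
  expect_equal(integrated_intensity(intensity_profile(s101, rep(1, 101))), 1)
  expect_equal(integrated_intensity(intensity_profile(s101, s101)), 0.5)
  # e^{-2s}: closed form (1 - e^{-2}) / 2
  expect_equal(integrated_intensity(make_exp_profile(2)),
               (1 - exp(-2)) / 2, tolerance = 5e-4)

  # linearity: area(a*g + b*h) = a*area(g) + b*area(h)
  set.seed(31)
  g <- runif(101, 0, 10)
  h <- runif(101, 0, 10)
  lhs <- integrated_intensity(intensity_profile(s101, 2.5 * g + 1.25 * h))
  rhs <- 2.5 * integrated_intensity(intensity_profile(s101, g)) +
    1.25 * integrated_intensity(intensity_profile(s101, h))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("ardi locates the half-mass position", {
  s101 <- seq(0, 1, length.out = 101)
  expect_equal(ardi(intensity_profile(s101, rep(3, 101))), 0.5)
  # all mass in the first grid cell sits at the concave edge
  v <- c(10, rep(0, 100))
  expect_lt(ardi(intensity_profile(s101, v)), 0.02)
  # e^{-2s} against the analytic value
  expect_equal(ardi(make_exp_profile(2)), analytic_ardi(2, 0, 1),
               tolerance = 1e-3)
  # scale invariance is exact
  p1 <- make_exp_profile(3, B = 5, S0 = 80)
  p2 <- intensity_profile(p1$positions, p1$values * 37.5)
  expect_equal(ardi(p1), ardi(p2), tolerance = 1e-12)
  expect_error(ardi(intensity_profile(s101, rep(0, 101))),
               class = "hookquant_degenerate_error")
})

test_that("ardi reflection and concave-shift monotonicity hold", {
  set.seed(41)
  s101 <- seq(0, 1, length.out = 101)
  for (i in 1:20) {
    v <- runif(101, 0.1, 10)
    a <- ardi(intensity_profile(s101, v))
    a_rev <- ardi(intensity_profile(s101, rev(v)))
    expect_equal(a_rev, 1 - a, tolerance = 0.01)  # one grid interval
  }
  # moving a quantum of signal from the convex half to the concave half
  # never increases the index
  for (i in 1:100) {
    v <- runif(101, 1, 10)
    a0 <- ardi(intensity_profile(s101, v))
    from <- sample(52:101, 1)
    to <- sample(1:50, 1)
    q <- runif(1, 0, v[from])
    v2 <- v
    v2[from] <- v2[from] - q
    v2[to] <- v2[to] + q
    expect_lte(ardi(intensity_profile(s101, v2)), a0 + 1e-12)
  }
})

test_that("fine-grid oracle agrees with grid-based area and ardi", {
  set.seed(53)
  for (i in 1:20) {
    lambda <- runif(1, 0, 5)
    B <- runif(1, 0, 50)
    S0 <- runif(1, 10, 200)
    prof <- make_exp_profile(lambda, B, S0)
    expect_equal(integrated_intensity(prof),
                 oracle_area_dense(lambda, B, S0, n = 1e5),
                 tolerance = 1e-3 * (B + S0))
    expect_equal(ardi(prof), oracle_ardi_dense(lambda, B, S0, n = 1e5),
                 tolerance = 1e-3)
  }
})

test_that("one-way ANOVA + Tukey matches independent computations", {
  # fixed 3 x 5 dataset: p-values against direct studentized-range oracle
  vals <- c(12.1, 13.4, 11.8, 12.9, 13.1,
            15.2, 14.8, 16.1, 15.7, 15.0,
            12.5, 12.9, 13.3, 12.0, 12.7)
  grp <- rep(c("a", "b", "c"), each = 5)
  cmp <- one_way_anova_tukey(vals, grp)
  orc <- oracle_tukey_p(vals, grp)
  expect_equal(unname(cmp$pairs$p_adj),
               unname(orc[paste(cmp$pairs$group1, cmp$pairs$group2,
                                sep = "-")]),
               tolerance = 1e-6)
  # cross-check against stats::TukeyHSD
  th <- stats::TukeyHSD(aov(vals ~ factor(grp)))$`factor(grp)`
  expect_equal(sort(cmp$pairs$p_adj), sort(unname(th[, "p adj"])),
               tolerance = 1e-9)

  # overwhelming separation: different letters
  cmp2 <- one_way_anova_tukey(c(1, 2, 3, 101, 102, 103),
                              rep(c("lo", "hi"), each = 3))
  expect_false(any(strsplit(cmp2$groups$letters[1], "")[[1]] %in%
                     strsplit(cmp2$groups$letters[2], "")[[1]]))

  expect_error(one_way_anova_tukey(1:5, c("a", "a", "a", "a", "b")),
               class = "hookquant_validation_error")
  expect_error(one_way_anova_tukey(1:4, rep("a", 4)),
               class = "hookquant_validation_error")
})

test_that("compact letter display is consistent with pairwise decisions", {
  set.seed(61)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    shift <- runif(k, 0, 4)
    vals <- rnorm(k * 8, rep(shift, each = 8), 1)
    grp <- rep(letters[1:k], each = 8)
    cmp <- one_way_anova_tukey(vals, grp)
    lts <- strsplit(cmp$groups$letters, "")
    names(lts) <- cmp$groups$group
    for (r in seq_len(nrow(cmp$pairs))) {
      share <- length(intersect(lts[[cmp$pairs$group1[r]]],
                                lts[[cmp$pairs$group2[r]]])) > 0
      if (cmp$pairs$p_adj[r] < cmp$alpha) {
        expect_false(share)
      } else {
        expect_true(share)
      }
    }
  }
})

test_that("two-way ANOVA: sums of squares, power, and design checks", {
  # balanced 2 x 2 toy data: SS partition matches the naive decomposition
  set.seed(71)
  fa <- rep(c("wt", "mut"), each = 6)
  fb <- rep(rep(c("mock", "npa"), each = 3), 2)
  y <- rnorm(12, 100, 5) + (fa == "mut") * 10 + (fb == "npa") * -30
  cmp <- two_way_anova_tukey(y, fa, fb)
  orc <- oracle_two_way_ss(y, fa, fb)
  expect_equal(cmp$anova_table[c("factor_a", "factor_b", "interaction",
                                 "residuals"), "Sum Sq"],
               unname(orc), tolerance = 1e-9)

  # all observations identical: nothing is significant
  cmp0 <- suppressWarnings(two_way_anova_tukey(rep(5, 12), fa, fb))
  expect_false(isTRUE(cmp0$anova_table$`Pr(>F)`[1] < 0.05))
  expect_false(isTRUE(cmp0$anova_table$`Pr(>F)`[2] < 0.05))

  # an injected 50-degree genotype effect at sd 1 is always detected
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    g <- rep(c("wt", "mut"), each = 8)
    tr <- rep(rep(c("m", "n"), each = 4), 2)
    yy <- rnorm(16, 120, 1) + (g == "mut") * 50
    two_way_anova_tukey(yy, g, tr)$anova_table$`Pr(>F)`[1] < 0.05
  }, TRUE)
  expect_equal(mean(hits), 1)

  # unbalanced design rejected, naming the cell
  expect_error(two_way_anova_tukey(y[-1], fa[-1], fb[-1]),
               "cell", class = "hookquant_validation_error")
})

test_that("dose-response slopes are per-decade and recover injected values", {
  gm <- data.frame(genotype = rep(c("Col-0", "hyl1-2", "se-1"), each = 2),
                   concentration_uM = rep(c(0.005, 0.05), 3),
                   mean_angle = c(160, 60, 150, 90, 170, 30))
  # zero noise: slopes are exactly the injected per-decade drops
  t0 <- simulate_angle_table(gm, noise_sd = 0, n_per_group = 5, seed = 2)
  sl0 <- dose_response_slope(t0, 0.005, 0.05)
  expect_equal(setNames(sl0$slope_deg_per_decade, sl0$genotype),
               c("Col-0" = -100, "hyl1-2" = -60, "se-1" = -140))

  # equal means: slope 0
  gm_eq <- data.frame(genotype = "x", concentration_uM = c(0.005, 0.05),
                      mean_angle = c(120, 120))
  teq <- simulate_angle_table(gm_eq, noise_sd = 0, n_per_group = 3)
  expect_equal(dose_response_slope(teq, 0.005, 0.05)$slope_deg_per_decade, 0)

  # 5-degree noise at n = 30: recovery within 10 deg/decade
  tn <- simulate_angle_table(gm, noise_sd = 5, n_per_group = 30, seed = 77)
  sln <- dose_response_slope(tn, 0.005, 0.05)
  expect_true(all(abs(setNames(sln$slope_deg_per_decade, sln$genotype) -
                        c("Col-0" = -100, "hyl1-2" = -60, "se-1" = -140))
                  < 10))

  # mock excluded from the log scale; missing cells reported
  expect_error(dose_response_slope(t0, 0, 0.05),
               class = "hookquant_validation_error")
  expect_error(dose_response_slope(t0, 0.005, 0.5),
               class = "hookquant_missing_cell_error")
})

test_that("minimum effective concentration finds the response threshold", {
  # no effect anywhere: "none"
  gm_null <- data.frame(genotype = "wt",
                        concentration_uM = c(0, 0.005, 0.05),
                        mean_angle = rep(150, 3))
  tnull <- simulate_angle_table(gm_null, noise_sd = 3, n_per_group = 15,
                                seed = 5)
  m0 <- minimum_effective_concentration(tnull)
  expect_true(is.na(m0$mec_uM))
  expect_equal(m0$mec_label, "none")

  # a single 80-degree shifted concentration is found
  gm_one <- data.frame(genotype = "wt",
                       concentration_uM = c(0, 0.05, 0.5),
                       mean_angle = c(160, 160, 80))
  tone <- simulate_angle_table(gm_one, noise_sd = 2, n_per_group = 20,
                               seed = 6)
  expect_equal(minimum_effective_concentration(tone)$mec_uM, 0.5)

  # threshold between the 2nd and 3rd nonzero dose: the 3rd is returned
  gm_thr <- data.frame(genotype = "wt",
                       concentration_uM = c(0, 0.005, 0.05, 0.5, 5),
                       mean_angle = c(160, 160, 160, 120, 120))
  hits <- vapply(1:100, function(s) {
    tb <- simulate_angle_table(gm_thr, noise_sd = 5, n_per_group = 20,
                               seed = 1000 + s)
    isTRUE(minimum_effective_concentration(tb)$mec_uM == 0.5)
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  # missing mock group rejected
  gm_nom <- data.frame(genotype = "wt", concentration_uM = c(0.05, 0.5),
                       mean_angle = c(150, 100))
  tnom <- simulate_angle_table(gm_nom, noise_sd = 2, n_per_group = 5)
  expect_error(minimum_effective_concentration(tnom),
               class = "hookquant_validation_error")
})

test_that("full pipeline separates steep from flat gradient ensembles", {
  wt <- simulate_profile_ensemble(20, mean_decay = 3, noise_sd = 8,
                                  seed = 201, genotype = "wt_like")
  hyl <- simulate_profile_ensemble(20, mean_decay = 0.3, noise_sd = 8,
                                   seed = 202, genotype = "hyl1_like")
  a_wt <- vapply(wt$profiles, ardi, 1)
  a_hyl <- vapply(hyl$profiles, ardi, 1)
  expect_lt(mean(a_wt), mean(a_hyl))
  cmp <- one_way_anova_tukey(c(a_wt, a_hyl),
                             rep(c("wt_like", "hyl1_like"), each = 20))
  expect_lt(cmp$pairs$p_adj[1], 0.05)
})
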