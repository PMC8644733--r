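# Synthetic generator: spec validation, rendering model, analytic ARDI,
# and the profile/angle-table simulators.

test_that("hook_spec rejects invalid parameters, naming the field", {
  expect_error(hook_spec(tissue_half_width = 1), "tissue_half_width",
               class = "hookquant_validation_error")
  expect_error(hook_spec(hook_angle_true = 200), "hook_angle_true",
               class = "hookquant_validation_error")
  expect_error(hook_spec(noise_sd = -1), "noise_sd",
               class = "hookquant_validation_error")
  expect_error(hook_spec(gradient_decay = -0.5), "gradient_decay",
               class = "hookquant_validation_error")
  expect_error(hook_spec(image_width = 40, image_height = 40),
               "too small", class = "hookquant_validation_error")
})

test_that("rendered signal follows the cross-section staining model", {
  # no staining, no noise: tissue = 0, background = background_level
  r0 <- render_hook_image(hook_spec(gradient_amplitude = 0,
                                    gradient_baseline = 0, noise_sd = 0,
                                    background_level = 40))
  interior <- r0$tissue_coverage == 1
  outside <- r0$tissue_coverage == 0
  expect_true(all(r0$image[interior] == 0))
  expect_true(all(r0$image[outside] == 40))

  # zero decay: every tissue cross-section is constant at B + S0
  r1 <- render_hook_image(hook_spec(gradient_decay = 0,
                                    gradient_amplitude = 5,
                                    gradient_baseline = 0, noise_sd = 0,
                                    background_level = 0))
  expect_true(all(abs(r1$image[r1$tissue_coverage == 1] - 5) < 1e-9))

  # decaying gradient: sampling along the true chord reproduces
  # B + S0 * exp(-lambda * u) at interior depths
  sp <- hook_spec(gradient_decay = 2, gradient_baseline = 20,
                  gradient_amplitude = 100, noise_sd = 0,
                  hook_angle_true = 120)
  r2 <- render_hook_image(sp)
  tr <- r2$truth$chord_endpoints_true
  u <- seq(0.1, 0.9, by = 0.1)
  pts <- sapply(u, function(ui) tr$concave + ui * (tr$convex - tr$concave))
  got <- hookquant:::bilinear_sample(r2$image, pts[1, ], pts[2, ])
  expect_equal(got, 20 + 100 * exp(-2 * u), tolerance = 0.02)
})

test_that("rendering is deterministic and truth matches the drawn geometry", {
  sp <- hook_spec(noise_sd = 6, seed = 42, hook_angle_true = 135)
  a <- render_hook_image(sp)
  b <- render_hook_image(sp)
  expect_identical(a$image, b$image)
  expect_equal(hook_angle(a$landmarks), 135, tolerance = 1e-9)
  expect_equal(a$truth$hook_angle_true, 135)
  # the true chord crosses the tissue: its midpoint is fully covered
  mid <- (a$truth$chord_endpoints_true$concave +
            a$truth$chord_endpoints_true$convex) / 2
  expect_equal(a$tissue_coverage[round(mid[1]) + 1, round(mid[2]) + 1], 1)
  # chord length is twice the tissue half-width
  d <- a$truth$chord_endpoints_true$convex -
    a$truth$chord_endpoints_true$concave
  expect_equal(sqrt(sum(d^2)), 2 * sp$tissue_half_width, tolerance = 1e-9)
})

test_that("analytic_ardi matches its closed-form and dense-grid oracles", {
  expect_identical(analytic_ardi(0, 0, 1), 0.5)
  # independent oracle: dense trapezoid + bisection on the cumulative
  expect_equal(analytic_ardi(2, 0, 1), oracle_ardi_dense(2), tolerance = 1e-5)
  expect_equal(analytic_ardi(2, 0, 1), 0.28311, tolerance = 1e-4)
  # baseline-dominated profile approaches uniform
  expect_equal(analytic_ardi(2, 1000, 1), 0.5, tolerance = 1e-3)
  expect_error(analytic_ardi(2, 0, 0), class = "hookquant_degenerate_error")
  expect_error(analytic_ardi(-1, 0, 1), class = "hookquant_validation_error")
})

test_that("analytic_ardi is strictly decreasing in decay and has the right limits", {
  lam <- c(0.5, 1, 2, 4, 8)
  vals <- vapply(lam, analytic_ardi, 1, gradient_baseline = 0,
                 gradient_amplitude = 1)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals < 0.5 & vals > 0))
  expect_equal(analytic_ardi(1e-8, 0, 1), 0.5, tolerance = 1e-6)
  expect_equal(analytic_ardi(3, 1e6, 1), 0.5, tolerance = 1e-5)
})

test_that("profile ensembles are reproducible and recover the analytic ARDI", {
  expect_error(simulate_profile_ensemble(0), class = "hookquant_validation_error")

  # degenerate distribution: identical profiles
  e0 <- simulate_profile_ensemble(3, sd_decay = 0, sd_baseline = 0,
                                  sd_amplitude = 0, noise_sd = 0, seed = 7)
  expect_identical(e0$profiles[[1]]$values, e0$profiles[[2]]$values)
  expect_identical(e0$profiles[[2]]$values, e0$profiles[[3]]$values)

  # determinism contract
  e1 <- simulate_profile_ensemble(5, sd_decay = 0.3, noise_sd = 8, seed = 11)
  e2 <- simulate_profile_ensemble(5, sd_decay = 0.3, noise_sd = 8, seed = 11)
  expect_identical(e1, e2)

  # recovery: measured ARDI ~ analytic ARDI at 5% value noise
  ens <- simulate_profile_ensemble(30, mean_decay = 3, mean_baseline = 60,
                                   mean_amplitude = 160, noise_sd = 8,
                                   seed = 123)
  measured <- vapply(ens$profiles, ardi, 1)
  expect_equal(mean(measured), analytic_ardi(3, 60, 160), tolerance = 0.02)
  expect_equal(ens$truth[[1]]$ardi_true, analytic_ardi(3, 60, 160))
})

test_that("angle tables carry the group structure and injected effects", {
  gm <- data.frame(genotype = c("Col-0", "hyl1-2"),
                   concentration_uM = c(0, 0), mean_angle = c(160, 120))
  expect_error(simulate_angle_table(gm, n_per_group = 1),
               class = "hookquant_validation_error")
  expect_error(simulate_angle_table(data.frame(g = 1)),
               class = "hookquant_validation_error")

  # zero noise: every record equals its group mean; count contract
  t0 <- simulate_angle_table(gm, noise_sd = 0, n_per_group = 5, seed = 3)
  expect_equal(nrow(t0), 10)
  expect_identical(unique(t0$angle_deg[t0$genotype == "Col-0"]), 160)
  expect_identical(unique(t0$angle_deg[t0$genotype == "hyl1-2"]), 120)

  # determinism
  expect_identical(simulate_angle_table(gm, 5, 10, seed = 9),
                   simulate_angle_table(gm, 5, 10, seed = 9))

  # a 100-degree group separation at sd 5 is detected essentially always
  gm2 <- data.frame(genotype = c("a", "b"), concentration_uM = 0,
                    mean_angle = c(160, 60))
  rejected <- vapply(1:200, function(s) {
    tb <- simulate_angle_table(gm2, noise_sd = 5, n_per_group = 20, seed = s)
    cmp <- one_way_anova_tukey(tb$angle_deg, tb$genotype)
    cmp$anova_table$`Pr(>F)`[1] < 0.05
  }, TRUE)
  expect_gte(mean(rejected), 0.99)
})
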