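# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense-grid integration, naive loops, and direct
# studentized-range arithmetic.

# Half-mass position of g(s) = B + S0*exp(-lambda*s) by dense trapezoid
# integration and bisection on the cumulative.
oracle_ardi_dense <- function(lambda, B = 0, S0 = 1, n = 1e6) {
  s <- seq(0, 1, length.out = n)
  g <- B + S0 * exp(-lambda * s)
  h <- s[2] - s[1]
  cum <- c(0, cumsum((g[-1] + g[-n]) / 2 * h))
  half <- cum[n] / 2
  lo <- 1L
  hi <- n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (cum[mid] < half) lo <- mid else hi <- mid
  }
  s[lo] + (half - cum[lo]) / (cum[hi] - cum[lo]) * h
}

# Dense-grid trapezoid area of the same profile family.
oracle_area_dense <- function(lambda, B = 0, S0 = 1, n = 1e6) {
  s <- seq(0, 1, length.out = n)
  g <- B + S0 * exp(-lambda * s)
  sum((g[-1] + g[-n]) / 2) * (s[2] - s[1])
}

# Naive per-point mean/SD loop over a list of profiles.
oracle_pointwise_mean_sd <- function(value_matrix) {
  npt <- nrow(value_matrix)
  mu <- numeric(npt)
  sdv <- numeric(npt)
  for (i in seq_len(npt)) {
    mu[i] <- mean(value_matrix[i, ])
    sdv[i] <- sd(value_matrix[i, ])
  }
  list(mean = mu, sd = sdv)
}

# Tukey HSD p-values computed directly from group summaries and the
# studentized-range CDF, independent of the package's pairing code.
oracle_tukey_p <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  ns <- tapply(values, group, length)
  means <- tapply(values, group, mean)
  dfr <- length(values) - k
  sse <- sum(unlist(lapply(levels(group), function(g) {
    v <- values[group == g]
    (v - mean(v))^2
  })))
  mse <- sse / dfr
  out <- list()
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    q <- abs(means[a] - means[b]) / sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
    out[[paste(levels(group)[a], levels(group)[b], sep = "-")]] <-
      unname(ptukey(q, nmeans = k, df = dfr, lower.tail = FALSE))
  }
  unlist(out)
}

# From-scratch balanced two-way sums-of-squares decomposition.
oracle_two_way_ss <- function(values, fa, fb) {
  fa <- factor(fa)
  fb <- factor(fb)
  gm <- mean(values)
  n_cell <- length(values) / (nlevels(fa) * nlevels(fb))
  ma <- tapply(values, fa, mean)
  mb <- tapply(values, fb, mean)
  mab <- tapply(values, interaction(fa, fb), mean)
  ss_a <- n_cell * nlevels(fb) * sum((ma - gm)^2)
  ss_b <- n_cell * nlevels(fa) * sum((mb - gm)^2)
  ss_cells <- n_cell * sum((mab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((values - gm)^2)
  c(factor_a = ss_a, factor_b = ss_b, interaction = ss_ab,
    residuals = ss_tot - ss_cells)
}

# Build an intensity_profile for the exponential family on an n-point grid.
make_exp_profile <- function(lambda, B = 0, S0 = 1, n_points = 101,
                             id = "oracle") {
  s <- seq(0, 1, length.out = n_points)
  intensity_profile(s, B + S0 * exp(-lambda * s), seedling_id = id)
}
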