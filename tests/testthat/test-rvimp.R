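test_that("subsample sizes follow the 0.632 rounding rule with distinct indices", {
  s1 <- draw_subsample(1000, seed = 1)
  expect_length(s1, 632)
  expect_length(unique(s1), 632)
  s2 <- draw_subsample(500, seed = 2)
  expect_length(s2, 316)
  expect_true(all(s2 %in% 1:500))
  expect_error(draw_subsample(1, fraction = 0.3), "zero rows")
})

test_that("subsampling is uniform over rows", {
  n <- 10
  draws <- 10000
  counts <- integer(n)
  for (s in seq_len(draws)) {
    idx <- draw_subsample(n, seed = s)
    counts[idx] <- counts[idx] + 1L
  }
  size <- floor(0.632 * n + 0.5)
  p <- size / n
  se <- sqrt(p * (1 - p) / draws)
  expect_true(all(abs(counts / draws - p) < 5 * se))
})

test_that("the quantile convention interpolates adjacent order statistics", {
  expect_identical(empirical_quantile(c(5, 1, 4, 2, 3), 0.5), 3)
  set.seed(3)
  v <- sort(rnorm(100))
  q95 <- empirical_quantile(v, 0.95)
  expect_gte(q95, v[95])
  expect_lte(q95, v[96])
  # independent sort-and-index oracle
  for (k in 1:200) {
    x <- rnorm(sample(5:200, 1))
    q <- runif(1, 0.01, 0.99)
    xs <- sort(x)
    h <- (length(x) - 1) * q + 1
    lo <- floor(h)
    oracle <- xs[lo] + (h - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
    expect_equal(empirical_quantile(x, q), oracle, tolerance = 1e-12)
  }
  expect_error(empirical_quantile(numeric(0), 0.5), "nonempty")
})

test_that("forced separation rejects both hypotheses at the minimal p-value", {
  m <- 100
  density_shifted <- seq(0.01, 0.5, length.out = m)
  dec <- resvimp:::rvimp_decide(vimp_a = 1, vimp_b_full = mean(density_shifted),
                                density_shifted = density_shifted, alpha = 0.05)
  expect_true(dec$reject_h1)
  expect_true(dec$reject_h2)
  expect_equal(dec$p1, 1 / (m + 1))
  expect_equal(dec$p2, 1 / (m + 1))
  # and the opposite corner: density entirely above vimp_a and straddling 0
  dec2 <- resvimp:::rvimp_decide(0.0, 0.1, seq(-0.2, 0.4, length.out = m), 0.05)
  expect_false(dec2$reject_h1)
  expect_false(dec2$reject_h2)
})

test_that("decisions and p-values derive consistently from the order statistics", {
  set.seed(4)
  for (k in 1:50) {
    m <- sample(c(50, 100, 200), 1)
    shifted <- rnorm(m)
    va <- rnorm(1)
    dec <- resvimp:::rvimp_decide(va, mean(shifted), shifted, 0.05)
    expect_identical(dec$reject_h1, va > empirical_quantile(shifted, 0.95))
    expect_identical(dec$reject_h2, empirical_quantile(shifted, 0.05) > 0)
    # p1 shrinks as vimp_a grows through the density
    dec_hi <- resvimp:::rvimp_decide(va + 1, mean(shifted), shifted, 0.05)
    expect_lte(dec_hi$p1, dec$p1)
  }
})

test_that("the shifted density is recentered at the full-sample VIMP_B", {
  sp <- scenario_spec(design = "A", n = 150, c = 0.3,
                      target_C = 0.6, target_spC = 0.4, seed = 5)
  d <- generate_design_a(sp)
  fit <- suppressWarnings(rvimp(d, z = "Z", m = 25,
                                forest = forest_spec(num_trees = 40), seed = 6))
  expect_equal(mean(fit$density_shifted), fit$vimp_b_full, tolerance = 1e-12)
  expect_identical(fit$q_upper, empirical_quantile(fit$density_shifted, 0.95))
  expect_identical(fit$q_lower, empirical_quantile(fit$density_shifted, 0.05))
  expect_length(fit$density_raw, 25)
})

test_that("the full test is deterministic under a fixed master seed", {
  sp <- scenario_spec(design = "A", n = 120, c = 0.3,
                      target_C = 0.6, target_spC = 0.2, seed = 7)
  d <- generate_design_a(sp)
  f1 <- suppressWarnings(rvimp(d, z = "Z", m = 20,
                               forest = forest_spec(num_trees = 30), seed = 8))
  f2 <- suppressWarnings(rvimp(d, z = "Z", m = 20,
                               forest = forest_spec(num_trees = 30), seed = 8))
  expect_identical(f1$vimp_a, f2$vimp_a)
  expect_identical(f1$density_raw, f2$density_raw)
  expect_identical(f1$p1, f2$p1)
})

test_that("model-B VIMP is plumbing-deterministic and row-sensitive", {
  d <- make_regression_data(n = 80, p = 3, seed = 9)
  v_all <- vimp_model_b(d, "x1", forest = small_spec(num_trees = 30), seed = 10)
  v_all2 <- vimp_model_b(d, "x1", forest = small_spec(num_trees = 30), seed = 10)
  rows <- draw_subsample(80, seed = 11)
  v_sub <- vimp_model_b(d, "x1", forest = small_spec(num_trees = 30),
                        rows = rows, seed = 10)
  expect_identical(v_all, v_all2)
  expect_false(identical(v_all, v_sub))
})

test_that("an exactly explained z has residual importance exactly zero", {
  set.seed(12)
  n <- 80
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  z <- 2 * x1  # no residual information at all
  d <- tabular_dataset(cbind(X1 = x1, X2 = x2, Z = z), x2 + rnorm(n), "regression")
  v <- vimp_model_b(d, "Z", forest = small_spec(num_trees = 30), seed = 13)
  expect_identical(v, 0)
})

test_that("residualizing an independent z leaves its importance unchanged", {
  # Z independent of the other predictors: eps_Z is centered Z, so the two
  # models estimate the same importance up to Monte-Carlo noise.
  set.seed(14)
  diffs <- vapply(1:8, function(k) {
    n <- 300
    x1 <- rnorm(n)
    z <- rnorm(n)
    y <- x1 + z + rnorm(n)
    d <- tabular_dataset(cbind(X1 = x1, Z = z), y, "regression")
    a <- vimp_model_a(d, "Z", forest = forest_spec(num_trees = 100),
                      seed = 100 + k, all = FALSE)
    b <- vimp_model_b(d, "Z", forest = forest_spec(num_trees = 100),
                      seed = 200 + k)
    a$vimp - b
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-8)
})

test_that("rvimp validates its configuration", {
  d <- make_regression_data(n = 60, p = 3, seed = 15)
  expect_error(rvimp(d, z = "x1", m = 10), "at least 20")
  expect_warning(rvimp(d, z = "x1", m = 25, forest = small_spec(10), seed = 1),
                 "m < 100")
  d1 <- tabular_dataset(d$features[, 1, drop = FALSE], d$outcome, "regression")
  expect_error(rvimp(d1, z = "x1"), "besides z")
})

test_that("the formula interface matches the dataset interface", {
  set.seed(16)
  df <- data.frame(X1 = rnorm(80), Z = rnorm(80))
  df$Y <- df$X1 + df$Z + rnorm(80)
  f1 <- suppressWarnings(rvimp(Y ~ ., data = df, z = "Z", m = 20,
                               forest = small_spec(num_trees = 30), seed = 17))
  d <- tabular_dataset(as.matrix(df[c("X1", "Z")]), df$Y, "regression")
  f2 <- suppressWarnings(rvimp(d, z = "Z", m = 20,
                               forest = small_spec(num_trees = 30), seed = 17))
  expect_identical(f1$vimp_a, f2$vimp_a)
  expect_identical(f1$density_shifted, f2$density_shifted)
  # binary outcomes switch to a classification forest automatically
  df$Yb <- as.numeric(df$Y > 0)
  fb <- suppressWarnings(rvimp(Yb ~ X1 + Z, data = df, z = "Z", m = 20,
                               forest = small_spec(num_trees = 30), seed = 18))
  expect_identical(fb$task, "classification")
})

test_that("print, summary and residuals expose the fitted quantities", {
  sp <- scenario_spec(design = "A", n = 120, c = 0.3,
                      target_C = 0.6, target_spC = 0.2, seed = 19)
  d <- generate_design_a(sp)
  fit <- suppressWarnings(rvimp(d, z = "Z", m = 20,
                                forest = small_spec(num_trees = 30), seed = 20))
  expect_output(print(fit), "VIMP_A\\(Z\\)")
  expect_output(print(summary(fit)), "Per-feature")
  expect_length(residuals(fit), 120)
  # residuals are the full-sample OLS residuals of Z on X1..X5
  r_oracle <- residuals(fit_g(d$features[, 1:5], d$features[, "Z"], "ols"))
  expect_equal(residuals(fit), r_oracle, tolerance = 1e-12)
})
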