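#' Draw a subsample of row indices
#'
#' Draws `round(fraction * n)` distinct row indices uniformly without
#' replacement. The default fraction 0.632 follows the 0.632-rule: each
#' observation's inclusion probability matches its probability of entering a
#' size-`n` bootstrap sample, while avoiding duplicate rows that would blur
#' the in-bag/out-of-bag split of the forests trained on the subsample.
#'
#' @param n Number of rows.
#' @param fraction Subsample fraction in (0, 1); ties in `fraction * n` round
#'   half up.
#' @param seed Integer seed.
#' @return Integer vector of distinct indices in `1:n`.
#' @examples
#' length(draw_subsample(500, seed = 1))  # 316
#' @export
draw_subsample <- function(n, fraction = 0.632, seed = 1L) {
  stopifnot(n >= 1, fraction > 0, fraction < 1)
  size <- floor(fraction * n + 0.5)
  if (size < 1L) stop("fraction * n rounds to zero rows", call. = FALSE)
  with_seed(seed, sample.int(n, size, replace = FALSE))
}

#' Empirical quantile (order-statistic, linear interpolation)
#'
#' The quantile convention used for all test decisions: linear interpolation
#' between the closest order statistics (type 7, the default of mainstream
#' numerical stacks). Fixed here because the rejection boundary of the
#' resampling test depends on the convention.
#'
#' @param values Nonempty numeric vector.
#' @param q Probability strictly between 0 and 1.
#' @return Scalar quantile.
#' @export
empirical_quantile <- function(values, q) {
  if (length(values) == 0L) stop("`values` must be nonempty", call. = FALSE)
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  unname(quantile(values, probs = q, type = 7, names = FALSE))
}

# Decision rule shared by the full test and by tests of the rule itself:
# order statistics of the shifted density against vimp_a and 0, with the
# add-one permutation-test correction for the p-values.
#' @noRd
rvimp_decide <- function(vimp_a, vimp_b_full, density_shifted, alpha) {
  m <- length(density_shifted)
  q_upper <- empirical_quantile(density_shifted, 1 - alpha)
  q_lower <- empirical_quantile(density_shifted, alpha)
  list(q_upper = q_upper, q_lower = q_lower,
       reject_h1 = vimp_a > q_upper,
       reject_h2 = q_lower > 0,
       p1 = (1 + sum(density_shifted >= vimp_a)) / (m + 1),
       p2 = (1 + sum(density_shifted <= 0)) / (m + 1))
}

#' VIMP of the feature of interest under the original model (model A)
#'
#' Trains a forest on all predictors (including `z`) and returns the
#' permutation importance of `z` together with the full importance vector.
#'
#' @param data A [tabular_dataset()].
#' @param z Column name or index of the feature of interest.
#' @param forest A [forest_spec()].
#' @param n_perm Permutations per tree.
#' @param seed Integer seed (forest and permutations).
#' @param all Also compute the importance of every other feature (skipped in
#'   large simulation loops).
#' @return List with elements `vimp` (scalar, importance of `z`) and
#'   `all` (a `"vimp_vector"` over every feature, `NULL` if `all = FALSE`).
#'   `vimp` is identical either way: the per-feature permutation seeds are
#'   spawned on the same schedule.
#' @export
vimp_model_a <- function(data, z, forest = forest_spec(), n_perm = 1L,
                         seed = 1L, all = TRUE) {
  j <- match_feature(data, z)
  s <- spawn_seeds(seed, 2L)
  fit <- train_forest(data, forest, seed = s[1])
  if (all) {
    av <- all_vimps(fit, data, n_perm = n_perm, seed = s[2])
    list(vimp = unname(av$values[j]), all = av)
  } else {
    vs <- spawn_seeds(s[2], ncol(data$features))
    v <- permutation_vimp(fit, data, j, n_perm = n_perm, seed = vs[j])
    list(vimp = as.numeric(v), all = NULL)
  }
}

#' VIMP of the residualized feature under the adjusted model (model B)
#'
#' On the given rows: fits `g` explaining `z` by the other predictors,
#' replaces the `z` column by the residuals, trains a forest on the adjusted
#' data and returns the permutation importance of the residual column.
#'
#' @inheritParams vimp_model_a
#' @param g Residualizing model class, see [fit_g()].
#' @param g_lambda Ridge penalty when `g = "ridge"`.
#' @param g_forest [forest_spec()] for `g = "rf"`.
#' @param rows Optional integer vector of rows to use (default: all). Both
#'   `g` and the forest are fit on exactly these rows.
#' @param all Also return the full importance vector of the adjusted model.
#' @return If `all = FALSE` (default) a scalar; otherwise a list `vimp`/`all`
#'   as in [vimp_model_a()].
#' @export
vimp_model_b <- function(data, z, g = c("ols", "ridge", "rf"),
                         forest = forest_spec(), g_lambda = 1,
                         g_forest = forest_spec(), rows = NULL,
                         n_perm = 1L, seed = 1L, all = FALSE) {
  g <- match.arg(g)
  j <- match_feature(data, z)
  if (!is.null(rows)) data <- subset_rows(data, rows)
  s <- spawn_seeds(seed, 3L)
  x_minus <- data$features[, -j, drop = FALSE]
  gfit <- fit_g(x_minus, data$features[, j], method = g, lambda = g_lambda,
                forest = g_forest, seed = s[1])
  data_b <- replace_feature(data, j, residuals(gfit))
  fit <- train_forest(data_b, forest, seed = s[2])
  if (all) {
    av <- all_vimps(fit, data_b, n_perm = n_perm, seed = s[3])
    list(vimp = unname(av$values[j]), all = av, g = gfit)
  } else {
    vs <- spawn_seeds(s[3], ncol(data$features))
    v <- permutation_vimp(fit, data_b, j, n_perm = n_perm, seed = vs[j])
    as.numeric(v)
  }
}

#' Residual permutation importance test
#'
#' Tests whether the permutation importance of a selected predictor `z` in a
#' random forest is partially borrowed from correlated predictors, and whether
#' the part of `z` they cannot explain still contributes to prediction.
#'
#' The procedure compares two quantities: `vimp_a`, the out-of-bag permutation
#' importance of `z` in the forest trained on all predictors, and
#' `vimp_b`, the importance of the residuals of `z` (after regressing `z` on
#' the other predictors with model class `g`) in a forest where `z` is
#' replaced by those residuals. The sampling distribution of `vimp_b` is
#' estimated by `m` subsamples of `round(0.632 n)` rows drawn without
#' replacement; within each subsample `g` is refit and the adjusted forest
#' retrained. Because importance estimates from subsamples of size `0.632 n`
#' are systematically attenuated relative to the full sample, the empirical
#' density is shifted so its mean equals the full-sample `vimp_b` before the
#' decisions are taken:
#'
#' * H0(1) (`vimp_a == vimp_b`) is rejected when `vimp_a` exceeds the
#'   empirical `(1 - alpha)`-quantile of the shifted density — evidence that
#'   part of `z`'s importance originates from correlated predictors.
#' * H0(2) (`vimp_b == 0`) is rejected when the empirical `alpha`-quantile of
#'   the shifted density exceeds 0 — evidence that `z`'s residual information
#'   contributes to prediction in its own right.
#'
#' @param x A [tabular_dataset()], or a formula `outcome ~ .` evaluated in
#'   `data`.
#' @param ... Passed on between methods.
#' @return An object of class `"rvimp"`; see Details for its main fields.
#'   Methods: [print.rvimp()], [summary.rvimp()], [plot.rvimp()],
#'   [residuals.rvimp()].
#'
#' @details The returned object contains `vimp_a`, `vimp_b_full`, the raw and
#' shifted subsample densities (`density_raw`, `density_shifted`), the
#' decision quantiles `q_upper`/`q_lower`, decisions `reject_h1`/`reject_h2`,
#' add-one-corrected p-values `p1`/`p2`, the full-sample residual vector, and
#' (when `companion = TRUE`) the importance vectors of every feature under
#' both models for [plot.rvimp()]'s comparison display.
#'
#' @examples
#' d <- generate_design_a(scenario_spec(n = 150, seed = 1))
#' fit <- rvimp(d, z = "Z", m = 30, forest = forest_spec(num_trees = 50),
#'              seed = 1)
#' fit
#' @export
rvimp <- function(x, ...) UseMethod("rvimp")

#' @rdname rvimp
#' @param data Data frame holding the model-frame variables (formula method).
#' @param task `"regression"` or `"classification"`; if `NULL`, classification
#'   is assumed when the outcome takes exactly the values 0/1.
#' @export
rvimp.formula <- function(x, data, task = NULL, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  feats <- mf[, -1, drop = FALSE]
  if (is.null(task)) {
    task <- if (all(y %in% c(0, 1)) && length(unique(y)) <= 2L)
      "classification" else "regression"
  }
  d <- tabular_dataset(as.matrix(feats), as.numeric(y), task)
  out <- rvimp.tabular_dataset(d, ...)
  out$call <- match.call()
  out
}

#' @rdname rvimp
#' @param z Column name or index of the feature of interest.
#' @param g Model class for the residualization, see [fit_g()].
#' @param m Number of subsamples for the density estimate (>= 20; the usual
#'   choice is 100).
#' @param subsample_fraction Subsample fraction, see [draw_subsample()].
#' @param alpha Significance level for both one-sided tests.
#' @param forest [forest_spec()] used for every forest (full-sample and
#'   subsample models alike).
#' @param g_lambda Ridge penalty when `g = "ridge"`.
#' @param g_forest [forest_spec()] when `g = "rf"`.
#' @param n_perm Permutations per tree in each VIMP evaluation.
#' @param seed Master seed; all subsampling, refitting and permutation seeds
#'   are spawned from it.
#' @param companion Also compute the importance of every other feature under
#'   both models (needed for the comparison plot; switch off in large
#'   simulation loops).
#' @export
rvimp.tabular_dataset <- function(x, z, g = c("ols", "ridge", "rf"),
                                  m = 100L, subsample_fraction = 0.632,
                                  alpha = 0.05, forest = forest_spec(),
                                  g_lambda = 1, g_forest = forest_spec(),
                                  n_perm = 1L, seed = 1L, companion = TRUE,
                                  ...) {
  g <- match.arg(g)
  data <- x
  j <- match_feature(data, z)
  zname <- colnames(data$features)[j]
  n <- nrow(data$features)
  p <- ncol(data$features)
  if (p < 2L) stop("the test needs at least one predictor besides z", call. = FALSE)
  m <- as.integer(m)
  if (m < 20L) stop("m must be at least 20 for quantile estimation", call. = FALSE)
  if (m < 100L) warning("m < 100 gives unstable tail quantiles; ",
                        "m = 100 is the usual choice", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  if (alpha * m < 1) {
    warning("alpha * m < 1: the requested tail holds less than one subsample; ",
            "decisions still use interpolated order statistics", call. = FALSE)
  }
  s <- spawn_seeds(seed, 4L)
  # Full-sample model A and model B
  a <- vimp_model_a(data, j, forest = forest, n_perm = n_perm, seed = s[1],
                    all = companion)
  sb <- spawn_seeds(s[2], 3L)
  x_minus <- data$features[, -j, drop = FALSE]
  g_full <- fit_g(x_minus, data$features[, j], method = g, lambda = g_lambda,
                  forest = g_forest, seed = sb[1])
  eps_full <- residuals(g_full)
  data_b <- replace_feature(data, j, eps_full)
  fit_b <- train_forest(data_b, forest, seed = sb[2])
  b_all <- if (companion) all_vimps(fit_b, data_b, n_perm = n_perm, seed = sb[3])
  vimp_b_full <- if (companion) {
    unname(b_all$values[j])
  } else {
    vs <- spawn_seeds(sb[3], p)
    as.numeric(permutation_vimp(fit_b, data_b, j, n_perm = n_perm, seed = vs[j]))
  }
  # Subsample density of the residual importance (g refit per subsample)
  sub_seeds <- matrix(spawn_seeds(s[3], 3L * m), nrow = m)
  density_raw <- numeric(m)
  for (b in seq_len(m)) {
    idx <- draw_subsample(n, subsample_fraction, seed = sub_seeds[b, 1])
    density_raw[b] <- vimp_model_b(data, j, g = g, forest = forest,
                                   g_lambda = g_lambda, g_forest = g_forest,
                                   rows = idx, n_perm = n_perm,
                                   seed = sub_seeds[b, 2])
  }
  density_shifted <- density_raw + (vimp_b_full - mean(density_raw))
  dec <- rvimp_decide(a$vimp, vimp_b_full, density_shifted, alpha)
  structure(c(list(z = zname, task = data$task, n = n, p = p,
                   vimp_a = a$vimp, vimp_b_full = vimp_b_full,
                   density_raw = density_raw, density_shifted = density_shifted),
              dec,
              list(alpha = alpha, m = m,
                   subsample_fraction = subsample_fraction,
                   g_method = g, residuals_full = eps_full,
                   vimp_a_all = a$all, vimp_b_all = b_all,
                   forest_spec = forest, seed = as.integer(seed),
                   version = as.character(utils::packageVersion("resvimp")),
                   call = match.call())),
            class = "rvimp")
}

#' @export
#' @describeIn rvimp Print the two importances, decisions and p-values.
print.rvimp <- function(x, digits = 4, ...) {
  cat("Residual permutation importance test\n")
  cat("  feature of interest: ", x$z, "  (", x$task, " forest, n = ", x$n,
      ", m = ", x$m, " subsamples, g = ", x$g_method, ")\n", sep = "")
  cat("  VIMP_A(", x$z, ")        = ", signif(x$vimp_a, digits), "\n", sep = "")
  cat("  VIMP_B(residual) = ", signif(x$vimp_b_full, digits), "\n", sep = "")
  cat("  H0(1) importance not inflated by correlated predictors: ",
      if (x$reject_h1) "rejected" else "not rejected",
      " (p = ", signif(x$p1, 3), ")\n", sep = "")
  cat("  H0(2) residual information unimportant:                 ",
      if (x$reject_h2) "rejected" else "not rejected",
      " (p = ", signif(x$p2, 3), ")\n", sep = "")
  invisible(x)
}

#' Summary of a residual-VIMP test
#'
#' @param object An [rvimp()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.rvimp"` with the test quantities and,
#'   when available, a per-feature table of model-A and model-B importances.
#' @export
summary.rvimp <- function(object, ...) {
  tab <- if (!is.null(object$vimp_a_all)) {
    data.frame(feature = object$vimp_a_all$feature_names,
               vimp_model_a = unname(object$vimp_a_all$values),
               vimp_model_b = unname(object$vimp_b_all$values))
  }
  structure(list(fit = object, table = tab), class = "summary.rvimp")
}

#' @export
print.summary.rvimp <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  f <- x$fit
  cat("  subsample density of VIMP_B (shifted): mean ",
      signif(mean(f$density_shifted), digits),
      ", [", signif(f$q_lower, digits), ", ", signif(f$q_upper, digits),
      "] = [alpha, 1-alpha] quantiles\n", sep = "")
  if (!is.null(x$table)) {
    cat("\nPer-feature permutation importance (model A vs model B):\n")
    tab <- x$table
    tab$feature[tab$feature == f$z] <- paste0(f$z, " (residual in B)")
    tab[-1] <- lapply(tab[-1], signif, digits = digits)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' @export
#' @describeIn rvimp Full-sample residuals of `z` given the other predictors.
residuals.rvimp <- function(object, ...) object$residuals_full
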