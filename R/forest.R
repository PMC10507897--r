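#' Random forest hyperparameters
#'
#' Collects the forest hyperparameters used throughout the package. Defaults
#' follow the conventions of the `ranger`/`randomForest` family: 500 trees,
#' `mtry = floor(sqrt(p))` for classification and `max(floor(p/3), 1)` for
#' regression, minimum node size 5 (regression) or 1 (classification), and
#' bootstrap samples of size `n` drawn with replacement. `mtry`/
#' `min_node_size` left `NULL` are resolved at training time from the data.
#'
#' @param num_trees Number of trees.
#' @param mtry Number of candidate split variables per node, or `NULL` for the
#'   task-dependent default.
#' @param min_node_size Minimal terminal node size, or `NULL` for the
#'   task-dependent default.
#' @param sample_fraction Fraction of `n` drawn for each tree, in (0, 1].
#' @param replace Draw with replacement (bootstrap, the default) or without.
#' @param seed Integer seed; the same spec, seed and data give an identical
#'   forest.
#' @return An object of class `"forest_spec"`.
#' @export
forest_spec <- function(num_trees = 500L, mtry = NULL, min_node_size = NULL,
                        sample_fraction = 1, replace = TRUE, seed = 1L) {
  stopifnot(num_trees >= 1, sample_fraction > 0, sample_fraction <= 1)
  if (!is.null(mtry)) stopifnot(mtry >= 1)
  if (!is.null(min_node_size)) stopifnot(min_node_size >= 1)
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = min_node_size,
                 sample_fraction = sample_fraction, replace = isTRUE(replace),
                 seed = as.integer(seed)),
            class = "forest_spec")
}

#' @noRd
resolve_spec <- function(spec, task, p) {
  if (is.null(spec$mtry)) {
    spec$mtry <- if (task == "classification") max(floor(sqrt(p)), 1L)
                 else max(floor(p / 3), 1L)
  }
  if (spec$mtry > p) stop("mtry exceeds the number of features", call. = FALSE)
  if (is.null(spec$min_node_size)) {
    spec$min_node_size <- if (task == "classification") 1L else 5L
  }
  spec
}

#' Train a random forest with out-of-bag bookkeeping
#'
#' Trains a regression or classification forest (via the `ranger` backend) and
#' records, for every tree, which rows were in its bootstrap sample and which
#' are out-of-bag (OOB). The OOB rows act as each tree's internal test set for
#' [oob_error()] and [permutation_vimp()].
#'
#' @param data A [tabular_dataset()].
#' @param spec A [forest_spec()]; `seed` may be overridden here.
#' @param seed Optional seed overriding `spec$seed`.
#' @param ensemble_oob Also compute the backend's aggregated out-of-bag
#'   predictions (`$ranger$predictions`). Off by default: the package's own
#'   per-tree OOB statistics do not need them, and skipping them speeds up
#'   the resampling loop.
#' @return An object of class `"rvimp_forest"`: the fitted backend forest plus
#'   per-tree in-bag counts (`inbag`), OOB row indices (`oob`), the resolved
#'   spec and the loss implied by the task (squared error for regression,
#'   0-1 loss for classification).
#' @examples
#' d <- tabular_dataset(matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b"))),
#'                      rnorm(30), "regression")
#' f <- train_forest(d, forest_spec(num_trees = 25))
#' oob_error(f, d)
#' @export
train_forest <- function(data, spec = forest_spec(), seed = NULL,
                         ensemble_oob = FALSE) {
  stopifnot(inherits(data, "tabular_dataset"), inherits(spec, "forest_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  p <- ncol(data$features)
  spec <- resolve_spec(spec, data$task, p)
  y <- if (data$task == "classification") factor(data$outcome, levels = c(0, 1))
       else data$outcome
  rf <- ranger::ranger(x = data$features, y = y,
                       num.trees = spec$num_trees, mtry = spec$mtry,
                       min.node.size = spec$min_node_size,
                       replace = spec$replace,
                       sample.fraction = spec$sample_fraction,
                       oob.error = ensemble_oob,
                       keep.inbag = TRUE, num.threads = 1L, seed = spec$seed)
  oob <- lapply(rf$inbag.counts, function(cnt) which(cnt == 0L))
  n_empty <- sum(lengths(oob) == 0L)
  if (n_empty > 0L) {
    warning(n_empty, " tree(s) have no out-of-bag rows and are skipped in ",
            "OOB error and importance averages", call. = FALSE)
  }
  # Outcome in the backend's tree-value coding: classification trees store
  # the predicted class as the factor level index, regression trees the value.
  y_tree <- if (data$task == "classification") {
    as.numeric(as.integer(y))
  } else data$outcome
  structure(list(ranger = rf, spec = spec, task = data$task,
                 loss = if (data$task == "regression") "squared_error" else "zero_one",
                 n = nrow(data$features), feature_names = colnames(data$features),
                 inbag = rf$inbag.counts, oob = oob, y_tree = y_tree),
            class = "rvimp_forest")
}

#' @export
print.rvimp_forest <- function(x, ...) {
  cat("<rvimp_forest> ", x$spec$num_trees, " trees, ", x$task,
      " (", x$loss, "), n = ", x$n, ", mtry = ", x$spec$mtry, "\n", sep = "")
  invisible(x)
}

#' @noRd
check_forest_data <- function(forest, data) {
  stopifnot(inherits(forest, "rvimp_forest"), inherits(data, "tabular_dataset"))
  if (nrow(data$features) != forest$n) {
    stop("forest was trained on ", forest$n, " rows but data has ",
         nrow(data$features), call. = FALSE)
  }
  if (!identical(colnames(data$features), forest$feature_names)) {
    stop("feature columns do not match the forest's training columns", call. = FALSE)
  }
}

#' Out-of-bag prediction error
#'
#' Mean over trees of each tree's loss on its own out-of-bag rows (squared
#' error for regression, 0-1 loss for classification). Trees without OOB rows
#' do not contribute to the average.
#'
#' @param forest An [train_forest()] fit.
#' @param data The dataset the forest was trained on.
#' @return Non-negative scalar.
#' @export
oob_error <- function(forest, data) {
  check_forest_data(forest, data)
  task <- if (forest$task == "regression") 0L else 1L
  losses <- cpp_tree_oob_losses(forest$ranger$forest, data$features,
                                forest$y_tree, forest$oob, task)
  mean(losses, na.rm = TRUE)
}

#' Out-of-bag permutation importance of one feature
#'
#' Breiman's permutation variable importance: for each tree, the feature's
#' values are permuted among that tree's out-of-bag rows only, the tree's OOB
#' loss is recomputed, and the difference to the unpermuted OOB loss is
#' averaged over trees (and over `n_perm` independent permutations per tree).
#' A feature unrelated to the outcome has importance near zero; negative
#' values are finite-sample noise and are reported as-is.
#'
#' @param forest An [train_forest()] fit.
#' @param data The dataset the forest was trained on.
#' @param feature Column name or index.
#' @param n_perm Number of permutations per tree (default 1, matching the
#'   usual convention; increase to reduce Monte-Carlo variance).
#' @param seed Seed for the permutations. One child seed is drawn per
#'   (tree, permutation) so results do not depend on evaluation order.
#' @param permute_fun Optional hook replacing the random permutation: a
#'   function `(values, tree, perm)` returning the permuted values for that
#'   tree's OOB rows. Intended for testing (e.g. forcing the identity).
#' @return Scalar importance, with attribute `"per_tree"` holding the vector
#'   of per-tree loss differences (NA for trees without OOB rows).
#' @export
permutation_vimp <- function(forest, data, feature, n_perm = 1L, seed = 1L,
                             permute_fun = NULL) {
  check_forest_data(forest, data)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  j <- match_feature(data, feature)
  task <- if (forest$task == "regression") 0L else 1L
  base <- cpp_tree_oob_losses(forest$ranger$forest, data$features,
                              forest$y_tree, forest$oob, task)
  ntree <- forest$spec$num_trees
  z <- data$features[, j]
  seeds <- if (is.null(permute_fun)) spawn_seeds(seed, ntree * n_perm) else NULL
  permvals <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    o <- forest$oob[[t]]
    no <- length(o)
    pv <- matrix(0, max(no, 1L), n_perm)
    if (no > 0L) {
      zo <- z[o]
      for (k in seq_len(n_perm)) {
        pv[, k] <- if (is.null(permute_fun)) {
          with_seed(seeds[(t - 1L) * n_perm + k], zo[sample.int(no)])
        } else {
          permute_fun(zo, t, k)
        }
      }
    }
    permvals[[t]] <- pv
  }
  perm <- cpp_perm_oob_losses(forest$ranger$forest, data$features,
                              forest$y_tree, forest$oob, j, permvals, task)
  per_tree <- rowMeans(perm) - base
  structure(mean(per_tree, na.rm = TRUE), per_tree = per_tree)
}

#' Permutation importance of every feature
#'
#' Applies [permutation_vimp()] to each column in order, using an independent
#' child seed per feature.
#'
#' @inheritParams permutation_vimp
#' @return An object of class `"vimp_vector"`: named importance values plus a
#'   `per_tree` matrix (trees x features) of per-tree loss differences.
#' @export
all_vimps <- function(forest, data, n_perm = 1L, seed = 1L) {
  check_forest_data(forest, data)
  p <- ncol(data$features)
  seeds <- spawn_seeds(seed, p)
  per_tree <- matrix(NA_real_, forest$spec$num_trees, p,
                     dimnames = list(NULL, forest$feature_names))
  values <- numeric(p)
  for (j in seq_len(p)) {
    v <- permutation_vimp(forest, data, j, n_perm = n_perm, seed = seeds[j])
    values[j] <- as.numeric(v)
    per_tree[, j] <- attr(v, "per_tree")
  }
  names(values) <- forest$feature_names
  structure(list(values = values, per_tree = per_tree,
                 feature_names = forest$feature_names),
            class = "vimp_vector")
}

#' @export
print.vimp_vector <- function(x, ...) {
  cat("<vimp_vector> permutation importance (", ncol(x$per_tree),
      " features, ", nrow(x$per_tree), " trees)\n", sep = "")
  print(x$values, ...)
  invisible(x)
}
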