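# Small datasets and specs shared across test files. Everything is generated
# in code under fixed seeds; nothing is read from disk.

make_regression_data <- function(n = 60, p = 3, seed = 1, signal = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- if (signal) x[, 1] + rnorm(n, sd = 0.3) else rnorm(n)
  tabular_dataset(x, y, "regression")
}

# Two exactly separable clusters: every tree can classify its OOB rows
# perfectly, so the 0-1 OOB error is identically zero.
make_separable_data <- function(n = 40, seed = 1) {
  set.seed(seed)
  half <- n / 2
  x <- cbind(x1 = c(rnorm(half, -5, 0.1), rnorm(half, 5, 0.1)),
             x2 = rnorm(n))
  y <- rep(c(0, 1), each = half)
  tabular_dataset(x, y, "classification")
}

small_spec <- function(num_trees = 25, seed = 1) {
  forest_spec(num_trees = num_trees, seed = seed)
}

# Independent per-tree OOB loss oracle built on the backend's own predict():
# no code shared with the package's Rcpp traversal.
oracle_tree_oob_loss <- function(forest, data, tree) {
  o <- forest$oob[[tree]]
  if (length(o) == 0) return(NA_real_)
  pred <- predict(forest$ranger, data.frame(data$features[o, , drop = FALSE]),
                  predict.all = TRUE, num.threads = 1)$predictions
  pred_t <- if (is.matrix(pred)) pred[, tree] else pred[tree]
  if (data$task == "regression") {
    mean((data$outcome[o] - pred_t)^2)
  } else {
    labels <- as.numeric(forest$ranger$forest$levels[pred_t])
    mean(labels != data$outcome[o])
  }
}
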