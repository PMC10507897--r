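#' Visualize the resampling test decision
#'
#' Kernel-density curve of the shifted subsample density of the residual
#' importance, with the observed marginal importance `vimp_a` as a solid
#' vertical line, the full-sample residual importance as a dotted line, and
#' the upper rejection tail (beyond the `(1 - alpha)`-quantile used for the
#' H0(1) decision) shaded. The kernel density is display-only; decisions are
#' taken on the empirical order statistics. A degenerate density (all `m`
#' values equal) falls back to a rug display.
#'
#' @param result An [rvimp()] fit.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `result`.
#' @export
plot_test_density <- function(result, ...) {
  stopifnot(inherits(result, "rvimp"))
  v <- result$density_shifted
  xr <- range(c(v, result$vimp_a, result$vimp_b_full, result$q_upper))
  xr <- xr + c(-1, 1) * 0.05 * diff(xr)
  if (diff(range(v)) == 0) {
    plot(NA, xlim = xr, ylim = c(0, 1), xlab = "VIMP_B(residual)", ylab = "",
         yaxt = "n", main = paste0("Resampling test for ", result$z), ...)
    graphics::rug(v, lwd = 2)
  } else {
    d <- density(v)
    plot(d, xlim = xr, xlab = "VIMP_B(residual)",
         main = paste0("Resampling test for ", result$z), ...)
    tail_x <- d$x[d$x >= result$q_upper]
    if (length(tail_x) > 1) {
      tail_y <- d$y[d$x >= result$q_upper]
      graphics::polygon(c(tail_x[1], tail_x, tail_x[length(tail_x)]),
                        c(0, tail_y, 0), col = "grey80", border = NA)
      graphics::lines(d)
    }
  }
  graphics::abline(v = result$vimp_a, lty = 1, lwd = 2)
  graphics::abline(v = result$vimp_b_full, lty = 3, lwd = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 3), lwd = 2,
                   legend = c(paste0("VIMP_A(", result$z, ")"),
                              "VIMP_B (full sample)"))
  invisible(result)
}

#' Compare per-feature importance under the original and adjusted models
#'
#' Paired bars of each feature's permutation importance in model A (original
#' predictors) and model B (feature of interest replaced by its residuals),
#' sorted by the model-A importance, top `top_k` shown. The bar of the
#' feature of interest under model B refers to its residual information.
#'
#' @param result An [rvimp()] fit with `companion = TRUE`.
#' @param top_k Number of features to display (clipped to `p` with a warning).
#' @param ... Further arguments passed to [graphics::barplot()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_vimp_comparison <- function(result, top_k = 10L, ...) {
  stopifnot(inherits(result, "rvimp"))
  if (is.null(result$vimp_a_all)) {
    stop("fit was run with companion = FALSE; per-feature importances are ",
         "not available", call. = FALSE)
  }
  p <- length(result$vimp_a_all$values)
  if (top_k > p) {
    warning("top_k exceeds the number of features; showing all ", p, call. = FALSE)
    top_k <- p
  }
  ord <- order(result$vimp_a_all$values, decreasing = TRUE)[seq_len(top_k)]
  lab <- result$vimp_a_all$feature_names[ord]
  lab[lab == result$z] <- paste0(result$z, "*")
  mat <- rbind(model_A = unname(result$vimp_a_all$values[ord]),
               model_B = unname(result$vimp_b_all$values[ord]))
  graphics::barplot(mat, beside = TRUE, names.arg = lab,
                    legend.text = c("model A", "model B"),
                    ylab = "permutation importance",
                    main = paste0("VIMP comparison (", result$z,
                                  "* = residual in model B)"), ...)
  invisible(mat)
}

#' Plot method for residual-VIMP tests
#'
#' @param x An [rvimp()] fit.
#' @param kind `"density"` for the test-density display
#'   ([plot_test_density()]) or `"comparison"` for the per-feature importance
#'   comparison ([plot_vimp_comparison()]).
#' @param ... Passed to the underlying plot function.
#' @return Invisibly, the underlying plot function's value.
#' @export
plot.rvimp <- function(x, kind = c("density", "comparison"), ...) {
  kind <- match.arg(kind)
  if (kind == "density") plot_test_density(x, ...)
  else plot_vimp_comparison(x, ...)
}
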