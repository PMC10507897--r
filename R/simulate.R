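#' Simulation scenario parameters
#'
#' Describes one simulated dataset from the package's two study designs.
#' Features `X1..X5` are standard normal with `corr(X1, X2) = c` and all
#' other pairwise correlations zero; the feature of interest is
#' `Z = 0.5 X1 + 0.5 X2 + eps2` with `eps2 ~ N(0, sigma2_sq)`, so `Z` shares
#' information with `X1`/`X2` by construction. Design A (regression) draws
#' `Y = b1 X1 + ... + b5 X5 + b6 Z + eps1`, `eps1 ~ N(0, sigma1_sq)`;
#' Design B (classification) draws `Y ~ Bernoulli(plogis(linear predictor))`
#' with the noise `eps1` inside the inverse logit.
#'
#' The noise variances control the population correlation `C(Y, Z)` and
#' semipartial correlation `spC(Y, Z | X1..X5) = C(Y, eps2)`; supply
#' `target_C`/`target_spC` to have them solved for via [solve_sigmas()]
#' (requires `b[6] != 0`). When `b[6] = 0` the semipartial correlation is
#' exactly zero whatever the variances; the defaults `sigma1_sq = 4.04`,
#' `sigma2_sq = 0.26` are then the pair used by the classification design.
#'
#' @param design `"A"` (regression) or `"B"` (classification).
#' @param n Number of observations.
#' @param b Coefficients `b1..b6` of the linear predictor (`b6` multiplies
#'   `Z`). Defaults: `c(0.5, 0.5, 1, 0, 0, 1)` for design A,
#'   `c(1, 1, 1, 0, 0, 0)` for design B.
#' @param c Correlation between `X1` and `X2`, in `[0, 1)`.
#' @param sigma1_sq,sigma2_sq Noise variances (>= 0); ignored when targets
#'   are supplied.
#' @param target_C,target_spC Optional population targets for `C(Y, Z)` and
#'   `spC(Y, Z)`.
#' @param seed Integer seed for the generator.
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec(n = 500, c = 0.3, target_C = 0.3, target_spC = 0.2, seed = 1)
#' @export
scenario_spec <- function(design = c("A", "B"), n = 500L, b = NULL, c = 0.3,
                          sigma1_sq = NULL, sigma2_sq = NULL,
                          target_C = NULL, target_spC = NULL, seed = 1L) {
  design <- match.arg(design)
  if (is.null(b)) {
    b <- if (design == "A") c(0.5, 0.5, 1, 0, 0, 1) else c(1, 1, 1, 0, 0, 0)
  }
  stopifnot(length(b) == 6L, is.numeric(b), n >= 2)
  if (abs(c) >= 1) stop("|c| must be < 1 for a valid covariance", call. = FALSE)
  if (!is.null(target_C) || !is.null(target_spC)) {
    if (is.null(target_C) || is.null(target_spC)) {
      stop("supply both target_C and target_spC, or neither", call. = FALSE)
    }
    sv <- solve_sigmas(b, c, target_C, target_spC)
    sigma1_sq <- sv$sigma1_sq
    sigma2_sq <- sv$sigma2_sq
  }
  sigma1_sq <- sigma1_sq %||% 4.04
  sigma2_sq <- sigma2_sq %||% 0.26
  stopifnot(sigma1_sq >= 0, sigma2_sq >= 0)
  structure(list(design = design, n = as.integer(n), b = as.numeric(b), c = c,
                 sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
                 target_C = target_C, target_spC = target_spC,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> design ", x$design, ", n = ", x$n,
      ", b = (", paste(x$b, collapse = ", "), "), c = ", x$c,
      ", sigma1^2 = ", signif(x$sigma1_sq, 5),
      ", sigma2^2 = ", signif(x$sigma2_sq, 5), "\n", sep = "")
  invisible(x)
}

#' Population correlation and semipartial correlation of the linear design
#'
#' Closed-form `C(Y, Z)` and `spC(Y, Z | X1..X5) = C(Y, eps2)` implied by the
#' joint Gaussian covariance structure of the regression design. Writing
#' `a1 = b1 + 0.5 b6`, `a2 = b2 + 0.5 b6`:
#' `Var(Z) = 0.5 + 0.5 c + sigma2^2`,
#' `Var(Y) = a1^2 + a2^2 + 2 a1 a2 c + b3^2 + b4^2 + b5^2 + b6^2 sigma2^2 + sigma1^2`,
#' `Cov(Y, Z) = 0.5 (a1 + a2)(1 + c) + b6 sigma2^2`, and
#' `Cov(Y, eps2) = b6 sigma2^2`.
#'
#' @param spec A [scenario_spec()], or `NULL` if the remaining arguments are
#'   given directly.
#' @param b,c,sigma1_sq,sigma2_sq Parameters overriding / replacing `spec`.
#' @return List with `C_yz`, `spC_yz`, `var_y`, `var_z`, `cov_yz`.
#' @export
theoretical_moments <- function(spec = NULL, b = spec$b, c = spec$c,
                                sigma1_sq = spec$sigma1_sq,
                                sigma2_sq = spec$sigma2_sq) {
  stopifnot(length(b) == 6L, sigma1_sq >= 0, sigma2_sq >= 0, abs(c) < 1)
  a1 <- b[1] + 0.5 * b[6]
  a2 <- b[2] + 0.5 * b[6]
  var_z <- 0.5 + 0.5 * c + sigma2_sq
  var_y <- a1^2 + a2^2 + 2 * a1 * a2 * c + b[3]^2 + b[4]^2 + b[5]^2 +
    b[6]^2 * sigma2_sq + sigma1_sq
  if (var_y <= 0 || var_z <= 0) stop("non-positive variance", call. = FALSE)
  cov_yz <- 0.5 * (a1 + a2) * (1 + c) + b[6] * sigma2_sq
  list(C_yz = cov_yz / sqrt(var_y * var_z),
       spC_yz = b[6] * sqrt(sigma2_sq) / sqrt(var_y),
       var_y = var_y, var_z = var_z, cov_yz = cov_yz)
}

#' Solve for noise variances achieving target correlations
#'
#' Finds `sigma1_sq`, `sigma2_sq` such that [theoretical_moments()] returns
#' the requested `C(Y, Z)` and `spC(Y, Z)`. The two-equation system reduces to
#' one dimension: parameterizing by `v = Var(Y)`, the semipartial equation
#' gives `sigma2_sq(v) = target_spC^2 v / b6^2` exactly, and the remaining
#' correlation equation is solved for `v` by root finding; `sigma1_sq` then
#' follows from the variance decomposition. Infeasible targets (including
#' `target_spC >= target_C` and combinations forcing a negative `sigma1_sq`)
#' raise an error rather than being clipped.
#'
#' @inheritParams theoretical_moments
#' @param target_C Target correlation, in (0, 1).
#' @param target_spC Target semipartial correlation, in (0, target_C).
#' @return List with `sigma1_sq` and `sigma2_sq`.
#' @examples
#' s <- solve_sigmas(c(0.5, 0.5, 1, 0, 0, 1), c = 0.3,
#'                   target_C = 0.3, target_spC = 0.2)
#' theoretical_moments(b = c(0.5, 0.5, 1, 0, 0, 1), c = 0.3,
#'                     sigma1_sq = s$sigma1_sq, sigma2_sq = s$sigma2_sq)
#' @export
solve_sigmas <- function(b, c, target_C, target_spC) {
  stopifnot(length(b) == 6L, abs(c) < 1)
  if (b[6] == 0) {
    stop("b6 = 0 forces spC(Y, Z) = 0; the variances are not identified by ",
         "the targets", call. = FALSE)
  }
  if (!(target_spC > 0 && target_spC < target_C && target_C < 1)) {
    stop("targets must satisfy 0 < target_spC < target_C < 1", call. = FALSE)
  }
  a1 <- b[1] + 0.5 * b[6]
  a2 <- b[2] + 0.5 * b[6]
  K <- a1^2 + a2^2 + 2 * a1 * a2 * c + b[3]^2 + b[4]^2 + b[5]^2
  s2_of <- function(v) target_spC^2 * v / b[6]^2
  h <- function(v) {
    s2 <- s2_of(v)
    0.5 * (a1 + a2) * (1 + c) + b[6] * s2 -
      target_C * sqrt(v * (0.5 + 0.5 * c + s2))
  }
  lo <- 1e-8
  hi <- max(K, 1)
  while (h(hi) > 0 && hi < 1e12) hi <- hi * 2
  if (h(lo) * h(hi) > 0) {
    stop("targets are infeasible for these coefficients", call. = FALSE)
  }
  v <- uniroot(h, c(lo, hi), tol = .Machine$double.eps^0.9,
               maxiter = 2000L)$root
  sigma2_sq <- s2_of(v)
  sigma1_sq <- v - K - b[6]^2 * sigma2_sq
  if (sigma1_sq <= 0) {
    stop("targets are infeasible: they require a non-positive sigma1_sq",
         call. = FALSE)
  }
  mom <- theoretical_moments(b = b, c = c, sigma1_sq = sigma1_sq,
                             sigma2_sq = sigma2_sq)
  if (abs(mom$C_yz - target_C) > 1e-8 || abs(mom$spC_yz - target_spC) > 1e-8) {
    stop("root finding did not converge to the requested targets", call. = FALSE)
  }
  list(sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq)
}

#' @noRd
draw_features <- function(spec) {
  n <- spec$n
  e <- matrix(rnorm(n * 5L), n, 5L)
  x <- e
  x[, 2] <- spec$c * e[, 1] + sqrt(1 - spec$c^2) * e[, 2]
  eps2 <- rnorm(n, 0, sqrt(spec$sigma2_sq))
  z <- 0.5 * x[, 1] + 0.5 * x[, 2] + eps2
  list(x = x, z = z)
}

#' Generate a regression dataset (Design A)
#'
#' @param spec A [scenario_spec()] with `design = "A"`.
#' @return A [tabular_dataset()] with features `X1..X5, Z` and a continuous
#'   outcome.
#' @export
generate_design_a <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$design != "A") stop("spec is not a design A scenario", call. = FALSE)
  with_seed(spec$seed, {
    f <- draw_features(spec)
    eps1 <- rnorm(spec$n, 0, sqrt(spec$sigma1_sq))
    y <- drop(f$x %*% spec$b[1:5]) + spec$b[6] * f$z + eps1
    feats <- cbind(f$x, f$z)
    colnames(feats) <- c(paste0("X", 1:5), "Z")
    tabular_dataset(feats, y, "regression")
  })
}

#' Generate a classification dataset (Design B)
#'
#' The binary outcome is drawn `Y ~ Bernoulli(p)` with
#' `p = plogis(b1 X1 + ... + b5 X5 + b6 Z + eps1)` — the Gaussian noise sits
#' inside the inverse logit, so the linear predictor is symmetric about zero
#' and `E(Y) = 1/2`.
#'
#' @param spec A [scenario_spec()] with `design = "B"`.
#' @return A [tabular_dataset()] with features `X1..X5, Z` and a 0/1 outcome.
#' @export
generate_design_b <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$design != "B") stop("spec is not a design B scenario", call. = FALSE)
  with_seed(spec$seed, {
    f <- draw_features(spec)
    eps1 <- rnorm(spec$n, 0, sqrt(spec$sigma1_sq))
    lp <- drop(f$x %*% spec$b[1:5]) + spec$b[6] * f$z + eps1
    y <- rbinom(spec$n, 1L, stats::plogis(lp))
    feats <- cbind(f$x, f$z)
    colnames(feats) <- c(paste0("X", 1:5), "Z")
    tabular_dataset(feats, y, "classification")
  })
}

#' @noRd
generate_scenario <- function(spec) {
  if (spec$design == "A") generate_design_a(spec) else generate_design_b(spec)
}

#' Empirical rejection-rate study
#'
#' Repeatedly generates datasets from one or more scenarios, runs the
#' residual-VIMP test on the requested feature(s), and tabulates empirical
#' rejection rates of both hypotheses with Monte-Carlo standard errors
#' `sqrt(r (1 - r) / reps)`. Replication seeds are derived deterministically
#' from the master seed and the (scenario, replication) pair, so results are
#' invariant to execution order and restarts.
#'
#' @param scenarios A [scenario_spec()] or list of them.
#' @param reps Replications per scenario.
#' @param tested Character vector of feature(s) to test in each replication
#'   (each gets its own full resampling test).
#' @param m,alpha,g,forest,g_lambda,n_perm Passed to [rvimp()].
#' @param seed Master seed.
#' @param checkpoint Optional directory; per-replication decisions are
#'   appended to one TSV per scenario and completed replications are skipped
#'   on restart, so interrupted studies resume where they stopped.
#' @param verbose Print a line per scenario.
#' @return A data frame of class `"rejection_study"`: one row per
#'   (scenario, tested feature) with columns `design`, `n`, `C_yz`, `spC_yz`,
#'   `tested`, `reps`, `rate_h1`, `rate_h2`, `se_h1`, `se_h2`.
#' @export
run_rejection_study <- function(scenarios, reps, tested = "Z", m = 100L,
                                alpha = 0.05, g = "ols",
                                forest = forest_spec(num_trees = 100L),
                                g_lambda = 1, n_perm = 1L, seed = 1L,
                                checkpoint = NULL, verbose = FALSE) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  stopifnot(reps >= 1)
  if (!is.null(checkpoint) && !dir.exists(checkpoint)) {
    dir.create(checkpoint, recursive = TRUE)
  }
  out <- list()
  for (i in seq_along(scenarios)) {
    spec <- scenarios[[i]]
    done <- NULL
    ckfile <- if (!is.null(checkpoint)) {
      file.path(checkpoint, sprintf("scenario_%03d.tsv", i))
    }
    if (!is.null(ckfile) && file.exists(ckfile)) {
      done <- read.delim(ckfile)
    }
    rec <- done
    for (r in seq_len(reps)) {
      if (!is.null(done) && any(done$rep == r)) next
      spec_r <- spec
      spec_r$seed <- hash_seed(seed, i, 2L * r)
      ds <- generate_scenario(spec_r)
      rows <- lapply(seq_along(tested), function(k) {
        fit <- rvimp(ds, z = tested[k], g = g, m = m, alpha = alpha,
                     forest = forest, g_lambda = g_lambda, n_perm = n_perm,
                     seed = hash_seed(seed, i, 2L * r + 1L) + k - 1L,
                     companion = FALSE)
        data.frame(rep = r, tested = tested[k],
                   reject_h1 = fit$reject_h1, reject_h2 = fit$reject_h2)
      })
      rows <- do.call(rbind, rows)
      rec <- rbind(rec, rows)
      if (!is.null(ckfile)) {
        utils::write.table(rows, ckfile, sep = "\t", row.names = FALSE,
                           col.names = !file.exists(ckfile), append = file.exists(ckfile))
      }
    }
    mom <- if (spec$design == "A") theoretical_moments(spec) else NULL
    for (tk in tested) {
      rk <- rec[rec$tested == tk & rec$rep <= reps, ]
      r1 <- mean(rk$reject_h1)
      r2 <- mean(rk$reject_h2)
      out[[length(out) + 1L]] <- data.frame(
        scenario = i, design = spec$design, n = spec$n,
        C_yz = if (is.null(mom)) NA_real_ else mom$C_yz,
        spC_yz = if (is.null(mom)) NA_real_ else mom$spC_yz,
        tested = tk, reps = reps,
        rate_h1 = r1, rate_h2 = r2,
        se_h1 = sqrt(r1 * (1 - r1) / reps),
        se_h2 = sqrt(r2 * (1 - r2) / reps))
    }
    if (verbose) {
      message(sprintf("scenario %d/%d done (design %s, n = %d)",
                      i, length(scenarios), spec$design, spec$n))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("rejection_study", "data.frame")
  res
}
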