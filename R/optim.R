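#' Maximize a fitted quadratic surface over the design cube
#'
#' Writes the fitted polynomial as \eqn{\hat Y(x) = \beta_0 + b'x + x'Bx}
#' with B the symmetric quadratic-form matrix (off-diagonal entries are
#' half the interaction coefficients). If the stationary point
#' \eqn{x^* = -B^{-1} b / 2} lies inside the cube and B is negative
#' definite, it is the constrained maximizer and is returned
#' analytically. Otherwise a deterministic dense coded grid (step 0.01)
#' is scanned and the best point is polished with box-constrained
#' quasi-Newton refinement.
#'
#' @param model A `quadratic_model`.
#' @param lower,upper Cube bounds in coded units (defaults -1, 1).
#' @return An `optimization_result`: `argmax_coded`, `argmax_natural`
#'   (when the model carries factors), `value` and `method`
#'   (`"analytic-stationary"` or `"grid+polish"`).
#' @export
maximize_quadratic <- function(model, lower = -1, upper = 1) {
  stopifnot(inherits(model, "quadratic_model"))
  k <- ncol(model$X)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  beta <- model$coefficients
  fn <- colnames(model$X)
  bvec <- beta[fn]
  B <- diag(beta[paste0(fn, "^2")], k)
  pairs <- utils::combn(k, 2L, simplify = FALSE)
  for (ij in pairs) {
    v <- beta[paste(fn[ij], collapse = ":")] / 2
    B[ij[1L], ij[2L]] <- B[ij[2L], ij[1L]] <- v
  }
  analytic <- NULL
  if (abs(det(B)) > .Machine$double.eps^0.5) {
    xs <- drop(-0.5 * solve(B, bvec))
    neg_def <- all(eigen(B, symmetric = TRUE, only.values = TRUE)$values < 0)
    if (neg_def && all(xs >= lower & xs <= upper)) analytic <- xs
  }
  if (!is.null(analytic)) {
    x <- analytic
    method <- "analytic-stationary"
  } else {
    x <- grid_polish_max(function(m) predict(model, m), k, lower, upper,
                         step = 0.01)
    method <- "grid+polish"
  }
  optimization_result(x, predict(model, x), method, model$factors, fn)
}

#' Maximize a fitted LS-SVM surface over the design cube
#'
#' Exhaustive evaluation on a regular coded grid with the given step,
#' followed by coordinate-wise local refinement at step/10 around the
#' incumbent (repeated until no coordinate moves). Ties on the grid are
#' broken by the lexicographically smallest coded point; a grid whose
#' maximum is flat (all values within 1e-12 of each other) is flagged.
#'
#' @param model An `lssvm_model`.
#' @param step Coded grid step (> 0). The default 0.05 keeps a 4-factor
#'   grid under 3 million points; grids above 1e7 points are refused.
#' @param lower,upper Cube bounds in coded units.
#' @return An `optimization_result` with method `"grid+polish"` (or
#'   `"grid+polish (flat)"` when the surface is constant on the grid).
#' @export
maximize_lssvm <- function(model, step = 0.05, lower = -1, upper = 1) {
  stopifnot(inherits(model, "lssvm_model"), is.numeric(step), step > 0)
  k <- ncol(model$X)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  n_axis <- floor((upper - lower) / step) + 1
  if (prod(n_axis) > 1e7)
    stop(sprintf("grid of %.3g points is too large; use a coarser step",
                 prod(n_axis)))
  axes <- lapply(seq_len(k), function(j) lower[j] + step * (seq_len(n_axis[j]) - 1))
  best <- grid_scan_max(function(m) predict(model, m), axes)
  x <- coordinate_refine(function(m) predict(model, m), best$x,
                         step / 10, step, lower, upper)
  method <- if (best$flat) "grid+polish (flat)" else "grid+polish"
  optimization_result(x, predict(model, x), method, model$factors,
                      colnames(model$X))
}

# chunked exhaustive scan; lexicographic-smallest tie-break
grid_scan_max <- function(f, axes) {
  grid <- as.matrix(rev(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)))
  colnames(grid) <- NULL
  n <- nrow(grid)
  chunk <- 100000L
  best_val <- -Inf; best_x <- grid[1L, ]; vmin <- Inf
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    v <- f(grid[idx, , drop = FALSE])
    vmin <- min(vmin, v)
    b <- which.max(v)  # first occurrence: rows are lexicographically ordered
    if (v[b] > best_val) {
      best_val <- v[b]
      best_x <- grid[idx[b], ]
    }
  }
  list(x = best_x, value = best_val, flat = (best_val - vmin) <= 1e-12)
}

# iterated coordinate-wise line search on a fine local grid
coordinate_refine <- function(f, x, fine_step, radius, lower, upper,
                              max_pass = 25L) {
  k <- length(x)
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (j in seq_len(k)) {
      cand <- seq(max(lower[j], x[j] - radius),
                  min(upper[j], x[j] + radius), by = fine_step)
      pts <- matrix(rep(x, each = length(cand)), ncol = k)
      pts[, j] <- cand
      v <- f(pts)
      b <- which.max(v)
      if (abs(cand[b] - x[j]) > 1e-15 && v[b] > f(matrix(x, 1L))) {
        x[j] <- cand[b]; moved <- TRUE
      }
    }
    if (!moved) break
  }
  x
}

# dense grid + L-BFGS-B polish for the quadratic fallback path
grid_polish_max <- function(f, k, lower, upper, step) {
  coarse <- max(step, if (k >= 4) 0.1 else step)
  axes <- lapply(seq_len(k), function(j) seq(lower[j], upper[j], by = coarse))
  best <- grid_scan_max(f, axes)
  opt <- stats::optim(best$x, function(z) -f(matrix(z, 1L)),
                      method = "L-BFGS-B", lower = lower, upper = upper)
  if (-opt$value >= best$value) opt$par else best$x
}

optimization_result <- function(coded, value, method, factors, names) {
  coded <- stats::setNames(as.numeric(coded), names)
  natural <- if (!is.null(factors)) decode_levels(coded, factors) else NULL
  structure(list(argmax_coded = coded, argmax_natural = natural,
                 value = as.numeric(value), method = method,
                 factors = factors),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Constrained maximum (%s): predicted value %.4f\n",
              x$method, x$value))
  cat("  coded:  ", paste(sprintf("%s = %.4f", names(x$argmax_coded),
                                  x$argmax_coded), collapse = ", "), "\n")
  if (!is.null(x$argmax_natural)) {
    u <- vapply(x$factors, `[[`, character(1), "unit")
    cat("  natural:", paste(sprintf("%s = %.2f %s", names(x$argmax_natural),
                                    x$argmax_natural, u), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Relative deviation of an observed mean from a model prediction
#'
#' \deqn{100 \cdot |predicted - observed| / predicted,}
#' the validation metric used to rank competing models: the percentage
#' by which the observed validation mean misses the model's predicted
#' optimum.
#'
#' @param observed_mean Observed mean response.
#' @param predicted Model-predicted response (nonzero).
#' @return The relative deviation in percent.
#' @export
#' @examples
#' relative_deviation(12.8402, 13.0870)  # 1.886
relative_deviation <- function(observed_mean, predicted) {
  if (!is.numeric(predicted) || predicted == 0)
    stop("predicted value must be nonzero")
  abs(predicted - observed_mean) / predicted * 100
}

#' Summarize a validation experiment against a predicted optimum
#'
#' Scores each validation replicate with the composite weights, then
#' reports the replicate mean, the standard deviation and the relative
#' deviation from the model's predicted optimum. The SD uses the
#' n-denominator (population) convention, matching how replicate
#' spreads are conventionally reported alongside such validation means
#' in this literature.
#'
#' @param replicates An `experiment_table` of validation runs, a
#'   data.frame with the analyte columns, or a numeric vector of
#'   already-computed composite values (then `weights` is ignored).
#' @param predicted Predicted optimum value of the model under test.
#' @param weights A `weight_scheme` (required for tabular input).
#' @param label Optional model label carried into comparisons.
#' @return A `validation_report`: `composites`, `mean`, `sd`,
#'   `predicted`, `relative_deviation_pct`, `label`.
#' @export
validation_report <- function(replicates, predicted, weights = NULL,
                              label = NULL) {
  comp <- if (is.numeric(replicates) && is.null(dim(replicates))) {
    replicates
  } else {
    if (is.null(weights)) stop("weights are required for tabular replicates")
    composite_score(replicates, weights)
  }
  if (length(comp) < 2L)
    stop("need at least 2 replicates for a standard deviation")
  m <- mean(comp)
  s <- sqrt(mean((comp - m)^2))  # n-denominator SD (see Details)
  structure(list(composites = comp, mean = m, sd = s,
                 predicted = predicted,
                 relative_deviation_pct = relative_deviation(m, predicted),
                 label = label),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s: %.4f +/- %.4f (n = %d), predicted %.4f, relative deviation %.2f%%\n",
              if (is.null(x$label)) "Validation" else x$label,
              x$mean, x$sd, length(x$composites), x$predicted,
              x$relative_deviation_pct))
  invisible(x)
}

#' Rank competing models by validation relative deviation
#'
#' @param reports A list of `validation_report` objects (>= 2).
#' @return A `model_comparison`: data.frame `table` ranked by relative
#'   deviation ascending, `winner` label, `margin_pct` (runner-up minus
#'   winner) and `tie` flag.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2L) stop("need at least two validation reports")
  stopifnot(all(vapply(reports, inherits, logical(1), "validation_report")))
  labels <- vapply(seq_along(reports), function(i) {
    l <- reports[[i]]$label
    if (is.null(l)) sprintf("model_%d", i) else l
  }, character(1))
  t <- data.frame(
    model = labels,
    mean = vapply(reports, `[[`, numeric(1), "mean"),
    sd = vapply(reports, `[[`, numeric(1), "sd"),
    predicted = vapply(reports, `[[`, numeric(1), "predicted"),
    relative_deviation_pct = vapply(reports, `[[`, numeric(1),
                                    "relative_deviation_pct"),
    stringsAsFactors = FALSE)
  t <- t[order(t$relative_deviation_pct, t$model), , drop = FALSE]
  t$rank <- seq_len(nrow(t))
  rownames(t) <- NULL
  tie <- nrow(t) >= 2L &&
    abs(t$relative_deviation_pct[1L] - t$relative_deviation_pct[2L]) <= 1e-12
  structure(list(table = t, winner = t$model[1L],
                 margin_pct = t$relative_deviation_pct[2L] -
                              t$relative_deviation_pct[1L],
                 tie = tie),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (x$tie) cat("Tie on relative deviation.\n")
  else cat(sprintf("Winner: %s (margin %.2f percentage points)\n",
                   x$winner, x$margin_pct))
  invisible(x)
}
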