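#' Radial basis function kernel
#'
#' Default convention (that of the classic LS-SVM toolbox, where `g`
#' plays the role of the squared bandwidth sigma^2):
#' \deqn{K(u, v) = \exp(-\|u - v\|^2 / g).}
#' The alternative "gamma" convention \eqn{\exp(-g \|u-v\|^2)} is
#' available through `kernel = "rbf_gamma"` in the fitting functions;
#' which convention a published model used is often unstated, so both
#' are first-class.
#'
#' @param u,v Numeric vectors of equal length.
#' @param g Positive kernel parameter.
#' @return Kernel value in (0, 1].
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(0, 0), g = 0.1)  # 1
rbf_kernel <- function(u, v, g) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (!is.numeric(g) || length(g) != 1L || g <= 0) stop("g must be > 0")
  exp(-sum((u - v)^2) / g)
}

#' Kernel Gram matrix
#'
#' @param X,Z Numeric matrices of points (rows); `Z` defaults to `X`.
#' @param kernel `"rbf"` (\eqn{\exp(-d^2/g)}), `"rbf_gamma"`
#'   (\eqn{\exp(-g d^2)}) or `"linear"` (\eqn{u'v}).
#' @param g Kernel parameter (ignored for `"linear"`).
#' @return `nrow(X)` x `nrow(Z)` kernel matrix.
#' @export
kernel_matrix <- function(X, Z = X, kernel = c("rbf", "rbf_gamma", "linear"),
                          g = 1) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) stop("X and Z must have the same number of columns")
  if (kernel == "linear") return(X %*% t(Z))
  if (!is.numeric(g) || length(g) != 1L || g <= 0) stop("g must be > 0")
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * X %*% t(Z)
  d2[d2 < 0] <- 0  # clip numerical negatives
  if (kernel == "rbf") exp(-d2 / g) else exp(-g * d2)
}

#' Fit a least-squares support vector machine regression
#'
#' LS-SVM replaces the epsilon-insensitive loss and inequality
#' constraints of standard SVM regression with a squared-error loss and
#' equality constraints, so training reduces to one linear system. With
#' kernel matrix K, penalty C and responses y, the dual variables
#' (alpha, b) solve the (n+1) x (n+1) saddle system
#' \deqn{\begin{bmatrix} 0 & 1' \\ 1 & K + I/C \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ y \end{bmatrix}.}
#' Two identities follow from the KKT conditions and are checked after
#' every fit: \eqn{\sum_i \alpha_i = 0}, and the training-point
#' prediction \eqn{\hat y_i = y_i - \alpha_i / C}.
#'
#' Duplicate rows in `X` make the system singular and are refused;
#' average replicate responses first with [aggregate_replicates()].
#'
#' @param X Matrix of training inputs (rows), typically coded levels in
#'   \[-1, 1\].
#' @param y Numeric response vector.
#' @param g Kernel parameter (see [rbf_kernel()]).
#' @param C Positive regularization (penalty) factor; larger C tolerates
#'   less training error.
#' @param kernel Kernel spec, as in [kernel_matrix()].
#' @param factors Optional `bbd_factors` carried along so predictions
#'   can be reported in natural units.
#' @return An object of class `lssvm_model` with elements `X`, `alpha`,
#'   `b`, `kernel`, `g`, `C`.
#' @export
fit_lssvm <- function(X, y, g = 1, C = 1,
                      kernel = c("rbf", "rbf_gamma", "linear"),
                      factors = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be > 0")
  if (anyDuplicated(apply(X, 1L, paste, collapse = "|")))
    stop("duplicate rows in X make the LS-SVM system singular; ",
         "average replicates first (see aggregate_replicates)")
  K <- kernel_matrix(X, X, kernel, g)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("LS-SVM system is singular; try a different g or add jitter to X"))
  resid_rel <- sqrt(sum((A %*% sol - rhs)^2)) / max(1, sqrt(sum(rhs^2)))
  if (resid_rel > 1e-8)
    stop(sprintf("LS-SVM solve did not converge (relative residual %.2e)", resid_rel))
  model <- structure(list(X = X, alpha = unname(sol[-1L]), b = unname(sol[1L]),
                          kernel = kernel, g = g, C = C, y = y,
                          factors = factors),
                     class = "lssvm_model")
  stopifnot(abs(sum(model$alpha)) <= 1e-8 * max(1, sum(abs(model$alpha))))
  model
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("LS-SVM regression: %d support points, kernel %s (g = %g), C = %g, b = %.4f\n",
              nrow(x$X), x$kernel, x$g, x$C, x$b))
  invisible(x)
}

#' Predict from a fitted LS-SVM
#'
#' \eqn{\hat y(x) = b + \sum_i \alpha_i K(x_i, x)}.
#'
#' @param object An `lssvm_model`.
#' @param newdata Coded point (vector) or matrix of points (rows);
#'   defaults to the training inputs.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lssvm_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  if (!is.matrix(newdata) && !is.data.frame(newdata))
    newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop("newdata dimension does not match training inputs")
  K <- kernel_matrix(newdata, object$X, object$kernel, object$g)
  drop(K %*% object$alpha + object$b)
}

#' Mean squared error
#'
#' \eqn{MSE = n^{-1} \sum_i (y_i - \hat y_i)^2}.
#'
#' @param pred,actual Numeric vectors of equal length (n >= 1).
#' @return The mean squared error.
#' @export
mse <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("pred and actual lengths differ")
  if (!length(pred)) stop("need at least one observation")
  mean((actual - pred)^2)
}

#' Grid search for LS-SVM hyperparameters by cross-validation
#'
#' Evaluates every (g, C) pair on the grid by cross-validated mean
#' squared error and returns the full error surface together with the
#' winning pair. Leave-one-out (the default, deterministic) refits the
#' model n times per pair; k-fold uses a seeded random fold assignment.
#' Ties are broken deterministically: smallest g, then smallest C.
#'
#' @param X,y Training data as in [fit_lssvm()].
#' @param g_grid,C_grid Non-empty numeric grids of candidate values.
#' @param kernel Kernel spec, as in [kernel_matrix()].
#' @param folds `"loo"` for leave-one-out, or an integer number of folds
#'   in \[2, n\].
#' @param seed Seed for the k-fold shuffle (ignored for LOO).
#' @return An object of class `lssvm_cv`: data.frame `grid` with columns
#'   g, C, cv_error, plus `best_g`, `best_C`, `best_error`.
#' @export
cv_grid_search <- function(X, y, g_grid, C_grid,
                           kernel = c("rbf", "rbf_gamma", "linear"),
                           folds = "loo", seed = 1L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  if (!length(g_grid) || !length(C_grid)) stop("hyperparameter grids must be non-empty")
  if (identical(folds, "loo")) {
    assign_id <- seq_len(n)
  } else {
    folds <- as.integer(folds)
    if (is.na(folds) || folds < 2L || folds > n)
      stop(sprintf("folds must be 'loo' or an integer in [2, %d]", n))
    assign_id <- local({
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      sample(rep_len(seq_len(folds), n))
    })
  }
  grid <- expand.grid(g = as.numeric(g_grid), C = as.numeric(C_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_error <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(unique(assign_id), function(f) {
      hold <- assign_id == f
      fit <- fit_lssvm(X[!hold, , drop = FALSE], y[!hold],
                       g = grid$g[i], C = grid$C[i], kernel = kernel)
      mean((y[hold] - predict(fit, X[hold, , drop = FALSE]))^2)
    }, numeric(1))
    # LOO: every fold has size 1, so the mean of fold errors is the CV MSE;
    # k-fold: weight folds by size
    sizes <- tabulate(assign_id)[unique(assign_id)]
    sum(errs * sizes) / sum(sizes)
  }, numeric(1))
  ord <- order(grid$cv_error, grid$g, grid$C)
  best <- grid[ord[1L], ]
  structure(list(grid = grid, best_g = best$g, best_C = best$C,
                 best_error = best$cv_error, kernel = kernel,
                 scheme = if (identical(folds, "loo")) "loo"
                          else sprintf("%d-fold", folds)),
            class = "lssvm_cv")
}

#' @export
print.lssvm_cv <- function(x, ...) {
  cat(sprintf("LS-SVM %s cross-validation over %d (g, C) pairs\n",
              x$scheme, nrow(x$grid)))
  cat(sprintf("  best: g = %g, C = %g (CV MSE %.6g)\n",
              x$best_g, x$best_C, x$best_error))
  invisible(x)
}

#' Serialize / restore an LS-SVM model as JSON
#'
#' Stores training inputs, dual coefficients, bias and the kernel spec
#' so predictions are reproducible without refitting.
#'
#' @param model An `lssvm_model`.
#' @param path JSON file path.
#' @return `write_lssvm()` returns `path` invisibly; `read_lssvm()`
#'   returns the restored `lssvm_model`.
#' @export
write_lssvm <- function(model, path) {
  stopifnot(inherits(model, "lssvm_model"))
  jsonlite::write_json(list(
    X = unname(apply(model$X, 1L, as.numeric, simplify = FALSE)),
    colnames = colnames(model$X),
    alpha = model$alpha, b = model$b,
    kernel = model$kernel, g = model$g, C = model$C, y = model$y),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lssvm
#' @export
read_lssvm <- function(path) {
  o <- jsonlite::fromJSON(path)
  X <- if (is.matrix(o$X)) o$X else do.call(rbind, lapply(o$X, as.numeric))
  storage.mode(X) <- "double"
  if (!is.null(o$colnames) && length(o$colnames) == ncol(X))
    colnames(X) <- o$colnames
  structure(list(X = X, alpha = as.numeric(o$alpha), b = as.numeric(o$b),
                 kernel = o$kernel, g = as.numeric(o$g), C = as.numeric(o$C),
                 y = as.numeric(o$y), factors = NULL),
            class = "lssvm_model")
}
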