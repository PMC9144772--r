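#' Fit a full second-order response-surface model
#'
#' Fits, by ordinary least squares on the coded design matrix, the
#' quadratic polynomial
#' \deqn{Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j
#'       + \sum_i \beta_{ii} x_i^2 + \varepsilon}
#' with all k linear, choose(k,2) interaction and k pure-quadratic terms
#' (15 terms for k = 4). Coefficients are kept at full precision; any
#' rounding is a display concern only.
#'
#' @param table An `experiment_table` whose factor columns are in
#'   natural units (they are coded internally).
#' @param response Name of the response column: the composite column
#'   (default, if present) or any analyte column.
#' @return An object of class `quadratic_model`: coefficients, the coded
#'   model matrix, response values, fitted values and residuals.
#' @export
fit_quadratic <- function(table, response = NULL) {
  stopifnot(inherits(table, "experiment_table"))
  factors <- attr(table, "factors")
  if (is.null(response)) response <- attr(table, "composite")
  if (is.null(response))
    stop("table has no composite column; name a response explicitly")
  if (!response %in% names(table))
    stop(sprintf("response column '%s' not found", response))
  X <- coded_matrix(table)
  y <- as.numeric(table[[response]])
  M <- quadratic_model_matrix(X)
  p <- ncol(M)
  if (nrow(M) < p)
    stop(sprintf("need at least %d runs to fit %d model terms (got %d)",
                 p, p, nrow(M)))
  qr_m <- qr(M)
  if (qr_m$rank < p) {
    aliased <- colnames(M)[qr_m$pivot[(qr_m$rank + 1L):p]]
    stop("design matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qr_m, y)
  fitted <- drop(M %*% beta)
  structure(list(coefficients = beta, factors = factors,
                 response = response, X = X, y = y,
                 model_matrix = M, fitted = fitted,
                 residuals = y - fitted,
                 xtx_inv = solve(crossprod(M))),
            class = "quadratic_model")
}

# columns: intercept, linear, pairwise interactions (i<j), squares
quadratic_model_matrix <- function(X) {
  k <- ncol(X)
  nm <- colnames(X)
  pairs <- if (k >= 2L) utils::combn(k, 2L, simplify = FALSE) else list()
  inter <- vapply(pairs, function(ij) X[, ij[1L]] * X[, ij[2L]],
                  numeric(nrow(X)))
  if (length(pairs) && is.null(dim(inter))) inter <- matrix(inter, nrow = 1L)
  M <- cbind(`(Intercept)` = 1, X, inter, X^2)
  colnames(M) <- c("(Intercept)", nm,
                   vapply(pairs, function(ij) paste(nm[ij], collapse = ":"),
                          character(1)),
                   paste0(nm, "^2"))
  M
}

#' @export
coef.quadratic_model <- function(object, ...) object$coefficients

#' @export
print.quadratic_model <- function(x, digits = 4, ...) {
  cat(sprintf("Second-order response-surface model for '%s' (%d runs, %d terms)\n",
              x$response, length(x$y), length(x$coefficients)))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Evaluate a fitted quadratic surface
#'
#' Exact polynomial evaluation in coded units. `newdata` may be a coded
#' vector, a coded matrix/data.frame (one row per point), or natural-unit
#' values with `natural = TRUE`.
#'
#' @param object A `quadratic_model`.
#' @param newdata Points to predict at; defaults to the training design.
#' @param natural If `TRUE`, `newdata` is in natural units and is coded
#'   first using the model's factors.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.quadratic_model <- function(object, newdata = NULL, natural = FALSE, ...) {
  if (is.null(newdata)) return(object$fitted)
  m <- as_level_matrix(newdata, object$factors, if (natural) "natural" else "coded")
  if (natural) m <- code_levels(m, object$factors)
  drop(quadratic_model_matrix(m) %*% object$coefficients)
}

#' Significance marks for p-values
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#' `""` otherwise (vectorized).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of marks.
#' @export
significance_marks <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
  out[is.na(p)] <- ""
  out
}

#' ANOVA of a fitted quadratic response-surface model
#'
#' Produces the complete analysis-of-variance table for the fit:
#' an overall model row, one row per model term with its partial
#' (drop-one-term, Type-III-style) sum of squares
#' \eqn{SS_j = \hat\beta_j^2 / [(X'X)^{-1}]_{jj}}, the residual, and —
#' when the design carries replicated points — the lack-of-fit /
#' pure-error partition of the residual. Per-term and lack-of-fit F
#' statistics use the residual and pure-error mean squares respectively;
#' p-values come from the exact F distribution.
#'
#' Fit statistics: \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, adjusted
#' \eqn{R^2 = 1 - (SS_{res}/df_{res}) / (SS_{tot}/(n-1))}, and predicted
#' \eqn{R^2 = 1 - PRESS/SS_{tot}} with
#' \eqn{PRESS = \sum_i (e_i / (1 - h_{ii}))^2} built from the
#' leave-one-out residuals.
#'
#' If every replicate group is degenerate (pure-error SS exactly 0) the
#' lack-of-fit F is infinite and is reported with p = 0 and a warning.
#' Without any replicated points the lack-of-fit rows are omitted with a
#' warning.
#'
#' @param model A `quadratic_model`.
#' @param table Optional `experiment_table`; defaults to the data stored
#'   in the model (supplying a different table refits nothing — it only
#'   changes the replicate grouping and must contain the same runs).
#' @return An object of class `rsm_anova`: list with the term table
#'   (`table`), `r2`, `adj_r2`, `pred_r2`, `press`, `ss_total` and df
#'   bookkeeping.
#' @export
anova_quadratic <- function(model, table = NULL) {
  stopifnot(inherits(model, "quadratic_model"))
  y <- model$y
  M <- model$model_matrix
  n <- length(y)
  p <- ncol(M)
  df_res <- n - p
  if (df_res < 1L) stop("no residual degrees of freedom")
  res <- model$residuals
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1L
  ms_res <- ss_res / df_res

  # partial (drop-one-term) SS from the coefficient variances
  dinv <- diag(model$xtx_inv)
  beta <- model$coefficients
  term_idx <- 2:p  # skip intercept in the displayed partition
  ss_term <- beta[term_idx]^2 / dinv[term_idx]
  f_term <- ss_term / ms_res
  p_term <- stats::pf(f_term, 1, df_res, lower.tail = FALSE)

  f_mod <- (ss_mod / df_mod) / ms_res
  p_mod <- stats::pf(f_mod, df_mod, df_res, lower.tail = FALSE)

  rows <- data.frame(
    source = c("Model", names(beta)[term_idx], "Residual"),
    ss = c(ss_mod, ss_term, ss_res),
    df = c(df_mod, rep(1L, length(term_idx)), df_res),
    stringsAsFactors = FALSE)
  rows$ms <- rows$ss / rows$df
  rows$f <- c(f_mod, f_term, NA)
  rows$p <- c(p_mod, p_term, NA)

  # lack-of-fit partition from replicated design points
  grp <- apply(model$X, 1L, paste, collapse = "|")
  reps <- split(y, grp)
  n_groups <- length(reps)
  df_pe <- n - n_groups
  lof <- NULL
  if (df_pe < 1L) {
    warning("no replicated design points: lack-of-fit partition unavailable")
  } else {
    ss_pe <- sum(vapply(reps, function(v) sum((v - mean(v))^2), numeric(1)))
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    if (df_lof < 1L) {
      warning("model saturates the distinct design points: no lack-of-fit df")
    } else if (ss_pe == 0) {
      warning("pure-error SS is zero; lack-of-fit F is infinite (reported p = 0)")
      lof <- list(ss_lof = ss_lof, df_lof = df_lof, ss_pe = ss_pe,
                  df_pe = df_pe, f = Inf, p = 0)
    } else {
      f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
      lof <- list(ss_lof = ss_lof, df_lof = df_lof, ss_pe = ss_pe,
                  df_pe = df_pe, f = f_lof,
                  p = stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE))
    }
    if (!is.null(lof)) {
      extra <- data.frame(
        source = c("Lack of fit", "Pure error"),
        ss = c(lof$ss_lof, lof$ss_pe), df = c(lof$df_lof, lof$df_pe),
        ms = c(lof$ss_lof / lof$df_lof, lof$ss_pe / lof$df_pe),
        f = c(lof$f, NA), p = c(lof$p, NA), stringsAsFactors = FALSE)
      rows <- rbind(rows, extra)
    }
  }
  rows$significance <- significance_marks(ifelse(is.na(rows$p), NA, rows$p))

  # leverages for PRESS
  h <- rowSums((M %*% model$xtx_inv) * M)
  press <- sum((res / (1 - h))^2)

  out <- structure(list(
    table = rows,
    r2 = 1 - ss_res / ss_tot,
    adj_r2 = 1 - (ss_res / df_res) / (ss_tot / (n - 1)),
    pred_r2 = 1 - press / ss_tot,
    press = press,
    ss_total = ss_tot, ss_model = ss_mod, ss_residual = ss_res,
    df_model = df_mod, df_residual = df_res, n = n,
    lack_of_fit = lof, response = model$response),
    class = "rsm_anova")
  # internal consistency of the partition
  stopifnot(abs(out$ss_model + out$ss_residual - out$ss_total) <=
              1e-6 * max(1, out$ss_total),
            out$df_model + out$df_residual == n - 1L)
  out
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("ANOVA for response '%s'\n", x$response))
  t <- x$table
  fmt_p <- function(p) ifelse(is.na(p), "", ifelse(p < 1e-4, "< 0.0001",
                                                   sprintf("%.4f", p)))
  cat(sprintf("%-14s %12s %4s %12s %10s %9s %s\n",
              "Source", "SS", "df", "MS", "F", "p", ""))
  for (i in seq_len(nrow(t)))
    cat(sprintf("%-14s %12.4f %4d %12.4f %10s %9s %s\n",
                t$source[i], t$ss[i], t$df[i], t$ms[i],
                ifelse(is.na(t$f[i]), "", sprintf("%.4f", t$f[i])),
                fmt_p(t$p[i]), t$significance[i]))
  cat(sprintf("R2 %.4f   adjusted R2 %.4f   predicted R2 %.4f\n",
              x$r2, x$adj_r2, x$pred_r2))
  invisible(x)
}

#' Write an ANOVA table to CSV
#'
#' Columns: source, sum of squares, df, mean square, F, p, significance,
#' followed by rows carrying the fit statistics.
#'
#' @param anova An `rsm_anova`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_anova <- function(anova, path) {
  stopifnot(inherits(anova, "rsm_anova"))
  t <- anova$table
  stats_rows <- data.frame(source = c("R2", "Adjusted R2", "Predicted R2"),
                           ss = c(anova$r2, anova$adj_r2, anova$pred_r2),
                           df = NA, ms = NA, f = NA, p = NA,
                           significance = "", stringsAsFactors = FALSE)
  utils::write.csv(rbind(t, stats_rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Gridded predictions over one factor pair
#'
#' Evaluates the fitted surface on a regular coded grid over two chosen
#' factors, holding all other factors at 0, for external contour or
#' surface plotting.
#'
#' @param model A `quadratic_model` (or `lssvm_model`).
#' @param pair Two factor names or indices.
#' @param step Coded grid step in (0, 2].
#' @param fix Coded level the remaining factors are held at.
#' @return A data.frame with the two coded coordinates, their
#'   natural-unit equivalents and the predicted response.
#' @export
surface_grid <- function(model, pair, step = 0.05, fix = 0) {
  factors <- model$factors
  k <- length(factors)
  fn <- factor_names(factors)
  if (is.character(pair)) pair <- match(pair, fn)
  stopifnot(length(pair) == 2L, !anyNA(pair), all(pair >= 1 & pair <= k),
            step > 0, step <= 2)
  s <- seq(-1, 1, by = step)
  g <- expand.grid(a = s, b = s)
  pts <- matrix(fix, nrow(g), k)
  pts[, pair[1L]] <- g$a
  pts[, pair[2L]] <- g$b
  colnames(pts) <- fn
  nat <- decode_levels(pts, factors)
  out <- data.frame(g$a, g$b, nat[, pair[1L]], nat[, pair[2L]],
                    predicted = predict(model, pts))
  names(out)[1:4] <- c(paste0(fn[pair], "_coded"), fn[pair])
  out
}
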