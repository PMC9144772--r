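#' Construct a Box-Behnken design
#'
#' Builds the coded Box-Behnken design (BBD) for 3 to 7 factors. For
#' k = 3, 4, 5 the design places runs at the midpoints of the cube
#' edges: every pair of factors takes all four (+/-1, +/-1) sign
#' combinations while the remaining factors sit at 0, giving
#' `4*choose(k,2)` edge runs. For k = 6 and 7 the catalog designs based
#' on balanced triples of factors are used (48 and 56 non-center runs;
#' each run has exactly three nonzero coordinates). `n_center` all-zero
#' center runs are appended.
#'
#' Every coded column sums to zero and the linear columns are mutually
#' orthogonal, which is what makes the per-term ANOVA partition of
#' [anova_quadratic()] clean.
#'
#' @param factors A `bbd_factors` object (3 to 7 factors).
#' @param n_center Number of replicated center points (>= 1).
#' @return A data.frame of coded levels, one column per factor, one row
#'   per run, with attribute `factors`.
#' @export
#' @examples
#' f <- bbd_factors(bbd_factor("a", "", -1, 0, 1),
#'                  bbd_factor("b", "", -1, 0, 1),
#'                  bbd_factor("c", "", -1, 0, 1))
#' nrow(build_bbd(f, n_center = 1))  # 13
build_bbd <- function(factors, n_center = 1L) {
  stopifnot(inherits(factors, "bbd_factors"))
  k <- length(factors)
  if (k < 3L || k > 7L)
    stop(sprintf("Box-Behnken designs are supported for 3 to 7 factors (got %d)", k))
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1L) stop("n_center must be a positive integer")

  blocks <- bbd_blocks(k)
  signs2 <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  signs3 <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  rows <- lapply(blocks, function(bl) {
    s <- if (length(bl) == 2L) signs2 else signs3
    m <- matrix(0, nrow(s), k)
    m[, bl] <- s
    m
  })
  m <- rbind(do.call(rbind, rows), matrix(0, n_center, k))
  colnames(m) <- factor_names(factors)
  d <- as.data.frame(m)
  attr(d, "factors") <- factors
  d
}

# factor subsets varied together in the catalog designs
bbd_blocks <- function(k) {
  if (k <= 5L) {
    combn(k, 2L, simplify = FALSE)
  } else if (k == 6L) {
    list(c(1L, 2L, 4L), c(2L, 3L, 5L), c(3L, 4L, 6L),
         c(4L, 5L, 1L), c(5L, 6L, 2L), c(6L, 1L, 3L))
  } else {
    # Fano-plane triples
    list(c(1L, 2L, 4L), c(2L, 3L, 5L), c(3L, 4L, 6L), c(4L, 5L, 7L),
         c(5L, 6L, 1L), c(6L, 7L, 2L), c(7L, 1L, 3L))
  }
}

#' Assemble an experiment table
#'
#' An experiment table is the package's tabular container for a designed
#' experiment: one row per run, with a `run_id` column, one natural-unit
#' column per factor, one yield column per analyte and (optionally) a
#' composite-response column `Y`.
#'
#' @param data A data.frame holding `run_id`, the factor columns (natural
#'   units, named as in `factors`) and the analyte columns.
#' @param factors A `bbd_factors` object.
#' @param analytes Character vector of analyte column names.
#' @param composite Name of the composite column, if present in `data`.
#' @return The data.frame with class `experiment_table` and attributes
#'   `factors`, `analytes`, `composite`.
#' @export
experiment_table <- function(data, factors, analytes, composite = NULL) {
  stopifnot(is.data.frame(data), inherits(factors, "bbd_factors"),
            is.character(analytes), length(analytes) >= 1L)
  fn <- factor_names(factors)
  need <- unique(c("run_id", fn, analytes, composite))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("experiment table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$run_id)) stop("run_id values must be unique")
  data <- as.data.frame(data)[, need, drop = FALSE]
  structure(data, factors = factors, analytes = analytes,
            composite = composite,
            class = c("experiment_table", "data.frame"))
}

#' @export
print.experiment_table <- function(x, ...) {
  cat(sprintf("Experiment table: %d runs, %d factors (%s), analytes: %s\n",
              nrow(x), length(attr(x, "factors")),
              paste(factor_names(attr(x, "factors")), collapse = ", "),
              paste(attr(x, "analytes"), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Coded design matrix of an experiment table
#'
#' @param table An `experiment_table`.
#' @return Numeric matrix of coded levels (columns = factors).
#' @export
coded_matrix <- function(table) {
  factors <- attr(table, "factors")
  code_levels(as.matrix(table[, factor_names(factors), drop = FALSE]), factors)
}

#' Read or write an experiment table as CSV
#'
#' The CSV holds `run_id`, one natural-unit column per factor, one
#' column per analyte and, optionally, the composite column `Y`.
#' UTF-8, header row required.
#'
#' @param path CSV file path.
#' @param factors A `bbd_factors` object naming the factor columns.
#' @param analytes Analyte column names; by default every non-factor,
#'   non-`run_id`, non-`Y` column.
#' @return `read_experiment()` returns an `experiment_table`;
#'   `write_experiment()` returns `path` invisibly.
#' @export
read_experiment <- function(path, factors, analytes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  fn <- factor_names(factors)
  if (is.null(analytes)) {
    analytes <- setdiff(names(df), c("run_id", fn, "Y"))
    # composite-only tables (e.g. simulator output) carry Y as their sole response
    if (!length(analytes) && "Y" %in% names(df)) analytes <- "Y"
  }
  composite <- if ("Y" %in% names(df)) "Y" else NULL
  experiment_table(df, factors, analytes, composite)
}

#' @rdname read_experiment
#' @param table An `experiment_table`.
#' @export
write_experiment <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive analyte weights from a precedence chart
#'
#' A precedence chart scores every ordered pair of quality indicators:
#' 1 if the row indicator dominates the column indicator, 0 if it is
#' dominated, 0.5 for equal importance (so `pairwise[i,j] +
#' pairwise[j,i] = 1` off the diagonal). Weights are the row sums
#' normalized to sum 1.
#'
#' Note that for two strictly-ordered indicators the row-sum rule gives
#' weights (1, 0); schemes like 0.75/0.25 arise from additional
#' normalization steps and can be supplied directly via
#' [weight_scheme()].
#'
#' @param pairwise Square numeric matrix of precedence scores in
#'   \{0, 0.5, 1\}; the diagonal is ignored.
#' @param analytes Character vector naming the indicators, in row order.
#' @return A `weight_scheme` object.
#' @export
#' @examples
#' precedence_weights(matrix(c(NA, .5, .5, NA), 2), c("A", "B"))
precedence_weights <- function(pairwise, analytes) {
  pairwise <- as.matrix(pairwise)
  m <- length(analytes)
  if (!all(dim(pairwise) == m))
    stop("pairwise matrix must be ", m, "x", m)
  diag(pairwise) <- 0
  comp <- pairwise + t(pairwise)
  off <- comp[upper.tri(comp)]
  if (any(abs(off - 1) > 1e-9))
    stop("inconsistent precedence chart: pairwise[i,j] + pairwise[j,i] must equal 1")
  w <- rowSums(pairwise)
  weight_scheme(stats::setNames(w / sum(w), analytes), pairwise = pairwise)
}

#' Explicit analyte weight scheme
#'
#' @param weights Named nonnegative numeric vector summing to 1
#'   (renormalized if it does not, with a warning).
#' @param pairwise Optional precedence matrix the weights were derived
#'   from, kept for provenance.
#' @return A `weight_scheme` object.
#' @export
#' @examples
#' weight_scheme(c(DISS = 0.75, PolyIII = 0.25))
weight_scheme <- function(weights, pairwise = NULL) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be a named vector")
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must have a positive sum")
  if (abs(s - 1) > 1e-8) {
    warning("weights renormalized to sum 1")
    weights <- weights / s
  }
  structure(list(weights = weights, pairwise = pairwise),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Weight scheme:\n")
  for (a in names(x$weights))
    cat(sprintf("  %-12s %g\n", a, x$weights[[a]]))
  invisible(x)
}

#' Composite evaluation value of analyte yields
#'
#' The composite score is the weighted linear combination
#' \eqn{Y = \sum_a w_a \cdot yield_a} of the per-analyte yields, with
#' weights from a precedence chart or supplied explicitly.
#'
#' @param yields A named numeric vector of yields, or a data.frame /
#'   `experiment_table` with one column per analyte (rows scored
#'   independently).
#' @param weights A `weight_scheme` covering every analyte present.
#' @return A numeric scalar (vector input) or vector (tabular input).
#' @export
#' @examples
#' w <- weight_scheme(c(DISS = 0.75, PolyIII = 0.25))
#' composite_score(c(DISS = 15.5484, PolyIII = 1.4456), w)  # 12.0227
composite_score <- function(yields, weights) {
  stopifnot(inherits(weights, "weight_scheme"))
  w <- weights$weights
  if (is.data.frame(yields)) {
    analytes <- if (inherits(yields, "experiment_table"))
      attr(yields, "analytes") else intersect(names(yields), names(w))
    miss <- setdiff(analytes, names(w))
    if (length(miss))
      stop("weight scheme lacks analytes: ", paste(miss, collapse = ", "))
    ym <- as.matrix(as.data.frame(yields)[, analytes, drop = FALSE])
    drop(ym %*% w[analytes])
  } else {
    miss <- setdiff(names(yields), names(w))
    if (length(miss))
      stop("weight scheme lacks analytes: ", paste(miss, collapse = ", "))
    sum(w[names(yields)] * yields)
  }
}

#' Attach (or recompute) the composite column of an experiment table
#'
#' @param table An `experiment_table`.
#' @param weights A `weight_scheme` covering the table's analytes.
#' @return The table with its `Y` column set to the weighted composite.
#' @export
add_composite <- function(table, weights) {
  stopifnot(inherits(table, "experiment_table"))
  y <- composite_score(table, weights)
  df <- as.data.frame(table)
  df$Y <- y
  experiment_table(df, attr(table, "factors"), attr(table, "analytes"),
                   composite = "Y")
}

#' Average replicated runs
#'
#' Runs whose coded factor levels are identical (exact equality, as for
#' the integer -1/0/+1 levels of a standard design) are collapsed to a
#' single run whose responses are arithmetic means. This mirrors the
#' usual preprocessing before kernel regression on a replicated design:
#' duplicate inputs make the kernel system singular, so replicate
#' responses are averaged first.
#'
#' @param table An `experiment_table`.
#' @return An `experiment_table` with one row per distinct design point,
#'   in order of first appearance; `run_id` is the first id of each
#'   group.
#' @export
aggregate_replicates <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  factors <- attr(table, "factors")
  analytes <- attr(table, "analytes")
  composite <- attr(table, "composite")
  cm <- coded_matrix(table)
  key <- apply(cm, 1L, paste, collapse = "|")
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  df <- as.data.frame(table)
  out <- df[first, , drop = FALSE]
  for (col in c(analytes, composite))
    out[[col]] <- as.vector(tapply(df[[col]], grp, mean))[order(unique(grp))]
  rownames(out) <- NULL
  experiment_table(out, factors, analytes, composite)
}
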