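#' Define an experimental factor with three anchor levels
#'
#' A factor is described by its natural-unit values at the three coded
#' anchor levels of a three-level design: `low` (coded -1), `mid`
#' (coded 0) and `high` (coded +1). The mid level is *not* required to be
#' the arithmetic midpoint of `low` and `high`; the coding map is
#' piecewise linear on each side of `mid` (see [code_levels()]).
#'
#' @param name Factor name (single string), used as a column name in
#'   design and experiment tables.
#' @param unit Measurement unit, free text (e.g. `"min"`, `"degC"`).
#' @param low,mid,high Natural-unit values at coded -1, 0, +1. Must be
#'   strictly increasing.
#' @return An object of class `bbd_factor`.
#' @seealso [bbd_factors()], [code_levels()]
#' @export
#' @examples
#' bbd_factor("time", "min", 60, 90, 120)
bbd_factor <- function(name, unit = "", low, mid, high) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(is.numeric(low) && is.numeric(mid) && is.numeric(high)))
    stop("factor levels must be numeric")
  if (!(low < mid && mid < high))
    stop(sprintf("factor '%s': levels must satisfy low < mid < high (got %g, %g, %g)",
                 name, low, mid, high))
  structure(list(name = name, unit = unit,
                 low = as.numeric(low), mid = as.numeric(mid),
                 high = as.numeric(high)),
            class = "bbd_factor")
}

#' Collect factors into a factor set
#'
#' @param ... `bbd_factor` objects (or a single list of them).
#' @return An object of class `bbd_factors`: a list of `bbd_factor`
#'   objects with unique names.
#' @export
#' @examples
#' bbd_factors(bbd_factor("time", "min", 60, 90, 120),
#'             bbd_factor("temperature", "degC", 40, 50, 60))
bbd_factors <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && is.list(fs[[1L]]) && !inherits(fs[[1L]], "bbd_factor"))
    fs <- fs[[1L]]
  if (!length(fs) || !all(vapply(fs, inherits, logical(1), "bbd_factor")))
    stop("all arguments must be bbd_factor objects")
  nm <- vapply(fs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("factor names must be unique")
  names(fs) <- nm
  structure(fs, class = "bbd_factors")
}

#' @export
print.bbd_factors <- function(x, ...) {
  cat(sprintf("Factor set with %d factors (coded -1 / 0 / +1):\n", length(x)))
  for (f in x)
    cat(sprintf("  %-14s %8g / %8g / %8g %s\n",
                f$name, f$low, f$mid, f$high, f$unit))
  invisible(x)
}

#' @export
as.data.frame.bbd_factors <- function(x, ...) {
  data.frame(name = vapply(x, `[[`, character(1), "name"),
             unit = vapply(x, `[[`, character(1), "unit"),
             low = vapply(x, `[[`, numeric(1), "low"),
             mid = vapply(x, `[[`, numeric(1), "mid"),
             high = vapply(x, `[[`, numeric(1), "high"),
             row.names = NULL)
}

factor_names <- function(factors) {
  vapply(factors, `[[`, character(1), "name")
}

#' Read or write factor definitions as JSON
#'
#' The JSON file holds an array of objects with fields `name`, `unit`,
#' `low`, `mid`, `high`.
#'
#' @param path File path.
#' @return `read_factors()` returns a `bbd_factors` object;
#'   `write_factors()` returns `path` invisibly.
#' @export
read_factors <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(rec$unit)) rec$unit <- ""
  bbd_factors(lapply(seq_len(nrow(rec)), function(i)
    bbd_factor(rec$name[i], rec$unit[i], rec$low[i], rec$mid[i], rec$high[i])))
}

#' @rdname read_factors
#' @param factors A `bbd_factors` object.
#' @export
write_factors <- function(factors, path) {
  jsonlite::write_json(as.data.frame(factors), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Convert between natural and coded factor levels
#'
#' The coding map sends `low` to -1, `mid` to 0 and `high` to +1 and is
#' linear on each side of `mid`:
#' \deqn{x_{coded} = (x - mid)/(high - mid) \quad (x \ge mid), \qquad
#'       x_{coded} = (x - mid)/(mid - low) \quad (x < mid).}
#' For symmetric levels this reduces to the usual
#' \eqn{(x - mid)/\Delta} with \eqn{\Delta} the half-range.
#' `decode_levels()` is the exact inverse on \eqn{[-1, 1]} (and beyond,
#' by linear extrapolation of the corresponding branch).
#'
#' Natural values outside `[low, high]` are allowed (for prediction-only
#' use) but raise a warning.
#'
#' @param natural,coded A numeric vector of length `length(factors)`, or
#'   a matrix/data.frame with one column per factor.
#' @param factors A `bbd_factors` object.
#' @return A vector or matrix of the same shape as the input.
#' @export
#' @examples
#' f <- bbd_factors(bbd_factor("time", "min", 60, 90, 120),
#'                  bbd_factor("ethanol", "%", 55, 70, 85))
#' code_levels(c(120, 70), f)   # -> c(1, 0)
#' decode_levels(c(-1, 1), f)   # -> c(60, 85)
code_levels <- function(natural, factors) {
  m <- as_level_matrix(natural, factors, "natural")
  out <- m
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    x <- m[, j]
    if (any(x < f$low | x > f$high))
      warning(sprintf("values outside [%g, %g] for factor '%s'; coding extrapolates",
                      f$low, f$high, f$name))
    up <- x >= f$mid
    out[, j] <- ifelse(up, (x - f$mid) / (f$high - f$mid),
                           (x - f$mid) / (f$mid - f$low))
  }
  restore_shape(out, natural)
}

#' @rdname code_levels
#' @export
decode_levels <- function(coded, factors) {
  m <- as_level_matrix(coded, factors, "coded")
  out <- m
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    x <- m[, j]
    up <- x >= 0
    out[, j] <- ifelse(up, f$mid + x * (f$high - f$mid),
                           f$mid + x * (f$mid - f$low))
  }
  restore_shape(out, coded)
}

as_level_matrix <- function(x, factors, what) {
  k <- length(factors)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != k)
      stop(sprintf("%s matrix has %d columns; expected %d factors", what, ncol(x), k))
  } else {
    if (length(x) != k)
      stop(sprintf("%s vector has length %d; expected %d factors", what, length(x), k))
    x <- matrix(x, nrow = 1L)
  }
  colnames(x) <- factor_names(factors)
  storage.mode(x) <- "double"
  x
}

restore_shape <- function(m, original) {
  if (is.matrix(original) || is.data.frame(original)) m else drop(m)
}
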