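#' Specify a quadratic true surface for simulation
#'
#' The data model the analysis pipeline assumes: a (usually concave)
#' quadratic response surface on the coded design cube plus i.i.d.
#' homoscedastic Gaussian replicate noise,
#' \eqn{Y = \beta_0 + \sum \beta_i x_i + \sum \beta_{ij} x_i x_j +
#' \sum \beta_{ii} x_i^2 + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}.
#'
#' @param beta Named coefficient vector in the term naming of
#'   [fit_quadratic()]: `(Intercept)`, the factor names, `a:b`
#'   interactions and `a^2` squares. Missing terms default to 0.
#' @param noise_sd Replicate noise standard deviation (>= 0).
#' @param n_center Number of replicated center points in the design.
#' @param seed Integer seed; the same spec always generates the same
#'   table.
#' @return A `surface_spec` object.
#' @export
surface_spec <- function(beta, noise_sd = 0.066, n_center = 6L, seed = 1L) {
  if (is.null(names(beta)) || any(!nzchar(names(beta))))
    stop("beta must be a named coefficient vector")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(beta = beta, noise_sd = as.numeric(noise_sd),
                 n_center = as.integer(n_center), seed = as.integer(seed)),
            class = "surface_spec")
}

#' Simulate a Box-Behnken experiment from a known surface
#'
#' Builds the Box-Behnken design for `factors` with `spec$n_center`
#' center replicates, evaluates the specified quadratic surface at every
#' coded run and adds i.i.d. Gaussian noise — replicated center points
#' share their design point but draw independent noise. The result is a
#' regular `experiment_table` (single response column `Y`) that every
#' downstream stage accepts, so the whole pipeline can be exercised with
#' a known ground truth.
#'
#' In the extended two-analyte mode (`analyte_betas` given) each analyte
#' gets its own quadratic surface and noise SD, with optionally
#' correlated noise between analytes; the composite column is then the
#' weighted score of the simulated yields.
#'
#' @param factors A `bbd_factors` object.
#' @param spec A `surface_spec`.
#' @param analyte_betas Optional named list of per-analyte coefficient
#'   vectors for the extended mode.
#' @param analyte_noise_sd Per-analyte noise SDs (recycled).
#' @param noise_cor Correlation of the two analytes' noise (default 0).
#' @param weights A `weight_scheme` (extended mode only) used to build
#'   the composite column.
#' @return An `experiment_table` with attribute `true_beta` (the
#'   generating composite-surface coefficients, where defined).
#' @export
#' @examples
#' f <- bbd_factors(bbd_factor("a", "", -1, 0, 1),
#'                  bbd_factor("b", "", -1, 0, 1),
#'                  bbd_factor("c", "", -1, 0, 1))
#' s <- surface_spec(c(`(Intercept)` = 10, a = 1, `a^2` = -2),
#'                   noise_sd = 0, n_center = 3, seed = 7)
#' simulate_bbd_experiment(f, s)
simulate_bbd_experiment <- function(factors, spec, analyte_betas = NULL,
                                    analyte_noise_sd = spec$noise_sd,
                                    noise_cor = 0, weights = NULL) {
  stopifnot(inherits(factors, "bbd_factors"), inherits(spec, "surface_spec"))
  design <- build_bbd(factors, spec$n_center)
  cm <- as.matrix(design)
  M <- quadratic_model_matrix(cm)
  n <- nrow(cm)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  nat <- decode_levels(cm, factors)
  df <- data.frame(run_id = seq_len(n))
  df[colnames(nat)] <- as.data.frame(nat)

  if (is.null(analyte_betas)) {
    mu <- drop(M %*% expand_beta(spec$beta, colnames(M)))
    df$Y <- mu + stats::rnorm(n, 0, spec$noise_sd)
    out <- experiment_table(df, factors, analytes = "Y", composite = "Y")
    attr(out, "true_beta") <- expand_beta(spec$beta, colnames(M))
  } else {
    if (length(analyte_betas) != 2L || is.null(names(analyte_betas)))
      stop("extended mode expects a named list of two analyte coefficient sets")
    if (abs(noise_cor) > 1) stop("noise_cor must be in [-1, 1]")
    sds <- rep_len(analyte_noise_sd, 2L)
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    eps <- cbind(z1, noise_cor * z1 + sqrt(1 - noise_cor^2) * z2) %*% diag(sds)
    for (a in seq_along(analyte_betas))
      df[[names(analyte_betas)[a]]] <-
        drop(M %*% expand_beta(analyte_betas[[a]], colnames(M))) + eps[, a]
    out <- experiment_table(df, factors, analytes = names(analyte_betas))
    if (!is.null(weights)) out <- add_composite(out, weights)
  }
  out
}

expand_beta <- function(beta, term_names) {
  unknown <- setdiff(names(beta), term_names)
  if (length(unknown))
    stop("unknown surface terms: ", paste(unknown, collapse = ", "),
         " (expected among: ", paste(term_names, collapse = ", "), ")")
  full <- stats::setNames(numeric(length(term_names)), term_names)
  full[names(beta)] <- beta
  full
}
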