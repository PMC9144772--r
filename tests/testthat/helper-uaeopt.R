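# shared builders for the test suite; everything is generated in code

# symmetric unit-cube factor set with k factors
unit_factors <- function(k) {
  bbd_factors(lapply(seq_len(k), function(i)
    bbd_factor(paste0("f", i), "", -1, 0, 1)))
}

paper_factors <- function() load_fixture("table1")
paper_weights <- function() fixture_weights()

# random full quadratic coefficient vector with a negative-definite
# quadratic form (concave surface), stationary point pulled inside the cube
random_concave_beta <- function(k, scale = 1) {
  nm <- paste0("f", seq_len(k))
  A <- matrix(stats::rnorm(k * k, sd = scale), k)
  B <- -(crossprod(A) / k + diag(k) * 0.2 * scale)   # negative definite
  xs <- stats::runif(k, -0.7, 0.7)                   # interior stationary point
  bvec <- drop(-2 * B %*% xs)
  beta <- c(stats::rnorm(1, 10), bvec)
  names(beta) <- c("(Intercept)", nm)
  pairs <- utils::combn(k, 2, simplify = FALSE)
  for (ij in pairs)
    beta[paste(nm[ij], collapse = ":")] <- 2 * B[ij[1], ij[2]]
  beta[paste0(nm, "^2")] <- diag(B)
  list(beta = beta, B = B, b = bvec, xs = xs)
}

# evaluate a named full-quadratic coefficient vector at coded points
eval_quadratic_beta <- function(beta, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  M <- uaeopt:::quadratic_model_matrix(X)
  drop(M %*% beta[colnames(M)])
}

# noiseless experiment table from a beta on a BBD
noiseless_table <- function(k, beta, n_center = 3) {
  f <- unit_factors(k)
  simulate_bbd_experiment(f, surface_spec(beta, noise_sd = 0,
                                          n_center = n_center, seed = 1))
}
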