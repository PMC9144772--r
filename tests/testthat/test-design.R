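test_that("build_bbd produces the catalog designs for k = 3..7", {
  sizes <- c(`3` = 12L, `4` = 24L, `5` = 40L, `6` = 48L, `7` = 56L)
  nonzero <- c(`3` = 2L, `4` = 2L, `5` = 2L, `6` = 3L, `7` = 3L)
  for (k in 3:7) {
    d <- build_bbd(unit_factors(k), n_center = 2)
    m <- as.matrix(d)
    expect_equal(nrow(m), sizes[[as.character(k)]] + 2L)
    expect_true(all(m %in% c(-1, 0, 1)))
    # coded columns sum to zero; edge runs have the catalog nonzero count
    expect_equal(unname(colSums(m)), rep(0, k))
    edge <- m[rowSums(m != 0) > 0, , drop = FALSE]
    expect_equal(unique(rowSums(edge != 0)), nonzero[[as.character(k)]])
    # brute-force orthogonality of the linear columns
    expect_equal(crossprod(m) - diag(diag(crossprod(m))),
                 matrix(0, k, k), ignore_attr = TRUE)
  }
})

test_that("build_bbd validates its inputs", {
  expect_error(build_bbd(unit_factors(3), n_center = 0), "positive")
  f2 <- bbd_factors(bbd_factor("a", "", -1, 0, 1), bbd_factor("b", "", -1, 0, 1))
  expect_error(build_bbd(f2), "3 to 7")
})

test_that("the 4-factor design with 6 centers matches the published coded matrix as a set", {
  d <- build_bbd(paper_factors(), n_center = 6)
  expect_equal(nrow(d), 30L)
  printed <- coded_matrix(load_fixture("table2"))
  key <- function(m) unname(sort(apply(m, 1, paste, collapse = ",")))
  expect_identical(key(as.matrix(d)), key(printed))
})

test_that("code_levels and decode_levels are mutual inverses and hit the anchors", {
  f <- paper_factors()
  expect_equal(code_levels(c(90, 50, 10, 70), f), rep(0, 4), ignore_attr = TRUE)
  expect_equal(code_levels(c(120, 60, 12, 85), f), rep(1, 4), ignore_attr = TRUE)
  expect_equal(code_levels(c(60, 40, 8, 55), f), rep(-1, 4), ignore_attr = TRUE)
  expect_equal(decode_levels(c(0.5, -0.5, 0.25, -1), f),
               c(105, 45, 10.5, 55), ignore_attr = TRUE)
  set.seed(42)
  for (i in 1:100) {
    x <- c(runif(1, 60, 120), runif(1, 40, 60), runif(1, 8, 12), runif(1, 55, 85))
    expect_equal(decode_levels(code_levels(x, f), f), x, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("piecewise-linear coding honors an asymmetric mid level", {
  f <- bbd_factors(bbd_factor("ethanol", "%", 50, 70, 85))
  expect_equal(code_levels(60, f), -0.5, ignore_attr = TRUE)
  expect_equal(code_levels(77.5, f), 0.5, ignore_attr = TRUE)
  expect_equal(decode_levels(-0.5, f), 60, ignore_attr = TRUE)
  expect_warning(code_levels(95, f), "outside")
  expect_error(code_levels(c(70, 70), f), "length")
})

test_that("precedence weights follow row-sum normalization", {
  w2 <- precedence_weights(matrix(c(0, .5, .5, 0), 2), c("A", "B"))
  expect_equal(w2$weights, c(A = 0.5, B = 0.5))
  # strict order a > b > c: rows sum (2, 1, 0)
  pw <- matrix(c(0, 1, 1,
                 0, 0, 1,
                 0, 0, 0), 3, byrow = TRUE)
  w3 <- precedence_weights(pw, c("a", "b", "c"))
  expect_equal(w3$weights, c(a = 2/3, b = 1/3, c = 0))
  expect_error(precedence_weights(matrix(c(0, 1, 1, 0), 2), c("A", "B")),
               "inconsistent")
})

test_that("precedence weights sum to 1 and are permutation-equivariant", {
  set.seed(7)
  for (i in 1:20) {
    m <- sample(2:5, 1)
    pw <- matrix(0, m, m)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      s <- sample(c(0, 0.5, 1), 1)
      pw[a, b] <- s; pw[b, a] <- 1 - s
    }
    nm <- paste0("an", seq_len(m))
    w <- precedence_weights(pw, nm)
    expect_equal(sum(w$weights), 1)
    expect_true(all(w$weights >= 0))
    perm <- sample(m)
    wp <- precedence_weights(pw[perm, perm], nm[perm])
    expect_equal(wp$weights[nm], w$weights[nm])
  }
})

test_that("composite_score reproduces the published column and is linear", {
  w <- paper_weights()
  expect_equal(composite_score(c(DISS = 15.5484, PolyIII = 1.4456), w),
               12.0227, tolerance = 5e-5)
  expect_equal(composite_score(c(DISS = 16.8183, PolyIII = 1.7018), w),
               13.0392, tolerance = 5e-5)
  expect_equal(composite_score(c(DISS = 0, PolyIII = 0), w), 0)
  expect_error(composite_score(c(DISS = 1, Other = 2), w), "Other")
  tab2 <- load_fixture("table2")
  # half-ulp printed rounding sits exactly on the 5e-5 bound; 1e-12 is float slack
  expect_true(all(abs(composite_score(tab2, w) - tab2$Y) <= 5e-5 + 1e-12))
  # linear in each yield
  y0 <- composite_score(c(DISS = 10, PolyIII = 2), w)
  expect_equal(composite_score(c(DISS = 12, PolyIII = 2), w) - y0, 2 * 0.75)
})

test_that("explicit weight schemes validate and renormalize", {
  expect_error(weight_scheme(c(1, 2)), "named")
  expect_error(weight_scheme(c(a = -1, b = 2)), "nonnegative")
  expect_warning(w <- weight_scheme(c(a = 1, b = 3)), "renormalized")
  expect_equal(w$weights, c(a = 0.25, b = 0.75))
})

test_that("aggregate_replicates averages identical coded points", {
  tab2 <- load_fixture("table2")
  avg <- aggregate_replicates(tab2)
  expect_equal(nrow(avg), 25L)
  expect_equal(avg$Y[25], mean(tab2$Y[25:30]), tolerance = 1e-12)
  expect_equal(avg$Y[25], 13.0107, tolerance = 5e-5)
  expect_equal(avg$Y[1:24], tab2$Y[1:24])     # non-replicated rows unchanged
  expect_identical(as.data.frame(aggregate_replicates(avg)),
                   as.data.frame(avg))        # idempotent / identity
  # two duplicate rows average
  f <- unit_factors(2)
  df <- data.frame(run_id = 1:3, f1 = c(0, 0, 1), f2 = c(0, 0, 0),
                   A = c(1, 3, 7))
  t <- experiment_table(df, f, "A")
  a <- aggregate_replicates(t)
  expect_equal(a$A, c(2, 7))
  expect_equal(a$run_id, c(1, 3))
})

test_that("experiment tables round-trip through CSV", {
  f <- paper_factors()
  tab2 <- load_fixture("table2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_experiment(tab2, path)
  back <- read_experiment(path, f)
  expect_equal(as.data.frame(back), as.data.frame(tab2))
  expect_identical(attr(back, "analytes"), c("PolyIII", "DISS"))
  expect_identical(attr(back, "composite"), "Y")
})

test_that("experiment_table validates structure", {
  f <- unit_factors(2)
  expect_error(experiment_table(data.frame(run_id = 1, f1 = 0), f, "A"),
               "missing columns")
  expect_error(experiment_table(
    data.frame(run_id = c(1, 1), f1 = 0, f2 = 0, A = 1), f, "A"), "unique")
})
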