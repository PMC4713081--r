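read_fixture <- function() {
  read.table(system.file("extdata", "regression_example.tsv",
                         package = "regulogr"),
             sep = "\t", header = TRUE)
}

test_that("coefficients match the explicit normal-equations solution", {
  d <- read_fixture()
  Y <- d$frac_dual
  X <- as.matrix(d[, c("genome_size", "global_regulators", "nap_function")])
  fit <- fit_multivariate(Y, X)
  oracle <- normal_equations(Y, X)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-10)
  b_oracle <- oracle[-1] * apply(X, 2, sd) / sd(Y)
  expect_equal(unname(fit$standardized_b), unname(b_oracle),
               tolerance = 1e-10)
  expect_equal(fit$df, nrow(d) - 4L)
  expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
})

test_that("standardized coefficients are invariant under predictor rescaling", {
  d <- read_fixture()
  Y <- d$frac_dual
  X <- as.matrix(d[, c("genome_size", "global_regulators", "nap_function")])
  b0 <- fit_multivariate(Y, X)$standardized_b
  X2 <- X
  X2[, 1] <- X2[, 1] / 10 + 3       # rescaled with an offset
  X2[, 3] <- 100 * X2[, 3]          # percent
  b1 <- fit_multivariate(Y, X2)$standardized_b
  # the shift induces extra cancellation in the uncentered QR, so the
  # affine-invariance check runs at 1e-9; pure rescaling holds to 1e-12
  expect_equal(unname(b1), unname(b0), tolerance = 1e-9)
  X3 <- sweep(X, 2, c(0.001, 10, 100), `*`)
  expect_equal(unname(fit_multivariate(Y, X3)$standardized_b), unname(b0),
               tolerance = 1e-12)
})

test_that("degenerate designs are reported", {
  set.seed(11)
  X <- cbind(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  Y <- 2 * X[, 1]
  fit <- fit_multivariate(Y, X)
  expect_equal(unname(fit$standardized_b[1]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$standardized_b[2:3]), c(0, 0), tolerance = 1e-10)

  expect_warning(fitc <- fit_multivariate(rep(0.5, 20), X), "constant")
  expect_true(all(is.na(fitc$standardized_b)))
  expect_equal(unname(fitc$coefficients[-1]), c(0, 0, 0), tolerance = 1e-12)

  Xc <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])   # exact collinearity
  expect_error(fit_multivariate(rnorm(20), Xc), "rank deficient")
  expect_error(fit_multivariate(rnorm(4), X[1:4, ]), "n > p")
})

test_that("predictors rank by |b| among the significant ones", {
  fake <- structure(list(
    predictors = c("genome_size", "global_regulators", "nap_function"),
    standardized_b = c(genome_size = 0.10, global_regulators = 0.49,
                       nap_function = 0.07),
    p_values = c(`(Intercept)` = 0.9, genome_size = 0.50,
                 global_regulators = 2e-4, nap_function = 0.61)),
    class = "tf_regression")
  cp <- compare_predictors(fake)
  expect_equal(cp$predictor[cp$influential], "global_regulators")
  expect_equal(sum(cp$influential), 1L)

  fake$p_values[] <- 0.5
  expect_equal(sum(compare_predictors(fake)$influential), 0L)

  fake$p_values[] <- 0.01
  fake$standardized_b[] <- c(0.3, 0.2, 0.05)
  expect_equal(compare_predictors(fake)$predictor[1:2],
               c("genome_size", "global_regulators"))
})

test_that("predictor redundancy is plain Pearson correlation", {
  expect_equal(predictor_redundancy(1:5, 1:5)$r, 1)
  expect_true(predictor_redundancy(1:5, 1:5)$redundant)
  expect_equal(predictor_redundancy(c(1, 2, 3, 4), c(1, 2, 4, 3))$r, 0.8,
               tolerance = 1e-12)
  x <- c(-1, 0, 1, 0)
  y <- c(0, -1, 0, 1)
  expect_equal(predictor_redundancy(x, y)$r, 0)
  expect_false(predictor_redundancy(x, y)$redundant)
  expect_error(predictor_redundancy(rep(1, 4), 1:4), "zero-variance")
})

test_that("known coefficients are recovered from simulated data", {
  beta <- c(0.4, -0.3, 0.2, 0.05)
  ok <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    X <- cbind(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
    Y <- beta[1] + X %*% beta[-1] + rnorm(100, 0, 0.3)
    fit <- fit_multivariate(drop(Y), X)
    all(abs(fit$coefficients - beta) <= 3 * fit$se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
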