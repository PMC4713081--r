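# Multivariate least squares relating each TF-type fraction (criterion) to
# genome size, global-regulator fraction and NAP fraction (predictors), with
# standardized partial coefficients b_j = beta_j * sd(X_j) / sd(Y). The b's
# are unit-free, so their relative magnitudes (together with their p-values)
# compare the strength of the predictors.

#' Multivariate least-squares fit with standardized partial coefficients
#'
#' Ordinary least squares of `Y` on the columns of `X` with an intercept.
#' Per-coefficient two-sided t-tests use `n - p - 1` residual degrees of
#' freedom. Standardized coefficients use the sample (n-1) standard
#' deviation of each predictor and of `Y`; they are invariant under affine
#' rescaling of any predictor.
#'
#' @param Y numeric response vector (e.g. a TF-type fraction per genome).
#' @param X numeric matrix or data.frame of predictors, one column each
#'   (e.g. genome size, global-regulator fraction, NAP fraction).
#' @param condition_threshold condition number of the design above which a
#'   collinearity warning with variance-inflation factors is issued.
#' @return A `tf_regression` object: list with `coefficients` (named, incl.
#'   `(Intercept)`), `se`, `t`, `p_values`, `standardized_b`, `r_squared`,
#'   `n`, `df`, `predictors`.
#' @export
fit_multivariate <- function(Y, X, condition_threshold = 1e8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  n <- length(Y)
  p <- ncol(X)
  if (nrow(X) != n) stop("Y and X have different lengths")
  if (n <= p + 1) stop("need more observations than coefficients (n > p + 1)")
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("design matrix is rank deficient (exactly collinear predictors)")
  kap <- kappa(design, exact = TRUE)
  if (kap > condition_threshold) {
    cx <- stats::cor(X)
    vif <- diag(solve(cx))
    warning("ill-conditioned design (condition number ", format(kap),
            "); variance inflation factors: ",
            paste(sprintf("%s=%.2f", colnames(X), vif), collapse = ", "))
  }
  fit <- stats::lm.fit(design, Y)
  beta <- fit$coefficients
  df <- n - p - 1
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- names(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  sdY <- stats::sd(Y)
  sdX <- apply(X, 2, stats::sd)
  if (sdY == 0) {
    warning("response is constant (sd(Y) = 0); standardized coefficients ",
            "undefined")
    b <- setNames(rep(NA_real_, p), colnames(X))
  } else {
    b <- beta[-1] * sdX / sdY
  }
  tss <- sum((Y - mean(Y))^2)
  structure(list(coefficients = beta, se = se, t = tval, p_values = pval,
                 standardized_b = b,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = n, df = df, predictors = colnames(X)),
            class = "tf_regression")
}

#' @export
print.tf_regression <- function(x, ...) {
  cat(sprintf("Multivariate regression (n = %d, df = %d, R^2 = %.3f)\n",
              x$n, x$df, x$r_squared))
  tab <- data.frame(beta = x$coefficients,
                    se = x$se,
                    t = x$t,
                    p = x$p_values,
                    b = c(NA, x$standardized_b))
  print(round(tab, 4))
  invisible(x)
}

#' Rank predictors by standardized influence
#'
#' Orders predictors by the magnitude of their standardized coefficients,
#' flagging as influential those significant at `alpha`.
#'
#' @param result a `tf_regression` from [fit_multivariate()].
#' @param alpha significance level.
#' @return data.frame `predictor, b, p_value, influential`, influential
#'   predictors first, each group ordered by decreasing `|b|`.
#' @export
compare_predictors <- function(result, alpha = 0.05) {
  b <- result$standardized_b
  p <- result$p_values[result$predictors]
  out <- data.frame(predictor = result$predictors, b = unname(b),
                    p_value = unname(p),
                    influential = unname(p < alpha))
  out <- out[order(-out$influential, -abs(out$b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Redundancy between two predictors
#'
#' Ordinary Pearson correlation; predictors more correlated than `threshold`
#' in magnitude carry largely the same information and are flagged redundant
#' (dropping either from a regression then changes little).
#'
#' @param x2,x3 numeric vectors of equal length (at least 3).
#' @param threshold redundancy flag cutoff on `|r|`.
#' @return List with `r` and logical `redundant`.
#' @export
predictor_redundancy <- function(x2, x3, threshold = 0.7) {
  stopifnot(length(x2) == length(x3))
  if (length(x2) < 3) stop("need at least 3 observations")
  if (stats::sd(x2) == 0 || stats::sd(x3) == 0)
    stop("zero-variance predictor")
  r <- stats::cor(x2, x3)
  list(r = r, redundant = abs(r) > threshold)
}
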