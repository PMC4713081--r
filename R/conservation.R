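# Preferential-conservation tests. For a reference genome coding N TFs, K of
# a focal type, and a target genome conserving n orthologous TFs of which k
# are of that type, the one-sided question "is the focal type over-represented
# among the conserved TFs?" (H0: f_i <= f_r vs H1: f_i > f_r) is answered by
# the hypergeometric upper tail P(X >= k). Per-genome p-values are combined
# across genomes with Fisher's method.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` type-K elements when sampling `n` without replacement from a
#' population of `N` containing `K` of the type. Computed through the
#' log-space distribution function, so it is stable for populations of
#' thousands of genes.
#'
#' @param N population size (reference TF total).
#' @param K number of type elements in the population.
#' @param n sample size (conserved TFs).
#' @param k observed type count in the sample; the tail includes `k` itself.
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) != floor(c(N, K, n, k))))
    stop("hypergeometric parameters must be integers")
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > n)
    stop("invalid hypergeometric parameters: need 0 <= k <= n <= N and ",
         "0 <= K <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Reference type counts for the conservation tests
#'
#' @param annot TF annotation data.frame.
#' @return List with `N` (all reference TFs) and `K`, a named vector of
#'   per-type counts over `activator`, `repressor`, `dual`.
#' @export
reference_type_counts <- function(annot) {
  list(N = nrow(annot),
       K = c(activator = sum(annot$reg_type == "activator"),
             repressor = sum(annot$reg_type == "repressor"),
             dual = sum(annot$reg_type == "dual")))
}

#' One-sided conservation test for one genome and one TF type
#'
#' Tests H0: the genome's fraction of the focal type among conserved TFs is
#' no larger than the reference fraction, against H1: it is larger. Genomes
#' conserving no TFs (`n = 0`) cannot be tested and are flagged
#' `"untestable"`.
#'
#' @param ref_counts output of [reference_type_counts()].
#' @param tc a `type_counts` row from [count_conserved_tf_types()].
#' @param tf_type one of `"activator"`, `"repressor"`, `"dual"`.
#' @param alpha significance level (default 0.05).
#' @return A `conservation_test` object (one-row data.frame) with fields
#'   `genome_id`, `tf_type`, `N`, `K`, `n`, `k`, `f_i`, `f_r`, `p_value`,
#'   `reject`, `status`.
#' @export
conservation_test <- function(ref_counts, tc, tf_type, alpha = 0.05) {
  tf_type <- match.arg(tf_type, c("activator", "repressor", "dual"))
  K <- ref_counts$K[[tf_type]]
  N <- ref_counts$N
  k <- switch(tf_type, activator = tc$k_activators,
              repressor = tc$k_repressors, dual = tc$k_duals)
  n <- tc$n
  if (n == 0) {
    out <- data.frame(genome_id = tc$genome_id, tf_type = tf_type, N = N,
                      K = K, n = 0L, k = 0L, f_i = NA_real_, f_r = K / N,
                      p_value = NA_real_, reject = NA, status = "untestable")
  } else {
    p <- hypergeom_upper_tail(N, K, n, k)
    out <- data.frame(genome_id = tc$genome_id, tf_type = tf_type, N = N,
                      K = K, n = n, k = k, f_i = k / n, f_r = K / N,
                      p_value = p, reject = p < alpha, status = "tested")
  }
  class(out) <- c("conservation_test", "data.frame")
  out
}

#' Combine independent p-values with Fisher's method
#'
#' The statistic `X = -2 * sum(log(p_i))` follows a chi-square distribution
#' with `2m` degrees of freedom under the joint null. Zero p-values are
#' clamped to the smallest positive double with a warning.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]` from independent
#'   tests of the same one-sided hypothesis.
#' @return A `fisher_combined` object: list with `statistic`,
#'   `degrees_of_freedom`, `p_value`, `n_tests`.
#' @export
fisher_combine <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues))
    stop("no p-values to combine")
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (any(pvalues == 0)) {
    warning("zero p-value(s) clamped to smallest positive double")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  structure(list(statistic = X, degrees_of_freedom = df,
                 p_value = stats::pchisq(X, df, lower.tail = FALSE),
                 n_tests = length(pvalues)),
            class = "fisher_combined")
}

#' @export
print.fisher_combined <- function(x, ...) {
  cat(sprintf("Fisher's method: X = %.4f on %d df (%d tests), p = %.4g\n",
              x$statistic, x$degrees_of_freedom, x$n_tests, x$p_value))
  invisible(x)
}
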