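# Felsenstein's phylogenetically independent contrasts. Under Brownian-motion
# trait evolution on a known phylogeny, the L-1 standardized contrasts of a
# bifurcating L-leaf tree are independent draws with variance equal to the
# Brownian rate, so they can enter ordinary statistics. Because each contrast
# has an arbitrary sign (which child is subtracted from which), correlation
# and regression between two sets of contrasts are computed through the
# origin, after "positivizing" the X-axis contrasts.

#' Parse a rooted Newick tree
#'
#' Thin wrapper over \pkg{ape}'s Newick reader that enforces the
#' preconditions of the contrast machinery: the tree must parse, be rooted,
#' and carry branch lengths (in expected-variance units).
#'
#' @param text Newick string.
#' @return An \pkg{ape} `phylo` object.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error in: ", substr(text, 1, 60))
  if (!ape::is.rooted(tree))
    stop("tree must be rooted")
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  tree
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @return `write_newick` returns the Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Resolve multifurcations into zero-length bifurcations
#'
#' Contrasts require a strictly bifurcating tree. Polytomies are expanded
#' into caterpillars of zero-length internal branches; the expansion order is
#' randomized but fully determined by `seed`.
#'
#' @param tree a rooted `phylo`.
#' @param seed integer seed controlling the expansion order.
#' @return A bifurcating `phylo`.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  set.seed(seed)
  ape::multi2di(tree, random = TRUE)
}

#' Standardized phylogenetically independent contrasts
#'
#' Post-order over the tree: at an internal node whose children carry values
#' `(x_a, x_b)` on branches with (augmented) lengths `(v_a, v_b)`, the raw
#' contrast is `x_a - x_b` with combined variance `v_a + v_b`; the node gets
#' the weighted ancestral value `(x_a/v_a + x_b/v_b) / (1/v_a + 1/v_b)` and
#' its own branch is augmented by `v_a*v_b/(v_a + v_b)`.
#'
#' @param tree bifurcating rooted `phylo` with branch lengths (use
#'   [resolve_polytomies()] first if needed).
#' @param trait named numeric vector covering every leaf.
#' @param trait_name label stored with the result.
#' @param epsilon variance used for both branches of a node whose combined
#'   variance is exactly zero (degenerate cherry); applied only then, with a
#'   warning.
#' @return A `contrast_set`: data.frame with columns `node`, `raw`,
#'   `variance`, `standardized` (one row per internal node, post-order),
#'   with attributes `trait_name` and `n_contrasts`.
#' @export
compute_contrasts <- function(tree, trait, trait_name = deparse(substitute(trait)),
                              epsilon = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2) {
    out <- data.frame(node = character(0), raw = numeric(0),
                      variance = numeric(0), standardized = numeric(0))
    return(structure(out, trait_name = trait_name, n_contrasts = 0L,
                     class = c("contrast_set", "data.frame")))
  }
  if (!ape::is.binary(tree))
    stop("tree must be strictly bifurcating; see resolve_polytomies()")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stop("trait missing for leaf/leaves: ",
         paste(head(miss, 5), collapse = ", "))
  tr <- stats::reorder(tree, "postorder")
  nn <- ntip + tr$Nnode
  x <- numeric(nn)
  x[seq_len(ntip)] <- as.numeric(trait[tr$tip.label])
  vadj <- numeric(nn)                   # branch length above node, augmented
  vadj[tr$edge[, 2]] <- tr$edge.length
  labs <- c(tr$tip.label,
            if (!is.null(tr$node.label) && all(nzchar(tr$node.label)))
              tr$node.label else paste0("N", ntip + seq_len(tr$Nnode)))
  internal <- unique(tr$edge[, 1])      # postorder
  res <- data.frame(node = labs[internal], raw = NA_real_,
                    variance = NA_real_, standardized = NA_real_)
  for (i in seq_along(internal)) {
    nd <- internal[i]
    ch <- tr$edge[tr$edge[, 1] == nd, 2]
    v <- vadj[ch]
    if (sum(v) == 0) {
      warning("zero combined variance at node ", labs[nd],
              "; using epsilon = ", epsilon, " for both branches")
      v <- c(epsilon, epsilon)
    }
    V <- sum(v)
    raw <- x[ch[1]] - x[ch[2]]
    res$raw[i] <- raw
    res$variance[i] <- V
    res$standardized[i] <- raw / sqrt(V)
    x[nd] <- if (v[1] == 0) x[ch[1]] else if (v[2] == 0) x[ch[2]] else
      (x[ch[1]] / v[1] + x[ch[2]] / v[2]) / (1 / v[1] + 1 / v[2])
    vadj[nd] <- vadj[nd] + v[1] * v[2] / V
  }
  structure(res, trait_name = trait_name, n_contrasts = nrow(res),
            ancestral = setNames(x[internal], labs[internal]),
            augmented_length = setNames(vadj[internal], labs[internal]),
            class = c("contrast_set", "data.frame"))
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("Independent contrasts for '%s': %d contrasts\n",
              attr(x, "trait_name"), attr(x, "n_contrasts")))
  print.data.frame(x)
  invisible(x)
}

contrast_values <- function(x) {
  if (inherits(x, "contrast_set")) x$standardized else as.numeric(x)
}

#' Positivize paired contrast sets
#'
#' Flips the sign of both members of every contrast pair whose X-axis
#' contrast is negative, so all X contrasts become non-negative. Through-
#' origin correlation magnitude is unaffected; the convention fixes the sign.
#'
#' @param cx,cy `contrast_set`s for the X and Y traits on the same tree.
#' @return List with elements `x` and `y`, the positivized sets.
#' @export
positivize <- function(cx, cy) {
  stopifnot(inherits(cx, "contrast_set"), inherits(cy, "contrast_set"))
  if (!identical(cx$node, cy$node))
    stop("contrast sets come from different trees or node orders")
  flip <- cx$standardized < 0
  for (col in c("raw", "standardized")) {
    cx[[col]][flip] <- -cx[[col]][flip]
    cy[[col]][flip] <- -cy[[col]][flip]
  }
  list(x = cx, y = cy)
}

#' Correlation through the origin between two contrast sets
#'
#' `r = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, with significance from a
#' t-statistic on `n_contrasts - 1` degrees of freedom (the convention of
#' origin-constrained contrast statistics).
#'
#' @param x,y `contrast_set`s (standardized contrasts are used) or numeric
#'   vectors.
#' @return List of class `origin_cor`: `r`, `t`, `df`, `p_value`, `n`.
#' @export
correlation_through_origin <- function(x, y) {
  xv <- contrast_values(x); yv <- contrast_values(y)
  stopifnot(length(xv) == length(yv))
  if (length(xv) < 2)
    stop("need at least 2 contrast pairs")
  sxx <- sum(xv^2); syy <- sum(yv^2)
  if (sxx == 0 || syy == 0)
    stop("undefined correlation: a contrast vector has zero norm")
  r <- sum(xv * yv) / sqrt(sxx * syy)
  df <- length(xv) - 1
  if (1 - r^2 < .Machine$double.eps) {
    t <- sign(r) * Inf; p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(r = r, t = t, df = df, p_value = p, n = length(xv)),
            class = "origin_cor")
}

#' @export
print.origin_cor <- function(x, ...) {
  cat(sprintf("Through-origin correlation: r = %.4f (t = %.3f, df = %d, p = %.3g)\n",
              x$r, x$t, x$df, x$p_value))
  invisible(x)
}

#' Regression through the origin between two contrast sets
#'
#' `slope = sum(x*y) / sum(x^2)` with residual degrees of freedom
#' `n_contrasts - 1`.
#'
#' @inheritParams correlation_through_origin
#' @return List of class `origin_reg`: `slope`, `se`, `t`, `df`, `p_value`,
#'   `n`.
#' @export
regression_through_origin <- function(x, y) {
  xv <- contrast_values(x); yv <- contrast_values(y)
  stopifnot(length(xv) == length(yv))
  if (length(xv) < 2)
    stop("need at least 2 contrast pairs")
  sxx <- sum(xv^2)
  if (sxx == 0)
    stop("undefined regression: sum of squared x contrasts is zero")
  slope <- sum(xv * yv) / sxx
  df <- length(xv) - 1
  rss <- sum((yv - slope * xv)^2)
  se <- sqrt(rss / df / sxx)
  if (se == 0) {
    t <- if (slope == 0) 0 else sign(slope) * Inf
    p <- if (slope == 0) 1 else 0
  } else {
    t <- slope / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(slope = slope, se = se, t = t, df = df, p_value = p,
                 n = length(xv)),
            class = "origin_reg")
}

#' @export
print.origin_reg <- function(x, ...) {
  cat(sprintf("Through-origin regression: slope = %.4f (se = %.4f, df = %d, p = %.3g)\n",
              x$slope, x$se, x$df, x$p_value))
  invisible(x)
}
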