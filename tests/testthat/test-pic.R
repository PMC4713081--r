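test_that("Newick parsing validates and round-trips", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  one <- parse_newick("(A:1);")
  expect_equal(nrow(compute_contrasts(one, c(A = 1))), 0L)
  expect_error(parse_newick("((A:1,B:1):1,C:2"), "parse error")
  expect_error(parse_newick("(A:1,B:1,C:1);"), "rooted")
  expect_error(parse_newick("((A,B),C);"), "branch lengths")

  set.seed(31)
  tr20 <- ape::rcoal(20)
  back <- parse_newick(write_newick(tr20))
  expect_true(ape::all.equal.phylo(tr20, back, tolerance = 1e-8))
})

test_that("polytomies resolve into zero-length bifurcations, reproducibly", {
  tri <- ape::read.tree(text = "(A:1,B:1,C:1):0;")
  r1 <- resolve_polytomies(tri, seed = 4)
  expect_true(ape::is.binary(r1))
  expect_equal(length(r1$tip.label), 3L)
  expect_true(any(r1$edge.length == 0))
  expect_identical(write_newick(resolve_polytomies(tri, seed = 4)),
                   write_newick(r1))
  # a k-furcation adds k - 2 internal nodes
  poly5 <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1):0;")
  expect_equal(resolve_polytomies(poly5, seed = 1)$Nnode, poly5$Nnode + 3L)
  bif <- parse_newick("((A:1,B:1):1,C:2);")
  expect_identical(resolve_polytomies(bif, seed = 1), bif)
})

test_that("contrasts reproduce the hand-worked Felsenstein recursion", {
  cherry <- parse_newick("(A:1,B:1);")
  cs <- compute_contrasts(cherry, c(A = 3, B = 1))
  expect_equal(cs$standardized, 2 / sqrt(2), tolerance = 1e-5)

  tr <- parse_newick("((A:1,B:1):1,C:2);")
  cs3 <- compute_contrasts(tr, c(A = 1, B = 3, C = 6))
  expect_equal(sort(cs3$standardized), c(-2.13809, -1.41421),
               tolerance = 1e-5)
  anc <- attr(cs3, "ancestral")
  aug <- attr(cs3, "augmented_length")
  # ancestral value of the (A,B) node and its augmented branch
  expect_equal(unname(anc[cs3$node[1]]), 2)
  expect_equal(unname(aug[cs3$node[1]]), 1.5)

  flat <- compute_contrasts(tr, c(A = 7, B = 7, C = 7))
  expect_true(all(flat$standardized == 0))
  expect_equal(attr(cs3, "n_contrasts"), 2L)
})

test_that("contrasts agree with ape's implementation on random trees", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::rcoal(16)
    x <- setNames(rnorm(16), tr$tip.label)
    mine <- compute_contrasts(tr, x)
    theirs <- ape::pic(x, tr)
    expect_equal(sort(abs(mine$standardized)), sort(abs(unname(theirs))),
                 tolerance = 1e-10)
  }
})

test_that("contrast count is leaves - 1 and zero branches are handled", {
  tr <- simulate_tree(24, seed = 8)
  x <- simulate_brownian_trait(tr, rate = 1, seed = 9)
  expect_equal(nrow(compute_contrasts(tr, x)), 23L)
  zero <- parse_newick("((A:0,B:0):1,C:2);")
  expect_warning(cz <- compute_contrasts(zero, c(A = 1, B = 2, C = 3)),
                 "zero combined variance")
  expect_true(all(is.finite(cz$standardized)))
})

test_that("positivization flips pairs jointly and preserves |r|", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  cx <- compute_contrasts(tr, c(A = 1, B = 3, C = 6))
  cy <- compute_contrasts(tr, c(A = 2, B = 1, C = 4))
  ps <- positivize(cx, cy)
  expect_true(all(ps$x$standardized >= 0))
  flipped <- cx$standardized < 0
  expect_equal(ps$y$standardized[flipped], -cy$standardized[flipped])
  expect_equal(abs(correlation_through_origin(ps$x, ps$y)$r),
               abs(correlation_through_origin(cx, cy)$r), tolerance = 1e-12)
  # already non-negative x: identity
  ps2 <- positivize(ps$x, ps$y)
  expect_equal(ps2$x$standardized, ps$x$standardized)
  expect_equal(ps2$y$standardized, ps$y$standardized)
  cy_bad <- compute_contrasts(parse_newick("(A:1,B:1);"), c(A = 1, B = 2))
  expect_error(positivize(cx, cy_bad), "different trees")
})

test_that("through-origin correlation and regression match direct formulas", {
  expect_equal(correlation_through_origin(c(1, 2), c(2, 4))$r, 1)
  expect_equal(correlation_through_origin(c(1, 0), c(0, 1))$r, 0)
  co <- correlation_through_origin(c(1, 2, 3), c(1, 1, 1))
  expect_equal(co$r, 6 / sqrt(42), tolerance = 1e-6)
  expect_equal(co$df, 2L)
  expect_equal(co$t, co$r * sqrt(2 / (1 - co$r^2)), tolerance = 1e-12)

  expect_equal(regression_through_origin(c(1, 2), c(3, 6))$slope, 3)
  expect_equal(regression_through_origin(c(1, 0), c(0, 1))$slope, 0)
  rg <- regression_through_origin(c(1, 2, 3), c(2, 3, 5))
  expect_equal(rg$slope, 23 / 14, tolerance = 1e-10)
  expect_error(correlation_through_origin(c(0, 0), c(1, 2)), "zero norm")
  expect_error(regression_through_origin(c(0, 0), c(1, 2)), "zero")
})

test_that("on a resolved star tree, contrast correlation equals Pearson", {
  set.seed(7)
  n <- 12
  star <- ape::read.tree(
    text = paste0("(", paste(sprintf("t%d:1", 1:n), collapse = ","), ");"))
  star2 <- resolve_polytomies(star, seed = 3)
  x <- setNames(rnorm(n), star$tip.label)
  y <- setNames(0.6 * x + rnorm(n, 0, 0.5), star$tip.label)
  ps <- positivize(compute_contrasts(star2, x), compute_contrasts(star2, y))
  expect_equal(abs(correlation_through_origin(ps$x, ps$y)$r),
               abs(cor(x, y)), tolerance = 1e-10)
})
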