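small_spec <- function() {
  list(N_TF = 20, N_SF = 3, N_G = 150, n_edges = 320,
       proportions = c(activator = 0.35, repressor = 0.35, dual = 0.25,
                       unclassified = 0.05),
       nap_count = 3, zipf_exponent = 0.8, sigma_edge_fraction = 0.25)
}

small_scenario <- function(seed = 1L, ...) {
  reduction_scenario(n_genomes = 12, reference = small_spec(), seed = seed,
                     ...)
}

test_that("Yule trees are ultrametric and seeded", {
  tr <- simulate_tree(5, seed = 3)
  expect_equal(length(tr$tip.label), 5L)
  expect_equal(tr$Nnode, 4L)
  expect_identical(write_newick(simulate_tree(5, seed = 3)),
                   write_newick(tr))
  expect_false(identical(write_newick(simulate_tree(5, seed = 4)),
                         write_newick(tr)))
  cherry <- simulate_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2L)
  d <- ape::node.depth.edgelength(simulate_tree(64, seed = 5))
  expect_equal(diff(range(d[1:64])), 0, tolerance = 1e-10)  # ultrametric
})

test_that("the reference generator hits requested totals exactly", {
  ref <- simulate_reference_network(small_spec(), seed = 2)
  expect_equal(unname(network_summary(ref$network)[1:3]),
               c(20L, 3L, 150L))
  expect_equal(unname(network_summary(ref$network)[["n_edges"]]), 320L)
  expect_equal(nrow(ref$annotation), 20L)
  expect_equal(sum(ref$annotation$reg_type == "dual"), 5L)
  # dual hubs carry the NAP flags; the flagged set is non-empty
  expect_true(all(ref$annotation$reg_type[ref$annotation$is_nap] == "dual"))
  expect_gte(sum(ref$annotation$is_global), 1L)

  full <- list(N_TF = 196, N_SF = 7, N_G = 1581, n_edges = 4058,
               proportions = c(activator = 0.35, repressor = 0.37,
                               dual = 0.25, unclassified = 0.03),
               nap_count = 12, zipf_exponent = 0.8,
               sigma_edge_fraction = 0.25)
  fnet <- simulate_reference_network(full, seed = 1)$network
  # round-trip the full-scale template through the reader
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(fnet, f)
  back <- read_network(f)
  expect_equal(nrow(back$nodes), 1784L)
  expect_equal(nrow(back$edges), 4058L)
})

test_that("gene loss limits behave: no hazard, lethal hazard", {
  scn <- small_scenario()
  tree <- simulate_tree(8, seed = 6)
  ref <- simulate_reference_network(scn$reference, seed = 7)
  none <- simulate_gene_loss(tree, ref$network, ref$annotation,
                             hazards = c(activator = 0, repressor = 0,
                                         dual = 0, unclassified = 0,
                                         sigma = 0, tg = 0),
                             size_model = c(bp_per_gene = 1000,
                                            intercept = 0, noise_sd = 0),
                             seed = 8)
  expect_true(all(none$presence))
  expect_true(all(none$genomes$size_bp == 1000 * nrow(ref$network$nodes)))

  hot <- simulate_gene_loss(tree, ref$network, ref$annotation,
                            hazards = c(activator = 100, repressor = 0,
                                        dual = 0, unclassified = 0,
                                        sigma = 0, tg = 0),
                            seed = 9)
  acts <- ref$annotation$tf_id[ref$annotation$reg_type == "activator"]
  duals <- ref$annotation$tf_id[ref$annotation$reg_type == "dual"]
  expect_true(all(!hot$presence[acts, ]))
  expect_true(all(hot$presence[duals, ]))
  expect_setequal(unique(hot$genomes$category),
                  c("tiny", "obligate", "host_restricted", "free_living"))
})

test_that("homogeneous survival matches its closed form within MC error", {
  scn <- reduction_scenario()
  tree <- simulate_tree(64, seed = 11)
  D <- max(ape::node.depth.edgelength(tree))
  ref <- simulate_reference_network(scn$reference, seed = 12)
  cls <- ifelse(grepl("^TG", ref$network$nodes$id), "tg",
                ifelse(grepl("^SF", ref$network$nodes$id), "sigma", NA))
  type <- ref$annotation$reg_type[match(ref$network$nodes$id,
                                        ref$annotation$tf_id)]
  cls[is.na(cls)] <- type[is.na(cls)]
  per_type <- sapply(1:6, function(s) {
    loss <- simulate_gene_loss(tree, ref$network, ref$annotation,
                               scn$hazards, rate_sd = 0, seed = 100 + s)
    vapply(c("activator", "repressor", "dual", "tg"),
           function(cl) mean(loss$presence[cls == cl, ]), numeric(1))
  })
  expected <- exp(-scn$hazards[c("activator", "repressor", "dual", "tg")] * D)
  obs <- rowMeans(per_type)
  tol <- 3 * apply(per_type, 1, sd) / sqrt(ncol(per_type)) + 0.005
  expect_true(all(abs(obs - unname(expected)) <= tol))
})

test_that("gene content carries phylogenetic signal", {
  scn <- small_scenario()
  tree <- simulate_tree(32, seed = 21)
  ref <- simulate_reference_network(scn$reference, seed = 22)
  loss <- simulate_gene_loss(tree, ref$network, ref$annotation, scn$hazards,
                             rate_sd = scn$rate_sd, seed = 23)
  pd <- ape::cophenetic.phylo(tree)
  gd <- as.matrix(dist(t(loss$presence), method = "binary"))  # Jaccard
  lt <- lower.tri(pd)
  expect_gt(cor(pd[colnames(gd), colnames(gd)][lt], gd[lt]), 0.1)
})

test_that("Brownian traits follow the random-walk model", {
  tr <- simulate_tree(16, seed = 31)
  still <- simulate_brownian_trait(tr, rate = 1e-12, root_value = 5,
                                   seed = 32)
  expect_equal(unname(still), rep(5, 16), tolerance = 1e-4)
  cherry <- parse_newick("(A:1,B:1);")
  raws <- vapply(1:300, function(s)
    compute_contrasts(cherry, simulate_brownian_trait(cherry, 1, 0, s))$raw,
    numeric(1))
  expect_equal(var(raws), 2, tolerance = 0.5)
})

test_that("hit tables are faithful and decoys never change the map", {
  scn <- small_scenario()
  sim <- simulate_scenario(scn)
  for (g in names(sim$hits$tables)[1:4]) {
    om <- bidirectional_best_hits(sim$hits$tables[[g]]$forward,
                                  sim$hits$tables[[g]]$reverse,
                                  genome_id = g)
    expect_equal(nrow(om), sum(sim$presence[, g]))
    expect_setequal(om$ref_gene_id, rownames(sim$presence)[sim$presence[, g]])
  }
  # a table reduced to its decoy rows yields an empty map
  g <- names(sim$hits$tables)[1]
  fwd <- sim$hits$tables[[g]]$forward
  decoy_rows <- fwd[grepl("decoy", fwd$subject_id) |
                      !fwd$query_id %in% rownames(sim$presence)[sim$presence[, g]], ]
  om0 <- bidirectional_best_hits(decoy_rows, sim$hits$tables[[g]]$reverse)
  expect_equal(nrow(om0), 0L)
})

test_that("scenario simulation is deterministic in the seed", {
  a <- simulate_scenario(small_scenario(seed = 7))
  b <- simulate_scenario(small_scenario(seed = 7))
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$presence, b$presence)
  expect_identical(a$hits, b$hits)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  c2 <- simulate_scenario(small_scenario(seed = 8))
  expect_false(identical(a$genomes, c2$genomes))
})
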