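# Synthetic genome-reduction scenarios. The generator emulates every input
# the pipeline consumes: an ultrametric Yule phylogeny, a reference network
# with a few dual-typed hub regulators, irreversible gene loss along branches
# with per-type hazards and heritable lineage-specific intensity, genome
# sizes affine in surviving gene count, and reciprocal BLAST-tabular hit
# tables (with optional decoys) from which orthology is re-derived.

#' Default genome-reduction scenario
#'
#' The scenario's defaults define the study conditions used throughout the
#' package's validation: 64 genomes, per-type loss hazards ordered
#' `activator (0.8) > repressor (0.5) > dual (0.1)` with target genes at 0.3
#' (so dual regulators are the recoverable, preferentially conserved type),
#' sigma factors nearly immortal (0.05), and a reference network of 60 TFs,
#' 5 sigma factors and 400 target genes with 1000 interactions whose hubs
#' are preferentially dual and NAP-flagged. Lineage loss intensity evolves
#' as Brownian motion on the log scale (`rate_sd`), creating the wide,
#' phylogenetically clustered genome-size gradient that reduced genomes
#' display in nature.
#'
#' @param n_genomes number of leaves (reduced genomes).
#' @param birth_rate Yule birth rate of the simulated phylogeny.
#' @param reference list: `N_TF`, `N_SF`, `N_G`, `n_edges`, `proportions`
#'   (named, over activator/repressor/dual/unclassified, summing to 1),
#'   `nap_count`, `zipf_exponent`, `sigma_edge_fraction`.
#' @param hazards named loss hazards per unit branch length for `activator`,
#'   `repressor`, `dual`, `unclassified`, `sigma`, `tg`.
#' @param rate_sd standard deviation (per unit sqrt branch length) of the
#'   Brownian log loss-intensity; 0 gives homogeneous loss.
#' @param size_model named vector `bp_per_gene`, `intercept`, `noise_sd` for
#'   genome size in bp.
#' @param decoy_fraction fraction of decoy hits added per hit table.
#' @param global_quantile quantile above which reference TFs are flagged
#'   global regulators.
#' @param seed integer seed.
#' @return List of class `reduction_scenario`.
#' @export
reduction_scenario <- function(n_genomes = 64,
                               birth_rate = 1,
                               reference = list(
                                 N_TF = 60, N_SF = 5, N_G = 400,
                                 n_edges = 1000,
                                 proportions = c(activator = 0.35,
                                                 repressor = 0.37,
                                                 dual = 0.25,
                                                 unclassified = 0.03),
                                 nap_count = 6, zipf_exponent = 0.8,
                                 sigma_edge_fraction = 0.25),
                               hazards = c(activator = 0.8, repressor = 0.5,
                                           dual = 0.1, unclassified = 0.5,
                                           sigma = 0.05, tg = 0.3),
                               rate_sd = 0.75,
                               size_model = c(bp_per_gene = 1000,
                                              intercept = 0,
                                              noise_sd = 10000),
                               decoy_fraction = 0.1,
                               global_quantile = 0.9,
                               seed = 1L) {
  stopifnot(n_genomes >= 2, all(hazards >= 0),
            abs(sum(reference$proportions) - 1) < 1e-8)
  structure(list(n_genomes = n_genomes, birth_rate = birth_rate,
                 reference = reference, hazards = hazards, rate_sd = rate_sd,
                 size_model = size_model, decoy_fraction = decoy_fraction,
                 global_quantile = global_quantile, seed = as.integer(seed)),
            class = "reduction_scenario")
}

#' @export
print.reduction_scenario <- function(x, ...) {
  cat(sprintf("Genome-reduction scenario: %d genomes, seed %d\n",
              x$n_genomes, x$seed))
  cat(sprintf("  reference: %d TFs, %d sigma, %d TGs, %d edges\n",
              x$reference$N_TF, x$reference$N_SF, x$reference$N_G,
              x$reference$n_edges))
  cat("  hazards:", paste(sprintf("%s=%.2f", names(x$hazards), x$hazards),
                          collapse = " "), "\n")
  invisible(x)
}

#' Simulate an ultrametric Yule phylogeny
#'
#' Pure-birth tree with `n_leaves` extant tips, reproducible from the seed.
#' Branch lengths are in the same time units the loss hazards refer to.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return A `phylo` with leaf labels `g001, g002, ...`.
#' @export
simulate_tree <- function(n_leaves, birth_rate = 1, seed = 1L) {
  stopifnot(n_leaves >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_leaves, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("g%03d", seq_len(n_leaves))
  tree
}

largest_remainder <- function(weights, total) {
  # integer allocation of `total` proportional to `weights`, exact sum
  q <- weights / sum(weights) * total
  base <- floor(q)
  short <- total - sum(base)
  if (short > 0) {
    o <- order(q - base, decreasing = TRUE)
    base[o[seq_len(short)]] <- base[o[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Simulate a reference regulatory network and its TF annotation
#'
#' Builds a network with exactly the requested node and edge totals.
#' Out-degrees are Zipf-like (a few hubs, many small regulons); the largest
#' regulons are assigned to dual-typed TFs, and the top dual hubs are
#' NAP-flagged, so that duality, globality and NAP function co-occur as they
#' do in real reference networks. Sigma factors hold a fixed share of the
#' edges. Global-regulator flags come from the top decile of the globality
#' score computed on the finished network.
#'
#' @param spec the `reference` element of a [reduction_scenario()].
#' @param seed integer seed.
#' @param global_quantile passed to [rank_global_regulators()].
#' @return List with `network` (a [regulatory_network()]) and `annotation`
#'   (data.frame as in [read_tf_annotation()]).
#' @export
simulate_reference_network <- function(spec, seed = 1L,
                                       global_quantile = 0.9) {
  set.seed(seed)
  N_TF <- spec$N_TF; N_SF <- spec$N_SF; N_G <- spec$N_G; E <- spec$n_edges
  tf_ids <- sprintf("TF%04d", seq_len(N_TF))
  sf_ids <- sprintf("SF%02d", seq_len(N_SF))
  tg_ids <- sprintf("TG%05d", seq_len(N_G))
  # TF types: counts by largest remainder; dual TFs occupy the hub slots
  tcounts <- largest_remainder(spec$proportions, N_TF)
  names(tcounts) <- names(spec$proportions)
  rest <- sample(rep(c("activator", "repressor", "unclassified"),
                     tcounts[c("activator", "repressor", "unclassified")]))
  types <- c(rep("dual", tcounts[["dual"]]), rest)   # index 1 = biggest hub
  # edge allocation
  sigma_E <- round(spec$sigma_edge_fraction * E)
  sf_deg <- largest_remainder(rep(1, N_SF), sigma_E)
  tf_deg <- largest_remainder(seq_len(N_TF)^(-spec$zipf_exponent),
                              E - sigma_E)
  while (any(tf_deg == 0)) {            # every TF regulates something
    i <- which.max(tf_deg); j <- which(tf_deg == 0)[1]
    tf_deg[i] <- tf_deg[i] - 1L; tf_deg[j] <- 1L
  }
  sample_targets <- function(self, deg) {
    pool <- c(tg_ids, setdiff(tf_ids, self), sf_ids)
    w <- c(rep(1, length(tg_ids)),
           rep(0.15, length(setdiff(tf_ids, self))),
           rep(0.05, length(sf_ids)))
    sample(pool, min(deg, length(pool)), prob = w)
  }
  edge_list <- vector("list", N_TF + N_SF)
  for (i in seq_len(N_TF)) {
    tg <- sample_targets(tf_ids[i], tf_deg[i])
    eff <- switch(types[i],
                  activator = "activation", repressor = "repression",
                  dual = sample(c("activation", "repression", "dual"),
                                length(tg), replace = TRUE),
                  unclassified = "unknown")
    edge_list[[i]] <- data.frame(regulator_id = tf_ids[i], target_id = tg,
                                 effect = eff)
  }
  for (j in seq_len(N_SF)) {
    tg <- sample_targets(sf_ids[j], sf_deg[j])
    edge_list[[N_TF + j]] <- data.frame(regulator_id = sf_ids[j],
                                        target_id = tg,
                                        effect = "activation")
  }
  edges <- do.call(rbind, edge_list)
  nodes <- data.frame(id = c(tf_ids, sf_ids, tg_ids),
                      kind = c(rep("TF", N_TF), rep("SIGMA", N_SF),
                               rep("TG", N_G)))
  net <- regulatory_network(nodes, edges, name = "synthetic_reference")
  nap_count <- min(spec$nap_count, tcounts[["dual"]])
  annot <- data.frame(tf_id = tf_ids, reg_type = types,
                      is_nap = seq_len(N_TF) <= nap_count & types == "dual",
                      is_global = FALSE)
  glob <- rank_global_regulators(net, global_quantile)
  annot$is_global <- annot$tf_id %in% glob$tf_id[glob$is_global]
  list(network = net, annotation = annot)
}

gene_hazards <- function(network, annot, hazards) {
  kind <- network$nodes$kind
  lam <- numeric(nrow(network$nodes))
  lam[kind == "TG"] <- hazards[["tg"]]
  lam[kind == "SIGMA"] <- hazards[["sigma"]]
  tf <- kind == "TF"
  type <- annot$reg_type[match(network$nodes$id[tf], annot$tf_id)]
  type[is.na(type)] <- "unclassified"
  lam[tf] <- hazards[type]
  setNames(lam, network$nodes$id)
}

#' Simulate irreversible gene loss along a phylogeny
#'
#' Every gene is present at the root and is lost along each branch of length
#' `t` with probability `1 - exp(-lambda * t * m)`, where `lambda` is the
#' hazard of the gene's class and `m` the branch's loss-intensity multiplier;
#' once lost, a gene is absent in the whole subtree (ratchet-like loss, no
#' regain). With `rate_sd > 0` the log intensity evolves as Brownian motion
#' along the tree, so heavily reducing lineages cluster phylogenetically;
#' with `rate_sd = 0` loss is homogeneous and leaf survival of a class has
#' closed-form expectation `exp(-lambda * depth)`.
#'
#' Genome size is `intercept + bp_per_gene * surviving genes` plus Gaussian
#' noise, floored at 1 bp. Leaves are labeled `free_living`,
#' `host_restricted`, `obligate`, `tiny` by descending quartile of surviving
#' gene count.
#'
#' @param tree `phylo` from [simulate_tree()].
#' @param network reference [regulatory_network()].
#' @param annot TF annotation table.
#' @param hazards named hazard vector (see [reduction_scenario()]).
#' @param size_model named vector `bp_per_gene`, `intercept`, `noise_sd`.
#' @param rate_sd Brownian sd of the log loss intensity.
#' @param seed integer seed.
#' @return List with `presence` (logical matrix, genes x leaves), `genomes`
#'   (metadata data.frame with `n_genes`), `branch_rates` (per-edge
#'   multipliers).
#' @export
simulate_gene_loss <- function(tree, network, annot, hazards,
                               size_model = c(bp_per_gene = 1000,
                                              intercept = 0, noise_sd = 0),
                               rate_sd = 0, seed = 1L) {
  set.seed(seed)
  lam <- gene_hazards(network, annot, hazards)
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")   # parents before children
  nn <- ntip + tr$Nnode
  pres <- matrix(FALSE, nn, length(lam))
  root <- ntip + 1L
  pres[root, ] <- TRUE
  logm <- numeric(nn)
  edge_m <- numeric(nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
    logm[ch] <- logm[par] + stats::rnorm(1, 0, rate_sd * sqrt(t))
    m <- exp((logm[par] + logm[ch]) / 2)
    edge_m[e] <- m
    surv <- exp(-lam * t * m)
    alive <- pres[par, ]
    pres[ch, ] <- alive & (stats::runif(length(lam)) < surv)
  }
  presence <- t(pres[seq_len(ntip), , drop = FALSE])
  rownames(presence) <- names(lam)
  colnames(presence) <- tr$tip.label
  counts <- colSums(presence)
  size <- pmax(1, round(size_model[["intercept"]] +
                          size_model[["bp_per_gene"]] * counts +
                          stats::rnorm(ntip, 0, size_model[["noise_sd"]])))
  # quartiles of surviving gene count, assigned by rank so ties never break
  # the four-way split (smallest quartile = tiny, largest = free_living)
  qidx <- ceiling(4 * rank(counts, ties.method = "first") / ntip)
  category <- c("tiny", "obligate", "host_restricted",
                "free_living")[pmax(1L, qidx)]
  genomes <- data.frame(genome_id = colnames(presence),
                        size_bp = unname(size),
                        category = category,
                        n_genes = unname(counts))
  list(presence = presence, genomes = genomes, branch_rates = edge_m)
}

#' Simulate a Brownian-motion trait on a tree
#'
#' `child = parent + Normal(0, rate * branch_length)` from `root_value`
#' downward; the generative model under which independent contrasts are
#' exact.
#'
#' @param tree a `phylo`.
#' @param rate Brownian rate (variance per unit branch length).
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @return Named numeric vector over the leaves.
#' @export
simulate_brownian_trait <- function(tree, rate = 1, root_value = 0,
                                    seed = 1L) {
  stopifnot(rate >= 0)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")
  x <- numeric(ntip + tr$Nnode)
  x[ntip + 1L] <- root_value
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    x[ch] <- x[par] + stats::rnorm(1, 0, sqrt(rate * tr$edge.length[e]))
  }
  setNames(x[seq_len(ntip)], tr$tip.label)
}

#' Emit reciprocal BLAST-tabular hit tables from a presence matrix
#'
#' Every present gene gets a reciprocal forward/reverse hit pair that passes
#' the ortholog-acceptance thresholds (identity ~ U(35, 95), e-value
#' 10^-U(8, 50), coverage > 0.7). A configurable fraction of decoy hits is
#' added, each failing exactly one acceptance predicate (identity, e-value,
#' or coverage) or reciprocity; decoys never displace a genuine best hit.
#'
#' @param presence logical matrix, reference genes x genomes.
#' @param seed integer seed.
#' @param decoy_fraction decoys added per genome as a fraction of its
#'   present-gene count.
#' @param gene_lengths optional named protein lengths for the reference
#'   genes; drawn once (Normal(300, 60), min 80) if omitted.
#' @return List with `tables` (per genome: list `forward`, `reverse` of hit
#'   data.frames with lengths attached) and `lengths` (named vector covering
#'   all ids).
#' @export
emit_hit_tables <- function(presence, seed = 1L, decoy_fraction = 0,
                            gene_lengths = NULL) {
  set.seed(seed)
  genes <- rownames(presence)
  if (is.null(gene_lengths))
    gene_lengths <- setNames(pmax(80, round(stats::rnorm(length(genes),
                                                         300, 60))), genes)
  lengths_all <- gene_lengths
  make_row <- function(q, s, ident, ev, aln, L) {
    nr <- length(q)
    data.frame(query_id = q, subject_id = s, percent_identity = ident,
               alignment_length = aln,
               mismatches = round((1 - ident / 100) * aln),
               gap_opens = rep(0L, nr),
               qstart = rep(1L, nr), qend = aln, sstart = rep(1L, nr),
               send = aln, evalue = ev,
               bitscore = round(2 * aln * ident / 100, 1))
  }
  tables <- list()
  for (g in colnames(presence)) {
    present <- genes[presence[, g]]
    tgt <- paste0(g, "|", present)
    L <- unname(gene_lengths[present])
    np <- length(present)
    if (np) {
      ident <- stats::runif(np, 35, 95)
      ev <- 10^-stats::runif(np, 8, 50)
      aln <- ceiling(stats::runif(np, 0.75, 1) * L)
      fwd <- make_row(present, tgt, ident, ev, aln, L)
      rev <- make_row(tgt, present, ident, ev, aln, L)
    } else {
      fwd <- rev <- make_row(character(0), character(0), numeric(0),
                             numeric(0), integer(0), numeric(0))
    }
    if (np) lengths_all[tgt] <- L
    nd <- round(decoy_fraction * np)
    if (nd > 0) {
      modes <- rep(c("identity", "evalue", "coverage", "nonreciprocal"),
                   length.out = nd)
      true_ev <- setNames(ev, present)
      absent <- setdiff(genes, present)
      for (d in seq_len(nd)) {
        gi <- sample(present, 1)
        Ld <- unname(gene_lengths[gi])
        did <- paste0(g, "|decoy", d)
        lengths_all[did] <- Ld
        row <- switch(modes[d],
          identity = make_row(gi, did, stats::runif(1, 10, 29),
                              min(1e-7, true_ev[gi] * 100),
                              ceiling(0.8 * Ld), Ld),
          evalue = make_row(gi, did, stats::runif(1, 40, 90),
                            10^-stats::runif(1, 3, 5.9),
                            ceiling(0.8 * Ld), Ld),
          coverage = make_row(gi, did, stats::runif(1, 40, 90),
                              min(1e-7, true_ev[gi] * 100),
                              floor(0.4 * Ld), Ld),
          nonreciprocal = {
            if (length(absent)) {
              ga <- sample(absent, 1)
              La <- unname(gene_lengths[ga])
              # an absent gene's only (passing) hit lands on a taken target,
              # whose reverse best points elsewhere: reciprocity fails
              make_row(ga, sample(tgt, 1), stats::runif(1, 40, 90),
                       10^-stats::runif(1, 8, 20), ceiling(0.8 * La), La)
            } else NULL
          })
        if (!is.null(row)) fwd <- rbind(fwd, row)
      }
    }
    tables[[g]] <- list(forward = fwd, reverse = rev)
  }
  # attach lengths so tables are directly usable by the orthology module
  for (g in names(tables)) {
    tables[[g]]$forward <- attach_lengths(tables[[g]]$forward, lengths_all)
    tables[[g]]$reverse <- attach_lengths(tables[[g]]$reverse, lengths_all)
  }
  list(tables = tables, lengths = lengths_all)
}

#' Simulate a complete genome-reduction scenario
#'
#' Runs the full generator: phylogeny, reference network and annotation,
#' gene loss, genome metadata, and hit tables. Sub-seeds for the stages are
#' derived from the scenario seed, so identical seeds give identical output.
#'
#' @param scenario a [reduction_scenario()].
#' @return List of class `scenario_data` with `scenario`, `tree`, `network`,
#'   `annotation`, `presence`, `genomes`, `hits` (from [emit_hit_tables()]).
#' @export
simulate_scenario <- function(scenario = reduction_scenario()) {
  stopifnot(inherits(scenario, "reduction_scenario"))
  s <- scenario$seed
  tree <- simulate_tree(scenario$n_genomes, scenario$birth_rate, seed = s)
  ref <- simulate_reference_network(scenario$reference, seed = s + 1L,
                                    global_quantile = scenario$global_quantile)
  loss <- simulate_gene_loss(tree, ref$network, ref$annotation,
                             scenario$hazards, scenario$size_model,
                             rate_sd = scenario$rate_sd, seed = s + 2L)
  hits <- emit_hit_tables(loss$presence, seed = s + 3L,
                          decoy_fraction = scenario$decoy_fraction)
  structure(list(scenario = scenario, tree = tree, network = ref$network,
                 annotation = ref$annotation, presence = loss$presence,
                 genomes = loss$genomes, hits = hits),
            class = "scenario_data")
}

#' Write a simulated scenario to a directory of standard files
#'
#' Emits every dialect the pipeline reads: `network.tsv`, `annotation.tsv`,
#' `genomes.tsv`, `tree.nwk`, `lengths.tsv`, and per-genome
#' `hits/<genome>_fwd.tsv` / `hits/<genome>_rev.tsv` BLAST tabular files.
#'
#' @param sim a `scenario_data` from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(file.path(dir, "hits"), recursive = TRUE, showWarnings = FALSE)
  write_network(sim$network, file.path(dir, "network.tsv"))
  write_tf_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_genome_metadata(sim$genomes, file.path(dir, "genomes.tsv"))
  writeLines(write_newick(sim$tree), file.path(dir, "tree.nwk"))
  lt <- sim$hits$lengths
  writeLines(sprintf("%s\t%g", names(lt), lt), file.path(dir, "lengths.tsv"))
  fmt <- function(h) sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.6g\t%.1f",
                             h$query_id, h$subject_id, h$percent_identity,
                             as.integer(h$alignment_length), h$mismatches,
                             h$gap_opens, h$qstart, as.integer(h$qend),
                             h$sstart, as.integer(h$send), h$evalue,
                             h$bitscore)
  for (g in names(sim$hits$tables)) {
    writeLines(fmt(sim$hits$tables[[g]]$forward),
               file.path(dir, "hits", paste0(g, "_fwd.tsv")))
    writeLines(fmt(sim$hits$tables[[g]]$reverse),
               file.path(dir, "hits", paste0(g, "_rev.tsv")))
  }
  invisible(dir)
}
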