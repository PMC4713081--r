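# Orchestration: orthology -> reconstruction -> conservation statistics ->
# globality -> independent contrasts -> standardized regression, with a
# TSV report. The nine traits carried into the contrast analyses are genome
# size, the per-type conserved-TF counts, the per-type fractions, and the
# global-regulator and NAP fractions.

TRAIT_VARS <- c("size_bp", "freq_activator", "freq_repressor", "freq_dual",
                "frac_activator", "frac_repressor", "frac_dual",
                "frac_global", "frac_nap")
FRACTION_VARS <- c("frac_activator", "frac_repressor", "frac_dual",
                   "frac_global", "frac_nap")

#' Pipeline configuration
#'
#' Paths to the five standard inputs plus the thresholds and options every
#' stage uses. `hits_dir` must contain `<genome>_fwd.tsv` and
#' `<genome>_rev.tsv` BLAST tabular files for every genome in the metadata,
#' and a companion `lengths.tsv` is required for the coverage criterion.
#'
#' @param network,annotation,genomes,tree,lengths,hits_dir input paths.
#' @param out_dir report directory.
#' @param evalue_max,identity_min,coverage_min ortholog thresholds (see
#'   [bbh_thresholds()]).
#' @param alpha significance level.
#' @param global_quantile globality cutoff (see
#'   [rank_global_regulators()]).
#' @param positivize positivize X contrasts before through-origin statistics.
#' @param regression_mode `"raw"` (per-genome variables with intercept) or
#'   `"contrasts"` (through-origin on contrasts).
#' @param seed integer seed (polytomy resolution).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(network, annotation, genomes, tree, lengths,
                            hits_dir, out_dir = "report",
                            evalue_max = 1e-6, identity_min = 30,
                            coverage_min = 0.6, alpha = 0.05,
                            global_quantile = 0.9, positivize = TRUE,
                            regression_mode = c("raw", "contrasts"),
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(network = network, annotation = annotation,
                 genomes = genomes, tree = tree, lengths = lengths,
                 hits_dir = hits_dir, out_dir = out_dir,
                 evalue_max = evalue_max, identity_min = identity_min,
                 coverage_min = coverage_min, alpha = alpha,
                 global_quantile = global_quantile,
                 positivize = isTRUE(as.logical(positivize)),
                 regression_mode = match.arg(regression_mode),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a flat key = value pipeline configuration file
#'
#' @param path config file path; lines are `key = value`, `#` comments
#'   allowed. Keys match the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- vapply(kv, `[[`, character(1), 3)
  args <- as.list(vals)
  names(args) <- keys
  num <- intersect(keys, c("evalue_max", "identity_min", "coverage_min",
                           "alpha", "global_quantile", "seed"))
  args[num] <- lapply(args[num], as.numeric)
  if ("positivize" %in% keys)
    args$positivize <- as.logical(args$positivize)
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param dir scenario directory holding the standard file names (as written
#'   by [write_scenario()]); a convenience for `config --init`.
#' @export
write_default_config <- function(path, dir = ".") {
  writeLines(c(
    "# regulogr pipeline configuration",
    paste0("network = ", file.path(dir, "network.tsv")),
    paste0("annotation = ", file.path(dir, "annotation.tsv")),
    paste0("genomes = ", file.path(dir, "genomes.tsv")),
    paste0("tree = ", file.path(dir, "tree.nwk")),
    paste0("lengths = ", file.path(dir, "lengths.tsv")),
    paste0("hits_dir = ", file.path(dir, "hits")),
    paste0("out_dir = ", file.path(dir, "report")),
    "evalue_max = 1e-6", "identity_min = 30", "coverage_min = 0.6",
    "alpha = 0.05", "global_quantile = 0.9", "positivize = TRUE",
    "regression_mode = raw", "seed = 1"), path)
  invisible(path)
}

#' Full conservation analysis from in-memory inputs
#'
#' The analytical core shared by [run_reduction_study()] and
#' [run_full_analysis()]: takes the reference network, TF annotation, genome
#' metadata, phylogeny and per-genome ortholog maps, and produces type
#' counts, per-genome conservation tests, Fisher-combined per-type p-values,
#' the globality ranking, the nine contrast analyses against genome size,
#' and the three standardized multivariate regressions.
#'
#' Genomes conserving no TFs are reported as untestable: they are dropped
#' from the Fisher combination, from the fraction-trait contrast analyses
#' (the tree is pruned accordingly) and from the regressions; count traits
#' use all genomes.
#'
#' @param network reference [regulatory_network()].
#' @param annotation TF annotation data.frame.
#' @param genomes metadata data.frame (`genome_id`, `size_bp`, `category`).
#' @param tree rooted `phylo` whose tips are the genome ids.
#' @param omaps named list of ortholog maps, one per genome.
#' @param alpha significance level.
#' @param global_quantile globality cutoff.
#' @param positivize positivize contrasts before through-origin statistics.
#' @param regression_mode `"raw"` or `"contrasts"`.
#' @param seed seed for polytomy resolution.
#' @return A `reduction_study` object; see its print method for an overview.
#' @export
analyze_study <- function(network, annotation, genomes, tree, omaps,
                          alpha = 0.05, global_quantile = 0.9,
                          positivize = TRUE,
                          regression_mode = c("raw", "contrasts"),
                          seed = 1L) {
  regression_mode <- match.arg(regression_mode)
  tree <- resolve_polytomies(tree, seed = seed)
  miss <- setdiff(genomes$genome_id, tree$tip.label)
  if (length(miss))
    stop("genome(s) missing from tree: ", paste(head(miss, 5), collapse = ", "))
  ref_counts <- reference_type_counts(annotation)
  glob <- rank_global_regulators(network, global_quantile)
  global_ids <- glob$tf_id[glob$is_global]
  nap_ids <- annotation$tf_id[annotation$is_nap]
  tf_ids <- network$nodes$id[network$nodes$kind == "TF"]

  counts_list <- list(); tests_list <- list(); traits_list <- list()
  for (g in genomes$genome_id) {
    om <- omaps[[g]]
    if (is.null(om)) stop("no ortholog map for genome ", g)
    tc <- count_conserved_tf_types(om, annotation, network)
    tc$genome_id <- g
    counts_list[[g]] <- tc
    for (ty in c("activator", "repressor", "dual"))
      tests_list[[paste(g, ty)]] <- conservation_test(ref_counts, tc, ty,
                                                      alpha)
    conserved_tfs <- intersect(om$ref_gene_id, tf_ids)
    tr <- data.frame(genome_id = g,
                     size_bp = genomes$size_bp[genomes$genome_id == g],
                     n = tc$n,
                     freq_activator = tc$k_activators,
                     freq_repressor = tc$k_repressors,
                     freq_dual = tc$k_duals)
    if (tc$n > 0) {
      f <- tf_fractions(tc)
      tr$frac_activator <- f[["f_act"]]
      tr$frac_repressor <- f[["f_rep"]]
      tr$frac_dual <- f[["f_dual"]]
      tr$frac_global <- length(intersect(conserved_tfs, global_ids)) / tc$n
      tr$frac_nap <- length(intersect(conserved_tfs, nap_ids)) / tc$n
    } else {
      tr[FRACTION_VARS] <- NA_real_
    }
    traits_list[[g]] <- tr
  }
  type_counts <- do.call(rbind, counts_list)
  tests <- do.call(rbind, tests_list)
  traits <- do.call(rbind, traits_list)
  rownames(type_counts) <- rownames(tests) <- rownames(traits) <- NULL
  untestable <- traits$genome_id[traits$n == 0]

  combined <- lapply(c(activator = "activator", repressor = "repressor",
                       dual = "dual"), function(ty) {
    fisher_combine(tests$p_value[tests$tf_type == ty &
                                   tests$status == "tested"])
  })

  contrast_stats <- contrast_analyses(tree, traits, positivize)
  regressions <- type_regressions(traits, regression_mode, tree, positivize)
  redundancy <- tryCatch(
    predictor_redundancy(traits$frac_global[traits$n > 0],
                         traits$frac_nap[traits$n > 0]),
    error = function(e) list(r = NA_real_, redundant = NA))

  structure(list(type_counts = type_counts, tests = tests,
                 combined = combined, globality = glob, traits = traits,
                 contrast_stats = contrast_stats, regressions = regressions,
                 redundancy = redundancy, untestable = untestable,
                 alpha = alpha, tree = tree),
            class = "reduction_study")
}

trait_contrasts <- function(tree, traits, var) {
  ok <- !is.na(traits[[var]])
  ids <- traits$genome_id[ok]
  if (length(ids) < 3) return(NULL)
  tr <- if (length(ids) < length(tree$tip.label))
    ape::keep.tip(tree, ids) else tree
  x <- setNames(traits$size_bp[ok], traits$genome_id[ok])
  y <- setNames(traits[[var]][ok], traits$genome_id[ok])
  list(x = compute_contrasts(tr, x, trait_name = "size_bp"),
       y = compute_contrasts(tr, y, trait_name = var))
}

contrast_analyses <- function(tree, traits, positivize_x = TRUE) {
  rows <- list()
  for (var in TRAIT_VARS) {
    cs <- trait_contrasts(tree, traits, var)
    if (is.null(cs)) next
    if (positivize_x) cs <- positivize(cs$x, cs$y)
    res <- tryCatch({
      co <- correlation_through_origin(cs$x, cs$y)
      rg <- regression_through_origin(cs$x, cs$y)
      data.frame(variable = var, n_contrasts = co$n, r = co$r, t = co$t,
                 df = co$df, p_value = co$p_value, slope = rg$slope)
    }, error = function(e)
      data.frame(variable = var, n_contrasts = attr(cs$x, "n_contrasts"),
                 r = NA_real_, t = NA_real_, df = NA_integer_,
                 p_value = NA_real_, slope = NA_real_))
    rows[[var]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

type_regressions <- function(traits, mode, tree, positivize_x = TRUE) {
  ok <- traits$n > 0
  out <- list()
  for (ty in c("activator", "repressor", "dual")) {
    yvar <- paste0("frac_", ty)
    if (mode == "raw") {
      Y <- traits[[yvar]][ok]
      X <- cbind(genome_size = traits$size_bp[ok],
                 global_regulators = traits$frac_global[ok],
                 nap_function = traits$frac_nap[ok])
      out[[ty]] <- tryCatch(fit_multivariate(Y, X),
                            error = function(e) NULL)
    } else {
      # origin-constrained fit on contrasts of Y against the 3 predictors
      sub <- traits[ok, , drop = FALSE]
      tr <- if (sum(ok) < length(tree$tip.label))
        ape::keep.tip(tree, sub$genome_id) else tree
      getc <- function(v) compute_contrasts(
        tr, setNames(sub[[v]], sub$genome_id), trait_name = v)$standardized
      Y <- getc(yvar)
      X <- cbind(genome_size = getc("size_bp"),
                 global_regulators = getc("frac_global"),
                 nap_function = getc("frac_nap"))
      out[[ty]] <- tryCatch(fit_multivariate(Y, X),
                            error = function(e) NULL)
    }
  }
  out
}

#' @export
print.reduction_study <- function(x, ...) {
  cat("Genome-reduction conservation study\n")
  cat(sprintf("  %d genomes (%d untestable: no conserved TFs)\n",
              nrow(x$traits), length(x$untestable)))
  cat("  Fisher-combined conservation p-values:\n")
  for (ty in names(x$combined))
    cat(sprintf("    %-10s p = %.3g\n", ty, x$combined[[ty]]$p_value))
  cat("  Through-origin contrast correlations with genome size:\n")
  cs <- x$contrast_stats
  for (i in seq_len(nrow(cs)))
    cat(sprintf("    %-15s r = %+.3f (p = %.3g)\n", cs$variable[i], cs$r[i],
                cs$p_value[i]))
  invisible(x)
}

#' Simulate a scenario and analyze it end to end
#'
#' Generates a complete synthetic scenario, derives ortholog maps from its
#' hit tables by bidirectional best hits, and runs the full conservation
#' analysis.
#'
#' @param scenario a [reduction_scenario()].
#' @param seed overrides the scenario seed when given.
#' @return A `reduction_study` with the `scenario_data` attached as
#'   attribute `"sim"`.
#' @export
run_reduction_study <- function(scenario = reduction_scenario(),
                                seed = NULL) {
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  sim <- simulate_scenario(scenario)
  th <- bbh_thresholds()
  omaps <- lapply(setNames(nm = names(sim$hits$tables)), function(g)
    bidirectional_best_hits(sim$hits$tables[[g]]$forward,
                            sim$hits$tables[[g]]$reverse, th, genome_id = g))
  study <- analyze_study(sim$network, sim$annotation, sim$genomes, sim$tree,
                         omaps, global_quantile = scenario$global_quantile,
                         seed = scenario$seed)
  attr(study, "sim") <- sim
  study
}

#' Run the full analysis from files and write a report directory
#'
#' Executes orthology, reconstruction, conservation statistics, globality,
#' independent contrasts and regression from the files named in the
#' configuration, writing per-stage TSVs plus a human-readable
#' `summary.txt`. A stage failure writes a `FAILED` marker naming the stage
#' and re-raises the error; earlier outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return The `reduction_study`, invisibly; report files under
#'   `config$out_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$network, config$annotation, config$genomes, config$tree,
              config$lengths))
    if (!file.exists(f)) stop("input file not found: ", f)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste0("stage: ", name), conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- stage("read_inputs", {
    list(network = read_network(config$network),
         annotation = read_tf_annotation(config$annotation),
         genomes = read_genome_metadata(config$genomes),
         tree = parse_newick(paste(readLines(config$tree), collapse = "")),
         lengths = read_length_table(config$lengths))
  })
  th <- bbh_thresholds(config$evalue_max, config$identity_min,
                       config$coverage_min)
  omaps <- stage("orthology", {
    lapply(setNames(nm = inputs$genomes$genome_id), function(g) {
      fwd <- read_hit_table(file.path(config$hits_dir, paste0(g, "_fwd.tsv")),
                            inputs$lengths)
      rev <- read_hit_table(file.path(config$hits_dir, paste0(g, "_rev.tsv")),
                            inputs$lengths)
      bidirectional_best_hits(fwd, rev, th, genome_id = g)
    })
  })
  study <- stage("analysis", {
    analyze_study(inputs$network, inputs$annotation, inputs$genomes,
                  inputs$tree, omaps, alpha = config$alpha,
                  global_quantile = config$global_quantile,
                  positivize = config$positivize,
                  regression_mode = config$regression_mode,
                  seed = config$seed)
  })
  stage("report", write_report(study, config$out_dir, config, omaps,
                               inputs$network))
  invisible(study)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA,
                                                sprintf("%.10g", x)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

write_report <- function(study, out_dir, config = NULL, omaps = NULL,
                         network = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(study$type_counts, file.path(out_dir, "type_counts.tsv"))
  write_tsv(study$tests, file.path(out_dir, "conservation_tests.tsv"))
  comb <- do.call(rbind, lapply(names(study$combined), function(ty) {
    f <- study$combined[[ty]]
    data.frame(tf_type = ty, statistic = f$statistic,
               degrees_of_freedom = f$degrees_of_freedom,
               combined_p = f$p_value, n_tests = f$n_tests)
  }))
  write_tsv(comb, file.path(out_dir, "fisher_combined.tsv"))
  write_tsv(study$globality, file.path(out_dir, "globality.tsv"))
  write_tsv(study$traits, file.path(out_dir, "traits.tsv"))
  write_tsv(study$contrast_stats, file.path(out_dir, "contrast_stats.tsv"))
  reg <- do.call(rbind, lapply(names(study$regressions), function(ty) {
    r <- study$regressions[[ty]]
    if (is.null(r)) return(NULL)
    data.frame(criterion = paste0("frac_", ty), predictor = r$predictors,
               b = unname(r$standardized_b),
               beta = unname(r$coefficients[r$predictors]),
               p_value = unname(r$p_values[r$predictors]))
  }))
  if (!is.null(reg)) write_tsv(reg, file.path(out_dir, "regression.tsv"))
  if (!is.null(omaps) && !is.null(network)) {
    dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
    for (g in names(omaps))
      write_network(reconstruct_trn(network, omaps[[g]]),
                    file.path(out_dir, "networks", paste0(g, ".tsv")))
  }
  lines <- c("regulogr analysis summary", "",
             sprintf("genomes analyzed: %d", nrow(study$traits)),
             sprintf("untestable (no conserved TFs): %s",
                     if (length(study$untestable))
                       paste(study$untestable, collapse = ", ") else "none"),
             "",
             "Fisher-combined conservation p-values:",
             vapply(names(study$combined), function(ty)
               sprintf("  %-10s X = %.4f  df = %d  p = %.6g", ty,
                       study$combined[[ty]]$statistic,
                       study$combined[[ty]]$degrees_of_freedom,
                       study$combined[[ty]]$p_value), character(1)),
             "",
             "Through-origin contrast statistics vs genome size:",
             vapply(seq_len(nrow(study$contrast_stats)), function(i)
               sprintf("  %-15s n = %3d  r = %+.4f  p = %.6g",
                       study$contrast_stats$variable[i],
                       study$contrast_stats$n_contrasts[i],
                       study$contrast_stats$r[i],
                       study$contrast_stats$p_value[i]), character(1)),
             "",
             sprintf("global/NAP predictor redundancy: r = %.4f%s",
                     study$redundancy$r,
                     if (isTRUE(study$redundancy$redundant))
                       " (redundant)" else ""))
  if (!is.null(config))
    lines <- c(lines, "",
               "thresholds applied:",
               sprintf("  evalue < %g, identity > %g, coverage > %g, alpha = %g",
                       config$evalue_max, config$identity_min,
                       config$coverage_min, config$alpha))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
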