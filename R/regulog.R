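# Regulog reconstruction: a regulatory interaction of the reference network
# is transferred to a target genome when both the regulator and the target
# have orthologs there. The assumptions inherited from the approach (TFs keep
# their regulatory type; conserved sequences imply conserved interactions)
# are not improved upon here.

#' Reconstruct a target genome's TRN from the reference and an ortholog map
#'
#' Edge `(r', t')` is present in the reconstruction iff edge `(r, t)` exists
#' in the reference and both `r` and `t` have ortholog pairs. Node kinds and
#' edge effects are inherited from the reference. Orthologous nodes whose
#' every reference interaction involves a lost partner are retained as
#' isolated nodes.
#'
#' @param reference the reference [regulatory_network()].
#' @param omap an ortholog map from [bidirectional_best_hits()].
#' @return A [regulatory_network()] over target-genome gene ids.
#' @export
reconstruct_trn <- function(reference, omap) {
  stopifnot(inherits(reference, "regulatory_network"))
  map <- setNames(omap$target_gene_id, omap$ref_gene_id)
  keep <- reference$nodes$id %in% names(map)
  nodes <- data.frame(id = unname(map[reference$nodes$id[keep]]),
                      kind = reference$nodes$kind[keep])
  e <- reference$edges
  keep_e <- e$regulator_id %in% names(map) & e$target_id %in% names(map)
  edges <- data.frame(regulator_id = unname(map[e$regulator_id[keep_e]]),
                      target_id = unname(map[e$target_id[keep_e]]),
                      effect = e$effect[keep_e])
  gid <- attr(omap, "genome_id")
  regulatory_network(nodes, edges,
                     name = if (is.na(gid)) "reconstruction" else gid)
}

#' Tabulate conserved TFs by regulatory type
#'
#' `n` counts every reference TF with an ortholog in the genome, including
#' unclassified ones; `k_<type>` counts the conserved TFs annotated with that
#' net regulatory type. Sigma factors are never counted.
#'
#' @param omap ortholog map for one genome.
#' @param annot TF annotation data.frame (see [read_tf_annotation()]).
#' @param network optional reference [regulatory_network()]; when given, TF
#'   identity comes from the network's node kinds (TFs absent from `annot`
#'   are counted in `n` only, with a warning), otherwise from `annot`.
#' @return A `type_counts` object: one-row data.frame with `genome_id`, `n`,
#'   `k_activators`, `k_repressors`, `k_duals`, `k_unclassified`.
#' @export
count_conserved_tf_types <- function(omap, annot, network = NULL) {
  tf_ids <- if (is.null(network)) annot$tf_id else
    network$nodes$id[network$nodes$kind == "TF"]
  conserved <- intersect(omap$ref_gene_id, tf_ids)
  unknown <- setdiff(conserved, annot$tf_id)
  if (length(unknown))
    warning("conserved TF(s) missing from annotation, counted in n only: ",
            paste(head(unknown, 5), collapse = ", "))
  type <- annot$reg_type[match(conserved, annot$tf_id)]
  out <- data.frame(genome_id = attr(omap, "genome_id"),
                    n = length(conserved),
                    k_activators = sum(type == "activator", na.rm = TRUE),
                    k_repressors = sum(type == "repressor", na.rm = TRUE),
                    k_duals = sum(type == "dual", na.rm = TRUE),
                    k_unclassified = sum(is.na(type) |
                                           type == "unclassified"))
  class(out) <- c("type_counts", "data.frame")
  out
}

#' Relative genome fraction of each TF type
#'
#' Fractions use the conserved-TF count `n` (all conserved TFs, classified or
#' not) as denominator, matching the hypergeometric sampling model of the
#' conservation tests.
#'
#' @param tc a `type_counts` row from [count_conserved_tf_types()].
#' @return Named numeric vector `(f_act, f_rep, f_dual)`, each in `[0, 1]`.
#' @export
tf_fractions <- function(tc) {
  if (tc$n == 0)
    stop("undefined fractions: genome '", tc$genome_id,
         "' conserves no TFs (n = 0)")
  c(f_act = tc$k_activators / tc$n, f_rep = tc$k_repressors / tc$n,
    f_dual = tc$k_duals / tc$n)
}
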