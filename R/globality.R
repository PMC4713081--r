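# Global-regulator metric. For a TF x in a network with N_TF transcription
# factors, N_SF sigma factors and N_G non-regulatory genes:
#
#   G(x) = 1/4 * ( TFR(x)/(N_TF + N_SF - 1) + GR(x)/N_G
#                  + SF(x)/N_SF + CR(x)/(N_TF - 1) )
#
# where TFR(x) is the number of regulators (TFs or sigma factors) regulated
# by x, GR(x) the number of non-regulatory genes regulated by x, SF(x) the
# number of sigma factors sharing at least one of x's targets, and CR(x) the
# number of other TFs sharing at least one of x's targets. Each term is a
# fraction of its own maximum, so G lies in [0, 1]; auto-regulation is
# excluded (hence the "-1" denominators).

#' Connectivity components of the globality metric for one TF
#'
#' @param net a [regulatory_network()].
#' @param tf_id id of a TF node.
#' @return Named integer vector `(TFR, GR, SF, CR)`.
#' @export
tf_regulatory_stats <- function(net, tf_id) {
  kind <- setNames(net$nodes$kind, net$nodes$id)
  if (is.na(kind[tf_id]))
    stop("unknown node id: ", tf_id)
  if (kind[tf_id] != "TF")
    stop("node '", tf_id, "' is not a TF (kind ", kind[tf_id], ")")
  e <- net$edges
  targets <- unique(e$target_id[e$regulator_id == tf_id])
  targets <- setdiff(targets, tf_id)           # no auto-regulation
  tk <- kind[targets]
  co_reg <- unique(e$regulator_id[e$target_id %in% targets])
  co_reg <- setdiff(co_reg, tf_id)
  c(TFR = sum(tk %in% c("TF", "SIGMA")),
    GR = sum(tk == "TG"),
    SF = sum(kind[co_reg] == "SIGMA"),
    CR = sum(kind[co_reg] == "TF"))
}

#' Globality score from connectivity components
#'
#' @param stats named vector `(TFR, GR, SF, CR)` from
#'   [tf_regulatory_stats()].
#' @param summary named vector with `N_TF`, `N_SF`, `N_G` (e.g. from
#'   [network_summary()]).
#' @return `G` in `[0, 1]`. A non-positive denominator (degenerate network)
#'   makes the corresponding term contribute 0, with a warning.
#' @export
#' @examples
#' net <- example_global_regulator_network()
#' globality_score(tf_regulatory_stats(net, "TF_G"), network_summary(net))
globality_score <- function(stats, summary) {
  den <- c(summary[["N_TF"]] + summary[["N_SF"]] - 1, summary[["N_G"]],
           summary[["N_SF"]], summary[["N_TF"]] - 1)
  num <- as.numeric(stats[c("TFR", "GR", "SF", "CR")])
  bad <- den <= 0
  if (any(bad)) {
    warning("degenerate network: non-positive denominator for term(s) ",
            paste(c("TFR", "GR", "SF", "CR")[bad], collapse = ", "),
            "; contributing 0")
    den[bad] <- 1
    num[bad] <- 0
  }
  sum(num / den) / 4
}

#' Rank the regulators of a network by globality
#'
#' Computes `G` for every TF, ranks descending (ties broken by id), and flags
#' the top decile as global regulators. The decile cutoff is operational: the
#' flag can also come straight from annotation when a curated list exists.
#'
#' @param net a [regulatory_network()].
#' @param global_quantile fraction of top-ranked TFs flagged as global
#'   regulators is `1 - global_quantile` (default: top decile).
#' @return data.frame `tf_id, TFR, GR, SF, CR, G, rank, is_global` ordered by
#'   decreasing `G`.
#' @export
rank_global_regulators <- function(net, global_quantile = 0.9) {
  s <- network_summary(net)
  tfs <- net$nodes$id[net$nodes$kind == "TF"]
  if (!length(tfs))
    return(data.frame(tf_id = character(0), TFR = integer(0), GR = integer(0),
                      SF = integer(0), CR = integer(0), G = numeric(0),
                      rank = integer(0), is_global = logical(0)))
  st <- t(vapply(tfs, function(id) tf_regulatory_stats(net, id),
                 c(TFR = 0L, GR = 0L, SF = 0L, CR = 0L)))
  G <- apply(st, 1, globality_score, summary = s)
  out <- data.frame(tf_id = tfs, st, G = G)
  out <- out[order(-out$G, out$tf_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  n_top <- max(1L, ceiling((1 - global_quantile) * nrow(out)))
  out$is_global <- out$rank <= n_top
  rownames(out) <- NULL
  out
}

#' Worked-example network for the globality metric
#'
#' A small network of 17 nodes and 26 interactions built around one hub
#' regulator `TF_G`: 4 TFs, 2 sigma factors and 11 target genes. `TF_G`
#' regulates 10 target genes and 2 TFs; 2 sigma factors and 3 other TFs share
#' targets with it, so its components are `(TFR, GR, SF, CR) = (2, 10, 2, 3)`
#' and its globality score is `0.82727...`.
#'
#' @return A [regulatory_network()].
#' @export
example_global_regulator_network <- function() {
  act <- function(r, t) data.frame(regulator_id = r, target_id = t,
                                   effect = "activation")
  edges <- rbind(
    act("TF_G", c(sprintf("TG_%d", 1:10), "TF_1", "TF_2")),  # regulon of TF_G
    act("SF_1", c("TG_3", "TG_4", "TG_7")),
    act("SF_2", c("TG_9", "TG_10", "TF_2")),
    act("TF_1", c("TG_1", "TG_4")),
    act("TF_2", c("TG_5", "TG_6")),
    act("TF_3", c("TG_8", "TG_9")),
    act("SF_1", "TG_11"),
    act("SF_2", "TG_11"))
  nodes <- data.frame(
    id = c("TF_G", "TF_1", "TF_2", "TF_3", "SF_1", "SF_2",
           sprintf("TG_%d", 1:11)),
    kind = c(rep("TF", 4), rep("SIGMA", 2), rep("TG", 11)))
  regulatory_network(nodes, edges, name = "global_regulator_example")
}
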