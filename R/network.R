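# Node and edge vocabularies are closed sets: regulators are transcription
# factors or sigma factors; everything regulated but never regulating is a
# target gene (TG).
NODE_KINDS <- c("TF", "SIGMA", "TG")
EDGE_EFFECTS <- c("activation", "repression", "dual", "unknown")

#' Construct a transcriptional regulatory network
#'
#' A `regulatory_network` is a directed, typed graph: nodes are transcription
#' factors (`TF`), sigma factors (`SIGMA`) or non-regulatory target genes
#' (`TG`); edges run from a regulator (TF or sigma) to a target and carry the
#' effect of the regulation. The node set is partitioned by kind, so the
#' counts `N_TF`, `N_SF`, `N_G` used by the globality metric always sum to
#' the node count. Duplicate edges collapse to one: the network is a set, not
#' a multigraph.
#'
#' @param nodes data.frame with columns `id` (character, unique) and `kind`
#'   (one of `"TF"`, `"SIGMA"`, `"TG"`).
#' @param edges data.frame with columns `regulator_id`, `target_id` and
#'   `effect` (one of `"activation"`, `"repression"`, `"dual"`, `"unknown"`).
#'   Every endpoint must appear in `nodes` and every regulator must be a TF
#'   or sigma factor.
#' @param name character scalar naming the network.
#' @return An object of class `regulatory_network`: a list with canonical
#'   (sorted) `nodes` and `edges` data.frames and a `name`.
#' @seealso [read_network()], [write_network()], [network_summary()]
#' @export
#' @examples
#' net <- regulatory_network(
#'   nodes = data.frame(id = c("tfA", "g1"), kind = c("TF", "TG")),
#'   edges = data.frame(regulator_id = "tfA", target_id = "g1",
#'                      effect = "activation"))
#' network_summary(net)
regulatory_network <- function(nodes = NULL, edges = NULL, name = "network") {
  if (is.null(nodes))
    nodes <- data.frame(id = character(), kind = character())
  if (is.null(edges))
    edges <- data.frame(regulator_id = character(), target_id = character(),
                        effect = character())
  nodes <- data.frame(id = as.character(nodes$id),
                      kind = as.character(nodes$kind),
                      stringsAsFactors = FALSE)
  edges <- data.frame(regulator_id = as.character(edges$regulator_id),
                      target_id = as.character(edges$target_id),
                      effect = as.character(edges$effect),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad <- setdiff(nodes$kind, NODE_KINDS)
  if (length(bad))
    stop("unknown node kind(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(edges$effect, EDGE_EFFECTS)
  if (length(bad))
    stop("unknown edge effect(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(union(edges$regulator_id, edges$target_id), nodes$id)
  if (length(missing))
    stop("edge endpoint(s) not in node table: ",
         paste(head(missing, 5), collapse = ", "))
  kind <- setNames(nodes$kind, nodes$id)
  notreg <- unique(edges$regulator_id[kind[edges$regulator_id] == "TG"])
  if (length(notreg))
    stop("node(s) of kind TG appear as regulators: ",
         paste(head(notreg, 5), collapse = ", "))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$regulator_id, edges$target_id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, name = as.character(name)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("Regulatory network '%s'\n", x$name))
  cat(sprintf("  %d nodes (%d TFs, %d sigma factors, %d target genes)\n",
              nrow(x$nodes), s[["N_TF"]], s[["N_SF"]], s[["N_G"]]))
  cat(sprintf("  %d interactions\n", s[["n_edges"]]))
  invisible(x)
}

#' @export
summary.regulatory_network <- function(object, ...) {
  s <- network_summary(object)
  eff <- table(factor(object$edges$effect, levels = EDGE_EFFECTS))
  out <- list(name = object$name, counts = s, effects = eff)
  class(out) <- "summary.regulatory_network"
  out
}

#' @export
print.summary.regulatory_network <- function(x, ...) {
  cat(sprintf("Network '%s': N_TF=%d N_SF=%d N_G=%d edges=%d\n", x$name,
              x$counts[["N_TF"]], x$counts[["N_SF"]], x$counts[["N_G"]],
              x$counts[["n_edges"]]))
  cat("Edge effects:\n")
  print(x$effects)
  invisible(x)
}

#' Node-kind and edge counts of a network
#'
#' @param net a [regulatory_network()].
#' @return Named integer vector `(N_TF, N_SF, N_G, n_edges)`; the first three
#'   partition the node set.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  k <- net$nodes$kind
  c(N_TF = sum(k == "TF"), N_SF = sum(k == "SIGMA"), N_G = sum(k == "TG"),
    n_edges = nrow(net$edges))
}

node_kind <- function(net, ids) {
  setNames(net$nodes$kind, net$nodes$id)[ids]
}

#' Read a regulatory network from its tab-separated edge list
#'
#' The dialect is a UTF-8 TSV with header
#' `regulator_id  target_id  effect  regulator_kind` and `#` comment lines.
#' Node kinds are inferred: an id seen as a regulator keeps its declared kind
#' (`TF` or `SIGMA`); ids seen only as targets become target genes. A row
#' with an empty `target_id` declares an isolated node whose kind is carried
#' in `regulator_kind` (this is how networks with ortholog-only, edge-less
#' nodes round-trip).
#'
#' @param path file path.
#' @param name network name; defaults to the file name.
#' @return A [regulatory_network()].
#' @export
read_network <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(regulatory_network(name = name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  if (!identical(hdr[1:2], c("regulator_id", "target_id")))
    stop("line ", lineno[1], ": expected header starting with ",
         "'regulator_id\ttarget_id'")
  fields <- fields[-1]
  lineno <- lineno[-1]
  if (!length(fields))
    return(regulatory_network(name = name))
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed row at line ", lineno[which(nf != 4L)[1]],
         ": expected 4 tab-separated fields, found ", nf[nf != 4L][1])
  m <- do.call(rbind, fields)
  iso <- m[, 2] == ""
  reg_kind <- m[!iso, 4]
  bad <- !reg_kind %in% c("TF", "SIGMA")
  if (any(bad))
    stop("line ", lineno[!iso][which(bad)[1]],
         ": regulator_kind must be TF or SIGMA, found '",
         reg_kind[which(bad)[1]], "'")
  # kind inference; a node claimed both TF and SIGMA is inconsistent
  kind_claims <- tapply(reg_kind, m[!iso, 1], function(k) unique(k),
                        simplify = FALSE)
  multi <- names(kind_claims)[lengths(kind_claims) > 1]
  if (length(multi))
    stop("node(s) declared with conflicting regulator kinds: ",
         paste(multi, collapse = ", "))
  kinds <- vapply(kind_claims, `[[`, character(1), 1)
  iso_ids <- m[iso, 1]
  iso_kinds <- m[iso, 4]
  conflict <- iso_ids %in% names(kinds) & iso_kinds != kinds[iso_ids]
  if (any(conflict))
    stop("node(s) declared with conflicting kinds: ",
         paste(iso_ids[conflict], collapse = ", "))
  all_ids <- unique(c(m[, 1][!iso], m[, 2][!iso], iso_ids))
  all_ids <- all_ids[nzchar(all_ids)]
  node_kinds <- kinds[all_ids]
  names(node_kinds) <- all_ids
  node_kinds[is.na(node_kinds)] <- "TG"
  node_kinds[iso_ids[!iso_ids %in% names(kinds)]] <-
    iso_kinds[!iso_ids %in% names(kinds)]
  regulatory_network(
    nodes = data.frame(id = names(node_kinds), kind = unname(node_kinds)),
    edges = data.frame(regulator_id = m[!iso, 1], target_id = m[!iso, 2],
                       effect = m[!iso, 3]),
    name = name)
}

#' Write a regulatory network to the package's TSV dialect
#'
#' Inverse of [read_network()]: `read_network(write_network(net, f))`
#' reproduces `net` exactly (up to the stored name). Isolated nodes are
#' written as rows with empty `target_id` and `effect`.
#'
#' @param net a [regulatory_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  kind <- setNames(net$nodes$kind, net$nodes$id)
  rows <- character(0)
  if (nrow(net$edges))
    rows <- sprintf("%s\t%s\t%s\t%s", net$edges$regulator_id,
                    net$edges$target_id, net$edges$effect,
                    kind[net$edges$regulator_id])
  iso <- setdiff(net$nodes$id,
                 union(net$edges$regulator_id, net$edges$target_id))
  if (length(iso))
    rows <- c(rows, sprintf("%s\t\t\t%s", iso, kind[iso]))
  writeLines(c("regulator_id\ttarget_id\teffect\tregulator_kind", rows), path,
             useBytes = TRUE)
  invisible(path)
}
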