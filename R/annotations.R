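REG_TYPES <- c("activator", "repressor", "dual", "unclassified")
GENOME_CATEGORIES <- c("free_living", "host_restricted", "obligate", "tiny",
                       "reference")

#' Read / write transcription-factor annotations
#'
#' The annotation TSV has columns `tf_id`, `reg_type` (net effective
#' regulation: `activator`, `repressor`, `dual`, or `unclassified`),
#' `is_nap` (0/1, nucleoid-associated protein) and `is_global` (0/1).
#' The regulation type is an input annotation, taken from curated resources,
#' not derived from the network's edges.
#'
#' @param path file path.
#' @return data.frame with columns `tf_id` (character), `reg_type`
#'   (character), `is_nap`, `is_global` (logical).
#' @export
read_tf_annotation <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = c("character", "character", "integer",
                                  "integer"))
  need <- c("tf_id", "reg_type", "is_nap", "is_global")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(df$reg_type, REG_TYPES)
  if (length(bad))
    stop("unknown reg_type(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$tf_id))
    stop("duplicate tf_id in annotation table")
  df$is_nap <- as.logical(df$is_nap)
  df$is_global <- as.logical(df$is_global)
  df
}

#' @rdname read_tf_annotation
#' @param annot annotation data.frame as returned by [read_tf_annotation()].
#' @export
write_tf_annotation <- function(annot, path) {
  out <- data.frame(tf_id = annot$tf_id, reg_type = annot$reg_type,
                    is_nap = as.integer(annot$is_nap),
                    is_global = as.integer(annot$is_global))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write genome metadata
#'
#' Genome metadata TSV: `genome_id`, `size_bp` (positive integer), and
#' `category`, the four-way lifestyle classification used to stage genome
#' reduction (`free_living`, `host_restricted`, `obligate`, `tiny`) plus
#' `reference`.
#'
#' @param path file path.
#' @return data.frame with columns `genome_id`, `size_bp`, `category`.
#' @export
read_genome_metadata <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = c("character", "numeric", "character"))
  need <- c("genome_id", "size_bp", "category")
  if (!all(need %in% names(df)))
    stop("genome metadata must have columns: ", paste(need, collapse = ", "))
  if (any(df$size_bp <= 0))
    stop("size_bp must be positive")
  bad <- setdiff(df$category, GENOME_CATEGORIES)
  if (length(bad))
    stop("unknown genome category(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_genome_metadata
#' @param genomes metadata data.frame.
#' @export
write_genome_metadata <- function(genomes, path) {
  write.table(genomes[, c("genome_id", "size_bp", "category")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
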