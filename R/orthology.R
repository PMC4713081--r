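# Bidirectional best-hit (BBH) orthology over BLAST tabular hit tables.
# The acceptance thresholds follow comparative-genomics practice for
# gamma-proteobacterial proteomes: e-value strictly below 1e-6, identity
# strictly above 30%, and alignment length strictly above 60% of EACH of the
# two proteins.

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Ortholog-acceptance thresholds
#'
#' @param evalue_max hits are accepted only with `evalue < evalue_max`.
#' @param identity_min percent identity must be strictly greater.
#' @param coverage_min alignment length must strictly exceed this fraction of
#'   both the query and the subject protein lengths.
#' @return A named list of class `bbh_thresholds`.
#' @export
bbh_thresholds <- function(evalue_max = 1e-6, identity_min = 30,
                           coverage_min = 0.60) {
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 coverage_min = coverage_min), class = "bbh_thresholds")
}

#' Read a protein-length table
#'
#' Two-column TSV (`id`, `length`) giving the length in residues of every
#' protein appearing in the companion hit tables.
#'
#' @param path file path.
#' @return Named numeric vector of lengths.
#' @export
read_length_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("id", "length"),
                   colClasses = c("character", "numeric"))
  setNames(df$length, df$id)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects the 12 standard columns
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`. Query and subject protein lengths, required for the
#' coverage criterion, are looked up in `lengths` and attached as two extra
#' columns.
#'
#' @param path file path (no header).
#' @param lengths named numeric vector from [read_length_table()], covering
#'   every id in the table.
#' @return data.frame of hits in file order with columns [BLAST6_COLS] plus
#'   `query_length`, `subject_length`.
#' @export
read_hit_table <- function(path, lengths) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) {
    df <- as.data.frame(setNames(rep(list(character(0)), 12), BLAST6_COLS))
    df$query_length <- numeric(0)
    df$subject_length <- numeric(0)
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1)) # base::lengths is shadowed here
  if (any(nf < 12L))
    stop("malformed hit table row ", which(nf < 12L)[1], ": expected 12 ",
         "columns, found ", nf[nf < 12L][1])
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  df <- data.frame(m, stringsAsFactors = FALSE)
  names(df) <- BLAST6_COLS
  num <- setdiff(BLAST6_COLS, c("query_id", "subject_id"))
  df[num] <- lapply(df[num], as.numeric)
  attach_lengths(df, lengths)
}

attach_lengths <- function(hits, lengths) {
  miss <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(lengths))
  if (length(miss))
    stop("missing length entry for id(s): ",
         paste(head(miss, 5), collapse = ", "))
  hits$query_length <- unname(lengths[hits$query_id])
  hits$subject_length <- unname(lengths[hits$subject_id])
  hits
}

#' Apply the ortholog-acceptance thresholds to hits
#'
#' All three comparisons are strict: `evalue < evalue_max`,
#' `identity > identity_min`, and alignment length greater than
#' `coverage_min` times each of the two protein lengths.
#'
#' @param hits hit data.frame with `query_length`/`subject_length` attached.
#' @param thresholds a [bbh_thresholds()].
#' @return Logical vector, one element per hit.
#' @export
passes_thresholds <- function(hits, thresholds = bbh_thresholds()) {
  hits$evalue < thresholds$evalue_max &
    hits$percent_identity > thresholds$identity_min &
    hits$alignment_length > thresholds$coverage_min * hits$query_length &
    hits$alignment_length > thresholds$coverage_min * hits$subject_length
}

#' Best hit per query
#'
#' The best hit has the lowest e-value; ties are broken by highest bitscore,
#' then lexicographically smallest subject id, so results are reproducible.
#'
#' @param hits hit data.frame for one directed genome pair.
#' @return data.frame with one row per distinct `query_id`.
#' @export
best_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Bidirectional best-hit ortholog calling
#'
#' A pair `(r, t)` is an ortholog pair when `t` is the best hit of reference
#' protein `r` in the forward search, `r` is the best hit of `t` in the
#' reverse search, and both best hits pass the acceptance thresholds.
#' The result is one-to-one by construction.
#'
#' @param forward_hits hits of the reference proteome against the target
#'   genome (with lengths attached, see [read_hit_table()]).
#' @param reverse_hits hits of the target proteome against the reference.
#' @param thresholds a [bbh_thresholds()].
#' @param genome_id identifier of the target genome.
#' @return An `ortholog_map`: data.frame with columns `ref_gene_id`,
#'   `target_gene_id`, with the genome id as attribute `genome_id`.
#' @export
bidirectional_best_hits <- function(forward_hits, reverse_hits,
                                    thresholds = bbh_thresholds(),
                                    genome_id = NA_character_) {
  fb <- best_hit_per_query(forward_hits)
  rb <- best_hit_per_query(reverse_hits)
  if (nrow(fb) && nrow(rb)) {
    i <- match(fb$subject_id, rb$query_id)
    ok <- !is.na(i) & rb$subject_id[i] == fb$query_id &
      passes_thresholds(fb, thresholds) &
      passes_thresholds(rb, thresholds)[ifelse(is.na(i), 1L, i)]
    ok[is.na(ok)] <- FALSE
    pairs <- data.frame(ref_gene_id = fb$query_id[ok],
                        target_gene_id = fb$subject_id[ok],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(ref_gene_id = character(0),
                        target_gene_id = character(0))
  }
  pairs <- pairs[order(pairs$ref_gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  stopifnot(!anyDuplicated(pairs$ref_gene_id),
            !anyDuplicated(pairs$target_gene_id))
  structure(pairs, genome_id = genome_id,
            class = c("ortholog_map", "data.frame"))
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("Ortholog map (%s): %d reciprocal best-hit pairs\n",
              attr(x, "genome_id"), nrow(x)))
  if (nrow(x)) print.data.frame(head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
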