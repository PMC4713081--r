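# Fixtures built in code: tiny networks and hand-rolled hit tables.

tiny_network <- function() {
  regulatory_network(
    nodes = data.frame(id = c("tfA", "sig1", "g1", "g2", "g3"),
                       kind = c("TF", "SIGMA", "TG", "TG", "TG")),
    edges = data.frame(
      regulator_id = c("tfA", "tfA", "sig1"),
      target_id = c("g1", "g2", "g2"),
      effect = c("activation", "repression", "activation")),
    name = "tiny")
}

# hit-table rows with lengths attached, defaulting to a comfortably passing hit
make_hits <- function(query, subject, ident = 50, aln = 180, ev = 1e-20,
                      bits = 300, qlen = 200, slen = 200) {
  nr <- length(query)
  data.frame(query_id = query, subject_id = subject,
             percent_identity = rep_len(ident, nr),
             alignment_length = rep_len(aln, nr),
             mismatches = rep_len(0L, nr), gap_opens = rep_len(0L, nr),
             qstart = rep_len(1L, nr), qend = rep_len(aln, nr),
             sstart = rep_len(1L, nr), send = rep_len(aln, nr),
             evalue = rep_len(ev, nr), bitscore = rep_len(bits, nr),
             query_length = rep_len(qlen, nr),
             subject_length = rep_len(slen, nr),
             stringsAsFactors = FALSE)
}

# an ortholog map without going through BBH
make_omap <- function(ref,
                      tgt = if (length(ref)) paste0(ref, "'") else character(0),
                      genome_id = "gX") {
  structure(data.frame(ref_gene_id = ref, target_gene_id = tgt,
                       stringsAsFactors = FALSE),
            genome_id = genome_id, class = c("ortholog_map", "data.frame"))
}

# annotation table covering given TFs
make_annot <- function(tf_id, reg_type, is_nap = FALSE, is_global = FALSE) {
  data.frame(tf_id = tf_id, reg_type = reg_type,
             is_nap = rep_len(is_nap, length(tf_id)),
             is_global = rep_len(is_global, length(tf_id)))
}

# brute-force hypergeometric upper tail by direct enumeration
enum_upper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (k > min(K, n)) return(0)     # empty upper tail
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# closed-form Fisher combined p for even df = 2m: exp(-X/2) * sum_{j<m} (X/2)^j / j!
fisher_closed_form <- function(X, m) {
  h <- X / 2
  exp(-h) * sum(h^(0:(m - 1)) / factorial(0:(m - 1)))
}

# explicit normal-equations least squares: beta = (X'X)^-1 X'Y with intercept
normal_equations <- function(Y, X) {
  D <- cbind(1, as.matrix(X))
  drop(solve(t(D) %*% D) %*% t(D) %*% Y)
}
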