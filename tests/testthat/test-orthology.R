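test_that("acceptance thresholds are strict on all three criteria", {
  th <- bbh_thresholds()
  expect_false(passes_thresholds(make_hits("A", "a", ident = 25), th))
  expect_false(passes_thresholds(make_hits("A", "a", ev = 1e-6), th))
  expect_true(passes_thresholds(
    make_hits("A", "a", ident = 45, ev = 1e-20, aln = 180, qlen = 200,
              slen = 200), th))
  # identity exactly at the cutoff fails (strict >)
  expect_false(passes_thresholds(make_hits("A", "a", ident = 30), th))
  # coverage is enforced against BOTH protein lengths
  expect_false(passes_thresholds(
    make_hits("A", "a", aln = 150, qlen = 200, slen = 300), th))
})

test_that("best hit per query: lowest e-value, then bitscore, then id", {
  h <- rbind(make_hits("A", "a1", ev = 1e-10), make_hits("A", "a2", ev = 1e-5))
  expect_equal(best_hit_per_query(h)$subject_id, "a1")
  h <- rbind(make_hits("A", "a1", ev = 1e-8, bits = 200),
             make_hits("A", "a2", ev = 1e-8, bits = 250))
  expect_equal(best_hit_per_query(h)$subject_id, "a2")
  h <- rbind(make_hits("A", "a2", ev = 1e-8, bits = 200),
             make_hits("A", "a1", ev = 1e-8, bits = 200))
  expect_equal(best_hit_per_query(h)$subject_id, "a1")
  expect_equal(nrow(best_hit_per_query(make_hits(character(0), character(0)))),
               0L)
})

test_that("bidirectional best hits require reciprocity and thresholds", {
  fwd <- make_hits("A", "a1")
  rev <- make_hits("a1", "A")
  om <- bidirectional_best_hits(fwd, rev, genome_id = "g")
  expect_equal(nrow(om), 1L)
  expect_equal(om$ref_gene_id, "A")

  # reverse best points at another reference gene: no pair
  rev2 <- rbind(make_hits("a1", "B", ev = 1e-30), make_hits("a1", "A"))
  expect_equal(nrow(bidirectional_best_hits(fwd, rev2)), 0L)

  # reciprocal but forward identity below the cutoff: no pair
  expect_equal(nrow(bidirectional_best_hits(
    make_hits("A", "a1", ident = 28), rev)), 0L)
})

test_that("ortholog maps are one-to-one and threshold-monotone", {
  fwd <- rbind(make_hits(c("A", "B", "C"), c("a", "b", "c"),
                         ident = c(80, 45, 35), ev = c(1e-40, 1e-20, 1e-9)))
  rev <- make_hits(c("a", "b", "c"), c("A", "B", "C"),
                   ident = c(80, 45, 35), ev = c(1e-40, 1e-20, 1e-9))
  base <- bidirectional_best_hits(fwd, rev)
  expect_equal(nrow(base), 3L)
  expect_false(anyDuplicated(base$ref_gene_id) > 0)
  expect_false(anyDuplicated(base$target_gene_id) > 0)
  # tightening any threshold never adds pairs
  for (th in list(bbh_thresholds(evalue_max = 1e-25),
                  bbh_thresholds(identity_min = 40),
                  bbh_thresholds(coverage_min = 0.95))) {
    tightened <- bidirectional_best_hits(fwd, rev, th)
    expect_true(all(tightened$ref_gene_id %in% base$ref_gene_id))
    expect_lte(nrow(tightened), nrow(base))
  }
})

test_that("swapping search directions transposes the map", {
  fwd <- make_hits(c("A", "B"), c("a", "b"))
  rev <- make_hits(c("a", "b"), c("A", "B"))
  m1 <- bidirectional_best_hits(fwd, rev)
  m2 <- bidirectional_best_hits(rev, fwd)
  expect_setequal(paste(m1$ref_gene_id, m1$target_gene_id),
                  paste(m2$target_gene_id, m2$ref_gene_id))
})

test_that("hit tables round-trip through files with length lookup", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\ta1\t45.0\t200\t10\t0\t1\t200\t1\t200\t1e-20\t300",
               "B\tb1\t60.0\t150\t5\t0\t1\t150\t1\t150\t1e-30\t280",
               "B\tb2\t40.0\t150\t9\t0\t1\t150\t1\t150\t1e-10\t180"), f)
  lens <- c(A = 200, a1 = 200, B = 160, b1 = 160, b2 = 150)
  hits <- read_hit_table(f, lens)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$query_id, c("A", "B", "B"))   # order preserved
  expect_equal(hits$evalue[1], 1e-20)
  expect_equal(hits$query_length[2], 160)
  expect_error(read_hit_table(f, lens[-2]), "a1")

  writeLines("A\ta1\t45.0\t200\t10\t0\t1\t200\t1e-20\t300", f)
  expect_error(read_hit_table(f, lens), "12 columns")
  writeLines(character(0), f)
  expect_equal(nrow(read_hit_table(f, lens)), 0L)
})
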