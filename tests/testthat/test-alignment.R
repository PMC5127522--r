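test_that("reading an aligned FASTA validates shape, labels and order", {
  a <- read_alignment(worked_fasta(), alphabet_kind = "categorical")
  expect_s3_class(a, "cite_alignment")
  expect_equal(n_taxa(a), 4L)
  expect_equal(n_sites(a), 5L)
  expect_equal(a$taxa, c("Tax1", "Tax2", "Tax3", "Tax4"))
  expect_equal(paste(a$mat["Tax4", ], collapse = ""), "AACAD")  # uppercased

  one <- tempfile(fileext = ".fasta")
  writeLines(c(">only", "MKV"), one)
  expect_equal(n_taxa(read_alignment(one, "protein")), 1L)

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGTC", ">B", "ACGT"), ragged)
  expect_error(read_alignment(ragged, "nucleotide"), "not an alignment.*'B'")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGT", ">A", "ACGT"), dup)
  expect_error(read_alignment(dup, "nucleotide"), "duplicate taxon labels.*A")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_alignment(empty, "nucleotide"))
  expect_error(read_alignment(tempfile(), "nucleotide"), "not found")

  expect_error(alignment(c(A = "ACGT", B = "AXGT"), "nucleotide"),
               "not in the nucleotide alphabet")
})

test_that("FASTA round trip preserves the alignment", {
  a <- worked_alignment()
  fa <- tempfile(fileext = ".fasta")
  write_alignment(a, fa)
  b <- read_alignment(fa, "categorical")
  expect_equal(b$mat, a$mat)
  expect_equal(b$taxa, a$taxa)
})

test_that("deduplication keeps first occurrences and reports the rest", {
  dd <- deduplicate_taxa(worked_alignment())
  expect_equal(dd$alignment$taxa, c("Tax1", "Tax3", "Tax4"))
  expect_equal(dd$report, data.frame(dropped = "Tax2", kept = "Tax1",
                                     stringsAsFactors = FALSE))

  # idempotent
  dd2 <- deduplicate_taxa(dd$alignment)
  expect_equal(dd2$alignment, dd$alignment)
  expect_equal(nrow(dd2$report), 0L)

  # all-unique input is untouched
  u <- random_alignment(6, 20, seed = 11)
  expect_equal(deduplicate_taxa(u)$alignment, u)

  # full collapse: five copies leave one
  seqs <- setNames(rep("ACGT", 5), paste0("T", 1:5))
  dd3 <- deduplicate_taxa(alignment(seqs, "nucleotide"))
  expect_equal(n_taxa(dd3$alignment), 1L)
  expect_equal(dd3$report$dropped, paste0("T", 2:5))
  expect_equal(dd3$report$kept, rep("T1", 4))
})

test_that("site_counts tabulates states under both gap policies", {
  a <- worked_alignment()
  sc <- site_counts(a, 3)
  expect_equal(sc$counts, c(A = 3L, C = 1L))
  expect_equal(sc$n_nongap, 4L)
  expect_equal(site_counts(a, 1)$counts, c(A = 4L))
  expect_error(site_counts(a, 0), "out of range")
  expect_error(site_counts(a, 6), "out of range")

  g <- alignment(c(T1 = "A", T2 = "-", T3 = "A", T4 = "C"), "nucleotide")
  ig <- site_counts(g, 1, "ignore_gaps")
  expect_equal(ig$counts, c(A = 2L, C = 1L))
  expect_equal(ig$n_nongap, 3L)
  gs <- site_counts(g, 1, "gap_as_state")
  expect_equal(gs$counts, c("-" = 1L, A = 2L, C = 1L))
  expect_equal(sum(gs$counts), 4L)
})

test_that("split patterns canonicalise the induced taxon partition", {
  a <- worked_alignment()
  expect_identical(split_pattern(a, 2)$key, split_pattern(a, 4)$key)
  expect_setequal(lapply(split_pattern(a, 2)$blocks, sort),
                  list(c(1L, 2L), c(3L, 4L)))
  # invariant site: one block of all taxa
  expect_equal(split_pattern(a, 1)$blocks, list(1:4))
  # after dedup, sites 2 (b,a,a) and 4 (c,a,a) still match despite
  # different state labels
  d <- deduplicate_taxa(a)$alignment
  expect_identical(split_pattern(d, 2)$key, split_pattern(d, 4)$key)
  expect_false(identical(split_pattern(d, 2)$key, split_pattern(d, 3)$key))
})

test_that("split pattern equality is invariant to state relabelling", {
  for (seed in 1:5) {
    a <- random_alignment(8, 12, seed = seed, alphabet_kind = "categorical")
    set.seed(seed + 100)
    perm <- sample(c("A", "B", "C"))
    b <- a
    b$mat[] <- perm[match(a$mat, c("A", "B", "C"))]
    for (i in seq_len(n_sites(a)))
      expect_identical(split_pattern(b, i)$key, split_pattern(a, i)$key)
  }
})

test_that("taxon reordering permutes block members but preserves structure", {
  a <- random_alignment(7, 10, seed = 3)
  set.seed(4)
  perm <- sample(n_taxa(a))
  b <- a
  b$mat <- a$mat[perm, , drop = FALSE]
  b$taxa <- a$taxa[perm]
  for (i in seq_len(n_sites(a))) {
    orig <- lapply(split_pattern(a, i)$blocks, sort)
    moved <- lapply(split_pattern(b, i)$blocks,
                    function(x) sort(perm[x]))  # map back to pool indices
    expect_setequal(moved, orig)
  }
})

test_that("gap footprints keep otherwise-identical splits apart", {
  g <- alignment(c(T1 = "AA", T2 = "A-", T3 = "CC", T4 = "CC"), "nucleotide")
  expect_false(identical(split_pattern(g, 1)$key, split_pattern(g, 2)$key))
  # but as a counted state the gap makes site 2 a three-way partition
  p <- split_pattern(g, 2, "gap_as_state")
  expect_equal(length(p$blocks), 3L)
})
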