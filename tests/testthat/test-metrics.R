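test_that("site entropy reproduces the hand-computed contributions", {
  c1 <- cfg1()
  expect_equal(site_entropy(c(a = 3, c = 1), c1), 0.8113, tolerance = 1e-4)
  expect_equal(site_entropy(c(a = 2, c = 1, d = 1), c1), 1.5)
  expect_equal(site_entropy(c(a = 4), c1), 0)
  expect_equal(site_entropy(c(a = 1, c = 1, d = 1), c1), log2(3))
  expect_error(site_entropy(structure(list(site = 1L, counts = integer(0),
                                           n_nongap = 0L),
                                      class = "state_counts")), "empty")
})

test_that("the parsimony threshold and denominator modes interact correctly", {
  # one retained state out of {a:3, c:1}: p = 3/4 against all counted
  expect_equal(site_entropy(c(a = 3, c = 1), metric_config()),
               -0.75 * log2(0.75))
  # against retained counts only the site is effectively invariant
  expect_equal(site_entropy(c(a = 3, c = 1),
                            metric_config(denominator_mode = "retained_only")),
               0)
  # no state reaches the threshold
  expect_equal(site_entropy(c(a = 1, c = 1, d = 1), metric_config()), 0)
  # natural-log scoring scales by log(2)
  expect_equal(site_entropy(c(a = 2, c = 2), cfg1(log_base = exp(1))), log(2))
})

test_that("CITE sums per-site entropies over the raw alignment", {
  a <- worked_alignment()
  r1 <- cite(a, cfg1())
  expect_equal(r1$per_site, c(0, 1, 0.8113, 1, 1.5), tolerance = 1e-4)
  expect_equal(r1$score, 4.3113, tolerance = 1e-4)
  # with the threshold on, singleton states drop out of each sum
  r2 <- cite(a, metric_config())
  expect_equal(r2$per_site, c(0, 1, 0.3113, 1, 0.5), tolerance = 1e-4)
  expect_equal(r2$score, 2.8113, tolerance = 1e-4)
  # all-invariant alignment
  inv <- alignment(c(T1 = "AAA", T2 = "AAA", T3 = "AAA"), "nucleotide")
  expect_equal(cite(inv, cfg1())$score, 0)
})

test_that("with singletons included CITE is the plain Shannon entropy sum", {
  for (seed in 1:5) {
    a <- random_alignment(9, 25, seed = seed)
    want <- sum(vapply(seq_len(n_sites(a)), function(i)
      shannon_bits(site_counts(a, i)$counts), numeric(1)))
    expect_equal(cite(a, cfg1())$score, want)
  }
})

test_that("delta_min counts twice-present states minus one, per site", {
  expect_equal(delta_min(worked_alignment()), 2L)  # sites 2 and 4 only
  inv <- alignment(c(T1 = "AAAA", T2 = "AAAA"), "nucleotide")
  expect_equal(delta_min(inv), 0L)
  # one site, states {A:5, C:5, G:2}: three states all >= 2
  seqs <- setNames(c(rep("A", 5), rep("C", 5), rep("G", 2)), paste0("T", 1:12))
  expect_equal(delta_min(alignment(seqs, "nucleotide")), 2L)
  # a single >=2 state plus singletons cannot witness a change
  seqs2 <- setNames(c("A", "A", "C", "G"), paste0("T", 1:4))
  expect_equal(delta_min(alignment(seqs2, "nucleotide")), 0L)
})

test_that("character diversity follows its definition and summary rules", {
  # protein site, 2 states among 4 non-gap taxa -> 2/min(4,20) = 0.5
  p <- alignment(c(T1 = "M", T2 = "M", T3 = "K", T4 = "K"), "protein")
  cd <- character_diversity(p)
  expect_equal(cd$per_site$diversity, 0.5)
  expect_equal(cd$summary$frac_le_0.5, 1)

  # nucleotide site with 3 states among 50 taxa -> 3/min(50,4) = 0.75
  seqs <- setNames(c(rep("A", 20), rep("C", 20), rep("G", 10)),
                   paste0("T", 1:50))
  expect_equal(character_diversity(alignment(seqs, "nucleotide"))$per_site$diversity,
               0.75)

  # invariant sites are excluded; all-invariant means undefined summary
  inv <- alignment(c(T1 = "AAA", T2 = "AAA"), "nucleotide")
  cd2 <- character_diversity(inv)
  expect_equal(nrow(cd2$per_site), 0L)
  expect_false(cd2$summary$defined)
})

test_that("metric totals are invariant to site and taxon order", {
  a <- random_alignment(8, 15, seed = 42)
  set.seed(1)
  sp <- sample(n_sites(a)); tp <- sample(n_taxa(a))
  b <- a; b$mat <- a$mat[, sp, drop = FALSE]
  c_ <- a; c_$mat <- a$mat[tp, , drop = FALSE]; c_$taxa <- a$taxa[tp]
  for (x in list(b, c_)) {
    expect_equal(cite(x, cfg1())$score, cite(a, cfg1())$score)
    expect_equal(delta_min(x), delta_min(a))
    expect_equal(total_cic(x), total_cic(a))
  }
})
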