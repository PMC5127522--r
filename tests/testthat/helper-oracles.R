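# Independent oracles, deliberately implemented by different algorithms than
# the package code they check.

# Plain Shannon entropy in bits over a full count vector (no thresholding).
shannon_bits <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Exhaustive enumeration of rooted binary trees on a leaf set, by recursive
# bipartition (the package builds them by leaf insertion instead). A leaf is
# an integer scalar; an internal node is list(left, right).
.enum_cache <- new.env(parent = emptyenv())

enum_rooted <- function(leaves) {
  key <- paste(leaves, collapse = ",")
  hit <- get0(key, envir = .enum_cache)
  if (!is.null(hit)) return(hit)
  res <- enum_rooted_raw(leaves)
  assign(key, res, envir = .enum_cache)
  res
}

enum_rooted_raw <- function(leaves) {
  if (length(leaves) == 1L) return(list(leaves))
  res <- list()
  rest <- leaves[-1L]
  for (m in 0:(2L^length(rest) - 1L)) {
    sel <- as.logical(intToBits(m))[seq_along(rest)]
    right <- rest[!sel]
    if (!length(right)) next
    left <- c(leaves[1L], rest[sel])
    for (L in enum_rooted(left))
      for (R in enum_rooted(right))
        res[[length(res) + 1L]] <- list(L, R)
  }
  res
}

# Sorted leaf-index clusters of every non-root, non-leaf node... the root
# cluster is included too (harmless: it is shared by all trees on the same
# leaves). Keys are comma-joined strings.
cluster_keys <- function(t) {
  keys <- character(0)
  rec <- function(node) {
    if (!is.list(node)) return(node)
    tips <- sort(c(rec(node[[1]]), rec(node[[2]])))
    keys <<- c(keys, paste(tips, collapse = ","))
    tips
  }
  rec(t)
  keys
}

# Number of rooted binary trees on n leaves that refine a (possibly
# multifurcating) phylo tree: brute-force check that every clade of the
# input is a clade of the candidate.
count_refinements <- function(phy) {
  n <- ape::Ntip(phy)
  want <- vapply(ape::prop.part(phy),
                 function(x) paste(sort(x), collapse = ","), character(1))
  sum(vapply(enum_rooted(seq_len(n)), function(b) {
    keys <- c(cluster_keys(b), as.character(seq_len(n)))
    all(want %in% keys)
  }, logical(1)))
}

# Number of rooted binary trees on n leaves on which a 2-state character
# with a copies of state 1 is homoplasy-free, via the convexity criterion:
# the tree must display the split {state-1 leaves} | {state-2 leaves},
# i.e. one side must be a cluster (a pendant leaf always is).
count_convex_2state <- function(n, a) {
  stopifnot(a >= 1, a <= n - 1)
  if (a == 1L || a == n - 1L) return(length(enum_rooted(seq_len(n))))
  kx <- paste(seq_len(a), collapse = ",")
  ky <- paste((a + 1L):n, collapse = ",")
  sum(vapply(enum_rooted(seq_len(n)), function(t) {
    keys <- cluster_keys(t)
    (kx %in% keys) || (ky %in% keys)
  }, logical(1)))
}

# Degeneracy by the literal recursion over a phylo tree.
degeneracy_recursive <- function(phy) {
  n <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(v) {
    if (v <= n) return(0L)
    ch <- kids[[as.character(v)]]
    length(ch) - 2L + sum(vapply(ch, rec, integer(1)))
  }
  rec(n + 1L)
}

# Plateau detection by scanning every window explicitly.
plateau_scan <- function(score, labels = seq_along(score), window = 15L,
                         tolerance = 15) {
  np <- length(score)
  sums <- vapply(seq_len(np - window - 1L), function(i)
    sum(abs(score[(i + 1L):(i + window + 1L)] - score[i:(i + window)])),
    numeric(1))
  hit <- which(sums <= tolerance)
  if (length(hit)) labels[min(hit)] else NA_integer_
}

# A random alignment with no engineered structure, for property tests.
random_alignment <- function(n_taxa, n_sites, seed,
                             alphabet_kind = "nucleotide") {
  alpha <- switch(alphabet_kind, nucleotide = c("A", "C", "G", "T"),
                  categorical = c("A", "B", "C"), LETTERS[1:20])
  set.seed(seed)
  m <- matrix(sample(alpha, n_taxa * n_sites, replace = TRUE), nrow = n_taxa)
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- paste0("T", seq_len(n_taxa))
  alignment(seqs, alphabet_kind = alphabet_kind)
}
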