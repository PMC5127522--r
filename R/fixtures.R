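fixture_alphabet <- function(alphabet_kind) {
  switch(alphabet_kind,
         nucleotide = c("A", "C", "G", "T"),
         protein = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                     "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
         categorical = c("A", "B", "C", "D", "E", "F"))
}

#' Generate a synthetic alignment with controlled cladistic structure
#'
#' Builds an alignment containing exactly the requested numbers of invariant
#' sites, saturated sites (states spread near-uniformly over the whole
#' alphabet — the mutational-saturation worst case), duplicate-split site
#' pairs, and duplicate taxa, so that every metric's behaviour can be tested
#' by construction. Duplicate-split sites are made by cyclically permuting
#' the state labels of an existing variable column: the taxon partition is
#' identical while every character differs, which exercises the canonical
#' split-pattern comparison rather than naive column equality. Duplicate
#' taxa are exact copies appended after the unique block, so deduplication
#' drops precisely the appended rows. Remaining sites are drawn with 2–4
#' states at random proportions, and are resampled as needed so that all
#' variable non-duplicate sites carry pairwise distinct split patterns.
#'
#' Columns are laid out in blocks: invariant, then free variable, then
#' saturated, then duplicate-split (each after its source). No evolution on
#' a tree is simulated; the generator targets metric structure, not
#' phylogenetic realism.
#'
#' @param n_taxa,n_sites dimensions of the alignment
#' @param alphabet_kind \code{"nucleotide"}, \code{"protein"} or
#'   \code{"categorical"}
#' @param fraction_invariant fraction of sites that are invariant
#' @param n_duplicate_taxa number of exact-copy taxa to append
#' @param n_duplicate_split_sites number of sites whose split pattern
#'   duplicates an earlier site's
#' @param fraction_saturated_sites fraction of sites with near-uniform
#'   full-alphabet states
#' @param seed integer seed; generation is deterministic given the seed
#' @return a \code{cite_alignment}
#' @export
generate_alignment <- function(n_taxa, n_sites,
                               alphabet_kind = c("protein", "nucleotide", "categorical"),
                               fraction_invariant = 0,
                               n_duplicate_taxa = 0L,
                               n_duplicate_split_sites = 0L,
                               fraction_saturated_sites = 0,
                               seed = 1L) {
  alphabet_kind <- match.arg(alphabet_kind)
  alpha <- fixture_alphabet(alphabet_kind)
  u <- n_taxa - n_duplicate_taxa
  if (u < 1L) stop("infeasible: more duplicate taxa than taxa")
  n_inv <- round(fraction_invariant * n_sites)
  n_sat <- round(fraction_saturated_sites * n_sites)
  n_dup <- as.integer(n_duplicate_split_sites)
  n_free <- n_sites - n_inv - n_sat - n_dup
  if (n_free < 0L)
    stop("infeasible: invariant + saturated + duplicate-split sites exceed n_sites")
  n_var <- n_free + n_sat
  if (n_dup > 0L && n_var < 1L)
    stop("infeasible: duplicate-split sites need at least one variable source site")
  if (n_var > 0L && u < 2L)
    stop("infeasible: variable sites need at least 2 unique taxa")

  with_rng_seed(seed, {
    free_col <- function() {
      k <- if (min(4L, u, length(alpha)) == 2L) 2L else
        sample(2:min(4L, u, length(alpha)), 1L)
      states <- sample(alpha, k)
      sample(states[c(seq_len(k), sample.int(k, u - k, replace = TRUE))])
    }
    sat_col <- function() sample(rep(alpha, length.out = u))
    cols <- c(replicate(n_free, free_col(), simplify = FALSE),
              replicate(n_sat, sat_col(), simplify = FALSE))

    # all variable, non-duplicate sites must carry pairwise distinct split
    # patterns, and the unique taxa must have pairwise distinct rows (exact
    # dedup accounting); resample offending free/saturated columns until
    # both hold
    key_of <- function(col) paste(match(col, unique(col)), collapse = ",")
    ok <- FALSE
    for (iter in seq_len(200L)) {
      bad <- which(duplicated(vapply(cols, key_of, character(1))))
      if (length(bad)) {
        for (b in bad)
          cols[[b]] <- if (b <= n_free) free_col() else sat_col()
        next
      }
      rows <- if (n_var)
        apply(do.call(cbind, cols), 1L, paste, collapse = "") else
        rep("", u)
      if (anyDuplicated(rows) && n_free >= 1L) {
        cols[[sample.int(n_free, 1L)]] <- free_col()
        next
      }
      ok <- TRUE
      break
    }
    if (!ok && n_var > 0L)
      stop("infeasible: could not realise ", n_var,
           " distinct split patterns over ", u, " distinct taxa")

    dup_cols <- if (n_dup > 0L) {
      src <- rep(seq_len(n_var), length.out = n_dup)
      lapply(src, function(s) {
        col <- cols[[s]]
        states <- unique(col)
        shifted <- states[c(seq_len(length(states))[-1L], 1L)]
        shifted[match(col, states)]
      })
    } else list()

    inv_cols <- replicate(n_inv, rep(sample(alpha, 1L), u), simplify = FALSE)
    all_cols <- c(inv_cols, cols, dup_cols)
    base <- if (length(all_cols))
      do.call(cbind, all_cols) else
      matrix(character(0), nrow = u, ncol = 0L)

    if (n_duplicate_taxa > 0L) {
      src <- sample.int(u, n_duplicate_taxa, replace = TRUE)
      base <- rbind(base, base[src, , drop = FALSE])
    }
    seqs <- apply(base, 1L, paste, collapse = "")
    names(seqs) <- paste0("T", seq_len(n_taxa))
    alignment(seqs, alphabet_kind = alphabet_kind)
  })
}

#' Generate a random rooted tree with controlled polytomies
#'
#' Draws a random rooted binary tree and collapses each internal edge
#' independently with probability \code{polytomy_rate}, so a rate of 0
#' yields a fully binary tree (degeneracy 0) and a rate of 1 yields a star
#' (degeneracy \code{n_leaves - 2}). Optionally attaches bootstrap-style
#' support values drawn uniformly on [50, 100] to the non-root internal
#' nodes.
#'
#' @param n_leaves number of leaves (>= 2)
#' @param polytomy_rate probability in [0, 1] that an internal edge is
#'   collapsed into its parent
#' @param seed integer seed; output is deterministic given the seed
#' @param supports attach support values?
#' @return an \code{ape} \code{phylo} object
#' @export
generate_tree <- function(n_leaves, polytomy_rate = 0, seed = 1L,
                          supports = FALSE) {
  stopifnot(n_leaves >= 2L, polytomy_rate >= 0, polytomy_rate <= 1)
  with_rng_seed(seed, {
    phy <- ape::rtree(n_leaves, rooted = TRUE)
    internal_edge <- phy$edge[, 2] > ape::Ntip(phy)
    len <- rep(1, nrow(phy$edge))
    len[internal_edge] <- ifelse(
      stats::runif(sum(internal_edge)) < polytomy_rate, 0, 1)
    phy$edge.length <- len
    phy <- ape::di2multi(phy, tol = 0.5)
    if (supports && phy$Nnode >= 1L) {
      lab <- as.character(round(stats::runif(phy$Nnode, 50, 100)))
      lab[1L] <- ""   # root carries no support
      phy$node.label <- lab
    }
    phy
  })
}
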