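#' Per-character cladistic information content I(chi)
#'
#' Quantifies the information in a single r-state character over n taxa via
#' the number of trees on which the character can be explained without
#' homoplasy. The default \code{"formula"} mode computes
#' \deqn{I(\chi) = \sum_{j=3}^{n-r+1} (1 - b_j)\, \log(2j - 3)}
#' where \eqn{b_j} is the number of states with at least j instances. Note
#' the summand can be negative wherever \eqn{b_j \ge 2}; a warning is issued
#' if the site total itself comes out negative.
#'
#' \code{"homoplasy_oracle"} mode instead evaluates the verbal definition
#' directly: it enumerates every rooted binary topology on n leaves
#' (feasible for n <= 8), scores the character on each by Fitch parsimony,
#' and returns \eqn{-\log(\mathrm{homoplasy\!-\!free}/\mathrm{all})}, where
#' a character with r states is homoplasy-free on a tree when its parsimony
#' score equals r - 1.
#'
#' @param c a \code{state_counts} object or named numeric vector of state
#'   counts \eqn{a_1, \dots, a_r}.
#' @param n number of taxa (must be at least \code{sum(counts)}).
#' @param mode \code{"formula"} (default) or \code{"homoplasy_oracle"}.
#' @param log_base base of the logarithm (default 2).
#' @param detail if \code{TRUE}, return a list with the value plus the
#'   \eqn{b_j} bookkeeping (formula mode) or the homoplasy-free/total tree
#'   counts (oracle mode).
#' @return numeric value, or a list when \code{detail = TRUE}.
#' @examples
#' i_chi(c(G = 7, A = 3), n = 10, detail = TRUE)$b   # b_3 = 2, b_4..b_7 = 1
#' i_chi(c(A = 2, C = 2), n = 4, mode = "homoplasy_oracle")  # log2(3)
#' @export
i_chi <- function(c, n, mode = c("formula", "homoplasy_oracle"),
                  log_base = 2, detail = FALSE) {
  mode <- match.arg(mode)
  c <- as_counts(c)
  a <- as.numeric(c$counts)
  r <- length(a)
  if (r < 1L) stop("at least one state is required")
  if (r > n) stop("more states (", r, ") than taxa (", n, ")")
  if (sum(a) > n) stop("state counts sum to ", sum(a), " > n = ", n)

  if (mode == "formula") {
    hi <- n - r + 1L
    if (hi < 3L) {
      val <- 0
      b <- stats::setNames(numeric(0), character(0))
    } else {
      j <- 3:hi
      b <- vapply(j, function(jj) sum(a >= jj), numeric(1))
      names(b) <- j
      val <- sum((1 - b) * log(2 * j - 3, base = log_base))
    }
    if (val < 0)
      warning("negative I(chi) at site ", c$site, ": ", format(val),
              " (the printed formula admits negative terms when b_j >= 2)")
    if (detail) return(list(value = val, b = b)) else return(val)
  }

  # homoplasy_oracle
  if (n > 8L)
    stop("homoplasy_oracle mode enumerates all rooted binary topologies ",
         "and is limited to n <= 8 taxa")
  states <- rep.int(seq_len(r), as.integer(a))
  # taxa absent from the counts (gap-bearing) cannot occur here: sum == n
  if (sum(a) < n) stop("oracle mode requires counts over all n taxa")
  trees <- all_rooted_binary_trees(n)
  hf <- sum(vapply(trees, function(t) fitch_length(t, states) == r - 1L,
                   logical(1)))
  total <- length(trees)
  val <- -log(hf / total, base = log_base)
  if (detail) list(value = val, homoplasy_free = hf, total = total) else val
}

# All rooted binary topologies on leaves 1..n, as nested pair lists
# (leaf = integer scalar). Built by successive leaf insertion on every
# branch, including the root branch; yields (2n-3)!! trees.
all_rooted_binary_trees <- function(n) {
  stopifnot(n >= 1L)
  trees <- list(1L)
  if (n == 1L) return(trees)
  for (leaf in 2:n) {
    out <- vector("list", length(trees) * (2L * (leaf - 1L) - 1L))
    k <- 0L
    for (t in trees) {
      for (nt in insert_leaf_everywhere(t, leaf)) {
        k <- k + 1L
        out[[k]] <- nt
      }
    }
    trees <- out
  }
  trees
}

# All trees obtained by attaching `leaf` on each branch of t, plus above the
# root.
insert_leaf_everywhere <- function(t, leaf) {
  res <- list(list(t, leaf))  # above the root
  if (is.integer(t) && length(t) == 1L) return(res)
  for (child in 1:2) {
    for (sub in insert_leaf_everywhere(t[[child]], leaf)) {
      nt <- t
      nt[[child]] <- sub
      res[[length(res) + 1L]] <- nt
    }
  }
  res
}

# Fitch parsimony length of a character on a nested-pair tree; states is an
# integer vector indexed by leaf number. State sets are encoded as bitmasks.
fitch_length <- function(t, states) {
  changes <- 0L
  rec <- function(node) {
    if (is.integer(node) && length(node) == 1L)
      return(bitwShiftL(1L, states[node] - 1L))
    l <- rec(node[[1]])
    r <- rec(node[[2]])
    inter <- bitwAnd(l, r)
    if (inter != 0L) inter else {
      changes <<- changes + 1L
      bitwOr(l, r)
    }
  }
  rec(t)
  changes
}

#' Total cladistic information content of an alignment
#'
#' Sums \code{\link{i_chi}} (formula mode) over all sites. For each site the
#' taxon count is the number of residues actually counted there (non-gap
#' residues under \code{"ignore_gaps"}), so gapped sites are scored on the
#' taxa they cover. Sites whose I(chi) comes out negative under the printed
#' formula are flagged with a single consolidated warning.
#'
#' @param a a \code{cite_alignment}
#' @param log_base base of the logarithm (default 2)
#' @param gap_policy see \code{\link{site_counts}}
#' @return numeric total
#' @export
total_cic <- function(a, log_base = 2, gap_policy = c("ignore_gaps", "gap_as_state")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(a, "cite_alignment"))
  neg <- integer(0)
  vals <- vapply(seq_len(n_sites(a)), function(i) {
    sc <- site_counts(a, i, gap_policy)
    if (!length(sc$counts)) return(0)
    v <- withCallingHandlers(
      i_chi(sc, n = sum(sc$counts), log_base = log_base),
      warning = function(w) invokeRestart("muffleWarning"))
    if (v < 0) neg <<- c(neg, i)
    v
  }, numeric(1))
  if (length(neg))
    warning("negative I(chi) at ", length(neg), " site(s): ",
            paste(utils::head(neg, 10L), collapse = ", "),
            if (length(neg) > 10L) ", ..." else "")
  sum(vals)
}
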