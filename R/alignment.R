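#' Construct a multiple sequence alignment object
#'
#' An alignment is a rectangular matrix of single-character states over a set
#' of uniquely labelled taxa, with a declared alphabet and gap symbol. All
#' cladistic metrics in this package consume this object.
#'
#' @param seqs named character vector of aligned sequences (one string per
#'   taxon); all strings must have equal length and names must be unique.
#' @param alphabet_kind one of \code{"nucleotide"}, \code{"protein"},
#'   \code{"categorical"}. Categorical alphabets are inferred from content;
#'   any non-gap character is accepted.
#' @param gap single gap character (default \code{"-"}).
#' @return an object of class \code{"cite_alignment"}: a list with elements
#'   \code{taxa} (character), \code{mat} (character matrix, taxa x sites),
#'   \code{alphabet_kind} and \code{gap}.
#' @examples
#' a <- alignment(c(Tax1 = "abaca", Tax2 = "abaca", Tax3 = "aaaac",
#'                  Tax4 = "aacad"), alphabet_kind = "categorical")
#' n_sites(a)
#' @export
alignment <- function(seqs, alphabet_kind = c("protein", "nucleotide", "categorical"),
                      gap = "-") {
  alphabet_kind <- match.arg(alphabet_kind)
  if (length(seqs) == 0L) stop("alignment is empty: no sequences given")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must carry a taxon label")
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (nchar(gap) != 1L) stop("gap symbol must be a single character")
  seqs <- toupper(seqs)
  gap <- toupper(gap)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop("not an alignment: record '", bad, "' has length ", nchar(seqs[bad]),
         ", expected ", lens[1L])
  }
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(names(seqs), NULL))
  allowed <- switch(alphabet_kind,
    nucleotide = c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "?"),
    protein = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "U",
                "O", "J", "*", "?"),
    categorical = NULL)
  if (!is.null(allowed)) {
    bad <- setdiff(unique(as.vector(mat)), c(allowed, gap))
    if (length(bad))
      stop("characters not in the ", alphabet_kind, " alphabet: ",
           paste(bad, collapse = ", "))
  }
  structure(list(taxa = names(seqs), mat = mat,
                 alphabet_kind = alphabet_kind, gap = gap),
            class = "cite_alignment")
}

#' @export
print.cite_alignment <- function(x, ...) {
  cat("Alignment: ", n_taxa(x), " taxa, ", n_sites(x), " sites (",
      x$alphabet_kind, ", gap = '", x$gap, "')\n", sep = "")
  show <- utils::head(x$taxa, 6L)
  for (t in show) {
    s <- paste(x$mat[t, seq_len(min(60L, n_sites(x)))], collapse = "")
    if (n_sites(x) > 60L) s <- paste0(s, "...")
    cat(sprintf("  %-12s %s\n", t, s))
  }
  if (n_taxa(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Number of taxa / sites in an alignment
#' @param a a \code{cite_alignment}
#' @return integer count
#' @export
n_taxa <- function(a) length(a$taxa)

#' @rdname n_taxa
#' @export
n_sites <- function(a) ncol(a$mat)

#' Read an aligned FASTA file
#'
#' Reads a standard FASTA file whose records all have equal length (an
#' alignment). Taxon labels are taken from the first whitespace-delimited
#' token of each header. Residues are uppercased.
#'
#' @param path path to an aligned FASTA file.
#' @inheritParams alignment
#' @return a \code{cite_alignment}
#' @export
read_alignment <- function(path, alphabet_kind = c("protein", "nucleotide", "categorical"),
                           gap = "-") {
  alphabet_kind <- match.arg(alphabet_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  alignment(seqs, alphabet_kind = alphabet_kind, gap = gap)
}

#' Write an alignment to FASTA
#'
#' @param a a \code{cite_alignment}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_alignment <- function(a, path) {
  seqs <- apply(a$mat, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Drop duplicate sequences, keeping the first occurrence
#'
#' Sequences that are character-identical to an earlier sequence carry no
#' additional cladistic information (the taxa are indistinguishable on this
#' evidence) but inflate the state proportions at every site, so they are
#' removed before scoring. Comparison is exact over the full aligned row,
#' gaps included, and case-insensitive (rows are stored uppercased). The
#' dropped taxa are reported, never silently discarded.
#'
#' @param a a \code{cite_alignment}
#' @return a list with \code{alignment} (duplicates removed, input order
#'   preserved) and \code{report}, a data frame with columns \code{dropped}
#'   and \code{kept} (one row per removed taxon, naming its retained
#'   representative). Idempotent: a second application changes nothing.
#' @examples
#' a <- alignment(c(Tax1 = "abaca", Tax2 = "abaca", Tax3 = "aaaac",
#'                  Tax4 = "aacad"), alphabet_kind = "categorical")
#' deduplicate_taxa(a)$report   # Tax2 -> Tax1
#' @export
deduplicate_taxa <- function(a) {
  stopifnot(inherits(a, "cite_alignment"))
  rows <- apply(a$mat, 1L, paste, collapse = "")
  first <- match(rows, rows)          # index of first occurrence
  dup <- which(first != seq_along(rows))
  report <- data.frame(dropped = a$taxa[dup], kept = a$taxa[first[dup]],
                       stringsAsFactors = FALSE)
  if (length(dup)) {
    keep <- setdiff(seq_along(rows), dup)
    a$mat <- a$mat[keep, , drop = FALSE]
    a$taxa <- a$taxa[keep]
  }
  list(alignment = a, report = report)
}

#' Per-site state counts
#'
#' Tabulates the character states observed at one alignment column. Under
#' \code{"ignore_gaps"} (the default everywhere in this package) gap
#' characters are not counted; under \code{"gap_as_state"} the gap is a
#' bona fide extra state (a fifth nucleotide / twenty-first amino acid).
#'
#' @param a a \code{cite_alignment}
#' @param i site index (1-based)
#' @param gap_policy \code{"ignore_gaps"} or \code{"gap_as_state"}
#' @return a list of class \code{"state_counts"}: \code{site}, \code{counts}
#'   (named integer vector, one entry per observed state), \code{n_nongap}.
#' @export
site_counts <- function(a, i, gap_policy = c("ignore_gaps", "gap_as_state")) {
  gap_policy <- match.arg(gap_policy)
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > n_sites(a))
    stop("site index out of range: ", i, " (alignment has ", n_sites(a), " sites)")
  col <- a$mat[, i]
  n_nongap <- sum(col != a$gap)
  if (gap_policy == "ignore_gaps") col <- col[col != a$gap]
  tab <- table(col)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(list(site = as.integer(i), counts = counts, n_nongap = n_nongap),
            class = "state_counts")
}

# Canonical key for the taxon partition induced by a site. Group ids are
# assigned in order of first appearance along the taxon index, so the key is
# invariant to any relabelling of states; the taxon footprint is part of the
# key, so sites with different gap footprints never compare equal.
split_key <- function(a, i, gap_policy = c("ignore_gaps", "gap_as_state")) {
  gap_policy <- match.arg(gap_policy)
  col <- a$mat[, i]
  idx <- seq_along(col)
  if (gap_policy == "ignore_gaps") {
    keep <- col != a$gap
    col <- col[keep]
    idx <- idx[keep]
  }
  if (!length(idx)) return("<empty>")
  gid <- match(col, unique(col))
  paste(idx, gid, sep = ":", collapse = ",")
}

#' Split pattern of an alignment site
#'
#' The partition of taxa induced by which state each taxon carries at a site.
#' Two sites with identical partitions convey the same grouping information
#' even when their actual characters differ, which is what drives the
#' duplicate-split deflation in \code{\link{dcite}}. Equality is invariant to
#' block order and to relabelling of states. Under \code{"ignore_gaps"} only
#' the gap-free taxa at the site are partitioned, so sites with different gap
#' footprints are never equal.
#'
#' @inheritParams site_counts
#' @return a list of class \code{"split_pattern"}: \code{site}, \code{blocks}
#'   (list of integer vectors of taxon indices) and \code{key} (canonical
#'   string; two patterns are equal iff their keys are identical).
#' @examples
#' a <- alignment(c(Tax1 = "abaca", Tax2 = "abaca", Tax3 = "aaaac",
#'                  Tax4 = "aacad"), alphabet_kind = "categorical")
#' identical(split_pattern(a, 2)$key, split_pattern(a, 4)$key)  # TRUE
#' @export
split_pattern <- function(a, i, gap_policy = c("ignore_gaps", "gap_as_state")) {
  gap_policy <- match.arg(gap_policy)
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > n_sites(a))
    stop("site index out of range: ", i, " (alignment has ", n_sites(a), " sites)")
  col <- a$mat[, i]
  idx <- seq_along(col)
  if (gap_policy == "ignore_gaps") {
    keep <- col != a$gap
    col <- col[keep]
    idx <- idx[keep]
  }
  blocks <- if (length(idx)) unname(split(idx, match(col, unique(col)))) else list()
  structure(list(site = as.integer(i), blocks = blocks,
                 key = split_key(a, i, gap_policy)),
            class = "split_pattern")
}

#' @export
print.split_pattern <- function(x, ...) {
  cat("Split pattern at site", x$site, ":",
      paste(vapply(x$blocks, function(b) paste0("{", paste(b, collapse = ","), "}"),
                   character(1)), collapse = " "), "\n")
  invisible(x)
}

# Subset an alignment to a set of taxa (by index or label), optionally
# dropping columns that become all-gap.
subset_taxa <- function(a, taxa, drop_allgap_sites = TRUE) {
  if (is.character(taxa)) taxa <- match(taxa, a$taxa)
  stopifnot(!anyNA(taxa), all(taxa >= 1L & taxa <= n_taxa(a)))
  a$mat <- a$mat[taxa, , drop = FALSE]
  a$taxa <- a$taxa[taxa]
  if (drop_allgap_sites && n_sites(a)) {
    allgap <- colSums(a$mat != a$gap) == 0L
    if (any(allgap)) a$mat <- a$mat[, !allgap, drop = FALSE]
  }
  a
}
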