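#' Configuration for entropy-based cladistic scoring
#'
#' @param min_state_count minimum number of instances a character state needs
#'   before it enters the entropy sum (default 2, the parsimony threshold:
#'   a state seen once cannot witness a split between two clades). Set to 1
#'   to include singleton states, as in the small worked examples.
#' @param gap_policy \code{"ignore_gaps"} (default; the gap carries no state
#'   information) or \code{"gap_as_state"} (gap counted as an extra state).
#' @param log_base base of the logarithm; 2 (default) scores in bits.
#' @param diversity_cap optional fraction in (0, 1]. When set, sites whose
#'   character diversity (see \code{\link{character_diversity}}) exceeds the
#'   cap are excluded from \code{\link{dcite}} — a guard against mutational
#'   saturation, where a site carrying most of the alphabet in near-equal
#'   proportions scores high entropy yet conveys little cladistic signal.
#'   0.75 corresponds to allowing at most 3 of 4 nucleotides.
#' @param denominator_mode how the proportions p_j are formed when singleton
#'   states are excluded: \code{"all_counted"} (default) divides each
#'   retained count by all counted residues at the site, so p_j is a true
#'   site-wide proportion; \code{"retained_only"} divides by the sum of
#'   retained counts, renormalising over the retained states. The two
#'   coincide when \code{min_state_count} is 1.
#' @return a list of class \code{"metric_config"}
#' @export
metric_config <- function(min_state_count = 2L,
                          gap_policy = c("ignore_gaps", "gap_as_state"),
                          log_base = 2,
                          diversity_cap = NULL,
                          denominator_mode = c("all_counted", "retained_only")) {
  gap_policy <- match.arg(gap_policy)
  denominator_mode <- match.arg(denominator_mode)
  if (!is.numeric(min_state_count) || min_state_count < 1)
    stop("min_state_count must be an integer >= 1")
  if (!is.null(diversity_cap) &&
      (!is.numeric(diversity_cap) || diversity_cap <= 0 || diversity_cap > 1))
    stop("diversity_cap must lie in (0, 1]")
  if (!is.numeric(log_base) || log_base <= 1)
    stop("log_base must be > 1")
  structure(list(min_state_count = as.integer(min_state_count),
                 gap_policy = gap_policy, log_base = log_base,
                 diversity_cap = diversity_cap,
                 denominator_mode = denominator_mode),
            class = "metric_config")
}

as_counts <- function(c) {
  if (inherits(c, "state_counts")) return(c)
  if (is.numeric(c) && !is.null(names(c)))
    return(structure(list(site = NA_integer_, counts = c, n_nongap = sum(c)),
                     class = "state_counts"))
  stop("expected a state_counts object or a named numeric vector of counts")
}

#' Entropy contribution of one site
#'
#' Shannon entropy of the state distribution at a site, restricted to states
#' with at least \code{min_state_count} instances:
#' \deqn{H_i = -\sum_{j=1}^{m_i} p_j \log_b p_j}
#' where the sum runs over the \eqn{m_i} retained states and \eqn{p_j} is
#' the proportion of the j-th state (denominator per
#' \code{denominator_mode}). Invariant sites contribute 0.
#'
#' @param c a \code{state_counts} object (from \code{\link{site_counts}}) or
#'   a named numeric vector of state counts.
#' @param cfg a \code{\link{metric_config}}
#' @return entropy in \code{log_base} units (bits by default)
#' @examples
#' site_entropy(c(a = 3, c = 1), metric_config(min_state_count = 1))  # 0.8113
#' @export
site_entropy <- function(c, cfg = metric_config()) {
  c <- as_counts(c)
  if (!length(c$counts)) stop("empty state counts at site ", c$site)
  retained <- c$counts[c$counts >= cfg$min_state_count]
  if (!length(retained)) return(0)
  denom <- switch(cfg$denominator_mode,
                  all_counted = sum(c$counts),
                  retained_only = sum(retained))
  p <- retained / denom
  -sum(p * log(p, base = cfg$log_base))
}

#' Raw CITE score of an alignment
#'
#' Cladistic Information based on Total Entropy: the sum of per-site entropy
#' contributions (\code{\link{site_entropy}}) over all sites, with no
#' deflation for duplicate taxa or duplicate split patterns. See
#' \code{\link{dcite}} for the deflated score.
#'
#' @param a a \code{cite_alignment}
#' @param cfg a \code{\link{metric_config}}
#' @return a list with \code{score} (total, in bits by default) and
#'   \code{per_site} (numeric vector of per-site contributions)
#' @examples
#' a <- alignment(c(Tax1 = "abaca", Tax2 = "abaca", Tax3 = "aaaac",
#'                  Tax4 = "aacad"), alphabet_kind = "categorical")
#' cite(a, metric_config(min_state_count = 1))$score  # 4.3113
#' @export
cite <- function(a, cfg = metric_config()) {
  stopifnot(inherits(a, "cite_alignment"))
  per_site <- vapply(seq_len(n_sites(a)), function(i) {
    sc <- site_counts(a, i, cfg$gap_policy)
    if (!length(sc$counts)) 0 else site_entropy(sc, cfg)
  }, numeric(1))
  list(score = sum(per_site), per_site = per_site)
}

#' Minimum parsimony-informative state changes
#'
#' \eqn{\Delta_{min}}: for each site, the number of character states present
#' in at least two taxa, minus one (floored at zero), summed over sites. A
#' site needs two such states before it can witness any split, so sites with
#' fewer contribute nothing. The \eqn{\ge 2} threshold is intrinsic to the
#' definition and is not affected by \code{cfg$min_state_count}.
#'
#' @inheritParams cite
#' @return integer total
#' @export
delta_min <- function(a, cfg = metric_config()) {
  stopifnot(inherits(a, "cite_alignment"))
  per_site <- vapply(seq_len(n_sites(a)), function(i) {
    r2 <- sum(site_counts(a, i, cfg$gap_policy)$counts >= 2L)
    max(0L, r2 - 1L)
  }, integer(1))
  sum(per_site)
}

alphabet_size <- function(a) {
  switch(a$alphabet_kind,
         nucleotide = 4L,
         protein = 20L,
         categorical = length(setdiff(unique(as.vector(a$mat)), a$gap)))
}

#' Character diversity per site
#'
#' For each variable site (two or more non-gap states), the number of states
#' divided by \code{min(non-gap taxa at the site, alphabet size)}. Diversity
#' near 1 means the site carries most of the reachable alphabet — a
#' site-specific proxy for mutational saturation. Invariant sites are
#' excluded from the statistics.
#'
#' @inheritParams cite
#' @return a list with \code{per_site} (data frame: site, n_states,
#'   n_nongap, diversity; variable sites only) and \code{summary} (list:
#'   mean, median, max, frac_le_0.5, n_variable, defined). When the
#'   alignment has no variable site, \code{per_site} is empty and
#'   \code{summary$defined} is \code{FALSE}.
#' @export
character_diversity <- function(a, cfg = metric_config()) {
  stopifnot(inherits(a, "cite_alignment"))
  asize <- alphabet_size(a)
  rows <- lapply(seq_len(n_sites(a)), function(i) {
    sc <- site_counts(a, i, "ignore_gaps")
    if (length(sc$counts) < 2L) return(NULL)
    data.frame(site = i, n_states = length(sc$counts), n_nongap = sc$n_nongap,
               diversity = length(sc$counts) / min(sc$n_nongap, asize))
  })
  per_site <- do.call(rbind, rows)
  if (is.null(per_site)) {
    per_site <- data.frame(site = integer(), n_states = integer(),
                           n_nongap = integer(), diversity = numeric())
    summary <- list(mean = NA_real_, median = NA_real_, max = NA_real_,
                    frac_le_0.5 = NA_real_, n_variable = 0L, defined = FALSE)
  } else {
    d <- per_site$diversity
    summary <- list(mean = mean(d), median = stats::median(d), max = max(d),
                    frac_le_0.5 = mean(d <= 0.5), n_variable = nrow(per_site),
                    defined = TRUE)
  }
  list(per_site = per_site, summary = summary)
}
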