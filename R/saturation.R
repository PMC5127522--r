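# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Taxon-addition saturation curve
#'
#' Emulates the incremental taxon-sampling design used to locate the point
#' where an alignment's cladistic information saturates: starting from a
#' random subset of \code{start} taxa, one further randomly chosen taxon is
#' added at a time and the full set of metrics is recomputed on each
#' sub-alignment. Sampling is uniform without replacement and entirely
#' governed by \code{seed}, so curves are reproducible bit-for-bit. Columns
#' that are all-gap within a subset are dropped before scoring.
#'
#' @param pool a \code{cite_alignment} holding the full taxon pool
#' @param start initial subset size (default 4)
#' @param stop final subset size (default: all taxa in the pool)
#' @param seed integer seed for the subset sampling
#' @param cfg a \code{\link{metric_config}}
#' @return a data frame of class \code{"saturation_curve"} with one row per
#'   subset size: \code{n_taxa}, \code{dcite}, \code{cite},
#'   \code{delta_min}, \code{total_cic}
#' @seealso \code{\link{plateau_point}}
#' @export
incremental_curve <- function(pool, start = 4L, stop = n_taxa(pool), seed = 1L,
                              cfg = metric_config()) {
  stopifnot(inherits(pool, "cite_alignment"))
  if (start < 2L) stop("start must be at least 2")
  if (stop > n_taxa(pool))
    stop("stop (", stop, ") exceeds the pool size (", n_taxa(pool), ")")
  if (stop < start) stop("stop must be >= start")
  order <- with_rng_seed(seed, sample(n_taxa(pool)))
  rows <- lapply(start:stop, function(k) {
    sub <- subset_taxa(pool, sort(order[seq_len(k)]))
    rep <- dcite(sub, cfg)
    data.frame(n_taxa = k, dcite = rep$dcite, cite = rep$cite,
               delta_min = rep$delta_min, total_cic = rep$total_cic)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Locate the saturation plateau of a dCITE curve
#'
#' Finds the smallest taxon count \eqn{\bar N} at which the curve has
#' levelled off: the first point such that the sum of absolute differences
#' between adjacent scores over the window starting there,
#' \deqn{\sum_{j=\bar N}^{\bar N + w} |s_{j+1} - s_j| \le \mathrm{tol},}
#' is within tolerance. With the defaults (window 15, tolerance 15 bits)
#' the window spans 16 adjacent-difference terms, so the curve must extend
#' at least \code{window + 2} points.
#'
#' @param curve a \code{saturation_curve} data frame (or any data frame with
#'   \code{n_taxa} and \code{dcite} columns), or a plain numeric vector of
#'   scores at consecutive taxon counts.
#' @param window number of additional counts ahead of the candidate over
#'   which flatness is summed (default 15)
#' @param tolerance maximum summed absolute change, in score units
#'   (default 15)
#' @return the plateau taxon count (position for a plain vector), or
#'   \code{NA} if the curve never flattens within reach of the window
#' @export
plateau_point <- function(curve, window = 15L, tolerance = 15) {
  if (is.data.frame(curve)) {
    stopifnot(all(c("n_taxa", "dcite") %in% names(curve)))
    score <- curve$dcite
    labels <- curve$n_taxa
  } else {
    score <- as.numeric(curve)
    labels <- seq_along(score)
  }
  np <- length(score)
  if (np < window + 2L)
    stop("curve too short: ", np, " points; the window needs at least ",
         window + 2L)
  d <- abs(diff(score))
  for (i in seq_len(np - window - 1L)) {
    if (sum(d[i:(i + window)]) <= tolerance) return(labels[i])
  }
  NA_integer_
}
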