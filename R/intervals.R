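#' Merge overlapping intervals to a single range
#'
#' The range-reduction engine of the pipeline: multiple overlapping
#' alignments of one sequence are reduced to a disjoint, sorted union.
#' Touching intervals (one ending where the next starts) are merged.
#' Coordinates are 0-based half-open. Reduction is delegated to
#' \code{IRanges::reduce}.
#'
#' @param start,end Numeric vectors of interval bounds; every
#'   \code{end} must exceed its \code{start}.
#' @return A \code{data.frame} with columns \code{start}, \code{end},
#'   sorted by \code{start}, pairwise disjoint and non-adjacent. The
#'   attribute \code{"total_bp"} carries the summed width.
#' @examples
#' mergeIntervals(c(0, 5, 30), c(10, 20, 40))
#' @export
mergeIntervals <- function(start, end = NULL) {
  if (is.null(end)) { end <- start[, 2]; start <- start[, 1] }
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (length(start) == 0L) {
    out <- data.frame(start = numeric(), end = numeric())
    attr(out, "total_bp") <- 0
    return(out)
  }
  if (any(end <= start)) stop("every interval must have end > start")
  out <- as_df0(IRanges::reduce(ir0(start, end)))
  attr(out, "total_bp") <- sum(out$end - out$start)
  out
}

#' Fraction of each sequence covered by merged alignments
#'
#' Per sequence, the merged covered bp divided by the sequence length;
#' the aggregate is total merged covered bp over total length of
#' \emph{all} sequences in \code{lengths} -- sequences without any
#' alignment contribute zero covered bp but their full length to the
#' denominator, as required for a genome-wide "total percent mapped"
#' statistic.
#'
#' @param x An \code{\linkS4class{AlignmentSet}}.
#' @param side \code{"query"} or \code{"reference"}: which side's
#'   coverage to compute.
#' @param lengths Named numeric vector of sequence lengths covering at
#'   least every sequence id appearing on the chosen side.
#' @return A list with \code{per_sequence} (named fractions in [0, 1])
#'   and \code{aggregate} (scalar fraction).
#' @examples
#' aln <- AlignmentSet(query_id = c("c", "c"), query_start = c(0, 25),
#'                     query_end = c(50, 75), ref_id = "r",
#'                     ref_start = c(0, 25), ref_end = c(50, 75),
#'                     identity_pct = 100)
#' coveredFraction(aln, "query", c(c = 100))$aggregate   # 0.75
#' @export
coveredFraction <- function(x, side = c("query", "reference"), lengths) {
  side <- match.arg(side)
  df <- as.data.frame(x)
  id <- if (side == "query") df$query_id else df$ref_id
  s <- if (side == "query") df$query_start else df$ref_start
  e <- if (side == "query") df$query_end else df$ref_end
  unknown <- setdiff(unique(id), names(lengths))
  if (length(unknown))
    stop("records reference unknown sequence(s): ",
         paste(unknown, collapse = ", "))
  covered <- stats::setNames(numeric(length(lengths)), names(lengths))
  if (length(id)) {
    cov_by_id <- vapply(split(data.frame(s, e), id),
                        function(d) merged_bp(d$s, d$e), numeric(1))
    covered[names(cov_by_id)] <- pmin(cov_by_id, lengths[names(cov_by_id)])
  }
  list(per_sequence = covered / lengths,
       aggregate = if (sum(lengths) > 0) sum(covered) / sum(lengths) else 0)
}

#' Alignment-length weighted mean identity
#'
#' The mean nucleotide identity over a set of alignments, weighting
#' each alignment by its aligned columns so that long alignments count
#' proportionally to the sequence they cover. An unweighted mean over
#' alignments would overweight short hits; that plain mean is exposed
#' separately by \code{\link{plainMeanIdentity}} so the difference
#' between the two conventions is measurable.
#'
#' @param x A nonempty \code{\linkS4class{AlignmentSet}}.
#' @return Percent identity in [0, 100], bounded by the minimum and
#'   maximum input identities.
#' @examples
#' aln <- AlignmentSet(query_id = c("a", "b"), query_start = 0,
#'                     query_end = c(100, 300), ref_id = "r",
#'                     ref_start = 0, ref_end = c(100, 300),
#'                     identity_pct = c(90, 98))
#' weightedIdentity(aln)   # 96
#' @export
weightedIdentity <- function(x) {
  df <- as.data.frame(x)
  if (nrow(df) == 0L)
    stop("weightedIdentity is undefined for an empty alignment set")
  sum(df$identity_pct * df$aligned_columns) / sum(df$aligned_columns)
}

#' @rdname weightedIdentity
#' @export
plainMeanIdentity <- function(x) {
  df <- as.data.frame(x)
  if (nrow(df) == 0L)
    stop("plainMeanIdentity is undefined for an empty alignment set")
  mean(df$identity_pct)
}

#' Bridge short gaps and count large regions
#'
#' Reproduces a repeat-masker style region statistic: gaps strictly
#' shorter than \code{max_gap} between merged regions are closed
#' ("stretches less than \code{max_gap} bp between repeats are also
#' masked", so a gap of exactly \code{max_gap} bp survives), then
#' bridged regions strictly longer than \code{min_region} are counted.
#'
#' @param regions A merged interval \code{data.frame} (columns
#'   \code{start}, \code{end}) as returned by
#'   \code{\link{mergeIntervals}}, or raw intervals (they are merged
#'   first).
#' @param max_gap Gaps < \code{max_gap} bp are closed (default 10).
#'   \code{max_gap = 0} is the identity on merged sets.
#' @param min_region Regions > \code{min_region} bp are counted
#'   (default 20000).
#' @return A list with \code{bridged} (interval \code{data.frame} with
#'   a \code{"total_bp"} attribute) and \code{n_large} (count of
#'   bridged regions longer than \code{min_region}).
#' @examples
#' bridgeAndCount(data.frame(start = c(0, 15005), end = c(15000, 26000)))
#' @export
bridgeAndCount <- function(regions, max_gap = 10, min_region = 20000) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  merged <- mergeIntervals(regions$start, regions$end)
  if (nrow(merged) == 0L)
    return(list(bridged = merged, n_large = 0L))
  r <- IRanges::reduce(ir0(merged$start, merged$end),
                       min.gapwidth = max(max_gap, 1))
  bridged <- as_df0(r)
  attr(bridged, "total_bp") <- sum(bridged$end - bridged$start)
  list(bridged = bridged,
       n_large = sum((bridged$end - bridged$start) > min_region))
}
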