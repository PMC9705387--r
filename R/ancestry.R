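# Core classifier: per-contig ancestry calls, recombinant detection,
# equal-contig disambiguation, depth partitioning and whole-genome
# comparison statistics.

# merged query-side coverage (IRanges, contig coordinates) of one contig
.contig_cov <- function(aln, contig_id) {
  df <- as.data.frame(aln)
  df <- df[df$query_id == contig_id, , drop = FALSE]
  if (nrow(df) == 0L) return(IRanges::IRanges())
  IRanges::reduce(ir0(df$query_start, df$query_end))
}

# Ancestor-exclusive coverage runs. Returns run extents tiling [0, length)
# plus per-run ancestry, or NULL when there is no exclusive evidence.
.exclusive_runs <- function(covA, covB, length, window_bp) {
  aonly <- BiocGenerics::setdiff(covA, covB)
  bonly <- BiocGenerics::setdiff(covB, covA)
  if (length(aonly) == 0L && length(bonly) == 0L) return(NULL)
  nwin <- ceiling(length / window_bp)
  tiles <- IRanges::IRanges(start = (seq_len(nwin) - 1L) * window_bp + 1L,
                            end = pmin(seq_len(nwin) * window_bp, length))
  win_bp <- function(excl) {
    v <- numeric(nwin)
    if (length(excl) == 0L) return(v)
    ov <- IRanges::findOverlaps(excl, tiles)
    w <- BiocGenerics::width(IRanges::pintersect(
      excl[S4Vectors::queryHits(ov)], tiles[S4Vectors::subjectHits(ov)]))
    tapply_idx <- S4Vectors::subjectHits(ov)
    for (k in seq_along(w)) v[tapply_idx[k]] <- v[tapply_idx[k]] + w[k]
    v
  }
  wa <- win_bp(aonly); wb <- win_bp(bonly)
  lab <- ifelse(wa > wb, "A", ifelse(wb > wa, "B", NA))
  ev <- which(!is.na(lab))
  if (!length(ev)) return(NULL)
  r <- rle(lab[ev])
  n_run <- length(r$values)
  last_idx <- cumsum(r$lengths)
  first_idx <- c(1L, last_idx[-n_run] + 1L)
  # evidence-window bp bounds of each run
  ev_start <- (ev[first_idx] - 1) * window_bp
  ev_end <- pmin(ev[last_idx] * window_bp, length)
  # extents: midpoints between adjacent runs' evidence, clamped to contig
  bound <- if (n_run > 1L)
    floor((ev_end[-n_run] + ev_start[-1]) / 2) else numeric(0)
  data.frame(ancestry = r$values,
             start = c(0, bound), end = c(bound, length))
}

# shared per-contig classification
.classify_contig <- function(covA, covB, length, params) {
  bp_a <- sum(BiocGenerics::width(covA))
  bp_b <- sum(BiocGenerics::width(covB))
  res <- list(bp_A = min(bp_a, length), bp_B = min(bp_b, length),
              category = "unaligned",
              segments = data.frame(start = numeric(), end = numeric(),
                                    ancestry = character()),
              breakpoints = numeric(0))
  if (max(bp_a, bp_b) / length < params@min_aligned_frac) return(res)
  aligned_len <- sum(BiocGenerics::width(BiocGenerics::union(covA, covB)))
  runs <- .exclusive_runs(covA, covB, length, params@window_bp)
  if (!is.null(runs)) {
    min_run <- max(params@recomb_min_segment_bp,
                   params@recomb_min_segment_frac * aligned_len)
    pass <- runs[(runs$end - runs$start) >= min_run, , drop = FALSE]
    if (nrow(pass) >= 2L && length(unique(pass$ancestry)) > 1L) {
      res$category <- "recombinant"
      res$segments <- pass[, c("start", "end", "ancestry")]
      alt <- which(pass$ancestry[-1] != pass$ancestry[-nrow(pass)])
      res$breakpoints <- floor((pass$end[alt] + pass$start[alt + 1]) / 2)
      return(res)
    }
  }
  ratio <- abs(bp_a - bp_b) / (bp_a + bp_b)
  if (ratio <= params@equal_tolerance) {
    res$category <- "equal"
  } else {
    anc <- if (bp_a > bp_b) "A" else "B"
    res$category <- paste0(anc, "_dominant")
    res$segments <- data.frame(start = 0, end = length, ancestry = anc)
  }
  res
}

#' Call the subgenome ancestry of a single contig
#'
#' Tallies the merged query-side bp aligned to each progenitor and
#' assigns one of five categories: \code{unaligned} when less than
#' \code{min_aligned_frac} of the contig aligns to either progenitor;
#' \code{recombinant} when the ancestor-exclusive coverage test of
#' \code{\link{detectRecombinant}} fires; \code{equal} when
#' |bp_A - bp_B| / (bp_A + bp_B) is within the equal tolerance; else
#' the dominant side.
#'
#' @param aln_A,aln_B \code{\linkS4class{AlignmentSet}}s of the contig
#'   against progenitor A and B (query-side coordinates on the contig).
#'   Records for other contigs raise an error.
#' @param contig_id The contig name.
#' @param length Contig length in bp.
#' @param params An \code{\linkS4class{AncestryParams}}.
#' @return A list with \code{bp_A}, \code{bp_B}, \code{category},
#'   \code{segments} (data.frame start/end/ancestry) and
#'   \code{breakpoints}.
#' @seealso \code{\link{callAncestry}} for whole-assembly calling.
#' @export
callContigAncestry <- function(aln_A, aln_B, contig_id, length,
                               params = ancestryParams()) {
  for (aln in list(aln_A, aln_B)) {
    ids <- unique(as.data.frame(aln)$query_id)
    if (length(ids) && !all(ids == contig_id))
      stop("alignment records for foreign contig(s): ",
           paste(setdiff(ids, contig_id), collapse = ", "))
  }
  .classify_contig(.contig_cov(aln_A, contig_id),
                   .contig_cov(aln_B, contig_id), length, params)
}

#' Detect recombination between subgenomes within one contig
#'
#' At high inter-progenitor identity most of a contig aligns to both
#' ancestors, so raw coverage cannot discriminate segments; detection
#' therefore uses ancestor-EXCLUSIVE coverage. The contig is tiled into
#' windows (\code{window_bp}); each window is labelled by the majority
#' of A-only versus B-only covered bp, windows without exclusive
#' evidence are absorbed into the flanking runs, and maximal
#' same-label runs are delimited at midpoints between adjacent runs'
#' evidence. The contig is recombinant iff at least two alternating
#' runs each span at least \code{max(recomb_min_segment_bp,
#' recomb_min_segment_frac * aligned bp)}; breakpoints are reported at
#' the midpoint of each transition.
#'
#' @inheritParams callContigAncestry
#' @return A list with \code{recombinant} (logical), \code{segments}
#'   and \code{breakpoints}.
#' @export
detectRecombinant <- function(aln_A, aln_B, contig_id, length,
                              params = ancestryParams()) {
  res <- callContigAncestry(aln_A, aln_B, contig_id, length, params)
  list(recombinant = res$category == "recombinant",
       segments = if (res$category == "recombinant") res$segments
                  else res$segments[0, ],
       breakpoints = res$breakpoints)
}

#' Call ancestry for every contig of an assembly
#'
#' Applies \code{\link{callContigAncestry}} across all contigs. Contigs
#' present in \code{contig_lengths} but absent from both alignment sets
#' are called \code{unaligned}.
#'
#' @param aln_A,aln_B \code{\linkS4class{AlignmentSet}}s of all contigs
#'   against progenitor A and B.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param params An \code{\linkS4class{AncestryParams}}.
#' @return An \code{\linkS4class{AncestryCalls}} object.
#' @examples
#' aln <- AlignmentSet(query_id = "c1", query_start = 0, query_end = 9e4,
#'                     ref_id = "chr1", ref_start = 0, ref_end = 9e4,
#'                     identity_pct = 100)
#' callTable(callAncestry(aln, AlignmentSet(), c(c1 = 1e5)))
#' @export
callAncestry <- function(aln_A, aln_B, contig_lengths,
                         params = ancestryParams()) {
  dfA <- as.data.frame(aln_A); dfB <- as.data.frame(aln_B)
  unknown <- setdiff(unique(c(dfA$query_id, dfB$query_id)),
                     names(contig_lengths))
  if (length(unknown))
    stop("alignments for contig(s) missing from contig_lengths: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  splitA <- split(dfA, dfA$query_id)
  splitB <- split(dfB, dfB$query_id)
  ids <- names(contig_lengths)
  if (!length(ids)) {
    empty <- DataFrame(contig_id = character(), length = numeric(),
                       bp_A = numeric(), bp_B = numeric(),
                       category = character(), n_breakpoints = integer(),
                       breakpoints = character(), disambiguated = logical())
    return(new("AncestryCalls", calls = empty,
               segments = data.frame(contig_id = character(),
                                     start = numeric(), end = numeric(),
                                     ancestry = character()),
               params = params))
  }
  rows <- vector("list", length(ids))
  segs <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    covA <- if (!is.null(splitA[[id]]))
      IRanges::reduce(ir0(splitA[[id]]$query_start,
                          splitA[[id]]$query_end)) else IRanges::IRanges()
    covB <- if (!is.null(splitB[[id]]))
      IRanges::reduce(ir0(splitB[[id]]$query_start,
                          splitB[[id]]$query_end)) else IRanges::IRanges()
    res <- .classify_contig(covA, covB, contig_lengths[[id]], params)
    rows[[k]] <- data.frame(
      contig_id = id, length = contig_lengths[[id]],
      bp_A = res$bp_A, bp_B = res$bp_B, category = res$category,
      n_breakpoints = length(res$breakpoints),
      breakpoints = paste(res$breakpoints, collapse = ","),
      disambiguated = FALSE)
    if (nrow(res$segments))
      segs[[k]] <- cbind(contig_id = id, res$segments)
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  new("AncestryCalls",
      calls = DataFrame(do.call(rbind, rows)),
      segments = if (length(segs)) do.call(rbind, segs) else
        data.frame(contig_id = character(), start = numeric(),
                   end = numeric(), ancestry = character()),
      params = params)
}

#' Disambiguate contigs that mapped equally to both progenitors
#'
#' Contigs called \code{equal} on the tally pass are re-examined on a
#' second alignment pass of different stringency (the two-pass design
#' mirrors running the mapper twice with different score settings; the
#' passes are deliberately named first/second rather than
#' strict/lenient). The tolerance test is recomputed on the second
#' pass's merged coverage; when it now fails, the contig is reassigned
#' to the dominant side and flagged \code{disambiguated}; otherwise it
#' stays \code{equal}. Stored bp tallies remain those of the first
#' (tally) pass. Equal contigs without second-pass records are kept
#' with a warning.
#'
#' @param calls An \code{\linkS4class{AncestryCalls}} from the first
#'   pass.
#' @param aln_A2,aln_B2 Second-pass \code{\linkS4class{AlignmentSet}}s.
#' @return The updated \code{\linkS4class{AncestryCalls}}.
#' @export
disambiguateEqual <- function(calls, aln_A2, aln_B2) {
  df <- calls@calls
  params <- calls@params
  eq <- which(df$category == "equal")
  if (!length(eq)) return(calls)
  dfA <- as.data.frame(aln_A2); dfB <- as.data.frame(aln_B2)
  missing_second <- character(0)
  for (k in eq) {
    id <- df$contig_id[k]
    a <- dfA[dfA$query_id == id, , drop = FALSE]
    b <- dfB[dfB$query_id == id, , drop = FALSE]
    if (nrow(a) == 0L && nrow(b) == 0L) {
      missing_second <- c(missing_second, id)
      next
    }
    bp_a2 <- merged_bp(a$query_start, a$query_end)
    bp_b2 <- merged_bp(b$query_start, b$query_end)
    if (bp_a2 + bp_b2 == 0) { missing_second <- c(missing_second, id); next }
    if (abs(bp_a2 - bp_b2) / (bp_a2 + bp_b2) > params@equal_tolerance) {
      df$category[k] <- if (bp_a2 > bp_b2) "A_dominant" else "B_dominant"
      df$disambiguated[k] <- TRUE
    }
  }
  if (length(missing_second))
    warning("no second-pass alignments for equal contig(s): ",
            paste(utils::head(missing_second, 5), collapse = ", "),
            "; kept as equal")
  initialize(calls, calls = df)
}

#' Per-category contig counts and bp totals
#'
#' The totals partition the assembly: summed category bp equals summed
#' contig lengths.
#'
#' @param calls An \code{\linkS4class{AncestryCalls}}.
#' @return A \code{data.frame} with one row per category (all five
#'   categories always present) and columns \code{category},
#'   \code{n_contigs}, \code{total_bp}.
#' @export
ancestryTotals <- function(calls) {
  df <- as.data.frame(calls@calls)
  lev <- c("A_dominant", "B_dominant", "equal", "recombinant", "unaligned")
  cat <- factor(df$category, levels = lev)
  data.frame(category = lev,
             n_contigs = as.integer(table(cat)),
             total_bp = as.numeric(tapply(df$length, cat, sum,
                                          default = 0)))
}

#' Chromosome-number normalised recombination ratio
#'
#' Compares recombinant-contig burdens between two assemblies with
#' different chromosome counts: the ratio of per-chromosome recombinant
#' rates, \code{(n1 / c1) / (n2 / c2)}. The statistic is scale
#' invariant (multiplying both counts of one assembly by a constant
#' leaves it unchanged) and swapping the assemblies gives the
#' reciprocal.
#'
#' @param n_recomb_1,n_recomb_2 Recombinant contig counts.
#' @param n_chrom_1,n_chrom_2 Chromosome counts (> 0).
#' @return The ratio of per-chromosome recombinant rates.
#' @examples
#' normalizedRecombRatio(6819, 56, 407, 10)   # about 3
#' @export
normalizedRecombRatio <- function(n_recomb_1, n_chrom_1,
                                  n_recomb_2, n_chrom_2) {
  if (n_chrom_1 <= 0 || n_chrom_2 <= 0)
    stop("chromosome counts must be > 0")
  (n_recomb_1 / n_chrom_1) / (n_recomb_2 / n_chrom_2)
}

#' Partition assembly bp into single- and multi-copy by read depth
#'
#' The genome-scale median is length-weighted (the lower weighted
#' median: the smallest depth at which the cumulative contig length
#' reaches half the assembly). A contig is multi-copy iff its depth
#' strictly exceeds \code{depth_multi_threshold} times that median;
#' ties at exactly the threshold are single copy. The two bp sums
#' partition the total assembly bp.
#'
#' @param depths A \code{data.frame} with columns \code{contig_id},
#'   \code{length}, \code{depth} (see \code{\link{readDepthTsv}}).
#' @param params An \code{\linkS4class{AncestryParams}} (only
#'   \code{depth_multi_threshold} is used).
#' @return A list with \code{median_depth}, \code{single_copy_bp},
#'   \code{multi_copy_bp}.
#' @examples
#' d <- data.frame(contig_id = c("a", "b", "c"), length = c(1, 1, 2) * 1e6,
#'                 depth = c(13, 13, 40))
#' depthPartition(d)
#' @export
depthPartition <- function(depths, params = ancestryParams()) {
  if (nrow(depths) == 0L) stop("empty depth table")
  if (any(depths$depth < 0)) stop("negative depth")
  o <- order(depths$depth)
  cum <- cumsum(depths$length[o])
  med <- depths$depth[o][min(which(cum >= sum(depths$length) / 2))]
  multi <- depths$depth > params@depth_multi_threshold * med
  list(median_depth = med,
       single_copy_bp = sum(depths$length[!multi]),
       multi_copy_bp = sum(depths$length[multi]))
}

#' Concordance of unplaced contigs with the chromosome painting
#'
#' Measures how much unplaced sequence aligns back onto the
#' pseudochromosomes and whether it carries the same ancestry as the
#' scaffolded sequence it lands on. The aligned fraction is merged
#' aligned unplaced bp over total unplaced bp. The concordance term
#' considers only positions where both the unplaced contig's call and
#' the painting at the target are a definite ancestry
#' (\code{A_dominant} or \code{B_dominant}); \code{equal},
#' \code{recombinant} and \code{unaligned} categories are excluded from
#' numerator and denominator.
#'
#' @param unplaced_calls \code{\linkS4class{AncestryCalls}} for the
#'   unplaced contigs.
#' @param alns \code{\linkS4class{AlignmentSet}} of unplaced contigs
#'   (query) against the pseudochromosomes (reference).
#' @param painting Painting blocks \code{data.frame} (columns
#'   \code{chrom}, \code{start}, \code{end}, \code{category}) as
#'   produced by \code{\link{buildPainting}}.
#' @return A list with \code{aligned_fraction} and
#'   \code{same_ancestry_fraction} (\code{NA} when no comparable
#'   aligned bp exists).
#' @export
unplacedConcordance <- function(unplaced_calls, alns, painting) {
  ct <- as.data.frame(unplaced_calls@calls)
  df <- as.data.frame(alns)
  total_bp <- sum(ct$length)
  if (nrow(df) == 0L)
    return(list(aligned_fraction = 0, same_ancestry_fraction = NA_real_))
  aligned_bp <- sum(vapply(split(df, df$query_id),
                           function(d) merged_bp(d$query_start,
                                                 d$query_end),
                           numeric(1)))
  # merged target footprints per contig, carrying the contig's category
  cat_of <- stats::setNames(ct$category, ct$contig_id)
  fp <- lapply(split(df, df$query_id), function(d) {
    g <- GenomicRanges::reduce(GenomicRanges::GRanges(
      d$ref_id, ir0(d$ref_start, d$ref_end)))
    S4Vectors::mcols(g)$category <- cat_of[[d$query_id[1]]]
    g
  })
  fp <- suppressWarnings(do.call(c, unname(fp)))
  paint <- GenomicRanges::GRanges(painting$chrom,
                                  ir0(painting$start, painting$end))
  S4Vectors::mcols(paint)$category <- painting$category
  keep_fp <- fp[S4Vectors::mcols(fp)$category %in%
                  c("A_dominant", "B_dominant")]
  keep_p <- paint[S4Vectors::mcols(paint)$category %in%
                    c("A_dominant", "B_dominant")]
  same <- 0; comparable <- 0
  if (length(keep_fp) && length(keep_p)) {
    ov <- GenomicRanges::findOverlaps(keep_fp, keep_p)
    w <- BiocGenerics::width(IRanges::pintersect(
      keep_fp[S4Vectors::queryHits(ov)],
      keep_p[S4Vectors::subjectHits(ov)]))
    match <- S4Vectors::mcols(keep_fp)$category[
      S4Vectors::queryHits(ov)] ==
      S4Vectors::mcols(keep_p)$category[S4Vectors::subjectHits(ov)]
    same <- sum(w[match]); comparable <- sum(w)
  }
  list(aligned_fraction = aligned_bp / total_bp,
       same_ancestry_fraction = if (comparable > 0) same / comparable
                                else NA_real_)
}

#' Whole-genome comparison report
#'
#' Composes the coverage and identity statistics of one genome aligned
#' against another into a single report: the fraction of the query
#' genome covered by merged alignments, the fraction of the reference
#' covered, the alignment-length weighted mean identity and the plain
#' (unweighted) mean identity.
#'
#' @param x An \code{\linkS4class{AlignmentSet}}.
#' @param query_lengths,ref_lengths Named numeric vectors of sequence
#'   lengths for the two genomes.
#' @return A list with \code{query_covered_fraction},
#'   \code{ref_covered_fraction}, \code{weighted_identity},
#'   \code{plain_mean_identity} (identities \code{NA} for an empty
#'   record set).
#' @export
compareGenomes <- function(x, query_lengths, ref_lengths) {
  if (length(x) == 0L)
    return(list(query_covered_fraction = 0, ref_covered_fraction = 0,
                weighted_identity = NA_real_,
                plain_mean_identity = NA_real_))
  list(query_covered_fraction =
         coveredFraction(x, "query", query_lengths)$aggregate,
       ref_covered_fraction =
         coveredFraction(x, "reference", ref_lengths)$aggregate,
       weighted_identity = weightedIdentity(x),
       plain_mean_identity = plainMeanIdentity(x))
}
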