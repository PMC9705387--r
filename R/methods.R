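#' @importFrom BiocGenerics start end width strand
NULL

#' @describeIn AlignmentSet-class number of alignment records.
#' @param x,object An \code{AlignmentSet}.
#' @export
setMethod("length", "AlignmentSet", function(x) nrow(x@records))

#' @describeIn AlignmentSet-class subset records.
#' @param i Row index.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "AlignmentSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i, , drop = FALSE])
})

#' @describeIn AlignmentSet-class records as a base data.frame.
#' @param row.names,optional Passed through.
#' @export
setMethod("as.data.frame", "AlignmentSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
  as.data.frame(x@records, row.names = row.names, optional = optional)
})

#' @describeIn AlignmentSet-class concatenate alignment sets.
#' @export
setMethod("c", "AlignmentSet", function(x, ...) {
  sets <- list(x, ...)
  initialize(x, records = do.call(rbind, lapply(sets, slot, "records")))
})

setMethod("show", "AlignmentSet", function(object) {
  df <- object@records
  cat("AlignmentSet with", nrow(df), "records\n")
  if (nrow(df)) {
    cat("  queries:", length(unique(df$query_id)),
        " references:", length(unique(df$ref_id)),
        " source:", paste(unique(df$source), collapse = ","), "\n")
    cat("  identity range:",
        sprintf("%.2f-%.2f", min(df$identity_pct), max(df$identity_pct)),
        "\n")
  }
})

#' Query-side or reference-side ranges of an AlignmentSet
#'
#' Returns the alignment footprints as a \code{GRanges} (1-based, as is
#' conventional for that container) on the query or reference sequences.
#'
#' @param x An \code{\linkS4class{AlignmentSet}}.
#' @return A \code{GRanges} with one range per record.
#' @examples
#' aln <- AlignmentSet(query_id = "ctg1", query_start = 0, query_end = 10,
#'                     ref_id = "chr1", ref_start = 5, ref_end = 15,
#'                     identity_pct = 100)
#' queryRanges(aln)
#' @export
queryRanges <- function(x) {
  df <- x@records
  GenomicRanges::GRanges(df$query_id, ir0(df$query_start, df$query_end),
                         strand = df$strand)
}

#' @rdname queryRanges
#' @export
refRanges <- function(x) {
  df <- x@records
  GenomicRanges::GRanges(df$ref_id, ir0(df$ref_start, df$ref_end),
                         strand = df$strand)
}

setMethod("show", "AncestryParams", function(object) {
  cat("AncestryParams:\n",
      " equal_tolerance:", object@equal_tolerance, "\n",
      " recomb_min_segment_frac:", object@recomb_min_segment_frac, "\n",
      " recomb_min_segment_bp:", object@recomb_min_segment_bp, "\n",
      " min_aligned_frac:", object@min_aligned_frac, "\n",
      " depth_multi_threshold:", object@depth_multi_threshold, "\n",
      " window_bp:", object@window_bp, "\n")
})

setMethod("show", "AncestryCalls", function(object) {
  df <- object@calls
  cat("AncestryCalls for", nrow(df), "contigs\n")
  if (nrow(df)) {
    tab <- table(factor(df$category,
                        levels = c("A_dominant", "B_dominant", "equal",
                                   "recombinant", "unaligned")))
    for (nm in names(tab)) cat(sprintf("  %-12s %d\n", nm, tab[[nm]]))
  }
})

#' @describeIn AncestryCalls-class number of contigs called.
#' @export
setMethod("length", "AncestryCalls", function(x) nrow(x@calls))

setMethod("show", "ProgenitorPair", function(object) {
  cat("ProgenitorPair:", length(object@genomeA), "chromosome segments,",
      sum(Biostrings::width(object@genomeA)), "bp\n")
  cat("  planted substitutions:", nrow(object@variants),
      sprintf("(rate %.4f)",
              nrow(object@variants) / sum(Biostrings::width(object@genomeA))),
      "\n")
  cat("  divergent islands:", nrow(object@islands), "\n")
})

setMethod("show", "HybridAssembly", function(object) {
  ct <- object@contigs
  cat("HybridAssembly:", nrow(ct), "contigs,", sum(ct$length), "bp\n")
  cat("  chimeric:", sum(ct$chimeric),
      " collapsed (copy number > 1):", sum(ct$copy_number > 1), "\n")
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams: genome", object@genome_length, "bp over",
      object@n_chromosomes, "chromosomes; divergence",
      object@divergence, "\n")
  cat("  contigs:", object@n_contigs, "of",
      object@contig_length_min, "-", object@contig_length_max, "bp;",
      "chimera fraction", object@chimera_fraction, "; seed",
      object@seed, "\n")
})

setMethod("show", "CorrectionModel", function(object) {
  cat("CorrectionModel: e =", object@error_rate,
      ", coverage A/B =", object@coverage_a, "/", object@coverage_b,
      ", margin =", object@margin, ", window =", object@window_bp, "bp\n")
})
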