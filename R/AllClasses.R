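#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.ALN_COLS <- c("query_id", "query_start", "query_end", "ref_id",
               "ref_start", "ref_end", "strand", "aligned_columns",
               "identity_pct", "score", "source", "record_type")

#' Container for pairwise alignment records
#'
#' An \code{AlignmentSet} holds one row per query-vs-reference alignment,
#' with all coordinates normalised to 0-based half-open intervals
#' regardless of the input dialect (show-coords and RepeatMasker inputs
#' are 1-based inclusive and converted at the boundary; PAF is already
#' 0-based half-open). Reversed query coordinates are stored as
#' \code{strand == "-"} with \code{query_start < query_end}.
#'
#' @slot records A \code{DataFrame} with columns \code{query_id},
#'   \code{query_start}, \code{query_end}, \code{ref_id},
#'   \code{ref_start}, \code{ref_end}, \code{strand} (\code{"+"} or
#'   \code{"-"}), \code{aligned_columns} (count of M/=/X/I/D alignment
#'   columns), \code{identity_pct} (percent in [0, 100]), \code{score}
#'   (aligner score, \code{NA} when absent), \code{source} (one of
#'   \code{"coords"}, \code{"paf"}, \code{"sam"}, \code{"truth"}) and
#'   \code{record_type} (\code{"primary"}, \code{"secondary"} or
#'   \code{"supplementary"}).
#'
#' @seealso \code{\link{readCoords}}, \code{\link{readPaf}},
#'   \code{\link{readSamAlignments}}, \code{\link{AlignmentSet}}
#' @export
setClass("AlignmentSet", slots = c(records = "DataFrame"))

setValidity("AlignmentSet", function(object) {
  df <- object@records
  missing_cols <- setdiff(.ALN_COLS, colnames(df))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(df$query_end <= df$query_start))
    return("query_end must be > query_start for every record")
  if (any(df$ref_end <= df$ref_start))
    return("ref_end must be > ref_start for every record")
  if (any(df$identity_pct < 0 | df$identity_pct > 100))
    return("identity_pct must lie in [0, 100]")
  if (!all(df$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  if (any(df$aligned_columns <= 0))
    return("aligned_columns must be positive")
  TRUE
})

#' Construct an AlignmentSet
#'
#' @param query_id,ref_id Character vectors of sequence names.
#' @param query_start,query_end,ref_start,ref_end Numeric vectors of
#'   0-based half-open coordinates.
#' @param strand \code{"+"} or \code{"-"} per record.
#' @param aligned_columns Number of M/=/X/I/D columns per record.
#' @param identity_pct Percent identity in [0, 100].
#' @param score Aligner score (\code{NA} when unavailable).
#' @param source Input dialect tag: \code{"coords"}, \code{"paf"},
#'   \code{"sam"} or \code{"truth"}.
#' @param record_type \code{"primary"}, \code{"secondary"} or
#'   \code{"supplementary"}.
#' @return An \code{\linkS4class{AlignmentSet}}.
#' @examples
#' AlignmentSet(query_id = "ctg1", query_start = 0, query_end = 100,
#'              ref_id = "chr1", ref_start = 500, ref_end = 600,
#'              identity_pct = 98.5)
#' @export
AlignmentSet <- function(query_id = character(), query_start = integer(),
                         query_end = integer(), ref_id = character(),
                         ref_start = integer(), ref_end = integer(),
                         strand = "+", aligned_columns = NULL,
                         identity_pct = numeric(), score = NA_real_,
                         source = "truth", record_type = "primary") {
  n <- length(query_id)
  if (is.null(aligned_columns))
    aligned_columns <- pmax(query_end - query_start, ref_end - ref_start)
  df <- DataFrame(query_id = as.character(query_id),
                  query_start = as.numeric(query_start),
                  query_end = as.numeric(query_end),
                  ref_id = as.character(ref_id),
                  ref_start = as.numeric(ref_start),
                  ref_end = as.numeric(ref_end),
                  strand = rep_len(as.character(strand), n),
                  aligned_columns = as.numeric(aligned_columns),
                  identity_pct = as.numeric(identity_pct),
                  score = rep_len(as.numeric(score), n),
                  source = rep_len(as.character(source), n),
                  record_type = rep_len(as.character(record_type), n))
  new("AlignmentSet", records = df)
}

# internal: build from a base data.frame with the canonical columns
.aln_from_df <- function(df) {
  do.call(AlignmentSet, as.list(df[.ALN_COLS]))
}

#' Parameters of the ancestry classifier
#'
#' Houses every threshold of the per-contig ancestry call. The
#' categories "mapped almost equally to both ancestors" and "mapped half
#' to one ancestor and half to the other" are only meaningful relative
#' to explicit tolerances, so all of them are configuration here.
#'
#' @slot equal_tolerance Fraction in [0, 1): a contig is called
#'   \code{equal} when |bp_A - bp_B| / (bp_A + bp_B) is at most this
#'   value. Default 0.10.
#' @slot recomb_min_segment_frac Minimum alternating-run size as a
#'   fraction of the contig's aligned bp. Default 0.20.
#' @slot recomb_min_segment_bp Minimum alternating-run size in bp.
#'   The effective minimum is the larger of the two. Default 10000.
#' @slot min_aligned_frac Minimum fraction of the contig length that
#'   must align to at least one progenitor for any call. Default 0.10.
#' @slot depth_multi_threshold Multiplier c on the length-weighted
#'   median depth; a contig is multi-copy iff depth > c * median.
#'   Default 1.5 (ties at exactly c * median are single copy).
#' @slot window_bp Window size for ancestor-exclusive coverage tallies
#'   in recombinant detection. Default 1000.
#' @export
setClass("AncestryParams",
         slots = c(equal_tolerance = "numeric",
                   recomb_min_segment_frac = "numeric",
                   recomb_min_segment_bp = "numeric",
                   min_aligned_frac = "numeric",
                   depth_multi_threshold = "numeric",
                   window_bp = "numeric"))

setValidity("AncestryParams", function(object) {
  t <- object@equal_tolerance
  if (t < 0 || t >= 1) return("equal_tolerance must be in [0, 1)")
  if (object@recomb_min_segment_frac < 0 ||
      object@recomb_min_segment_frac >= 1)
    return("recomb_min_segment_frac must be in [0, 1)")
  if (object@recomb_min_segment_bp < 0)
    return("recomb_min_segment_bp must be >= 0")
  if (object@min_aligned_frac < 0 || object@min_aligned_frac >= 1)
    return("min_aligned_frac must be in [0, 1)")
  if (object@depth_multi_threshold <= 0)
    return("depth_multi_threshold must be > 0")
  if (object@window_bp < 1) return("window_bp must be >= 1")
  TRUE
})

#' @param equal_tolerance,recomb_min_segment_frac,recomb_min_segment_bp
#'   See the class documentation.
#' @param min_aligned_frac,depth_multi_threshold,window_bp See the class
#'   documentation.
#' @return An \code{\linkS4class{AncestryParams}} object.
#' @rdname AncestryParams-class
#' @examples
#' ancestryParams(equal_tolerance = 0.05)
#' @export
ancestryParams <- function(equal_tolerance = 0.10,
                           recomb_min_segment_frac = 0.20,
                           recomb_min_segment_bp = 10000,
                           min_aligned_frac = 0.10,
                           depth_multi_threshold = 1.5,
                           window_bp = 1000) {
  new("AncestryParams",
      equal_tolerance = equal_tolerance,
      recomb_min_segment_frac = recomb_min_segment_frac,
      recomb_min_segment_bp = recomb_min_segment_bp,
      min_aligned_frac = min_aligned_frac,
      depth_multi_threshold = depth_multi_threshold,
      window_bp = window_bp)
}

#' Per-contig ancestry calls
#'
#' Result container of \code{\link{callAncestry}}. One row per contig
#' with its merged aligned bp against each progenitor, its category and
#' breakpoints; ancestry segments of recombinant (and dominant) contigs
#' are kept in a parallel table.
#'
#' @slot calls \code{DataFrame} with columns \code{contig_id},
#'   \code{length}, \code{bp_A}, \code{bp_B}, \code{category} (one of
#'   \code{A_dominant}, \code{B_dominant}, \code{equal},
#'   \code{recombinant}, \code{unaligned}), \code{n_breakpoints},
#'   \code{breakpoints} (comma-separated bp positions, "" when none)
#'   and \code{disambiguated}.
#' @slot segments \code{data.frame} with columns \code{contig_id},
#'   \code{start}, \code{end} (0-based half-open on the contig) and
#'   \code{ancestry} ("A" or "B").
#' @slot params The \code{\linkS4class{AncestryParams}} used.
#' @export
setClass("AncestryCalls",
         slots = c(calls = "DataFrame", segments = "data.frame",
                   params = "AncestryParams"))

setValidity("AncestryCalls", function(object) {
  df <- object@calls
  need <- c("contig_id", "length", "bp_A", "bp_B", "category",
            "n_breakpoints", "breakpoints", "disambiguated")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df) && any(df$bp_A > df$length | df$bp_B > df$length))
    return("bp_A and bp_B cannot exceed the contig length")
  ok <- c("A_dominant", "B_dominant", "equal", "recombinant", "unaligned")
  if (nrow(df) && !all(df$category %in% ok))
    return("invalid category value")
  TRUE
})

#' @describeIn AncestryCalls-class the call table as a base data.frame.
#' @param x,object An \code{AncestryCalls} object.
#' @export
callTable <- function(x) as.data.frame(x@calls)

#' @describeIn AncestryCalls-class the ancestry segment table.
#' @export
callSegments <- function(x) x@segments

#' Parameters of the synthetic hybrid-genome simulation
#'
#' Defines the study conditions for the no-download test bed: a pair of
#' progenitor genomes at a stated nucleotide divergence, a hybrid
#' assembly of pure and recombinant contigs with known breakpoints, and
#' collapsed-repeat depth inflation.
#'
#' @slot genome_length Total progenitor genome length in bp (default
#'   1e6), split over \code{n_chromosomes} chromosome segments.
#' @slot n_chromosomes Number of chromosome segments (default 5).
#' @slot divergence Genome-wide substitution fraction d between the two
#'   progenitors (default 0.057, i.e. 94.3 percent identity).
#' @slot indel_rate Indel rate between progenitors. Only 0 is
#'   supported: the substitution-only model keeps truth alignment
#'   coordinates exact.
#' @slot island_fraction Fraction of the genome lying in short
#'   "divergent islands" where the substitution rate is elevated
#'   (default 0.22). Islands emulate the indel/PAV-rich divergence of
#'   real genomes that fragments score-thresholded alignments; the
#'   genome-wide substitution fraction remains \code{divergence}.
#' @slot island_length Island length in bp (default 800).
#' @slot island_divergence_factor Multiplier on \code{divergence} inside
#'   islands (default 4.5). \code{island_fraction *
#'   island_divergence_factor} must be at most 1 so the background rate
#'   stays non-negative.
#' @slot n_contigs Number of assembly contigs (default 200).
#' @slot contig_length_min,contig_length_max Contig length range in bp
#'   (default 40000 to 160000).
#' @slot chimera_fraction Probability that a contig is chimeric
#'   (default 0.2).
#' @slot max_breakpoints Breakpoints per chimera are drawn uniformly
#'   from 1 to this value (default 3).
#' @slot min_segment_bp Minimum planted segment length (default 5000).
#' @slot collapsed_fraction Fraction of contigs planted with copy
#'   number 2 or 3 (default 0.1).
#' @slot base_depth Read depth of a single-copy contig (default 13).
#' @slot depth_noise_sd Standard deviation of integer depth noise
#'   (default 0).
#' @slot seed Mandatory RNG seed; identical parameters give
#'   byte-identical output.
#' @export
setClass("SimParams",
         slots = c(genome_length = "numeric", n_chromosomes = "numeric",
                   divergence = "numeric", indel_rate = "numeric",
                   island_fraction = "numeric", island_length = "numeric",
                   island_divergence_factor = "numeric",
                   n_contigs = "numeric", contig_length_min = "numeric",
                   contig_length_max = "numeric",
                   chimera_fraction = "numeric",
                   max_breakpoints = "numeric", min_segment_bp = "numeric",
                   collapsed_fraction = "numeric", base_depth = "numeric",
                   depth_noise_sd = "numeric", seed = "numeric"))

setValidity("SimParams", function(object) {
  if (object@genome_length < 1e4) return("genome_length must be >= 10 kb")
  if (object@n_chromosomes < 1) return("n_chromosomes must be >= 1")
  d <- object@divergence
  if (d < 0 || d >= 1) return("divergence must be in [0, 1)")
  if (object@indel_rate != 0)
    return("only indel_rate = 0 (substitution-only model) is supported")
  phi <- object@island_fraction
  if (phi < 0 || phi >= 1) return("island_fraction must be in [0, 1)")
  kap <- object@island_divergence_factor
  if (kap < 1) return("island_divergence_factor must be >= 1")
  if (phi * kap > 1)
    return("island_fraction * island_divergence_factor must be <= 1")
  if (d * kap >= 1)
    return("divergence * island_divergence_factor must be < 1")
  if (object@island_length < 1) return("island_length must be >= 1")
  if (object@n_contigs < 1) return("n_contigs must be >= 1")
  if (object@contig_length_min < 2 * object@min_segment_bp)
    return("contig_length_min must be >= 2 * min_segment_bp")
  if (object@contig_length_max < object@contig_length_min)
    return("contig_length_max must be >= contig_length_min")
  if (object@contig_length_max > object@genome_length / object@n_chromosomes)
    return("contig_length_max exceeds the chromosome length")
  for (nm in c("chimera_fraction", "collapsed_fraction")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) return(paste(nm, "must be in [0, 1]"))
  }
  if (object@max_breakpoints < 1) return("max_breakpoints must be >= 1")
  if (object@base_depth <= 0) return("base_depth must be > 0")
  if (object@depth_noise_sd < 0) return("depth_noise_sd must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a single non-missing seed is mandatory")
  TRUE
})

#' @param genome_length,n_chromosomes,divergence,indel_rate See the
#'   class documentation.
#' @param island_fraction,island_length,island_divergence_factor See the
#'   class documentation.
#' @param n_contigs,contig_length_min,contig_length_max See the class
#'   documentation.
#' @param chimera_fraction,max_breakpoints,min_segment_bp See the class
#'   documentation.
#' @param collapsed_fraction,base_depth,depth_noise_sd,seed See the
#'   class documentation.
#' @return A \code{\linkS4class{SimParams}} object.
#' @rdname SimParams-class
#' @examples
#' simParams(seed = 1, genome_length = 2e5, n_contigs = 40)
#' @export
simParams <- function(seed, genome_length = 1e6, n_chromosomes = 5,
                      divergence = 0.057, indel_rate = 0,
                      island_fraction = 0.22, island_length = 800,
                      island_divergence_factor = 4.5,
                      n_contigs = 200, contig_length_min = 40000,
                      contig_length_max = 160000, chimera_fraction = 0.2,
                      max_breakpoints = 3, min_segment_bp = 5000,
                      collapsed_fraction = 0.1, base_depth = 13,
                      depth_noise_sd = 0) {
  if (missing(seed)) stop("'seed' is mandatory: no unseeded randomness")
  new("SimParams", genome_length = genome_length,
      n_chromosomes = n_chromosomes, divergence = divergence,
      indel_rate = indel_rate, island_fraction = island_fraction,
      island_length = island_length,
      island_divergence_factor = island_divergence_factor,
      n_contigs = n_contigs, contig_length_min = contig_length_min,
      contig_length_max = contig_length_max,
      chimera_fraction = chimera_fraction,
      max_breakpoints = max_breakpoints, min_segment_bp = min_segment_bp,
      collapsed_fraction = collapsed_fraction, base_depth = base_depth,
      depth_noise_sd = depth_noise_sd, seed = seed)
}

#' A simulated progenitor genome pair
#'
#' Result of \code{\link{simulateProgenitors}}: genome B is derived from
#' genome A by planted substitutions whose genome-wide rate equals the
#' requested divergence, with part of the divergence budget concentrated
#' in short divergent islands (see \code{\linkS4class{SimParams}}).
#'
#' @slot genomeA,genomeB \code{DNAStringSet} of chromosome segments
#'   (identical names in both genomes; coordinates are directly
#'   comparable because the model is substitution-only).
#' @slot variants \code{data.frame} of planted substitutions:
#'   \code{chrom}, \code{pos} (0-based), \code{base_a}, \code{base_b},
#'   \code{island} (logical).
#' @slot islands \code{data.frame} of island locations: \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{divergence}.
#' @slot params The \code{\linkS4class{SimParams}} used.
#' @export
setClass("ProgenitorPair",
         slots = c(genomeA = "DNAStringSet", genomeB = "DNAStringSet",
                   variants = "data.frame", islands = "data.frame",
                   params = "SimParams"))

#' A simulated hybrid assembly with known ancestry
#'
#' Result of \code{\link{simulateHybridAssembly}}: the truth table for
#' all recovery experiments. Segments of each contig tile [0, length)
#' exactly; a contig is chimeric iff it has at least two segments of
#' differing ancestry.
#'
#' @slot contigs \code{data.frame}: \code{contig_id}, \code{length},
#'   \code{chimeric} (logical), \code{copy_number} (integer >= 1).
#' @slot segments \code{data.frame}: \code{contig_id}, \code{start},
#'   \code{end} (0-based half-open on the contig), \code{ancestry}
#'   ("A"/"B"), \code{src_chrom}, \code{src_start}, \code{src_end}
#'   (source interval on the progenitor chromosome).
#' @slot params The \code{\linkS4class{SimParams}} used.
#' @export
setClass("HybridAssembly",
         slots = c(contigs = "data.frame", segments = "data.frame",
                   params = "SimParams"))

setValidity("HybridAssembly", function(object) {
  seg <- object@segments
  if (nrow(seg)) {
    bad <- vapply(split(seg, seg$contig_id), function(s) {
      s <- s[order(s$start), ]
      any(s$start[-1] != s$end[-nrow(s)]) || s$start[1] != 0
    }, logical(1))
    if (any(bad)) return("segments must tile [0, length) exactly")
  }
  TRUE
})

#' @describeIn HybridAssembly-class the per-contig truth table.
#' @param x An \code{HybridAssembly}.
#' @export
truthContigs <- function(x) x@contigs

#' @describeIn HybridAssembly-class the planted ancestry segments.
#' @export
truthSegments <- function(x) x@segments

#' Minimal consensus long-read correction model
#'
#' Quantifies the mechanism by which consensus correction of noisy long
#' reads chimerises subgenomes: when the long-read error rate exceeds
#' the divergence between the subgenomes, short reads from the wrong
#' subgenome pass the identity recruitment filter and can out-vote the
#' correct allele. This is a deliberately minimal majority-vote model of
#' that verbal mechanism, not a reimplementation of any assembler's
#' correction stage.
#'
#' @slot error_rate Long-read error rate e in [0, 0.5). The recruitment
#'   identity threshold is 1 - e - margin; short-read errors occur at
#'   e / 10.
#' @slot coverage_a,coverage_b Number of short reads from subgenome A
#'   (the long read's own subgenome) and from subgenome B overlapping a
#'   diagnostic site. Defaults 8 and 8: at a conserved locus of a
#'   high-ploidy hybrid, reads from all homoeologous copies are
#'   recruited, so the two pools are comparable.
#' @slot margin Recruitment slack m added to the error allowance
#'   (default 0.05).
#' @slot window_bp Recruitment window length in bp (default 20).
#' @slot seed RNG seed for the Monte-Carlo mode.
#' @export
setClass("CorrectionModel",
         slots = c(error_rate = "numeric", coverage_a = "numeric",
                   coverage_b = "numeric", margin = "numeric",
                   window_bp = "numeric", seed = "numeric"))

setValidity("CorrectionModel", function(object) {
  e <- object@error_rate
  if (e < 0 || e >= 0.5) return("error_rate must be in [0, 0.5)")
  if (object@coverage_a < 0 || object@coverage_b < 0)
    return("coverages must be >= 0")
  if (object@margin < 0 || object@margin >= 1)
    return("margin must be in [0, 1)")
  if (object@window_bp < 1) return("window_bp must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a single non-missing seed is mandatory")
  TRUE
})

#' @param error_rate,coverage_a,coverage_b,margin,window_bp,seed See the
#'   class documentation.
#' @return A \code{\linkS4class{CorrectionModel}} object.
#' @rdname CorrectionModel-class
#' @examples
#' correctionModel(seed = 1, error_rate = 0.12)
#' @export
correctionModel <- function(seed, error_rate = 0.12, coverage_a = 8,
                            coverage_b = 8, margin = 0.05,
                            window_bp = 20) {
  if (missing(seed)) stop("'seed' is mandatory: no unseeded randomness")
  new("CorrectionModel", error_rate = error_rate, coverage_a = coverage_a,
      coverage_b = coverage_b, margin = margin, window_bp = window_bp,
      seed = seed)
}
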