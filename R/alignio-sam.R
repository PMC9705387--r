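#' Read alignments from a SAM text stream
#'
#' Extracts per-record query and reference ranges from the CIGAR string
#' of each mapped SAM record. The query range is the CIGAR
#' query-consuming span (M/I/=/X) excluding soft and hard clips, so a
#' record with CIGAR \code{10S40M5D30M20S} at 1-based POS 100 yields
#' query [10, 80) and reference [99, 174). \code{aligned_columns}
#' counts M/=/X + I + D columns. Identity is
#' \code{100 * (aligned_columns - NM) / aligned_columns} when the NM tag
#' is present, otherwise \code{100 * (=) / ((=) + X + I + D)} when the
#' CIGAR uses =/X operators; a record with neither raises an error
#' naming it. Hard clips are treated like soft clips for the query
#' offset, so clipped coordinates refer to the full-length query.
#'
#' Secondary (flag 0x100) and supplementary (0x800) records are
#' retained and tagged in the \code{record_type} column: the range-union
#' ancestry method requires multi-hit retention. Unmapped records are
#' skipped silently; mapped records with CIGAR \code{"*"} are skipped
#' with a warning.
#'
#' @param file Path to (or connection on) SAM text.
#' @param min_score Optional minimum AS (alignment score) tag value,
#'   mirroring a mapper's minimum output score threshold. When set,
#'   records lacking an AS tag raise an error rather than silently
#'   passing.
#' @return An \code{\linkS4class{AlignmentSet}} with
#'   \code{source == "sam"}.
#' @examples
#' f <- tempfile()
#' writeLines(c("@SQ\tSN:chr1\tLN:1000",
#'   "r1\t0\tchr1\t100\t60\t10S40M5D30M20S\t*\t0\t0\t*\t*\tNM:i:5"), f)
#' as.data.frame(readSamAlignments(f))
#' @export
readSamAlignments <- function(file, min_score = NULL) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(AlignmentSet())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 11L))
    stop("malformed SAM record at data line ", which(n_fields < 11L)[1])

  qname <- vapply(fields, `[`, "", 1L)
  flag  <- as.integer(vapply(fields, `[`, "", 2L))
  rname <- vapply(fields, `[`, "", 3L)
  pos   <- as.numeric(vapply(fields, `[`, "", 4L))
  cigar <- vapply(fields, `[`, "", 6L)

  tagval <- function(f, tag) {
    if (length(f) < 12L) return(NA_real_)
    hit <- grep(paste0("^", tag, ":i:"), f[12:length(f)], value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(sub(paste0(tag, ":i:"), "", hit[1]))
  }
  nm <- vapply(fields, tagval, numeric(1), tag = "NM")
  as_score <- vapply(fields, tagval, numeric(1), tag = "AS")

  mapped <- bitwAnd(flag, 4L) == 0L
  star <- cigar == "*" & mapped
  if (any(star))
    warning(sum(star), " mapped record(s) with CIGAR '*' skipped")
  keep <- mapped & !star
  if (!any(keep)) return(AlignmentSet())

  idx <- which(keep)
  ops  <- GenomicAlignments::explodeCigarOps(cigar[idx])
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar[idx])

  one <- function(k) {
    o <- ops[[k]]; l <- lens[[k]]; i <- idx[k]
    clip_lead <- 0
    j <- 1L
    while (j <= length(o) && o[j] %in% c("S", "H")) {
      clip_lead <- clip_lead + l[j]; j <- j + 1L
    }
    qcons <- sum(l[o %in% c("M", "I", "=", "X")])
    rcons <- sum(l[o %in% c("M", "D", "N", "=", "X")])
    ac <- sum(l[o %in% c("M", "=", "X", "I", "D")])
    if (!is.na(nm[i])) {
      ident <- 100 * (ac - nm[i]) / ac
    } else if (any(o %in% c("=", "X"))) {
      eq <- sum(l[o == "="])
      ident <- 100 * eq / (eq + sum(l[o == "X"]) +
                             sum(l[o %in% c("I", "D")]))
    } else {
      stop("record '", qname[i],
           "': neither NM tag nor =/X operators; identity undefined")
    }
    rt <- if (bitwAnd(flag[i], 2048L)) "supplementary"
          else if (bitwAnd(flag[i], 256L)) "secondary" else "primary"
    data.frame(query_id = qname[i], query_start = clip_lead,
               query_end = clip_lead + qcons, ref_id = rname[i],
               ref_start = pos[i] - 1, ref_end = pos[i] - 1 + rcons,
               strand = if (bitwAnd(flag[i], 16L)) "-" else "+",
               aligned_columns = ac, identity_pct = ident,
               score = as_score[i], source = "sam", record_type = rt)
  }
  df <- do.call(rbind, lapply(seq_along(idx), one))

  if (!is.null(min_score)) {
    if (anyNA(df$score))
      stop("min_score given but AS tag absent for record(s): ",
           paste(unique(df$query_id[is.na(df$score)]), collapse = ", "))
    df <- df[df$score >= min_score, , drop = FALSE]
  }
  .aln_from_df(df)
}
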