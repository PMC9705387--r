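#' Read PAF alignments
#'
#' PAF is accepted as an equivalent alignment carrier to show-coords
#' output: coordinates are already 0-based half-open and are passed
#' through. Identity is \code{100 * residue_matches / block_length}
#' (columns 10 and 11) and \code{aligned_columns} is the block length.
#' An \code{AS:i:} tag, when present, populates \code{score}.
#'
#' @param file Path to (or connection on) PAF text.
#' @param min_score Optional minimum AS tag value; when set, records
#'   lacking the tag raise an error.
#' @return An \code{\linkS4class{AlignmentSet}} with
#'   \code{source == "paf"}.
#' @seealso \code{\link{writePaf}}, \code{\link{readCoords}}
#' @export
readPaf <- function(file, min_score = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(AlignmentSet())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 12L
  if (any(short))
    stop("malformed PAF line ", which(short)[1], ": fewer than 12 columns")
  get <- function(i) vapply(fields, `[`, "", i)
  num <- function(i) as.numeric(get(i))
  score <- vapply(fields, function(f) {
    hit <- grep("^AS:i:", f[-(1:12)], value = TRUE)
    if (length(hit)) as.numeric(sub("AS:i:", "", hit[1])) else NA_real_
  }, numeric(1))
  df <- data.frame(query_id = get(1), query_start = num(3),
                   query_end = num(4), ref_id = get(6),
                   ref_start = num(8), ref_end = num(9),
                   strand = get(5), aligned_columns = num(11),
                   identity_pct = 100 * num(10) / num(11),
                   score = score, source = "paf",
                   record_type = "primary")
  if (!is.null(min_score)) {
    if (anyNA(df$score))
      stop("min_score given but AS tag absent for record(s): ",
           paste(unique(df$query_id[is.na(df$score)]), collapse = ", "))
    df <- df[df$score >= min_score, , drop = FALSE]
  }
  .aln_from_df(df)
}

#' Write alignments as PAF
#'
#' Residue matches are reconstructed as
#' \code{round(identity_pct / 100 * aligned_columns)} and the block
#' length is \code{aligned_columns}, so records whose identity was
#' computed from an integer mismatch count round-trip exactly.
#'
#' @param x An \code{\linkS4class{AlignmentSet}}.
#' @param file Output path or connection.
#' @param query_lengths,ref_lengths Named numeric vectors giving the
#'   full sequence lengths for PAF columns 2 and 7.
#' @return Invisibly, \code{file}.
#' @export
writePaf <- function(x, file, query_lengths, ref_lengths) {
  df <- as.data.frame(x)
  miss_q <- setdiff(unique(df$query_id), names(query_lengths))
  miss_r <- setdiff(unique(df$ref_id), names(ref_lengths))
  if (length(miss_q) || length(miss_r))
    stop("lengths missing for: ",
         paste(c(miss_q, miss_r), collapse = ", "))
  matches <- round(df$identity_pct / 100 * df$aligned_columns)
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   df$query_id,
                   as.integer(query_lengths[df$query_id]),
                   as.integer(df$query_start), as.integer(df$query_end),
                   df$strand, df$ref_id,
                   as.integer(ref_lengths[df$ref_id]),
                   as.integer(df$ref_start), as.integer(df$ref_end),
                   as.integer(matches), as.integer(df$aligned_columns),
                   60L)
  writeLines(lines, file)
  invisible(file)
}
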