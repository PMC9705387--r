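#' Read MUMmer show-coords tabular output
#'
#' Parses the tabular listing produced by MUMmer's show-coords: columns
#' S1 E1 S2 E2 LEN1 LEN2 \%IDY followed by the reference and query
#' sequence tags (both the pipe-decorated default layout and the
#' tab-separated \code{-T} layout are accepted; \code{"|"} and
#' \code{"="} ruler tokens are ignored). Input coordinates are 1-based
#' inclusive and converted to the package's 0-based half-open
#' convention; reversed query coordinates (S2 > E2) become
#' \code{strand == "-"} with start < end. \code{aligned_columns} is set
#' to \code{max(LEN1, LEN2)}.
#'
#' Header lines (file names, "NUCMER", the column caption) are
#' tolerated before the first data line; after data has started, any
#' malformed line raises an error naming its line number. Reference
#' coordinates with E1 < S1 are rejected: that dialect is not emitted
#' by show-coords and almost always indicates a column mix-up.
#'
#' @param file Path to (or connection on) a show-coords listing.
#' @return An \code{\linkS4class{AlignmentSet}} with
#'   \code{source == "coords"}.
#' @seealso \code{\link{writeCoords}}, \code{\link{readPaf}}
#' @examples
#' f <- tempfile()
#' writeLines("101 200 51 150 100 100 95.00 refA ctg1", f)
#' as.data.frame(readCoords(f))
#' @export
readCoords <- function(file) {
  lines <- readLines(file)
  out <- vector("list", length(lines))
  seen_data <- FALSE
  for (i in seq_along(lines)) {
    toks <- strsplit(gsub("[|]", " ", lines[i]), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L || grepl("^=+$", toks[1])) next
    numeric_lead <- !is.na(suppressWarnings(as.numeric(toks[1])))
    if (!numeric_lead) {
      if (!seen_data) next           # header region
      stop("malformed coords line ", i, ": ", lines[i])
    }
    if (length(toks) < 9L)
      stop("malformed coords line ", i, ": expected >= 9 fields, got ",
           length(toks))
    vals <- suppressWarnings(as.numeric(toks[1:7]))
    if (anyNA(vals))
      stop("malformed coords line ", i, ": non-numeric coordinate field")
    seen_data <- TRUE
    s1 <- vals[1]; e1 <- vals[2]; s2 <- vals[3]; e2 <- vals[4]
    if (e1 < s1)
      stop("coords line ", i, ": E1 < S1 on the reference; ",
           "this dialect is not supported")
    if (s2 <= e2) {
      qs <- s2 - 1; qe <- e2; strand <- "+"
    } else {
      qs <- e2 - 1; qe <- s2; strand <- "-"
    }
    out[[i]] <- data.frame(
      query_id = toks[length(toks)], query_start = qs, query_end = qe,
      ref_id = toks[length(toks) - 1L], ref_start = s1 - 1, ref_end = e1,
      strand = strand, aligned_columns = max(vals[5], vals[6]),
      identity_pct = vals[7], score = NA_real_, source = "coords",
      record_type = "primary")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(AlignmentSet())
  .aln_from_df(do.call(rbind, out))
}

#' Write alignments as a show-coords style listing
#'
#' Serialises an \code{\linkS4class{AlignmentSet}} in the tabular
#' S1 E1 S2 E2 LEN1 LEN2 \%IDY ref query layout read back by
#' \code{\link{readCoords}} (1-based inclusive coordinates, query
#' coordinates reversed on the minus strand). Identity is printed with
#' four decimals so that exact truth identities round-trip; output is
#' byte-stable given identical record order.
#'
#' @param x An \code{\linkS4class{AlignmentSet}}.
#' @param file Output path or connection.
#' @return Invisibly, \code{file}.
#' @export
writeCoords <- function(x, file) {
  df <- as.data.frame(x)
  s2 <- ifelse(df$strand == "+", df$query_start + 1, df$query_end)
  e2 <- ifelse(df$strand == "+", df$query_end, df$query_start + 1)
  lines <- sprintf("%d %d %d %d %d %d %.4f %s %s",
                   as.integer(df$ref_start + 1), as.integer(df$ref_end),
                   as.integer(s2), as.integer(e2),
                   as.integer(df$ref_end - df$ref_start),
                   as.integer(df$query_end - df$query_start),
                   df$identity_pct, df$ref_id, df$query_id)
  writeLines(lines, file)
  invisible(file)
}
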