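#' Read RepeatMasker .out annotations
#'
#' Parses the standard RepeatMasker .out layout (two caption lines and a
#' blank line, then one annotation row per repeat hit). The class/family
#' column (column 11) is preserved verbatim; the 1-based inclusive
#' query coordinates (columns 6 and 7) are converted to 0-based
#' half-open.
#'
#' @param file Path to (or connection on) a RepeatMasker .out file.
#' @return A \code{data.frame} with columns \code{repeat_class},
#'   \code{target_id}, \code{start}, \code{end}.
#' @examples
#' f <- tempfile()
#' writeLines(c("   SW  perc ...", "score  div ...", "",
#'  "  239 12.1 0.0 0.0 chr1 101 200 (800) + rnd-1 LTR/Gypsy 1 100 (0) 1"),
#'  f)
#' readRepeatMaskerOut(f)
#' @export
readRepeatMaskerOut <- function(file) {
  lines <- readLines(file)
  out <- vector("list", length(lines))
  seen_data <- FALSE
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) next
    numeric_lead <- !is.na(suppressWarnings(as.numeric(toks[1])))
    if (!numeric_lead) {
      if (!seen_data) next           # the three header lines
      stop("malformed RepeatMasker line ", i, ": ", lines[i])
    }
    if (length(toks) < 11L)
      stop("malformed RepeatMasker line ", i,
           ": expected >= 11 fields, got ", length(toks))
    b <- suppressWarnings(as.numeric(toks[6]))
    e <- suppressWarnings(as.numeric(toks[7]))
    if (is.na(b) || is.na(e) || e < b)
      stop("malformed RepeatMasker line ", i, ": bad coordinates")
    seen_data <- TRUE
    out[[i]] <- data.frame(repeat_class = toks[11], target_id = toks[5],
                           start = b - 1, end = e)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(repeat_class = character(), target_id = character(),
                      start = numeric(), end = numeric()))
  do.call(rbind, out)
}

#' Read sequence lengths from a FASTA file
#'
#' @param file Path to a FASTA file.
#' @return Named numeric vector of sequence lengths (bp), names taken
#'   from the first word of each header.
#' @export
readFastaLengths <- function(file) {
  lens <- Biostrings::fasta.seqlengths(file)
  names(lens) <- sub("\\s.*$", "", names(lens))
  if (anyDuplicated(names(lens))) stop("duplicate sequence ids in FASTA")
  if (any(lens <= 0)) stop("zero-length sequence in FASTA")
  lens
}

#' Write a painting track as BED9
#'
#' Emits 0-based half-open BED with the itemRgb column carrying the
#' ancestry palette colour, suitable for genome-browser display of the
#' chromosome paintings. Output is byte-stable given identical block
#' order.
#'
#' @param blocks A \code{data.frame} with columns \code{chrom},
#'   \code{start}, \code{end}, \code{name} (or \code{contig_id}) and
#'   \code{category}; see \code{\link{buildPainting}}.
#' @param file Output path or connection.
#' @return Invisibly, \code{file}.
#' @export
writeBed9 <- function(blocks, file) {
  name <- if ("name" %in% colnames(blocks)) blocks$name
          else blocks$contig_id
  rgb <- paintingPalette(as_rgb = TRUE)[blocks$category]
  if (anyNA(rgb)) stop("unknown category in painting blocks")
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%d\t%d\t%s",
                   blocks$chrom, as.integer(blocks$start),
                   as.integer(blocks$end), name,
                   as.integer(blocks$start), as.integer(blocks$end), rgb)
  writeLines(lines, file)
  invisible(file)
}

#' Write a report table as TSV
#'
#' Plain tab-separated serialisation without quoting or row names:
#' byte-stable given identical input order.
#'
#' @param x A \code{data.frame} (or an object with an
#'   \code{as.data.frame} method, e.g. \code{AncestryCalls} call
#'   tables).
#' @param file Output path or connection.
#' @return Invisibly, \code{file}.
#' @export
writeTsv <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read and write per-contig depth tables
#'
#' The depth TSV carries one row per contig with its length and median
#' mapped-read depth, the input of \code{\link{depthPartition}}.
#'
#' @param file Path or connection.
#' @return \code{readDepthTsv}: a \code{data.frame} with columns
#'   \code{contig_id}, \code{length}, \code{depth}.
#' @export
readDepthTsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("contig_id", "length", "depth")
  if (!all(need %in% colnames(df)))
    stop("depth TSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$depth < 0)) stop("negative depth")
  df
}

#' @param x A depth \code{data.frame}.
#' @rdname readDepthTsv
#' @export
writeDepthTsv <- function(x, file) writeTsv(x, file)
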