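#' Read AGP v2.1 placements
#'
#' Parses the component-placement format describing how contigs tile
#' pseudochromosomes. Component types W (WGS contig), N and U (gaps)
#' are recognised; any other component type raises an error. Object
#' coordinates are validated to be non-overlapping and, for W lines,
#' the object span must equal the component span (no scaling). Output
#' coordinates are 0-based half-open.
#'
#' @param file Path to (or connection on) an AGP file. Lines starting
#'   with \code{#} are comments.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{part_number}, \code{component_type},
#'   \code{component_id} (\code{NA} for gaps), \code{component_start},
#'   \code{component_end} (0-based half-open on the contig, \code{NA}
#'   for gaps), \code{orientation} (\code{+}, \code{-} or \code{?};
#'   \code{NA} for gaps), \code{is_gap}, \code{gap_length}.
#' @seealso \code{\link{writeAgp}}, \code{\link{buildPainting}}
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t1\t1000\t1\tW\tctg1\t1\t1000\t+", f)
#' readAgp(f)
#' @export
readAgp <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), part_number = integer(),
                      component_type = character(),
                      component_id = character(),
                      component_start = numeric(),
                      component_end = numeric(),
                      orientation = character(), is_gap = logical(),
                      gap_length = numeric()))
  fields <- strsplit(lines, "[ \t]+")
  short <- lengths(fields) < 8L
  if (any(short))
    stop("malformed AGP line ", which(short)[1], ": fewer than 8 columns")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    type <- f[5]
    beg <- as.numeric(f[2]); end <- as.numeric(f[3])
    if (is.na(beg) || is.na(end) || end < beg)
      stop("malformed AGP line ", i, ": bad object coordinates")
    if (type == "W") {
      if (length(f) < 9L) stop("malformed AGP line ", i,
                               ": W line needs 9 columns")
      cb <- as.numeric(f[7]); ce <- as.numeric(f[8])
      if (!(f[9] %in% c("+", "-", "?")))
        stop("malformed AGP line ", i, ": bad orientation '", f[9], "'")
      if ((end - beg) != (ce - cb))
        stop("AGP line ", i, ": object span differs from component span")
      data.frame(chrom = f[1], start = beg - 1, end = end,
                 part_number = as.integer(f[4]), component_type = type,
                 component_id = f[6], component_start = cb - 1,
                 component_end = ce, orientation = f[9], is_gap = FALSE,
                 gap_length = NA_real_)
    } else if (type %in% c("N", "U")) {
      data.frame(chrom = f[1], start = beg - 1, end = end,
                 part_number = as.integer(f[4]), component_type = type,
                 component_id = NA_character_,
                 component_start = NA_real_, component_end = NA_real_,
                 orientation = NA_character_, is_gap = TRUE,
                 gap_length = as.numeric(f[6]))
    } else {
      stop("AGP line ", i, ": unknown component_type '", type, "'")
    }
  })
  agp <- do.call(rbind, rows)
  for (ch in unique(agp$chrom)) {
    sub <- agp[agp$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping object coordinates on '", ch, "'")
  }
  agp[order(agp$chrom, agp$start), , drop = FALSE]
}

#' Write AGP v2.1 placements
#'
#' @param agp A placement \code{data.frame} in the layout returned by
#'   \code{\link{readAgp}}.
#' @param file Output path or connection.
#' @return Invisibly, \code{file}.
#' @export
writeAgp <- function(agp, file) {
  lines <- vapply(seq_len(nrow(agp)), function(i) {
    r <- agp[i, ]
    if (isTRUE(r$is_gap)) {
      sprintf("%s\t%d\t%d\t%d\t%s\t%d\tscaffold\tyes\tproximity_ligation",
              r$chrom, as.integer(r$start + 1), as.integer(r$end),
              r$part_number, r$component_type, as.integer(r$gap_length))
    } else {
      sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s",
              r$chrom, as.integer(r$start + 1), as.integer(r$end),
              r$part_number, r$component_id,
              as.integer(r$component_start + 1),
              as.integer(r$component_end), r$orientation)
    }
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
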