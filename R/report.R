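# Chromosome paintings, repeat summaries and family-count tabulation.

#' The fixed ancestry painting palette
#'
#' One palette is used everywhere: progenitor A teal, progenitor B
#' green, contigs mapping almost equally to both pink, recombinant
#' contigs purple, unaligned grey.
#'
#' @param as_rgb If \code{TRUE}, return comma-separated RGB triplets
#'   for BED9 itemRgb instead of hex colours.
#' @return Named character vector keyed by category.
#' @export
paintingPalette <- function(as_rgb = FALSE) {
  hex <- c(A_dominant = "#1B9E77", B_dominant = "#66A61E",
           equal = "#E7298A", recombinant = "#7570B3",
           unaligned = "#BDBDBD")
  if (!as_rgb) return(hex)
  vapply(hex, function(h)
    paste(as.vector(grDevices::col2rgb(h)), collapse = ","),
    character(1))
}

#' Paint pseudochromosomes by contig ancestry
#'
#' Lays the per-contig ancestry calls along the AGP placements: every
#' non-gap component at least \code{min_display_bp} long becomes one
#' coloured block. Components below the display threshold are omitted
#' from the block list but retained in the per-chromosome totals, so
#' displayed + below-threshold + gap bp always reconstructs each
#' chromosome length. Components without a call are painted
#' \code{unaligned} with a warning.
#'
#' @param agp AGP placements as returned by \code{\link{readAgp}}.
#' @param calls An \code{\linkS4class{AncestryCalls}} covering the
#'   placed contigs.
#' @param min_display_bp Minimum component length to display (default
#'   100000, i.e. contigs larger than 100 kb).
#' @return A list with \code{blocks} (a \code{data.frame}: \code{chrom},
#'   \code{start}, \code{end}, \code{contig_id}, \code{category},
#'   \code{rgb}, \code{track = "placed"}) and \code{totals} (per
#'   chromosome: \code{displayed_bp}, \code{below_threshold_bp},
#'   \code{gap_bp}, \code{chrom_length}).
#' @seealso \code{\link{writeBed9}}, \code{\link{plotPainting}}
#' @export
buildPainting <- function(agp, calls, min_display_bp = 100000) {
  cat_of <- stats::setNames(as.data.frame(calls@calls)$category,
                            as.data.frame(calls@calls)$contig_id)
  comp <- agp[!agp$is_gap, , drop = FALSE]
  missing_call <- setdiff(unique(comp$component_id), names(cat_of))
  if (length(missing_call)) {
    warning("no ancestry call for component(s): ",
            paste(utils::head(missing_call, 5), collapse = ", "),
            "; painted as unaligned")
    cat_of[missing_call] <- "unaligned"
  }
  comp$category <- unname(cat_of[comp$component_id])
  comp$len <- comp$end - comp$start
  shown <- comp[comp$len >= min_display_bp, , drop = FALSE]
  pal <- paintingPalette()
  blocks <- data.frame(chrom = shown$chrom, start = shown$start,
                       end = shown$end, contig_id = shown$component_id,
                       category = shown$category,
                       rgb = unname(pal[shown$category]),
                       track = "placed")
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  chroms <- unique(agp$chrom)
  totals <- do.call(rbind, lapply(chroms, function(ch) {
    a <- agp[agp$chrom == ch, ]
    cc <- comp[comp$chrom == ch, ]
    data.frame(chrom = ch,
               displayed_bp = sum(cc$len[cc$len >= min_display_bp]),
               below_threshold_bp = sum(cc$len[cc$len < min_display_bp]),
               gap_bp = sum(a$end[a$is_gap] - a$start[a$is_gap]),
               chrom_length = max(a$end))
  }))
  list(blocks = blocks, totals = totals)
}

#' Two-track painting: scaffolded versus aligned unplaced ancestry
#'
#' The bottom track per chromosome is the \code{\link{buildPainting}}
#' of the scaffolded contigs; the top track positions each unplaced
#' contig at its merged alignment footprints on the chromosome,
#' coloured by the unplaced contig's own ancestry category.
#'
#' @param agp AGP placements of the scaffolded contigs.
#' @param placed_calls \code{\linkS4class{AncestryCalls}} for placed
#'   contigs.
#' @param unplaced_alns \code{\linkS4class{AlignmentSet}} of unplaced
#'   contigs (query) against the pseudochromosomes (reference).
#' @param unplaced_calls \code{\linkS4class{AncestryCalls}} for the
#'   unplaced contigs.
#' @param min_display_bp Display threshold for the bottom track.
#' @return A list with \code{blocks} (both tracks, distinguished by the
#'   \code{track} column: \code{"placed"} or \code{"unplaced"}) and the
#'   bottom-track \code{totals}.
#' @export
buildTwoTrackPainting <- function(agp, placed_calls, unplaced_alns,
                                  unplaced_calls,
                                  min_display_bp = 100000) {
  bottom <- buildPainting(agp, placed_calls, min_display_bp)
  df <- as.data.frame(unplaced_alns)
  pal <- paintingPalette()
  cat_of <- stats::setNames(as.data.frame(unplaced_calls@calls)$category,
                            as.data.frame(unplaced_calls@calls)$contig_id)
  top <- NULL
  if (nrow(df)) {
    unknown <- setdiff(unique(df$query_id), names(cat_of))
    if (length(unknown))
      stop("no call for unplaced contig(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    pieces <- lapply(split(df, list(df$query_id, df$ref_id), drop = TRUE),
                     function(d) {
      m <- mergeIntervals(d$ref_start, d$ref_end)
      data.frame(chrom = d$ref_id[1], start = m$start, end = m$end,
                 contig_id = d$query_id[1],
                 category = unname(cat_of[d$query_id[1]]))
    })
    top <- do.call(rbind, pieces)
    top$rgb <- unname(pal[top$category])
    top$track <- "unplaced"
    top <- top[order(top$chrom, top$start), , drop = FALSE]
    rownames(top) <- NULL
  }
  list(blocks = rbind(bottom$blocks, top), totals = bottom$totals)
}

#' Summarise repeat annotation by class
#'
#' Per repeat class, the element count and the masked bp after merging
#' that class's hits (a base hit twice by the same class counts once);
#' the grand total row is the sum of the per-class masked bp, so
#' classes overlapping each other are counted once per class. The
#' union view additionally merges across classes, closes gaps shorter
#' than 10 bp (masker convention: stretches less than 10 bp between
#' repeats are also masked) and counts bridged regions larger than
#' 20 kb. Both views are reported because they answer different
#' questions (repeat content by family versus total masked genome).
#'
#' @param hits Repeat hits as returned by
#'   \code{\link{readRepeatMaskerOut}} (\code{repeat_class},
#'   \code{target_id}, \code{start}, \code{end}).
#' @param genome_size Genome size in bp (> 0), the denominator of the
#'   percent columns.
#' @param bridge_max_gap,large_region_bp The union-view bridging gap
#'   and region-size threshold (defaults 10 bp and 20000 bp).
#' @return A list with \code{classes} (per-class \code{data.frame}:
#'   \code{repeat_class}, \code{element_count}, \code{masked_bp},
#'   \code{pct_genome}, sorted by decreasing \code{masked_bp}),
#'   \code{total_elements}, \code{total_masked_bp}, \code{total_pct}
#'   (sums of the per-class rows), \code{union_masked_bp},
#'   \code{union_pct} (bridged union across classes) and
#'   \code{regions_gt_20kb}.
#' @export
repeatSummary <- function(hits, genome_size, bridge_max_gap = 10,
                          large_region_bp = 20000) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  if (nrow(hits) && any(hits$end <= hits$start))
    stop("repeat hits must have end > start")
  per_class <- lapply(split(hits, hits$repeat_class), function(h) {
    masked <- sum(vapply(split(h, h$target_id),
                         function(d) merged_bp(d$start, d$end),
                         numeric(1)))
    data.frame(repeat_class = h$repeat_class[1],
               element_count = nrow(h), masked_bp = masked,
               pct_genome = 100 * masked / genome_size)
  })
  classes <- if (length(per_class)) do.call(rbind, per_class) else
    data.frame(repeat_class = character(), element_count = integer(),
               masked_bp = numeric(), pct_genome = numeric())
  classes <- classes[order(-classes$masked_bp), , drop = FALSE]
  rownames(classes) <- NULL
  union_bp <- 0; n_large <- 0L
  if (nrow(hits)) {
    per_target <- lapply(split(hits, hits$target_id), function(d) {
      b <- bridgeAndCount(mergeIntervals(d$start, d$end),
                          max_gap = bridge_max_gap,
                          min_region = large_region_bp)
      c(bp = attr(b$bridged, "total_bp"), n = b$n_large)
    })
    m <- do.call(rbind, per_target)
    union_bp <- sum(m[, "bp"]); n_large <- as.integer(sum(m[, "n"]))
  }
  list(classes = classes,
       total_elements = sum(classes$element_count),
       total_masked_bp = sum(classes$masked_bp),
       total_pct = 100 * sum(classes$masked_bp) / genome_size,
       union_masked_bp = union_bp,
       union_pct = 100 * union_bp / genome_size,
       regions_gt_20kb = n_large)
}

#' Tabulate gene-family assignments
#'
#' Counts assignments per family in order of first appearance, with a
#' computed total. The total is always recomputed from the data; a
#' printed total that disagrees with its own column is thereby exposed
#' rather than reproduced.
#'
#' @param gene_id Character vector of gene identifiers (or a
#'   \code{data.frame} with columns \code{gene_id} and \code{family}).
#' @param family Character vector of family labels parallel to
#'   \code{gene_id}.
#' @return A list with \code{table} (\code{data.frame}: \code{family},
#'   \code{count}) and \code{total} (number of assignments).
#' @examples
#' familyCountTable(paste0("g", 1:5),
#'                  c("SWEET", "TST", "SWEET", "PLT", "TST"))
#' @export
familyCountTable <- function(gene_id, family = NULL) {
  if (is.data.frame(gene_id)) {
    family <- gene_id$family; gene_id <- gene_id$gene_id
  }
  if (length(gene_id) != length(family))
    stop("gene_id and family must have equal length")
  if (!length(gene_id))
    return(list(table = data.frame(family = character(),
                                   count = integer()), total = 0L))
  fam <- factor(family, levels = unique(family))
  list(table = data.frame(family = levels(fam),
                          count = as.integer(table(fam))),
       total = length(gene_id))
}

#' Plot a chromosome painting
#'
#' Simple static rendering: one horizontal bar per chromosome, placed
#' ancestry blocks on the lower half and (when present) unplaced
#' footprints on the upper half, coloured by the fixed palette.
#'
#' @param painting Result of \code{\link{buildPainting}} or
#'   \code{\link{buildTwoTrackPainting}}.
#' @param main Plot title.
#' @return Invisibly, \code{NULL}.
#' @export
plotPainting <- function(painting, main = "Ancestry painting") {
  blocks <- painting$blocks
  totals <- painting$totals
  chroms <- totals$chrom
  graphics::plot(NULL, xlim = c(0, max(totals$chrom_length)),
                 ylim = c(0, length(chroms) + 1), xlab = "position (bp)",
                 ylab = "", yaxt = "n", main = main)
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 2)
  for (i in seq_along(chroms)) {
    graphics::rect(0, i - 0.35, totals$chrom_length[i], i + 0.35,
                   col = "grey95", border = "grey60")
    b <- blocks[blocks$chrom == chroms[i], , drop = FALSE]
    if (!nrow(b)) next
    lower <- b$track == "placed"
    graphics::rect(b$start[lower], i - 0.35, b$end[lower], i,
                   col = b$rgb[lower], border = NA)
    graphics::rect(b$start[!lower], i, b$end[!lower], i + 0.35,
                   col = b$rgb[!lower], border = NA)
  }
  invisible(NULL)
}
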