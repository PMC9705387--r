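# Synthetic hybrid-genome test bed: progenitor pair at a stated
# divergence, hybrid assembly with known ancestry segments and
# breakpoints, emulated score-thresholded alignments, truth alignments,
# depth profiles and AGP placements. All randomness is seeded through
# SimParams; structural draws (contig layout, islands, breakpoints) are
# made before and independently of the divergence-dependent draws, and
# substitutions are decided by one uniform per base, so simulations at
# different divergence levels under the same seed are coupled (the
# mismatch set at a lower divergence is a subset of that at a higher
# one).

#' Simulate a progenitor genome pair
#'
#' Genome B is derived from genome A by planted substitutions. The
#' genome-wide substitution rate equals \code{divergence}; part of the
#' budget is concentrated in short divergent islands
#' (\code{island_fraction} of the genome at \code{island_divergence_factor}
#' times the genome-wide rate, background rate lowered to compensate).
#' Uniformly spread substitutions alone would let every contig align
#' end-to-end to both progenitors, leaving per-contig ancestry
#' unidentifiable from coverage; the islands emulate the localised
#' divergence (indels, presence/absence variation) of real genomes that
#' fragments score-thresholded cross-subgenome alignments. A
#' substituted base is drawn uniformly from the three alternatives.
#'
#' @param params A \code{\linkS4class{SimParams}}.
#' @return A \code{\linkS4class{ProgenitorPair}}.
#' @examples
#' pp <- simulateProgenitors(simParams(seed = 1, genome_length = 5e4,
#'                                     n_chromosomes = 1,
#'                                     contig_length_min = 10000,
#'                                     contig_length_max = 20000,
#'                                     n_contigs = 5))
#' pp
#' @export
simulateProgenitors <- function(params) {
  stopifnot(is(params, "SimParams"))
  L <- params@genome_length
  n <- params@n_chromosomes
  lens <- rep(floor(L / n), n)
  lens[n] <- lens[n] + L - sum(lens)
  names(lens) <- paste0("chr", seq_len(n))
  d <- params@divergence
  kap <- params@island_divergence_factor
  isl_len <- params@island_length
  phi <- params@island_fraction

  res <- with_seed(params@seed, {
    bases <- c("A", "C", "G", "T")
    gA <- character(n); gB <- character(n)
    var_list <- vector("list", n)
    isl_list <- vector("list", n)
    for (ci in seq_len(n)) {
      len <- lens[ci]
      seq_a <- sample(bases, len, replace = TRUE)
      # jittered-regular island layout (divergence-independent draws)
      n_isl <- if (phi > 0) max(0L, floor(phi * len / isl_len)) else 0L
      island_mask <- logical(len)
      isl_start <- integer(0)
      if (n_isl > 0L) {
        period <- len / n_isl
        jit <- stats::runif(n_isl)
        isl_start <- pmin(floor((seq_len(n_isl) - 1) * period +
                                  jit * (period - isl_len)),
                          len - isl_len)
        for (s in isl_start)
          island_mask[(s + 1):(s + isl_len)] <- TRUE
      }
      phi_real <- mean(island_mask)
      d_island <- kap * d
      d_back <- if (phi_real < 1)
        d * (1 - phi_real * kap) / (1 - phi_real) else d_island
      d_back <- max(d_back, 0)
      p <- ifelse(island_mask, d_island, d_back)
      u <- stats::runif(len)
      v <- stats::runif(len)
      sub <- u < p
      seq_b <- seq_a
      if (any(sub)) {
        orig_idx <- match(seq_a[sub], bases)
        alt_idx <- ((orig_idx - 1L + 1L + floor(v[sub] * 3)) %% 4L) + 1L
        seq_b[sub] <- bases[alt_idx]
      }
      gA[ci] <- paste(seq_a, collapse = "")
      gB[ci] <- paste(seq_b, collapse = "")
      pos0 <- which(sub) - 1L
      var_list[[ci]] <- data.frame(
        chrom = rep(names(lens)[ci], length(pos0)), pos = pos0,
        base_a = seq_a[sub], base_b = seq_b[sub],
        island = island_mask[sub])
      isl_list[[ci]] <- if (n_isl > 0L)
        data.frame(chrom = names(lens)[ci], start = isl_start,
                   end = isl_start + isl_len, divergence = d_island)
      else
        data.frame(chrom = character(), start = numeric(),
                   end = numeric(), divergence = numeric())
    }
    list(gA = gA, gB = gB,
         variants = do.call(rbind, var_list),
         islands = do.call(rbind, isl_list))
  })
  genomeA <- Biostrings::DNAStringSet(res$gA)
  genomeB <- Biostrings::DNAStringSet(res$gB)
  names(genomeA) <- names(lens); names(genomeB) <- names(lens)
  rownames(res$variants) <- NULL
  new("ProgenitorPair", genomeA = genomeA, genomeB = genomeB,
      variants = res$variants, islands = res$islands, params = params)
}

#' Simulate a hybrid assembly with known ancestry
#'
#' Each contig copies a contiguous source interval from one progenitor
#' (pure) or, with probability \code{chimera_fraction}, switches
#' ancestor at 1 to \code{max_breakpoints} uniformly placed breakpoints
#' (chimeric). Because the progenitors are colinear, a chimeric contig
#' switches ancestry at the same homologous coordinate -- the signature
#' of consensus-correction chimerisation rather than of structural
#' rearrangement. Planted segments are at least \code{min_segment_bp}
#' long; a fraction \code{collapsed_fraction} of contigs receives copy
#' number 2 or 3 to emulate collapsed repeats.
#'
#' @param pair A \code{\linkS4class{ProgenitorPair}}.
#' @param params A \code{\linkS4class{SimParams}} (normally
#'   \code{pair@params}).
#' @return A \code{\linkS4class{HybridAssembly}} truth table.
#' @export
simulateHybridAssembly <- function(pair, params = pair@params) {
  lens <- Biostrings::width(pair@genomeA)
  chroms <- names(pair@genomeA)
  with_seed(params@seed + 1, {
    n <- params@n_contigs
    min_seg <- params@min_segment_bp
    contigs <- vector("list", n)
    segs <- vector("list", n)
    for (i in seq_len(n)) {
      clen <- floor(stats::runif(1, params@contig_length_min,
                                 params@contig_length_max + 1))
      ci <- sample(length(chroms), 1)
      cstart <- floor(stats::runif(1, 0, lens[ci] - clen + 1))
      chim <- stats::runif(1) < params@chimera_fraction
      if (chim) {
        k <- sample(seq_len(params@max_breakpoints), 1)
        # a contig can host at most floor(len / min_seg) - 1 breakpoints
        k <- min(k, floor(clen / min_seg) - 1)
        # uniform breakpoints subject to the segment-size floor, by
        # placing cuts in the slack and adding the floors back
        slack <- clen - (k + 1) * min_seg
        cuts <- sort(floor(stats::runif(k, 0, slack + 1)))
        b <- cuts + seq_len(k) * min_seg
        anc0 <- sample(c("A", "B"), 1)
        ancs <- rep(c(anc0, setdiff(c("A", "B"), anc0)),
                    length.out = k + 1)
        bounds <- c(0, b, clen)
      } else {
        ancs <- sample(c("A", "B"), 1)
        bounds <- c(0, clen)
      }
      cn <- if (stats::runif(1) < params@collapsed_fraction)
        sample(2:3, 1) else 1L
      id <- sprintf("ctg%04d", i)
      contigs[[i]] <- data.frame(contig_id = id, length = clen,
                                 chimeric = chim, copy_number = cn)
      segs[[i]] <- data.frame(
        contig_id = id, start = bounds[-length(bounds)],
        end = bounds[-1], ancestry = ancs, src_chrom = chroms[ci],
        src_start = cstart + bounds[-length(bounds)],
        src_end = cstart + bounds[-1])
    }
    new("HybridAssembly", contigs = do.call(rbind, contigs),
        segments = do.call(rbind, segs), params = params)
  })
}

#' Extract the nucleotide sequences of simulated contigs
#'
#' @param pair A \code{\linkS4class{ProgenitorPair}}.
#' @param truth A \code{\linkS4class{HybridAssembly}}.
#' @return A named \code{DNAStringSet}, one sequence per contig,
#'   spliced from the source progenitor at each planted segment.
#' @export
contigSequences <- function(pair, truth) {
  ga <- as.character(pair@genomeA)
  gb <- as.character(pair@genomeB)
  seg <- truth@segments
  pieces <- ifelse(seg$ancestry == "A",
                   substring(ga[seg$src_chrom], seg$src_start + 1,
                             seg$src_end),
                   substring(gb[seg$src_chrom], seg$src_start + 1,
                             seg$src_end))
  seqs <- vapply(split(pieces, seg$contig_id),
                 paste, character(1), collapse = "")
  out <- Biostrings::DNAStringSet(seqs[unique(seg$contig_id)])
  out
}

# pass-specific emulated-aligner settings
.pass_settings <- function(pass) {
  switch(pass,
         first = list(penalty = 4, min_score = 1000),
         second = list(penalty = 8, min_score = 500),
         stop("pass must be 'first' or 'second'"))
}

#' Emulate score-thresholded contig-to-progenitor alignments
#'
#' Produces the alignments a local aligner with a minimum output score
#' would report for each contig against each progenitor, without
#' running an aligner. Against its source ancestor a segment aligns
#' end-to-end at 100 percent identity. Against the other ancestor the
#' alignment is fragmented: divergent islands whose local substitution
#' rate exceeds 1 / (1 + mismatch_penalty) (where the expected local
#' score becomes negative) split the alignment, and each remaining
#' chunk is emitted only if its score, +1 per match and
#' -mismatch_penalty per planted mismatch, reaches \code{min_score}.
#' Two stringency settings are provided: the \code{"first"} (tally)
#' pass with penalty 4 and minimum score 1000, and the \code{"second"}
#' (disambiguation) pass with penalty 8 and minimum score 500.
#'
#' @param pair A \code{\linkS4class{ProgenitorPair}}.
#' @param truth A \code{\linkS4class{HybridAssembly}}.
#' @param pass \code{"first"} or \code{"second"}.
#' @return A list with elements \code{A} and \code{B}: one
#'   \code{\linkS4class{AlignmentSet}} of all contigs against each
#'   progenitor (query coordinates on the contig).
#' @seealso \code{\link{exportTruthAlignments}} for the exact
#'   full-coverage truth records.
#' @export
simulateAlignments <- function(pair, truth, pass = c("first", "second")) {
  pass <- match.arg(pass)
  st <- .pass_settings(pass)
  d_island <- pair@params@island_divergence_factor * pair@params@divergence
  breaking <- d_island >= 1 / (1 + st$penalty)
  vpos <- lapply(split(pair@variants$pos, pair@variants$chrom), sort)
  isl <- split(pair@islands, pair@islands$chrom)
  seg <- truth@segments
  recs <- vector("list", nrow(seg) * 2L)
  ri <- 0L
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    w <- s$src_end - s$src_start
    own <- s$ancestry
    other <- if (own == "A") "B" else "A"
    ri <- ri + 1L
    recs[[ri]] <- data.frame(
      ref_genome = own, query_id = s$contig_id, query_start = s$start,
      query_end = s$end, ref_id = s$src_chrom, ref_start = s$src_start,
      ref_end = s$src_end, identity_pct = 100,
      aligned_columns = w, score = w)
    # cross-ancestor chunks
    vp <- vpos[[s$src_chrom]]
    if (breaking && !is.null(isl[[s$src_chrom]])) {
      ib <- isl[[s$src_chrom]]
      ib <- ib[ib$end > s$src_start & ib$start < s$src_end, , drop = FALSE]
      chunks <- as_df0(BiocGenerics::setdiff(
        ir0(s$src_start, s$src_end),
        if (nrow(ib)) ir0(pmax(ib$start, s$src_start),
                          pmin(ib$end, s$src_end)) else IRanges::IRanges()))
    } else {
      chunks <- data.frame(start = s$src_start, end = s$src_end)
    }
    if (nrow(chunks) == 0L) next
    m <- findInterval(chunks$end - 0.5, vp) -
      findInterval(chunks$start - 0.5, vp)
    cw <- chunks$end - chunks$start
    sc <- (cw - m) - st$penalty * m
    keep <- sc >= st$min_score
    if (!any(keep)) next
    ri <- ri + 1L
    recs[[ri]] <- data.frame(
      ref_genome = other, query_id = s$contig_id,
      query_start = s$start + (chunks$start[keep] - s$src_start),
      query_end = s$start + (chunks$end[keep] - s$src_start),
      ref_id = s$src_chrom, ref_start = chunks$start[keep],
      ref_end = chunks$end[keep],
      identity_pct = 100 * (1 - m[keep] / cw[keep]),
      aligned_columns = cw[keep], score = sc[keep])
  }
  all <- do.call(rbind, recs[seq_len(ri)])
  make <- function(g) {
    df <- all[all$ref_genome == g, , drop = FALSE]
    if (!nrow(df)) return(AlignmentSet())
    AlignmentSet(query_id = df$query_id, query_start = df$query_start,
                 query_end = df$query_end, ref_id = df$ref_id,
                 ref_start = df$ref_start, ref_end = df$ref_end,
                 strand = "+", aligned_columns = df$aligned_columns,
                 identity_pct = df$identity_pct, score = df$score,
                 source = "truth", record_type = "primary")
  }
  list(A = make("A"), B = make("B"))
}

#' Export exact truth alignments for simulated contigs
#'
#' One record per planted segment and progenitor: identity 100 against
#' the source ancestor and, against the other ancestor, the exact
#' identity implied by the planted substitutions in the segment's
#' source window, with exact coordinates. These full-coverage records
#' stand in for whole-genome aligner output in tests.
#'
#' @inheritParams simulateAlignments
#' @return A list with \code{\linkS4class{AlignmentSet}}s \code{A} and
#'   \code{B}.
#' @export
exportTruthAlignments <- function(pair, truth) {
  vpos <- lapply(split(pair@variants$pos, pair@variants$chrom), sort)
  seg <- truth@segments
  w <- seg$src_end - seg$src_start
  m <- vapply(seq_len(nrow(seg)), function(i) {
    vp <- vpos[[seg$src_chrom[i]]]
    if (is.null(vp)) return(0)
    findInterval(seg$src_end[i] - 0.5, vp) -
      findInterval(seg$src_start[i] - 0.5, vp)
  }, numeric(1))
  base <- data.frame(query_id = seg$contig_id, query_start = seg$start,
                     query_end = seg$end, ref_id = seg$src_chrom,
                     ref_start = seg$src_start, ref_end = seg$src_end)
  own <- cbind(base, identity_pct = 100, aligned_columns = w,
               ref_genome = seg$ancestry)
  cross <- cbind(base, identity_pct = 100 * (1 - m / w),
                 aligned_columns = w,
                 ref_genome = ifelse(seg$ancestry == "A", "B", "A"))
  all <- rbind(own, cross)
  make <- function(g) {
    df <- all[all$ref_genome == g, , drop = FALSE]
    if (!nrow(df)) return(AlignmentSet())
    AlignmentSet(query_id = df$query_id, query_start = df$query_start,
                 query_end = df$query_end, ref_id = df$ref_id,
                 ref_start = df$ref_start, ref_end = df$ref_end,
                 strand = "+", aligned_columns = df$aligned_columns,
                 identity_pct = df$identity_pct, score = NA_real_,
                 source = "truth", record_type = "primary")
  }
  list(A = make("A"), B = make("B"))
}

#' Whole-genome truth alignments between the two progenitors
#'
#' One full-length record per chromosome of genome B (query) against
#' its homologous chromosome of genome A (reference), with identity
#' computed exactly from the planted substitution count. Feeding these
#' to \code{\link{compareGenomes}} yields the simulated analogue of a
#' genome-versus-genome comparison.
#'
#' @param pair A \code{\linkS4class{ProgenitorPair}}.
#' @return An \code{\linkS4class{AlignmentSet}}.
#' @export
progenitorAlignments <- function(pair) {
  lens <- Biostrings::width(pair@genomeA)
  chroms <- names(pair@genomeA)
  nvar <- table(factor(pair@variants$chrom, levels = chroms))
  AlignmentSet(query_id = chroms, query_start = 0, query_end = lens,
               ref_id = chroms, ref_start = 0, ref_end = lens,
               strand = "+", aligned_columns = lens,
               identity_pct = 100 * (1 - as.numeric(nvar) / lens),
               score = NA_real_, source = "truth")
}

#' Simulate per-contig read depth
#'
#' Depth is \code{base_depth * copy_number} plus, when
#' \code{depth_noise_sd > 0}, rounded Gaussian noise (clamped at 0).
#' With zero noise the planted copy-number partition is recoverable
#' exactly.
#'
#' @param truth A \code{\linkS4class{HybridAssembly}}.
#' @param params A \code{\linkS4class{SimParams}}.
#' @return A depth \code{data.frame} (\code{contig_id}, \code{length},
#'   \code{depth}).
#' @export
simulateDepth <- function(truth, params = truth@params) {
  ct <- truth@contigs
  with_seed(params@seed + 2, {
    noise <- if (params@depth_noise_sd > 0)
      round(stats::rnorm(nrow(ct), 0, params@depth_noise_sd)) else 0
    data.frame(contig_id = ct$contig_id, length = ct$length,
               depth = pmax(params@base_depth * ct$copy_number + noise, 0))
  })
}

#' Scaffold a random subset of simulated contigs into an AGP
#'
#' A fraction of contigs is "placed": contigs are grouped by source
#' chromosome and laid out in source order on one pseudochromosome per
#' source chromosome, separated by fixed-size gaps (orientation is
#' always \code{+}); the remainder is returned as unplaced. The AGP can
#' be written with \code{\link{writeAgp}} and read back with
#' \code{\link{readAgp}}.
#'
#' @param truth A \code{\linkS4class{HybridAssembly}}.
#' @param placed_fraction Fraction of contigs to place (default 0.6).
#' @param gap_bp Gap size between consecutive components (default 100).
#' @param params A \code{\linkS4class{SimParams}}.
#' @return A list with \code{agp} (placements \code{data.frame} in
#'   \code{\link{readAgp}} layout), \code{placed_ids} and
#'   \code{unplaced_ids}.
#' @export
simulateAgp <- function(truth, placed_fraction = 0.6, gap_bp = 100,
                        params = truth@params) {
  ct <- truth@contigs
  seg <- truth@segments
  first_seg <- seg[!duplicated(seg$contig_id), ]
  with_seed(params@seed + 3, {
    n_placed <- round(placed_fraction * nrow(ct))
    placed <- sort(sample(ct$contig_id, n_placed))
    info <- first_seg[first_seg$contig_id %in% placed, ]
    info <- info[order(info$src_chrom, info$src_start), ]
    lens <- stats::setNames(ct$length, ct$contig_id)
    rows <- list()
    for (ch in unique(info$src_chrom)) {
      ids <- info$contig_id[info$src_chrom == ch]
      pch <- sub("^chr", "pchr", ch)
      pos <- 0; part <- 0L
      for (k in seq_along(ids)) {
        if (k > 1L) {
          part <- part + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = pch, start = pos, end = pos + gap_bp,
            part_number = part, component_type = "U",
            component_id = NA_character_, component_start = NA_real_,
            component_end = NA_real_, orientation = NA_character_,
            is_gap = TRUE, gap_length = gap_bp)
          pos <- pos + gap_bp
        }
        part <- part + 1L
        clen <- lens[[ids[k]]]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = pch, start = pos, end = pos + clen,
          part_number = part, component_type = "W",
          component_id = ids[k], component_start = 0,
          component_end = clen, orientation = "+", is_gap = FALSE,
          gap_length = NA_real_)
        pos <- pos + clen
      }
    }
    list(agp = do.call(rbind, rows), placed_ids = placed,
         unplaced_ids = setdiff(ct$contig_id, placed))
  })
}

#' Truth alignments of unplaced contigs onto the pseudochromosomes
#'
#' For every unplaced contig, overlaps between its source interval and
#' the source intervals of placed contigs (the progenitors are
#' colinear, so source coordinates are comparable across ancestors)
#' are projected into pseudochromosome coordinates through the AGP
#' layout. Identity is exact: 100 for same-ancestry overlaps, the
#' planted-variant identity otherwise.
#'
#' @param pair A \code{\linkS4class{ProgenitorPair}}.
#' @param truth A \code{\linkS4class{HybridAssembly}}.
#' @param agp_sim Result of \code{\link{simulateAgp}}.
#' @param min_overlap_bp Minimum projected overlap to report (default
#'   1000).
#' @return An \code{\linkS4class{AlignmentSet}} of unplaced contigs
#'   (query) against pseudochromosomes (reference).
#' @export
simulateUnplacedAlignments <- function(pair, truth, agp_sim,
                                       min_overlap_bp = 1000) {
  seg <- truth@segments
  agp <- agp_sim$agp
  comp <- agp[!agp$is_gap, ]
  chrom_start <- stats::setNames(comp$start, comp$component_id)
  chrom_of <- stats::setNames(comp$chrom, comp$component_id)
  vpos <- lapply(split(pair@variants$pos, pair@variants$chrom), sort)
  useg <- seg[seg$contig_id %in% agp_sim$unplaced_ids, , drop = FALSE]
  pseg <- seg[seg$contig_id %in% agp_sim$placed_ids, , drop = FALSE]
  recs <- list()
  for (i in seq_len(nrow(useg))) {
    u <- useg[i, ]
    cand <- pseg[pseg$src_chrom == u$src_chrom &
                   pseg$src_end > u$src_start &
                   pseg$src_start < u$src_end, , drop = FALSE]
    if (!nrow(cand)) next
    o1 <- pmax(cand$src_start, u$src_start)
    o2 <- pmin(cand$src_end, u$src_end)
    keep <- (o2 - o1) >= min_overlap_bp
    if (!any(keep)) next
    cand <- cand[keep, ]; o1 <- o1[keep]; o2 <- o2[keep]
    vp <- vpos[[u$src_chrom]]
    m <- findInterval(o2 - 0.5, vp) - findInterval(o1 - 0.5, vp)
    ident <- ifelse(cand$ancestry == u$ancestry, 100,
                    100 * (1 - m / (o2 - o1)))
    recs[[length(recs) + 1L]] <- data.frame(
      query_id = u$contig_id,
      query_start = u$start + (o1 - u$src_start),
      query_end = u$start + (o2 - u$src_start),
      ref_id = unname(chrom_of[cand$contig_id]),
      ref_start = unname(chrom_start[cand$contig_id]) + cand$start +
        (o1 - cand$src_start),
      ref_end = unname(chrom_start[cand$contig_id]) + cand$start +
        (o2 - cand$src_start),
      identity_pct = ident, aligned_columns = o2 - o1)
  }
  if (!length(recs)) return(AlignmentSet())
  df <- do.call(rbind, recs)
  AlignmentSet(query_id = df$query_id, query_start = df$query_start,
               query_end = df$query_end, ref_id = df$ref_id,
               ref_start = df$ref_start, ref_end = df$ref_end,
               strand = "+", aligned_columns = df$aligned_columns,
               identity_pct = df$identity_pct, score = NA_real_,
               source = "truth")
}

#' Score ancestry calls against the planted truth
#'
#' Computes the recovery metrics of the classifier on a simulated
#' assembly: accuracy on pure contigs (fraction called to their true
#' ancestor), chimera sensitivity, false-positive rate (pure contigs
#' called recombinant) and breakpoint mean absolute error. Sensitivity
#' is reported both over all planted chimeras and over chimeras within
#' the caller's operating range -- those whose planted segments all
#' exceed the caller's minimum run size by a resolution margin
#' (default 10 percent); a caller with a documented minimum detectable
#' segment cannot be expected to find segments below it.
#'
#' @param truth A \code{\linkS4class{HybridAssembly}}.
#' @param calls An \code{\linkS4class{AncestryCalls}} for the same
#'   contigs.
#' @param margin Operating-range resolution margin (default 1.1).
#' @return A list with \code{pure_accuracy},
#'   \code{chimera_sensitivity} (operating range),
#'   \code{chimera_sensitivity_all}, \code{chimera_fpr},
#'   \code{breakpoint_mae_bp}, and the group sizes \code{n_pure},
#'   \code{n_chimeric}, \code{n_in_range}.
#' @export
evaluateRecovery <- function(truth, calls, margin = 1.1) {
  ct <- truth@contigs
  seg <- truth@segments
  df <- as.data.frame(calls@calls)
  df <- df[match(ct$contig_id, df$contig_id), ]
  if (anyNA(df$contig_id)) stop("calls missing for some contigs")
  p <- calls@params
  pure <- !ct$chimeric
  true_anc <- seg$ancestry[!duplicated(seg$contig_id)]
  true_anc <- true_anc[match(ct$contig_id,
                             seg$contig_id[!duplicated(seg$contig_id)])]
  acc <- mean(df$category[pure] == paste0(true_anc[pure], "_dominant"))
  detected <- df$category == "recombinant"
  thresh <- pmax(p@recomb_min_segment_bp,
                 p@recomb_min_segment_frac * ct$length)
  min_planted <- vapply(split(seg$end - seg$start, seg$contig_id),
                        min, numeric(1))[ct$contig_id]
  in_range <- ct$chimeric & min_planted >= margin * thresh
  mae <- NA_real_
  idx <- which(in_range & detected)
  if (length(idx)) {
    errs <- unlist(lapply(idx, function(k) {
      s <- seg[seg$contig_id == ct$contig_id[k], ]
      true_bp <- s$end[-nrow(s)]
      called <- as.numeric(strsplit(df$breakpoints[k], ",")[[1]])
      vapply(true_bp, function(b) min(abs(called - b)), numeric(1))
    }))
    mae <- mean(errs)
  }
  list(pure_accuracy = acc,
       chimera_sensitivity = if (any(in_range))
         mean(detected[in_range]) else NA_real_,
       chimera_sensitivity_all = if (any(ct$chimeric))
         mean(detected[ct$chimeric]) else NA_real_,
       chimera_fpr = if (any(pure)) mean(detected[pure]) else NA_real_,
       breakpoint_mae_bp = mae,
       n_pure = sum(pure), n_chimeric = sum(ct$chimeric),
       n_in_range = sum(in_range))
}
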