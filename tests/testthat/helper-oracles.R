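# Independent brute-force oracles. These deliberately avoid the
# package's interval and CIGAR machinery: positions are walked one by
# one over logical masks.

# boolean-mask union size of 0-based half-open intervals on [0, domain)
mask_total_bp <- function(start, end, domain) {
  mask <- logical(domain)
  for (i in seq_along(start)) mask[(start[i] + 1):end[i]] <- TRUE
  sum(mask)
}

# merged intervals via run-length encoding of the mask
mask_merge <- function(start, end, domain) {
  mask <- logical(domain)
  for (i in seq_along(start)) mask[(start[i] + 1):end[i]] <- TRUE
  r <- rle(mask)
  stops <- cumsum(r$lengths)
  starts <- c(0, stops[-length(stops)])
  data.frame(start = starts[r$values], end = stops[r$values])
}

# dilate-then-label oracle: close gaps < max_gap, count regions > min_region
mask_bridge <- function(start, end, domain, max_gap, min_region) {
  mask <- logical(domain)
  for (i in seq_along(start)) mask[(start[i] + 1):end[i]] <- TRUE
  r <- rle(mask)
  stops <- cumsum(r$lengths)
  starts <- c(0L, stops[-length(stops)])
  inner_gap <- !r$values & starts > 0 & stops < domain
  for (k in which(inner_gap & r$lengths < max_gap))
    mask[(starts[k] + 1):stops[k]] <- TRUE
  r2 <- rle(mask)
  list(total_bp = sum(mask),
       n_large = sum(r2$values & r2$lengths > min_region))
}

# per-base CIGAR walk: spans and column counts, independent of any
# cigar utility
cigar_walk <- function(cigar, pos1) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  qpos <- 0; rpos <- pos1 - 1
  qmin <- NA; qmax <- NA; rmin <- NA; rmax <- NA; cols <- 0
  for (k in seq_along(ops)) {
    for (j in seq_len(lens[k])) {
      op <- ops[k]
      if (op %in% c("S", "H")) {
        qpos <- qpos + 1
      } else if (op %in% c("M", "=", "X")) {
        if (is.na(qmin)) qmin <- qpos
        qmax <- qpos + 1
        if (is.na(rmin)) rmin <- rpos
        rmax <- rpos + 1
        qpos <- qpos + 1; rpos <- rpos + 1; cols <- cols + 1
      } else if (op == "I") {
        if (is.na(qmin)) qmin <- qpos
        qmax <- qpos + 1
        qpos <- qpos + 1; cols <- cols + 1
      } else if (op %in% c("D", "N")) {
        if (is.na(rmin)) rmin <- rpos
        rmax <- rpos + 1
        rpos <- rpos + 1
        if (op == "D") cols <- cols + 1
      }
    }
  }
  list(query_start = qmin, query_end = qmax,
       ref_start = rmin, ref_end = rmax, aligned_columns = cols)
}

# random valid CIGAR: optional clips around an M-delimited core
random_cigar <- function() {
  core_ops <- c("M")
  n_inner <- sample(0:4, 1)
  if (n_inner > 0)
    core_ops <- c("M", as.vector(rbind(sample(c("I", "D"), n_inner,
                                              replace = TRUE), "M")))
  lens <- sample(1:50, length(core_ops), replace = TRUE)
  cig <- paste0(lens, core_ops, collapse = "")
  if (runif(1) < 0.5) cig <- paste0(sample(1:30, 1), "S", cig)
  if (runif(1) < 0.5) cig <- paste0(cig, sample(1:30, 1), "S")
  cig
}

sam_line <- function(qname, flag, rname, pos, cigar, tags = character()) {
  paste(c(qname, flag, rname, pos, "60", cigar, "*", "0", "0", "*", "*",
          tags), collapse = "\t")
}
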