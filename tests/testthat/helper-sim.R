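# Shared simulation fixtures, built once per test session.
.sim_cache <- new.env(parent = emptyenv())

# small two-chromosome world for format and report tests
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    p <- simParams(seed = 11, genome_length = 2e5, n_chromosomes = 2,
                   n_contigs = 30, contig_length_min = 20000,
                   contig_length_max = 60000, min_segment_bp = 5000)
    pp <- simulateProgenitors(p)
    truth <- simulateHybridAssembly(pp)
    .sim_cache$small <- list(params = p, pair = pp, truth = truth)
  }
  .sim_cache$small
}

# full default-condition world shared by the recovery tests
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    p <- simParams(seed = 42)
    pp <- simulateProgenitors(p)
    truth <- simulateHybridAssembly(pp)
    aln1 <- simulateAlignments(pp, truth, "first")
    aln2 <- simulateAlignments(pp, truth, "second")
    lens <- stats::setNames(truthContigs(truth)$length,
                            truthContigs(truth)$contig_id)
    calls1 <- callAncestry(aln1$A, aln1$B, lens)
    calls <- suppressWarnings(disambiguateEqual(calls1, aln2$A, aln2$B))
    .sim_cache$default <- list(params = p, pair = pp, truth = truth,
                               aln1 = aln1, aln2 = aln2, lens = lens,
                               calls1 = calls1, calls = calls)
  }
  .sim_cache$default
}

# restrict an AncestryCalls object to a subset of contigs
subset_calls <- function(calls, ids) {
  out <- calls
  out@calls <- out@calls[out@calls$contig_id %in% ids, , drop = FALSE]
  out@segments <- out@segments[out@segments$contig_id %in% ids, ,
                               drop = FALSE]
  out
}
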