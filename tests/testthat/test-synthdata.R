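test_that("identical parameters give byte-identical simulations", {
  p <- simParams(seed = 5, genome_length = 5e4, n_chromosomes = 1,
                 n_contigs = 8, contig_length_min = 10000,
                 contig_length_max = 20000)
  a <- simulateProgenitors(p); b <- simulateProgenitors(p)
  expect_identical(as.character(a@genomeA), as.character(b@genomeA))
  expect_identical(as.character(a@genomeB), as.character(b@genomeB))
  expect_identical(a@variants, b@variants)
  ta <- simulateHybridAssembly(a); tb <- simulateHybridAssembly(b)
  expect_identical(truthSegments(ta), truthSegments(tb))
  # and the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); simulateProgenitors(p); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero divergence gives identical genomes", {
  p <- simParams(seed = 5, genome_length = 5e4, n_chromosomes = 1,
                 divergence = 0, n_contigs = 5,
                 contig_length_min = 10000, contig_length_max = 20000)
  pp <- simulateProgenitors(p)
  expect_identical(as.character(pp@genomeA), as.character(pp@genomeB))
  expect_equal(nrow(pp@variants), 0L)
})

test_that("realised mismatch fraction stays within the binomial bound", {
  p <- simParams(seed = 9, genome_length = 2e5, n_chromosomes = 2,
                 n_contigs = 5, contig_length_min = 20000,
                 contig_length_max = 60000)
  pp <- simulateProgenitors(p)
  d_hat <- nrow(pp@variants) / p@genome_length
  bound <- 4 * sqrt(0.057 * (1 - 0.057) / p@genome_length)
  expect_lte(abs(d_hat - 0.057), bound)
  # the variant list is the exact set of differing positions
  a <- strsplit(as.character(pp@genomeA[["chr1"]]), "")[[1]]
  b <- strsplit(as.character(pp@genomeB[["chr1"]]), "")[[1]]
  diff_pos <- which(a != b) - 1L
  expect_identical(diff_pos,
                   sort(pp@variants$pos[pp@variants$chrom == "chr1"]))
})

test_that("chimera planting follows chimera_fraction and breakpoints", {
  base <- function(cf, mb = 3, seed = 21)
    simParams(seed = seed, genome_length = 2e5, n_chromosomes = 1,
              n_contigs = 50, contig_length_min = 20000,
              contig_length_max = 60000, chimera_fraction = cf,
              max_breakpoints = mb)
  pp <- simulateProgenitors(base(0))
  t0 <- simulateHybridAssembly(pp)
  expect_false(any(truthContigs(t0)$chimeric))
  expect_equal(nrow(truthSegments(t0)), 50L)
  t1 <- simulateHybridAssembly(simulateProgenitors(base(1, mb = 1)))
  expect_true(all(truthContigs(t1)$chimeric))
  expect_equal(as.integer(table(truthSegments(t1)$contig_id)),
               rep(2L, 50))
  # planted segments respect the minimum size and tile each contig
  seg <- truthSegments(t1)
  expect_true(all(seg$end - seg$start >=
                    simParams(seed = 1)@min_segment_bp))
  tile <- tapply(seg$end - seg$start, seg$contig_id, sum)
  lens <- stats::setNames(truthContigs(t1)$length,
                          truthContigs(t1)$contig_id)
  expect_equal(as.numeric(tile[names(lens)]), as.numeric(lens))
})

test_that("planted chimera count lies in the binomial 99 percent interval", {
  s <- default_sim()
  n_chim <- sum(truthContigs(s$truth)$chimeric)
  expect_gte(n_chim, qbinom(0.005, 200, 0.2))
  expect_lte(n_chim, qbinom(0.995, 200, 0.2))
})

test_that("truth alignments have exact identities and partition chimeras", {
  s <- small_sim()
  tr <- exportTruthAlignments(s$pair, s$truth)
  dfA <- as.data.frame(tr$A); dfB <- as.data.frame(tr$B)
  seg <- truthSegments(s$truth)
  # own-ancestor records are perfect, cross records near 100 * (1 - d)
  ownA <- dfA[dfA$query_id %in%
                seg$contig_id[seg$ancestry == "A"] &
                dfA$identity_pct == 100, ]
  expect_gt(nrow(ownA), 0)
  cross <- dfB[dfB$identity_pct < 100, ]
  expect_true(all(abs(cross$identity_pct - 94.3) < 3))
  # chimeric contigs: records partition at the planted breakpoint
  chim <- truthContigs(s$truth)$contig_id[truthContigs(s$truth)$chimeric]
  if (length(chim)) {
    id <- chim[1]
    sc <- seg[seg$contig_id == id, ]
    recA <- dfA[dfA$query_id == id, ]
    expect_equal(sort(unique(c(recA$query_start, recA$query_end))),
                 sort(unique(c(sc$start, sc$end))))
  }
})

test_that("contig sequences splice the source genomes exactly", {
  s <- small_sim()
  seqs <- contigSequences(s$pair, s$truth)
  ct <- truthContigs(s$truth)
  expect_equal(unname(Biostrings::width(seqs[ct$contig_id])),
               ct$length)
  seg <- truthSegments(s$truth)
  pure_a <- ct$contig_id[!ct$chimeric][1]
  sa <- seg[seg$contig_id == pure_a, ]
  src <- if (sa$ancestry == "A") s$pair@genomeA else s$pair@genomeB
  expect_identical(as.character(seqs[[pure_a]]),
                   substring(as.character(src[[sa$src_chrom]]),
                             sa$src_start + 1, sa$src_end))
})

test_that("zero-noise depth recovers the planted copy-number partition", {
  s <- small_sim()
  dep <- simulateDepth(s$truth)
  ct <- truthContigs(s$truth)
  expect_equal(dep$depth, 13 * ct$copy_number)
  part <- depthPartition(dep)
  expect_equal(part$median_depth, 13)
  expect_equal(part$multi_copy_bp, sum(ct$length[ct$copy_number > 1]))
  expect_equal(part$single_copy_bp + part$multi_copy_bp, sum(ct$length))
  # planted 2x contig sits at exactly twice the base depth
  if (any(ct$copy_number == 2))
    expect_equal(dep$depth[ct$copy_number == 2][1], 26)
})

test_that("emulated alignments cover the own ancestor fully", {
  s <- small_sim()
  aln <- simulateAlignments(s$pair, s$truth, "first")
  seg <- truthSegments(s$truth)
  pure <- truthContigs(s$truth)
  idA <- pure$contig_id[!pure$chimeric &
                          pure$contig_id %in%
                            seg$contig_id[seg$ancestry == "A"]]
  lens <- stats::setNames(pure$length, pure$contig_id)
  covA <- coveredFraction(aln$A, "query", lens)$per_sequence
  expect_true(all(covA[idA] == 1))
  # and the cross-ancestor coverage is substantially lower
  covB <- coveredFraction(aln$B, "query", lens)$per_sequence
  expect_true(mean(covB[idA]) < 0.9)
})
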