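# compact helper: one AlignmentSet from interval list on one contig
aset <- function(id, ivals, ref = "chr1") {
  if (!length(ivals)) return(AlignmentSet())
  s <- vapply(ivals, `[`, numeric(1), 1)
  e <- vapply(ivals, `[`, numeric(1), 2)
  AlignmentSet(query_id = id, query_start = s, query_end = e,
               ref_id = ref, ref_start = s, ref_end = e,
               identity_pct = 100)
}

test_that("dominant, equal and unaligned categories follow the tallies", {
  # bp_A 80000 vs bp_B 5000 on a 100 kb contig: A dominant
  r <- callContigAncestry(aset("c", list(c(0, 80000))),
                          aset("c", list(c(0, 5000))), "c", 1e5)
  expect_equal(r$category, "A_dominant")
  expect_equal(r$bp_A, 80000)
  expect_equal(r$segments$ancestry, "A")
  # |41000 - 39000| / 80000 = 0.025 <= 0.10: equal
  r <- callContigAncestry(aset("c", list(c(0, 41000))),
                          aset("c", list(c(0, 39000))), "c", 1e5)
  expect_equal(r$category, "equal")
  # nothing aligned
  r <- callContigAncestry(AlignmentSet(), AlignmentSet(), "c", 1e5)
  expect_equal(r$category, "unaligned")
  # below min_aligned_frac
  r <- callContigAncestry(aset("c", list(c(0, 5000))), AlignmentSet(),
                          "c", 1e5)
  expect_equal(r$category, "unaligned")
  # records of a foreign contig are rejected
  expect_error(callContigAncestry(aset("other", list(c(0, 10))),
                                  AlignmentSet(), "c", 1e5), "foreign")
})

test_that("exclusive-coverage runs drive recombinant detection", {
  # A-only on the first half, B-only on the second: one clean breakpoint
  r <- detectRecombinant(aset("c", list(c(0, 100000))),
                         aset("c", list(c(100000, 200000))), "c", 2e5)
  expect_true(r$recombinant)
  expect_equal(length(r$breakpoints), 1L)
  expect_lte(abs(r$breakpoints - 100000), 500)
  expect_equal(r$segments$ancestry, c("A", "B"))
  # fully covered by both everywhere: no exclusive evidence
  r <- detectRecombinant(aset("c", list(c(0, 200000))),
                         aset("c", list(c(0, 200000))), "c", 2e5)
  expect_false(r$recombinant)
  # a short alternating run below the minimum size does not fire
  r <- detectRecombinant(aset("c", list(c(0, 55000))),
                         aset("c", list(c(50000, 60000))), "c", 6e4)
  expect_false(r$recombinant)
})

test_that("category order puts recombinant before equal", {
  # balanced tallies that would be 'equal', but alternating exclusive
  # runs fire first
  alnA <- aset("c", list(c(0, 100000), c(100000, 200000)))
  alnB <- aset("c", list(c(100000, 200000)))
  r <- callContigAncestry(alnA[1], alnB, "c", 2e5)
  expect_equal(r$category, "recombinant")
})

test_that("disambiguation reassigns equal contigs on a decisive second pass", {
  lens <- c(eq1 = 1e5, eq2 = 1e5)
  a1 <- c(aset("eq1", list(c(0, 40000))), aset("eq2", list(c(0, 40000))))
  b1 <- c(aset("eq1", list(c(0, 40000))), aset("eq2", list(c(0, 40000))))
  calls <- callAncestry(a1, b1, lens)
  expect_equal(unique(callTable(calls)$category), "equal")
  # second pass decisive for eq1 (30000 vs 2000), still equal for eq2
  a2 <- c(aset("eq1", list(c(0, 30000))), aset("eq2", list(c(0, 30000))))
  b2 <- c(aset("eq1", list(c(0, 2000))), aset("eq2", list(c(0, 29000))))
  out <- callTable(disambiguateEqual(calls, a2, b2))
  expect_equal(out$category[out$contig_id == "eq1"], "A_dominant")
  expect_true(out$disambiguated[out$contig_id == "eq1"])
  expect_equal(out$category[out$contig_id == "eq2"], "equal")
  expect_false(out$disambiguated[out$contig_id == "eq2"])
  # missing second-pass data: kept equal with a warning
  expect_warning(out2 <- disambiguateEqual(calls, a2[1], b2[1]),
                 "eq2")
  expect_equal(callTable(out2)$category[2], "equal")
})

test_that("ancestry totals partition the assembly", {
  lens <- c(a = 1e6, b = 2e6, c = 1e6)
  alnA <- aset("a", list(c(0, 9e5)))
  alnB <- c(aset("b", list(c(0, 1.9e6))), aset("c", list(c(0, 5e5))))
  alnA2 <- c(alnA, aset("c", list(c(0, 5e5))))
  calls <- callAncestry(alnA2, alnB, lens)
  tot <- ancestryTotals(calls)
  expect_equal(sum(tot$total_bp), sum(lens))
  expect_equal(tot$total_bp[tot$category == "A_dominant"], 1e6)
  expect_equal(tot$total_bp[tot$category == "B_dominant"], 2e6)
  expect_equal(tot$total_bp[tot$category == "equal"], 1e6)
  # empty call set: all zeros
  tot0 <- ancestryTotals(callAncestry(AlignmentSet(), AlignmentSet(),
                                      stats::setNames(numeric(),
                                                      character())))
  expect_equal(sum(tot0$total_bp), 0)
  expect_equal(sum(tot0$n_contigs), 0L)
})

test_that("normalised recombination ratio is scale invariant", {
  expect_equal(normalizedRecombRatio(10, 5, 20, 10), 1)
  expect_equal(normalizedRecombRatio(100, 5, 10, 5), 10)
  r <- normalizedRecombRatio(6819, 56, 407, 10)
  expect_equal(normalizedRecombRatio(68190, 56, 4070, 10), r)
  expect_equal(normalizedRecombRatio(407, 10, 6819, 56), 1 / r)
  expect_error(normalizedRecombRatio(1, 0, 1, 1), "> 0")
})

test_that("depth partition uses the length-weighted median", {
  d <- data.frame(contig_id = c("a", "b", "c"),
                  length = c(1, 1, 2) * 1e6, depth = c(13, 13, 40))
  p <- depthPartition(d)
  expect_equal(p$median_depth, 13)
  expect_equal(p$multi_copy_bp, 2e6)
  expect_equal(p$single_copy_bp, 2e6)
  # all equal depths: nothing is multi copy
  d2 <- data.frame(contig_id = letters[1:4], length = rep(1e5, 4),
                   depth = rep(13, 4))
  expect_equal(depthPartition(d2)$multi_copy_bp, 0)
  # a tie at exactly c * median stays single copy
  d3 <- data.frame(contig_id = c("a", "b"), length = c(1e6, 1e5),
                   depth = c(10, 15))
  expect_equal(depthPartition(d3)$multi_copy_bp, 0)
  expect_error(depthPartition(d2[0, ]), "empty")
})

test_that("compareGenomes composes coverage and identity", {
  lens <- c(s1 = 1000, s2 = 500)
  self <- AlignmentSet(query_id = names(lens), query_start = 0,
                       query_end = lens, ref_id = names(lens),
                       ref_start = 0, ref_end = lens, identity_pct = 100)
  r <- compareGenomes(self, lens, lens)
  expect_equal(r$query_covered_fraction, 1)
  expect_equal(r$ref_covered_fraction, 1)
  expect_equal(r$weighted_identity, 100)
  r0 <- compareGenomes(AlignmentSet(), lens, lens)
  expect_equal(r0$query_covered_fraction, 0)
  expect_true(is.na(r0$weighted_identity))
})

test_that("unplaced concordance counts ancestry-matched aligned bp", {
  calls <- callAncestry(aset("u1", list(c(0, 90000))), AlignmentSet(),
                        c(u1 = 1e5))
  expect_equal(callTable(calls)$category, "A_dominant")
  aln <- AlignmentSet(query_id = c("u1", "u1"),
                      query_start = c(0, 60000),
                      query_end = c(60000, 100000),
                      ref_id = "pchr1", ref_start = c(0, 60000),
                      ref_end = c(60000, 100000), identity_pct = 100)
  paint <- data.frame(chrom = "pchr1", start = c(0, 60000),
                      end = c(60000, 200000),
                      category = c("A_dominant", "B_dominant"))
  r <- unplacedConcordance(calls, aln, paint)
  expect_equal(r$aligned_fraction, 1)
  expect_equal(r$same_ancestry_fraction, 0.6)
  r0 <- unplacedConcordance(calls, AlignmentSet(), paint)
  expect_equal(r0$aligned_fraction, 0)
  expect_true(is.na(r0$same_ancestry_fraction))
})
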