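make_calls <- function(ids, cats, lens) {
  callAncestry(AlignmentSet(), AlignmentSet(),
               stats::setNames(lens, ids)) -> base
  df <- base@calls
  df$category <- cats
  methods::initialize(base, calls = df)
}

test_that("buildPainting colours components and keeps totals conserved", {
  agp <- data.frame(chrom = "pchr1", start = 0, end = 1e6,
                    part_number = 1L, component_type = "W",
                    component_id = "big", component_start = 0,
                    component_end = 1e6, orientation = "+",
                    is_gap = FALSE, gap_length = NA_real_)
  calls <- make_calls("big", "A_dominant", 1e6)
  p <- buildPainting(agp, calls)
  expect_equal(nrow(p$blocks), 1L)
  expect_equal(p$blocks$start, 0)
  expect_equal(p$blocks$end, 1e6)
  expect_equal(p$blocks$rgb, unname(paintingPalette()["A_dominant"]))
  # below the display threshold: no block, totals unchanged
  agp2 <- rbind(agp, data.frame(chrom = "pchr1", start = 1e6,
                                end = 1e6 + 5e4, part_number = 2L,
                                component_type = "W",
                                component_id = "small",
                                component_start = 0,
                                component_end = 5e4, orientation = "+",
                                is_gap = FALSE, gap_length = NA_real_))
  calls2 <- make_calls(c("big", "small"), c("A_dominant", "B_dominant"),
                       c(1e6, 5e4))
  p2 <- buildPainting(agp2, calls2)
  expect_equal(nrow(p2$blocks), 1L)
  expect_equal(p2$totals$below_threshold_bp, 5e4)
  expect_equal(p2$totals$displayed_bp + p2$totals$below_threshold_bp +
                 p2$totals$gap_bp, p2$totals$chrom_length)
  # a component without a call is painted unaligned with a warning
  expect_warning(p3 <- buildPainting(agp2, calls), "small")
  expect_equal(p3$totals$chrom_length, 1e6 + 5e4)
})

test_that("two-track painting places unplaced footprints on top", {
  agp <- data.frame(chrom = "pchr1", start = 0, end = 1e6,
                    part_number = 1L, component_type = "W",
                    component_id = "big", component_start = 0,
                    component_end = 1e6, orientation = "+",
                    is_gap = FALSE, gap_length = NA_real_)
  placed <- make_calls("big", "A_dominant", 1e6)
  unplaced <- make_calls("u1", "B_dominant", 1e5)
  # no unplaced alignments: top track empty
  t0 <- buildTwoTrackPainting(agp, placed, AlignmentSet(), unplaced)
  expect_equal(unique(t0$blocks$track), "placed")
  # one unplaced B contig aligned at [10 kb, 60 kb)
  ua <- AlignmentSet(query_id = "u1", query_start = 0, query_end = 5e4,
                     ref_id = "pchr1", ref_start = 1e4, ref_end = 6e4,
                     identity_pct = 95)
  t1 <- buildTwoTrackPainting(agp, placed, ua, unplaced)
  top <- t1$blocks[t1$blocks$track == "unplaced", ]
  expect_equal(nrow(top), 1L)
  expect_equal(top$start, 1e4)
  expect_equal(top$end, 6e4)
  expect_equal(top$category, "B_dominant")
  # top-track bp equals merged unplaced coverage
  ua2 <- c(ua, AlignmentSet(query_id = "u1", query_start = 0,
                            query_end = 3e4, ref_id = "pchr1",
                            ref_start = 3e4, ref_end = 6e4,
                            identity_pct = 95))
  t2 <- buildTwoTrackPainting(agp, placed, ua2, unplaced)
  top2 <- t2$blocks[t2$blocks$track == "unplaced", ]
  expect_equal(sum(top2$end - top2$start), 5e4)
})

test_that("repeat summary merges per class and bridges the union", {
  hits <- data.frame(repeat_class = "LTR/Gypsy", target_id = "chr1",
                     start = c(0, 300), end = c(100, 400))
  r <- repeatSummary(hits, 1000)
  expect_equal(r$classes$masked_bp, 200)
  expect_equal(r$classes$pct_genome, 20)
  expect_equal(r$total_masked_bp, 200)
  # overlapping hits of one class count once; across classes per class
  hits2 <- rbind(hits,
                 data.frame(repeat_class = c("LTR/Gypsy", "LTR/Copia"),
                            target_id = "chr1", start = c(50, 0),
                            end = c(150, 100)))
  r2 <- repeatSummary(hits2, 1000)
  gypsy <- r2$classes$masked_bp[r2$classes$repeat_class == "LTR/Gypsy"]
  expect_equal(gypsy, 250)            # [0,150) + [300,400)
  expect_equal(r2$total_masked_bp, 350)      # per-class sum
  expect_equal(r2$union_masked_bp, 250)      # cross-class union
  expect_gte(r2$total_masked_bp, r2$union_masked_bp)
  expect_error(repeatSummary(hits, 0), "genome_size")
})

test_that("repeat summary matches the boolean-mask oracle on random hits", {
  set.seed(106)
  n <- 150
  hits <- data.frame(
    repeat_class = sample(c("LTR/Gypsy", "LTR/Copia", "DNA/MULE"), n, TRUE),
    target_id = sample(c("c1", "c2"), n, TRUE),
    start = sample(0:9000, n, TRUE))
  hits$end <- pmin(hits$start + sample(20:900, n, TRUE), 10000)
  r <- repeatSummary(hits, 20000)
  for (cl in unique(hits$repeat_class)) {
    h <- hits[hits$repeat_class == cl, ]
    want <- sum(vapply(split(h, h$target_id), function(d)
      mask_total_bp(d$start, d$end, 10000), numeric(1)))
    expect_equal(r$classes$masked_bp[r$classes$repeat_class == cl], want)
  }
  union_want <- sum(vapply(split(hits, hits$target_id), function(d)
    mask_bridge(d$start, d$end, 10000, 10, 20000)$total_bp, numeric(1)))
  expect_equal(r$union_masked_bp, union_want)
})

test_that("family counts preserve first-appearance order and tally", {
  r <- familyCountTable(paste0("g", 1:5),
                        c("SWEET", "TST", "SWEET", "PLT", "TST"))
  expect_equal(r$table$family, c("SWEET", "TST", "PLT"))
  expect_equal(r$table$count, c(2L, 2L, 1L))
  expect_equal(r$total, 5L)
  r0 <- familyCountTable(character(), character())
  expect_equal(r0$total, 0L)
  expect_equal(nrow(r0$table), 0L)
  # random tally oracle
  set.seed(107)
  fam <- sample(LETTERS[1:9], 1000, replace = TRUE)
  r1 <- familyCountTable(paste0("g", 1:1000), fam)
  expect_equal(sum(r1$table$count), 1000L)
  for (f in unique(fam))
    expect_equal(r1$table$count[r1$table$family == f], sum(fam == f))
})
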