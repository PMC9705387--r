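test_that("mergeIntervals unions, sorts and merges touching intervals", {
  m <- mergeIntervals(c(0, 5, 30), c(10, 20, 40))
  expect_equal(m$start, c(0, 30))
  expect_equal(m$end, c(20, 40))
  expect_equal(attr(m, "total_bp"), 30)
  # touching intervals merge
  expect_equal(nrow(mergeIntervals(c(0, 10), c(10, 20))), 1L)
  # empty input is the empty set
  e <- mergeIntervals(numeric(), numeric())
  expect_equal(nrow(e), 0L)
  expect_equal(attr(e, "total_bp"), 0)
  expect_error(mergeIntervals(5, 5), "end > start")
})

test_that("merged totals equal the boolean-mask oracle on random sets", {
  set.seed(101)
  for (k in 1:200) {
    n <- sample(1:30, 1)
    s <- sample(0:9900, n, replace = TRUE)
    w <- sample(1:300, n, replace = TRUE)
    e <- pmin(s + w, 10000)
    m <- mergeIntervals(s, e)
    expect_equal(attr(m, "total_bp"), mask_total_bp(s, e, 10000))
    expect_equal(m, mask_merge(s, e, 10000), ignore_attr = TRUE)
  }
})

test_that("merge is idempotent and monotone", {
  set.seed(102)
  s <- sample(0:5000, 40, replace = TRUE); e <- s + sample(1:500, 40, TRUE)
  m1 <- mergeIntervals(s, e)
  m2 <- mergeIntervals(m1$start, m1$end)
  expect_equal(m1, m2, ignore_attr = TRUE)
  # adding an interval never decreases total bp
  m3 <- mergeIntervals(c(s, 9000), c(e, 9500))
  expect_gte(attr(m3, "total_bp"), attr(m1, "total_bp"))
})

test_that("coveredFraction merges per sequence and aggregates over all", {
  aln <- AlignmentSet(query_id = c("c1", "c1"), query_start = c(0, 25),
                      query_end = c(50, 75), ref_id = "r",
                      ref_start = c(0, 25), ref_end = c(50, 75),
                      identity_pct = 100)
  cf <- coveredFraction(aln, "query", c(c1 = 100))
  expect_equal(cf$per_sequence[["c1"]], 0.75)
  expect_equal(cf$aggregate, 0.75)
  # sequences with no alignments dilute the aggregate
  cf2 <- coveredFraction(aln, "query", c(c1 = 100, c2 = 100))
  expect_equal(cf2$per_sequence[["c2"]], 0)
  expect_equal(cf2$aggregate, 0.375)
  # no alignments at all
  expect_equal(coveredFraction(AlignmentSet(), "query",
                               c(c1 = 100))$aggregate, 0)
  expect_error(coveredFraction(aln, "query", c(zz = 5)), "c1")
})

test_that("full-length self-alignment gives coverage exactly 1", {
  lens <- c(a = 1234, b = 777)
  aln <- AlignmentSet(query_id = names(lens), query_start = 0,
                      query_end = lens, ref_id = names(lens),
                      ref_start = 0, ref_end = lens, identity_pct = 100)
  expect_identical(coveredFraction(aln, "query", lens)$aggregate, 1)
  expect_identical(coveredFraction(aln, "reference", lens)$aggregate, 1)
})

test_that("weighted identity is the column-weighted mean", {
  aln <- AlignmentSet(query_id = c("a", "b"), query_start = 0,
                      query_end = c(100, 300), ref_id = "r", ref_start = 0,
                      ref_end = c(100, 300), identity_pct = c(90, 98))
  expect_equal(weightedIdentity(aln), 96)
  expect_equal(plainMeanIdentity(aln), 94)
  expect_equal(weightedIdentity(aln[1]), 90)   # single record
  expect_error(weightedIdentity(AlignmentSet()), "empty")
  # brute-force check on random records
  set.seed(103)
  n <- 50
  cols <- sample(10:1000, n)
  idy <- runif(n, 60, 100)
  x <- AlignmentSet(query_id = paste0("q", 1:n), query_start = 0,
                    query_end = cols, ref_id = "r", ref_start = 0,
                    ref_end = cols, aligned_columns = cols,
                    identity_pct = idy)
  brute <- sum(idy * cols) / sum(cols)
  expect_equal(weightedIdentity(x), brute)
  expect_gte(weightedIdentity(x), min(idy))
  expect_lte(weightedIdentity(x), max(idy))
})

test_that("bridging closes only gaps strictly below max_gap", {
  b <- bridgeAndCount(data.frame(start = c(0, 15005),
                                 end = c(15000, 26000)))
  expect_equal(nrow(b$bridged), 1L)
  expect_equal(b$n_large, 1L)
  b2 <- bridgeAndCount(data.frame(start = c(0, 15020),
                                  end = c(15000, 26000)))
  expect_equal(nrow(b2$bridged), 2L)
  expect_equal(b2$n_large, 0L)
  # a gap of exactly max_gap survives
  b3 <- bridgeAndCount(data.frame(start = c(0, 110), end = c(100, 200)),
                       max_gap = 10, min_region = 50)
  expect_equal(nrow(b3$bridged), 2L)
  expect_error(bridgeAndCount(data.frame(start = 0, end = 1),
                              max_gap = -1), "max_gap")
})

test_that("bridge counts match the dilate-then-label oracle", {
  set.seed(104)
  for (k in 1:100) {
    n <- sample(2:25, 1)
    s <- sample(0:9000, n, replace = TRUE)
    e <- pmin(s + sample(1:800, n, replace = TRUE), 10000)
    gap <- sample(c(0, 3, 10, 25), 1)
    minr <- sample(c(200, 1000, 2000), 1)
    b <- bridgeAndCount(data.frame(start = s, end = e),
                        max_gap = gap, min_region = minr)
    o <- mask_bridge(s, e, 10000, gap, minr)
    expect_equal(attr(b$bridged, "total_bp"), o$total_bp)
    expect_equal(b$n_large, o$n_large)
  }
})

test_that("bridging with max_gap = 0 is the identity on merged sets", {
  set.seed(105)
  s <- sample(0:9000, 20); e <- s + sample(1:500, 20, TRUE)
  m <- mergeIntervals(s, e)
  b <- bridgeAndCount(m, max_gap = 0, min_region = 100)
  expect_equal(b$bridged, m, ignore_attr = TRUE)
})
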