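rleTrack <- function(...) {
  # build an RleList track from named per-chromosome numeric vectors
  vals <- list(...)
  as(lapply(vals, Rle), "RleList")
}

test_that("depth filter keeps positions within bounds in every sample", {
  t1 <- rleTrack(chr1 = rep(35, 1000))
  r <- depthReliableRegions(list(t1))
  expect_equal(regionSize(r), 1000)

  # one failing sample suffices to remove a position
  a <- rleTrack(chr1 = c(rep(10, 500), rep(10, 500)))
  b <- rleTrack(chr1 = c(rep(10, 500), rep(7, 500)))
  r <- depthReliableRegions(list(a, b))
  expect_equal(regionSize(r), 500)
  expect_equal(end(r), 500)

  # bounds are inclusive: exactly 8 and exactly 100 pass
  d <- rleTrack(chr1 = c(8, 100, 7, 101, 50))
  r <- depthReliableRegions(list(d))
  expect_true(regionMask(r, "chr1", 5)[1])
  expect_true(regionMask(r, "chr1", 5)[2])
  expect_false(regionMask(r, "chr1", 5)[3])
  expect_false(regionMask(r, "chr1", 5)[4])
  expect_error(depthReliableRegions(list()), "at least one")
})

test_that("hyperpolymorphic windows match the spec examples", {
  sl <- c(chr1 = 3000L)
  # two variants in [1,1000] discard that window; [501,1500] holds one
  calls <- makeCalls("chr1", c(100, 700), "C", "T")
  bad <- hyperpolymorphicWindows(calls, sl)
  m <- regionMask(bad, "chr1", 3000)
  expect_true(all(m[1:1000]))
  expect_false(any(m[1001:3000]))

  expect_equal(length(hyperpolymorphicWindows(
    makeCalls("chr1", 1234, "C", "T"), sl)), 0L)
  # 100 and 1600: no window holds both
  expect_equal(length(hyperpolymorphicWindows(
    makeCalls("chr1", c(100, 1600), "C", "T"), sl)), 0L)
})

test_that("window filter equals brute-force window enumeration", {
  set.seed(402)
  for (rep in 1:6) {
    len <- sample(20000:100000, 1)
    n <- sample(10:500, 1)
    pos <- sort(sample(len, n))
    calls <- makeCalls("chr1", pos, "C", "T")
    got <- hyperpolymorphicWindows(calls, c(chr1 = len))
    expect_identical(regionMask(got, "chr1", len),
                     bruteDiscardMask(pos, len))
  }
})

test_that("region subtraction and intersection follow set semantics", {
  a <- GRanges("chr1", IRanges(1, 1000))
  b <- GRanges("chr1", IRanges(501, 1500))
  d <- regionSubtract(a, b)
  expect_equal(start(d), 1); expect_equal(end(d), 500)
  expect_equal(regionSize(d), 500)
  expect_equal(regionSize(regionSubtract(a, GRanges())), 1000)
  expect_equal(regionSize(regionSubtract(a, a)), 0)

  i <- regionIntersect(a, b)
  expect_equal(start(i), 501); expect_equal(end(i), 1000)
  expect_equal(regionSize(regionIntersect(a, GRanges("chr1", IRanges(2000, 3000)))), 0)
})

test_that("region arithmetic matches per-base boolean-mask oracles", {
  set.seed(77)
  len <- 10000
  randRegions <- function() {
    s <- sort(sample(len, 12))
    GenomicRanges::reduce(GRanges("chr1",
                                  IRanges(s, pmin(s + sample(50:900, 12,
                                                             TRUE), len))))
  }
  for (rep in 1:8) {
    a <- randRegions(); b <- randRegions()
    ma <- regionMask(a, "chr1", len); mb <- regionMask(b, "chr1", len)
    expect_identical(regionMask(regionSubtract(a, b), "chr1", len), ma & !mb)
    expect_identical(regionMask(regionIntersect(a, b), "chr1", len), ma & mb)
    expect_identical(regionMask(regionIntersect(a, b), "chr1", len),
                     regionMask(regionIntersect(b, a), "chr1", len))
    expect_equal(regionSize(regionSubtract(a, b)), sum(ma & !mb))
  }
})

test_that("pairwise-distance mode drops mutual close neighbors", {
  calls <- makeCalls("chr1", c(100, 700, 2500, 4000, 4900), "C", "T")
  kept <- pairwiseDistanceFilter(calls, minSpacing = 1000)
  # 100/700 and 4000/4900 are mutual close pairs; only 2500 survives
  expect_equal(variantPos(kept), 2500L)
  # a 900-bp pair inside one window is discarded by both formulations ...
  sl <- c(chr1 = 6000L)
  calls2 <- makeCalls("chr1", c(550, 1450), "C", "T")
  expect_equal(length(hyperpolymorphicWindows(calls2, sl)), 1L)
  expect_equal(length(pairwiseDistanceFilter(calls2)), 0L)
  # ... but a 900-bp pair straddling a window boundary splits the two modes
  calls3 <- makeCalls("chr1", c(450, 1350), "C", "T")
  expect_equal(length(hyperpolymorphicWindows(calls3, sl)), 0L)
  expect_equal(length(pairwiseDistanceFilter(calls3)), 0L)
})
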