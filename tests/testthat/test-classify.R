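test_that("GQ filter masks at the boundary and drops evidence-free variants", {
  calls <- makeCalls("chr1", c(100, 200, 300), "C", "T",
                     gt = matrix(c("het", "het", "het",
                                   "hom_ref", "hom_ref", "het"), 3, 2),
                     gq = matrix(c(21, 20, 19, 80, 80, 25), 3, 2))
  out <- gqFilter(calls, minGQ = 20)
  # GQ 21 survives (strict inequality), GQ 20 and 19 are masked
  expect_equal(length(out), 2L)
  expect_equal(variantPos(out), c(100L, 300L))
  # position 300: first sample masked, second het call carries the evidence
  expect_equal(unname(genotypes(out)[2, ]), c("missing", "het"))
  # variant whose only carrier is masked is dropped entirely
  expect_false(200L %in% variantPos(out))
})

test_that("family genotype aggregates pooled samples by the any-het rule", {
  gt <- matrix(c("het", "hom_alt", "hom_alt", "hom_ref",
                 "hom_ref", "hom_alt", "het", "hom_ref",
                 "missing", "hom_alt", "hom_ref", "hom_ref",
                 "hom_ref", "hom_alt", "hom_ref", "hom_ref"), 4, 4)
  calls <- makeCalls("chr1", c(10, 20, 30, 40) * 100, "C", "T", gt = gt)
  expect_equal(familyGenotype(calls),
               c("het", "hom_alt", "het", "absent"))
})

test_that("classification splits shared / specific-hom / EMS correctly", {
  ns <- 4
  fam <- function(pos, ref, alt, zyg) {
    makeCalls("chr1", pos, ref, alt,
              gt = matrix(rep(zyg, each = ns), length(pos), ns, byrow = TRUE))
  }
  l1 <- fam(c(500, 1000, 1500, 2000), c("C", "G", "C", "A"),
            c("T", "A", "A", "G"), c("het", "hom_alt", "hom_alt", "het"))
  l2 <- fam(c(500, 3000), c("C", "G"), c("T", "T"), c("het", "het"))
  cl <- classifyVariants(list(L1 = l1, L2 = l2))
  expect_equal(length(sharedCalls(cl, "L1")), 1L)      # chr1:500 C>T
  expect_equal(variantPos(specificHomCalls(cl, "L1")), c(1000L, 1500L))
  expect_equal(variantPos(emsCalls(cl, "L1")), 2000L)
  expect_equal(variantPos(emsCalls(cl, "L2")), 3000L)
  expect_equal(length(specificHomCalls(cl, "L2")), 0L)

  # sharing requires the identical ALT allele, not just the position
  l2b <- fam(500, "C", "G", "het")
  cl2 <- classifyVariants(list(L1 = l1, L2 = l2b))
  expect_equal(length(sharedCalls(cl2, "L1")), 0L)

  # swapping families swaps the per-family sets and keeps shared fixed
  clSwap <- classifyVariants(list(L2 = l2, L1 = l1))
  expect_equal(variantKeys(emsCalls(clSwap, "L1")),
               variantKeys(emsCalls(cl, "L1")))
  expect_equal(length(sharedCalls(clSwap, "L2")), length(sharedCalls(cl, "L2")))
})

test_that("classification partitions every filtered record exactly once", {
  sim <- smallSim(seed = 23)
  calls <- lapply(sim$calls, gqFilter)
  cl <- classifyVariants(calls)
  for (f in familyIds(cl)) {
    keys <- variantKeys(calls[[f]])
    keys <- keys[familyGenotype(calls[[f]]) != "absent"]
    got <- c(variantKeys(sharedCalls(cl, f)),
             variantKeys(specificHomCalls(cl, f)),
             variantKeys(emsCalls(cl, f)))
    expect_setequal(got, keys)
    expect_equal(length(got), length(unique(got)))  # disjoint
  }
  # shared views of the two families list the same variant keys
  expect_setequal(variantKeys(sharedCalls(cl, "L1")),
                  variantKeys(sharedCalls(cl, "L2")))
})

test_that("shared fractions reproduce the percentage arithmetic", {
  expect_equal(sharedPercent(4031, 6140), 65.7)
  expect_equal(sharedPercent(4031, 5252), 76.8)
  expect_equal(sharedPercent(0, 10), 0)
  expect_error(sharedPercent(0, 0), "zero")

  sim <- smallSim(seed = 23)
  cl <- classifyVariants(lapply(sim$calls, gqFilter))
  ns <- length(sharedCalls(cl, "L1"))
  tot <- ns + length(specificHomCalls(cl, "L1")) + length(emsCalls(cl, "L1"))
  expect_equal(sharedFraction(cl, "L1"), roundHalfUp(100 * ns / tot, 1))
})
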