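posFixture <- function(chromA, chromB, pa = 50, pb = 50,
                       unknownChrom = "chrUn") {
  data.frame(id_a = sprintf("a%d", seq_along(chromA)),
             id_b = sprintf("b%d", seq_along(chromA)),
             chrom_a = chromA, chrom_b = chromB,
             pos_a_pct = pa, pos_b_pct = pb,
             placement_a = placementFromChrom(chromA, unknownChrom),
             placement_b = placementFromChrom(chromB, unknownChrom),
             stringsAsFactors = FALSE)
}

test_that("positions normalise to midpoint percent of chromosome length", {
  gsA <- GeneSet(c("chr1", "chr1"), c(100, 901), c(300, 1000), c("+", "+"),
                 c("a1", "a2"), versionLabel = "A")
  gsB <- GeneSet(c("chr1", "chr1"), c(100, 901), c(300, 1000), c("+", "+"),
                 c("b1", "b2"), versionLabel = "B")
  pos <- normalizePositions(data.frame(id_a = c("a1", "a2"),
                                       id_b = c("b1", "b2")),
                            gsA, gsB,
                            chromLengthsA = c(chr1 = 1000),
                            chromLengthsB = c(chr1 = 1000))
  expect_equal(pos$pos_a_pct, c(20, 95.05))
  expect_equal(pos$pos_b_pct, c(20, 95.05))
  # inferred lengths: max gene end
  pos2 <- normalizePositions(data.frame(id_a = "a1", id_b = "b1"), gsA, gsB)
  expect_equal(pos2$pos_a_pct, 20)
})

test_that("pair categories partition the pairs with unknown precedence", {
  pos <- posFixture(c("chr5", "chrUn", "chr6", "chr3", "chr16_random"),
                    c("chr5", "chr3", "chr15", "chrUn", "chr16_random"))
  out <- categorizePairs(pos)
  expect_equal(out$pair_category,
               c("same_chrom", "unknown_involved", "different_or_random",
                 "unknown_involved", "different_or_random"))
  counts <- attr(out, "counts")
  expect_equal(sum(counts), nrow(pos))
})

test_that("placement modifications are labelled by type", {
  pos <- categorizePairs(posFixture(
    c("chrUn", "chr16_random", "chr16_random", "chr6", "chr1"),
    c("chr7", "chr16", "chr3", "chr15", "chr1")))
  out <- detectModifications(pos)
  expect_equal(out$modification,
               c("newly_placed_from_unknown", "newly_placed_from_random",
                 "reassigned", "reassigned", "none"))
  flows <- attr(out, "summary")$flows
  expect_equal(sort(flows$chrom_a), c("chr16_random", "chr6"))
})

test_that("inversion runs are maximal descending stretches in B order", {
  # identity ordering: no runs
  n <- 20
  pos <- posFixture(rep("chr1", n), rep("chr1", n),
                    pa = seq(5, 95, length.out = n),
                    pb = seq(5, 95, length.out = n))
  pos <- categorizePairs(pos)
  expect_equal(nrow(detectInversionRuns(pos)$runs), 0)

  # one planted 12-gene inversion
  pa <- seq(5, 95, length.out = n)
  pa[5:16] <- rev(pa[5:16])
  pos2 <- categorizePairs(posFixture(rep("chr1", n), rep("chr1", n),
                                     pa = pa,
                                     pb = seq(5, 95, length.out = n)))
  inv <- detectInversionRuns(pos2)
  expect_equal(nrow(inv$runs), 1)
  expect_equal(inv$runs$length, 12)
  expect_equal(sum(inv$positions$modification == "inverted_block_member"),
               12)

  # two inversions separated by collinear genes
  n <- 30
  pa <- seq(2, 98, length.out = n)
  pa[3:8] <- rev(pa[3:8]); pa[20:27] <- rev(pa[20:27])
  pos3 <- categorizePairs(posFixture(rep("chr1", n), rep("chr1", n),
                                     pa = pa,
                                     pb = seq(2, 98, length.out = n)))
  runs3 <- detectInversionRuns(pos3)$runs
  expect_equal(nrow(runs3), 2)
  expect_setequal(runs3$length, c(6, 8))
})

test_that("globally reversing both coordinate systems is not an inversion", {
  set.seed(81)
  n <- 25
  pb <- sort(runif(n, 1, 99))
  pa <- pb + rnorm(n, 0, 0.2)
  pos <- categorizePairs(posFixture(rep("chr1", n), rep("chr1", n),
                                    pa = pa, pb = pb))
  rev <- categorizePairs(posFixture(rep("chr1", n), rep("chr1", n),
                                    pa = 100 - pa, pb = 100 - pb))
  expect_equal(nrow(detectInversionRuns(pos)$runs),
               nrow(detectInversionRuns(rev)$runs))
})

test_that("planted positional events are recovered from simulations", {
  sim <- simulateAssemblyPair(smallSimConfig(seed = 82, nRelocate = 2,
                                             chromosomes = 2,
                                             genesPerChromosome = 40))
  res <- reconcilePair(simGenesA(sim), simGenesB(sim),
                       proteins = simProteins(sim),
                       proteinFlags = simProteinFlags(sim))
  truth <- truthPositionLabels(sim)
  pos <- res$positions
  got <- setNames(pos$modification, pos$id_b)
  for (r in seq_len(nrow(truth)))
    expect_equal(unname(got[truth$id_b[r]]), truth$truth[r],
                 info = truth$id_b[r])
  # and no spurious inversion members
  expect_setequal(pos$id_b[pos$modification == "inverted_block_member"],
                  truth$id_b[truth$truth == "inverted_block_member"])
})

test_that("the position scatter plot renders without error", {
  pos <- categorizePairs(posFixture(rep("chr1", 5), rep("chr1", 5),
                                    pa = 1:5 * 10, pb = 1:5 * 10))
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plotPairPositions(pos))
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
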