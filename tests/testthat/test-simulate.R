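test_that("identical config and seed give byte-identical output", {
  s1 <- simulateAssemblyPair(smallSimConfig(seed = 9))
  s2 <- simulateAssemblyPair(smallSimConfig(seed = 9))
  expect_identical(geneTable(simGenesA(s1)), geneTable(simGenesA(s2)))
  expect_identical(geneTable(simGenesB(s1)), geneTable(simGenesB(s2)))
  expect_identical(as.character(geneSequences(simGenesB(s1))),
                   as.character(geneSequences(simGenesB(s2))))
  expect_identical(simTruth(s1), simTruth(s2))
  expect_identical(simEvents(s1), simEvents(s2))
  s3 <- simulateAssemblyPair(smallSimConfig(seed = 10))
  expect_false(identical(as.character(geneSequences(simGenesB(s1))),
                         as.character(geneSequences(simGenesB(s3)))))
})

test_that("with no events and zero divergence the versions are identical", {
  cfg <- simulationConfig(chromosomes = 1, genesPerChromosome = 25,
                          nSplitInB = 0, nMergeInB = 0,
                          nTandemExpandInB = 0, nChimeraInB = 0,
                          nChimeraTripleInB = 0, nChimeraInA = 0,
                          nInvertBlocks = 0, nRelocate = 0, nUnplaceInA = 0,
                          nDropFromA = 0, nDropFromB = 0, seed = 3)
  sim <- simulateAssemblyPair(cfg)
  tr <- simTruth(sim)
  seqA <- as.character(geneSequences(simGenesA(sim)))
  seqB <- as.character(geneSequences(simGenesB(sim)))
  expect_identical(unname(seqA[tr$ids_A]), unname(seqB[tr$ids_B]))
  # the downstream classifier must call every gene OK
  res <- reconcilePair(simGenesA(sim), simGenesB(sim))
  expect_true(all(res$calls$call == "OK"))
})

test_that("gene counts are conserved exactly against the event log", {
  sim <- simulateAssemblyPair(smallSimConfig(seed = 5))
  cfg <- sim@config
  ev <- simEvents(sim)
  kOf <- function(type) {
    sub <- ev[ev$type == type, , drop = FALSE]
    lengths(strsplit(sub$anc_ids, ","))
  }
  n <- cfg$chromosomes * cfg$genesPerChromosome
  expNumB <- n - cfg$nDropFromB - sum(kOf("chimera_in_B") - 1L) +
    cfg$nSplitInB + cfg$nTandemExpandInB * (cfg$tandemCopies - 1L)
  expNumA <- n - cfg$nDropFromA - sum(kOf("chimera_in_A") - 1L) +
    cfg$nMergeInB
  expect_equal(length(simGenesB(sim)), expNumB)
  expect_equal(length(simGenesA(sim)), expNumA)
  # the truth map covers every emitted gene exactly once
  tr <- simTruth(sim)
  idsB <- unlist(strsplit(tr$ids_B, ","))
  expect_setequal(unique(idsB), geneIds(simGenesB(sim)))
  idsA <- unlist(strsplit(tr$ids_A, ","))
  expect_setequal(unique(idsA), geneIds(simGenesA(sim)))
})

test_that("each ancestral gene participates in at most one event", {
  sim <- simulateAssemblyPair(smallSimConfig(seed = 2))
  ids <- unlist(strsplit(simEvents(sim)$anc_ids, ","))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("infeasible configurations are rejected before generation", {
  expect_error(
    simulationConfig(chromosomes = 1, genesPerChromosome = 10,
                     nSplitInB = 50) |> simulateAssemblyPair(),
    "infeasible")
})

test_that("protein evidence emission follows the rate and the seed", {
  anc <- setNames(replicate(100, randomDna(300)), sprintf("anc%03d", 1:100))
  set.seed(11)
  ev1 <- makeProteinEvidence(anc, evidenceRate = 0.5)
  set.seed(11)
  ev2 <- makeProteinEvidence(anc, evidenceRate = 0.5)
  expect_identical(names(ev1$flags), names(ev2$flags))
  expect_lt(length(ev1$flags), 100)
  expect_true(all(ev1$flags))
  full <- makeProteinEvidence(anc, evidenceRate = 1)
  expect_equal(length(full$flags), 100)
})

test_that("planted sequence edits follow their event semantics", {
  sim <- simulateAssemblyPair(smallSimConfig(seed = 4))
  tr <- simTruth(sim)
  seqA <- as.character(geneSequences(simGenesA(sim)))
  seqB <- as.character(geneSequences(simGenesB(sim)))
  anc <- as.character(sim@ancestral)

  # split parts partition the ancestral sequence
  sp <- tr[tr$event == "split_in_B", ][1, ]
  parts <- strsplit(sp$ids_B, ",")[[1]]
  expect_equal(paste(seqB[parts], collapse = ""), unname(anc[sp$anc_id]))
  expect_true(all(nchar(seqB[parts]) >= sim@config$minPartLength))

  # chimeras concatenate their members' sequences
  ch <- simEvents(sim)[simEvents(sim)$type == "chimera_in_B", ][1, ]
  members <- strsplit(ch$anc_ids, ",")[[1]]
  fusedId <- unique(unlist(strsplit(tr$ids_B[tr$anc_id %in% members], ",")))
  expect_length(fusedId, 1)
  expect_equal(unname(seqB[fusedId]),
               paste(anc[members], collapse = ""))

  # inverted blocks reverse gene order and strand in B
  inv <- simEvents(sim)[simEvents(sim)$type == "invert_block", ][1, ]
  mids <- strsplit(inv$anc_ids, ",")[[1]]
  bIds <- tr$ids_B[match(mids, tr$anc_id)]
  tabB <- geneTable(simGenesB(sim))
  rows <- tabB[match(bIds, tabB$gene_id), ]
  expect_true(all(rows$strand == "-"))
  expect_true(all(diff(rows$start) < 0))   # ancestral order reversed

  # unplace events move the gene to the unknown chromosome in A only
  up <- tr[tr$event == "unplace_in_A", ][1, ]
  tabA <- geneTable(simGenesA(sim))
  expect_equal(tabA$chromosome[tabA$gene_id == up$ids_A], "chrUn")
  expect_equal(tabB[tabB$gene_id == up$ids_B, "placement"], "placed")
})
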