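# build a MatchGraph directly from an edge table (test shortcut)
graphFromEdges <- function(edges, gsA, gsB) {
  new("MatchGraph", edges = edges, nodesA = geneIds(gsA),
      nodesB = geneIds(gsB), versionA = versionLabel(gsA),
      versionB = versionLabel(gsB))
}

edgeRow <- function(ida, idb, as, ae, bs, be, bits = 800) {
  data.frame(id_a = ida, id_b = idb, a_start = as, a_end = ae,
             b_start = bs, b_end = be, direction = "both",
             bit_score = bits, pct_identity = 99,
             stringsAsFactors = FALSE)
}

# evidence rows: protein hit fully covering itself, at a gene interval
evRow <- function(protein, gene, version, gs, ge, plen = ge - gs + 1) {
  data.frame(protein_id = protein, gene_id = gene, version = version,
             p_start = 1, p_end = plen, g_start = gs, g_end = ge,
             protein_length = plen, flagged = TRUE,
             stringsAsFactors = FALSE)
}

test_that("tandem expansions are called redundant on the B side", {
  gsA <- lineGeneSet("a1", "A")
  gsB <- lineGeneSet(c("b1", "b2"), "B")
  edges <- rbind(edgeRow("a1", "b1", 1, 1000, 1, 1000),
                 edgeRow("a1", "b2", 5, 995, 1, 990))
  calls <- classifyCardinality(graphFromEdges(edges, gsA, gsB), gsA, gsB)
  expect_equal(calls$call[calls$gene_id %in% c("b1", "b2")],
               c("redundant", "redundant"))
  expect_equal(calls$degree[calls$gene_id == "a1"], 2)
})

test_that("an incorrect split in B (one protein spans) is called overlap", {
  gsA <- lineGeneSet("a1", "A", geneLen = 1000)
  gsB <- lineGeneSet(c("b1", "b2"), "B", geneLen = 450)
  edges <- rbind(edgeRow("a1", "b1", 1, 450, 1, 450),
                 edgeRow("a1", "b2", 551, 1000, 1, 450))
  ev <- evRow("p1", "a1", "A", 1, 1000)
  calls <- classifyCardinality(graphFromEdges(edges, gsA, gsB), gsA, gsB,
                               evidence = ev)
  expect_true(all(calls$call[calls$gene_id %in% c("a1", "b1", "b2")] ==
                    "overlap"))
  expect_equal(unique(calls$evidence[calls$call == "overlap"]),
               "protein-single")
})

test_that("a correct split in B (distinct proteins) is called split", {
  gsA <- lineGeneSet("a1", "A", geneLen = 1000)
  gsB <- lineGeneSet(c("b1", "b2"), "B", geneLen = 450)
  edges <- rbind(edgeRow("a1", "b1", 1, 450, 1, 450),
                 edgeRow("a1", "b2", 551, 1000, 1, 450))
  ev <- rbind(evRow("p1", "a1", "A", 1, 450),
              evRow("p2", "a1", "A", 551, 1000))
  calls <- classifyCardinality(graphFromEdges(edges, gsA, gsB), gsA, gsB,
                               evidence = ev)
  expect_true(all(calls$call[calls$gene_id %in% c("a1", "b1", "b2")] ==
                    "split"))
})

test_that("chimeras in B are called to_split and proposals are emitted", {
  gsA <- lineGeneSet(c("a1", "a2"), "A", geneLen = 450)
  gsB <- lineGeneSet("b1", "B", geneLen = 1000)
  edges <- rbind(edgeRow("a1", "b1", 1, 450, 1, 450),
                 edgeRow("a2", "b1", 1, 450, 551, 1000))
  ev <- rbind(evRow("p1", "b1", "B", 1, 450),
              evRow("p2", "b1", "B", 551, 1000))
  calls <- classifyCardinality(graphFromEdges(edges, gsA, gsB), gsA, gsB,
                               evidence = ev)
  expect_equal(calls$call[calls$gene_id == "b1"], "to_split")
  expect_equal(calls$evidence[calls$gene_id == "b1"], "protein-multiple")
  prop <- proposeSplits(calls)
  expect_equal(prop$summary$n_new, 1)
  expect_equal(prop$proposals$new_id, c("b1", "b1_2"))

  # the same component without evidence must not be guessed
  calls0 <- classifyCardinality(graphFromEdges(edges, gsA, gsB), gsA, gsB)
  expect_equal(calls0$call[calls0$gene_id == "b1"], "unresolved")
  expect_true(calls0$unresolved[calls0$gene_id == "b1"])
})

test_that("a correct merge in B (one protein spans B) is called merged", {
  gsA <- lineGeneSet(c("a1", "a2"), "A", geneLen = 450)
  gsB <- lineGeneSet("b1", "B", geneLen = 1000)
  edges <- rbind(edgeRow("a1", "b1", 1, 450, 1, 450),
                 edgeRow("a2", "b1", 1, 450, 551, 1000))
  ev <- evRow("p1", "b1", "B", 1, 1000)
  calls <- classifyCardinality(graphFromEdges(edges, gsA, gsB), gsA, gsB,
                               evidence = ev)
  expect_true(all(calls$call[calls$gene_id %in% c("a1", "a2", "b1")] ==
                    "merged"))
})

test_that("same-portion hubs on the A side are not interpreted", {
  gsA <- lineGeneSet(c("a1", "a2"), "A")
  gsB <- lineGeneSet("b1", "B")
  edges <- rbind(edgeRow("a1", "b1", 1, 1000, 1, 1000, bits = 900),
                 edgeRow("a2", "b1", 1, 1000, 5, 995, bits = 700))
  calls <- classifyCardinality(graphFromEdges(edges, gsA, gsB), gsA, gsB)
  expect_equal(calls$call[calls$gene_id == "b1"], "OK")
  expect_equal(calls$partners[calls$gene_id == "b1"], "a1")
  expect_equal(calls$call[calls$gene_id == "a2"], "unmatched")
})

test_that("split accounting follows the sum of parts minus one", {
  mkParts <- function(src, k) {
    data.frame(source_gene = src, part_index = seq_len(k),
               g_start = (seq_len(k) - 1) * 600 + 1,
               g_end = (seq_len(k) - 1) * 600 + 450,
               protein_id = paste0(src, "_p", seq_len(k)),
               stringsAsFactors = FALSE)
  }
  parts <- rbind(
    do.call(rbind, lapply(sprintf("g%02d", 1:7), mkParts, k = 2)),
    do.call(rbind, lapply(sprintf("t%02d", 1:3), mkParts, k = 3)))
  prop <- proposeSplits(parts = parts)
  expect_equal(prop$summary$n_genes_split, 10)
  expect_equal(prop$summary$n_triple, 3)
  expect_equal(prop$summary$n_new, 13)   # 7*1 + 3*2
  expect_true(all(grepl("_2$", prop$proposals$new_id[
    prop$proposals$part_index == 2])))
  expect_equal(proposeSplits(parts = parts[0, ])$summary$n_new, 0)
})

test_that("overlapping split parts invalidate the proposal", {
  parts <- data.frame(source_gene = "g1", part_index = 1:2,
                      g_start = c(1, 100), g_end = c(500, 600),
                      protein_id = c("p1", "p2"))
  prop <- proposeSplits(parts = parts, overlapTolerance = 0.2)
  expect_equal(prop$summary$n_new, 0)
  expect_equal(prop$rejected, "g1")
})

test_that("the compound two-by-two topology enumerates three resolutions", {
  edges <- rbind(edgeRow("C", "bA", 1, 500, 1, 500),
                 edgeRow("C", "bB", 600, 1100, 1, 500),
                 edgeRow("D", "bB", 1, 400, 520, 900))
  res <- enumerateResolutions(edges)
  expect_equal(nrow(res), 3)
  expect_setequal(res$hypothesis,
                  c("no_change", "transfer_portion", "merge"))
  # degenerate one-by-one component is not this topology
  expect_error(enumerateResolutions(edgeRow("a1", "b1", 1, 10, 1, 10)),
               "topology")
})

test_that("every non-repeat gene receives exactly one call", {
  sim <- simulateAssemblyPair(smallSimConfig(seed = 71))
  res <- reconcilePair(simGenesA(sim), simGenesB(sim),
                       proteins = simProteins(sim),
                       proteinFlags = simProteinFlags(sim))
  calls <- res$calls
  expect_equal(anyDuplicated(paste(calls$version, calls$gene_id)), 0)
  expect_setequal(calls$gene_id[calls$version == "A"],
                  geneIds(simGenesA(sim)))
  expect_setequal(calls$gene_id[calls$version == "B"],
                  geneIds(simGenesB(sim)))
  expect_true(all(calls$degree[calls$call == "OK"] == 1))
  expect_true(all(calls$degree[calls$call == "unmatched"] == 0))
})

test_that("compound simulations route planted compounds to multiple", {
  sim <- simulateAssemblyPair(smallSimConfig(seed = 72, nCompound = 2))
  res <- reconcilePair(simGenesA(sim), simGenesB(sim),
                       proteins = simProteins(sim),
                       proteinFlags = simProteinFlags(sim))
  tr <- simTruth(sim)
  compound <- tr[tr$event == "compound", ]
  idsB <- unique(unlist(strsplit(compound$ids_B, ",")))
  got <- res$calls$call[res$calls$version == "B" &
                          res$calls$gene_id %in% idsB]
  expect_true(all(got == "multiple"))
  # and each compound component enumerates cleanly
  ed <- matchEdges(res$graph)
  for (eid in unique(compound$event_id)) {
    bIds <- unique(unlist(strsplit(
      compound$ids_B[compound$event_id == eid], ",")))
    sub <- ed[ed$id_b %in% bIds, ]
    expect_equal(nrow(enumerateResolutions(sub)), 3)
  }
})
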