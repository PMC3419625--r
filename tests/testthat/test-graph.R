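test_that("directional hits merge into single edges with direction flags", {
  gsA <- lineGeneSet(c("a1", "a2"), "A")
  gsB <- lineGeneSet(c("b1", "b2"), "B")
  hAB <- makeHit("a1", "b1", qs = 1, qe = 500, ss = 1, se = 500)
  hBA <- rbind(makeHit("b1", "a1", qs = 10, qe = 600, ss = 10, se = 600),
               makeHit("b2", "a2"))
  g <- buildMatchGraph(hAB, hBA, gsA, gsB)
  ed <- matchEdges(g)
  expect_equal(nrow(ed), 2)
  e1 <- ed[ed$id_a == "a1", ]
  expect_equal(e1$direction, "both")
  expect_equal(c(e1$a_start, e1$a_end), c(1, 600))   # interval hull
  expect_equal(ed[ed$id_a == "a2", "direction"], "BA")
})

test_that("node degrees match a brute-force edge recount", {
  gsA <- lineGeneSet("a1", "A")
  gsB <- lineGeneSet(c("b1", "b2", "b3"), "B")
  hAB <- do.call(rbind, lapply(c("b1", "b2", "b3"), function(b)
    makeHit("a1", b)))
  g <- buildMatchGraph(hAB, emptyHitsFixture(), gsA, gsB)
  ed <- matchEdges(g)
  expect_equal(sum(ed$id_a == "a1"), 3)
  expect_equal(nrow(ed), 3)
})

test_that("hits referencing unknown genes are rejected", {
  gsA <- lineGeneSet("a1", "A")
  gsB <- lineGeneSet("b1", "B")
  expect_error(
    buildMatchGraph(makeHit("aX", "b1"), emptyHitsFixture(), gsA, gsB),
    "unknown gene id")
})

test_that("repeat-track genes are excluded unless requested", {
  gsA <- GeneSet(rep("chr1", 2), c(1, 2000), c(1000, 3000), rep("+", 2),
                 c("a1", "a2"), track = c("main", "repeat"),
                 versionLabel = "A")
  gsB <- lineGeneSet(c("b1", "b2"), "B")
  hits <- rbind(makeHit("a1", "b1"), makeHit("a2", "b2"))
  g <- buildMatchGraph(hits, emptyHitsFixture(), gsA, gsB)
  expect_false("a2" %in% g@nodesA)
  expect_equal(nrow(matchEdges(g)), 1)
  g2 <- buildMatchGraph(hits, emptyHitsFixture(), gsA, gsB,
                        includeRepeat = TRUE)
  expect_equal(nrow(matchEdges(g2)), 2)
})

test_that("same-portion calls agree with the pairwise overlap oracle", {
  expect_equal(samePortion(c(1, 10), c(500, 490)), "same")
  expect_equal(samePortion(c(1, 600), c(400, 1000)), "different")
  # chained partial overlaps: mixed once the threshold admits the larger
  # pairwise overlap, different under the stricter default
  expect_equal(samePortion(c(1, 400, 850), c(500, 900, 1300),
                           threshold = 0.2), "mixed")
  expect_equal(samePortion(c(1, 400, 850), c(500, 900, 1300)), "different")

  oracle <- function(st, en, thr = 0.5) {
    votes <- c()
    for (i in seq_along(st)) for (j in seq_along(st)) {
      if (j <= i) next
      ov <- max(0, min(en[i], en[j]) - max(st[i], st[j]) + 1)
      shorter <- min(en[i] - st[i] + 1, en[j] - st[j] + 1)
      votes <- c(votes, ov >= thr * shorter)
    }
    if (all(votes)) "same" else if (!any(votes)) "different" else "mixed"
  }
  set.seed(61)
  for (trial in 1:30) {
    k <- sample(2:4, 1)
    st <- sample(1:1000, k)
    en <- st + sample(50:800, k)
    expect_equal(samePortion(st, en), oracle(st, en), info = trial)
  }
})
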