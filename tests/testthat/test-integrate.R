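threeSourceFixture <- function() {
  v1 <- lineGeneSet(c("v1_1", "v1_2", "v1_3"), "v1")
  v0 <- lineGeneSet(c("v0_1", "v0_2"), "v0")
  est <- lineGeneSet(c("est_1", "est_2"), "est")
  cross <- data.frame(
    source_a = c("v1", "v1"), id_a = c("v1_1", "v1_2"),
    source_b = c("v0", "est"), id_b = c("v0_1", "est_1"),
    stringsAsFactors = FALSE)
  list(sets = list(v1 = v1, v0 = v0, est = est), cross = cross,
       priority = c("v1", "v0", "est"))
}

test_that("unification follows the source priority order", {
  fx <- threeSourceFixture()
  rec <- unifyGeneSets(fx$sets, fx$cross, fx$priority)
  # gene present in v1 and v0 -> unique id from v1
  r <- rec[rec$id_in_v0 == "v0_1", ]
  expect_equal(r$unique_id, "v1_1")
  expect_equal(r$source_rank, 1)
  # gene present only in the lowest-priority EST set keeps its id
  r2 <- rec[rec$unique_id == "est_2", ]
  expect_equal(r2$source_rank, 3)
  # group count matches inclusion-exclusion: 3 + 2 + 2 - 2 overlaps
  expect_equal(nrow(rec), 5)
  # every input gene appears exactly once
  ids <- unlist(lapply(c("v1", "v0", "est"), function(s)
    unlist(strsplit(rec[[paste0("id_in_", s)]], ","))))
  expect_setequal(ids[nzchar(ids)],
                  unlist(lapply(fx$sets, geneIds)))
  expect_equal(anyDuplicated(ids[nzchar(ids)]), 0)
})

test_that("cross matches referencing unknown genes are rejected", {
  fx <- threeSourceFixture()
  bad <- rbind(fx$cross,
               data.frame(source_a = "v1", id_a = "nope",
                          source_b = "v0", id_b = "v0_2"))
  expect_error(unifyGeneSets(fx$sets, bad, fx$priority), "unknown gene")
  expect_error(unifyGeneSets(fx$sets, fx$cross, c("v1", "v1", "est")),
               "duplicate|exactly")
})

test_that("split-proposal records are appended with suffixed ids", {
  fx <- threeSourceFixture()
  parts <- data.frame(source_gene = "v1_3", part_index = 1:2,
                      g_start = c(1, 600), g_end = c(450, 1000),
                      protein_id = c("p1", "p2"))
  rec <- unifyGeneSets(fx$sets, fx$cross, fx$priority,
                       splitProposals = proposeSplits(parts = parts))
  expect_true("v1_3_2" %in% rec$unique_id)
  expect_true(rec$needs_review[rec$unique_id == "v1_3_2"])
})

test_that("venn region counts sum to the record total", {
  fx <- threeSourceFixture()
  rec <- unifyGeneSets(fx$sets, fx$cross, fx$priority)
  venn <- vennMembership(rec)
  expect_equal(sum(venn), nrow(rec))
  expect_equal(unname(venn[["v1+v0"]]), 1)
  expect_equal(unname(venn[["v1+est"]]), 1)

  # brute-force recount on random memberships
  set.seed(91)
  n <- 60
  rr <- data.frame(
    id_in_x = ifelse(runif(n) < 0.6, sprintf("x%d", 1:n), ""),
    id_in_y = ifelse(runif(n) < 0.6, sprintf("y%d", 1:n), ""),
    stringsAsFactors = FALSE)
  rr <- rr[nzchar(rr$id_in_x) | nzchar(rr$id_in_y), ]
  venn2 <- vennMembership(rr)
  brute <- table(apply(rr, 1, function(r)
    paste(c("x", "y")[nzchar(r)], collapse = "+")))
  expect_equal(sum(venn2), nrow(rr))
  for (nm in names(brute))
    expect_equal(unname(venn2[[nm]]), unname(as.integer(brute[[nm]])))
})

test_that("annotation transfer flags every cardinality issue for review", {
  gsA <- lineGeneSet(c("a1", "a2", "a3"), "A")
  gsB <- lineGeneSet(c("b1", "b2", "b3", "b4"), "B")
  cross <- data.frame(source_a = "B", id_a = c("b1", "b2"),
                      source_b = "A", id_b = c("a1", "a2"))
  rec <- unifyGeneSets(list(B = gsB, A = gsA), cross, c("B", "A"))
  calls <- data.frame(
    gene_id = c("b1", "b2", "b3", "b4", "a1", "a2", "a3"),
    version = c(rep("B", 4), rep("A", 3)),
    call = c("OK", "to_split", "unmatched", "OK_split",
             "OK", "to_split", "unmatched"),
    stringsAsFactors = FALSE)
  prior <- c(a1 = "putative kinase", a2 = "ABC transporter")
  out <- transferAnnotation(rec, prior, calls, priorSource = "A",
                            newSource = "B")
  r1 <- out[out$unique_id == "b1", ]
  expect_equal(r1$functional_annotation, "putative kinase")
  expect_false(r1$needs_review)
  expect_equal(r1$cardinality_comment, "OK")
  r2 <- out[out$unique_id == "b2", ]
  expect_true(r2$needs_review)
  expect_equal(r2$cardinality_comment, "To split")
  r3 <- out[out$unique_id == "b3", ]
  expect_true(r3$needs_review)
  expect_equal(r3$cardinality_comment, "XX")
  expect_equal(r3$functional_annotation, "")
  expect_false(out[out$unique_id == "b4", "needs_review"])
  # count identity: reviews = non-OK calls + unmatched among B records
  nReview <- sum(out$needs_review[nzchar(out$id_in_B)])
  expect_equal(nReview,
               sum(!calls$call[calls$version == "B"] %in%
                     c("OK", "OK_split")))
})

test_that("four-group assignment is exhaustive and mutually exclusive", {
  rec <- data.frame(unique_id = c("g1", "g2", "g3", "g4"),
                    stringsAsFactors = FALSE)
  hits <- c(g2 = "retrotransposon gag protein",
            g3 = "uncharacterized protein At1g01010",
            g4 = "cytochrome P450 monooxygenase")
  out <- assignFourGroup(rec, hits)
  expect_equal(out$four_group,
               c("no_hit", "viral_te", "unknown_function",
                 "known_function"))
  # saturation: every gene with an informative hit
  allHits <- setNames(rep("cellulose synthase", 4), rec$unique_id)
  expect_true(all(assignFourGroup(rec, allHits)$four_group ==
                    "known_function"))
})

test_that("catalog rollup counts once per distinct ancestor", {
  cat <- readCategoryCatalog(system.file("extdata", "synthetic_catalog.tsv",
                                         package = "geneRecon"))
  rec <- data.frame(unique_id = c("g1", "g2", "g3"),
                    categories = c("1.1.1;2.1.1",  # two distinct roots
                                   "1.1;1.3.1",    # one shared root
                                   ""),
                    stringsAsFactors = FALSE)
  roll <- catalogRollup(rec, cat)
  top <- setNames(roll$topLevel$n_genes, roll$topLevel$code)
  expect_equal(unname(top[["1"]]), 2)   # g1 and g2 once each
  expect_equal(unname(top[["2"]]), 1)
  expect_equal(roll$nMultiCategory, 2)
  expect_equal(roll$nAssigned, 2)

  # conservation: top-level counts equal summed per-gene distinct roots
  rootOf <- function(code) strsplit(code, ".", fixed = TRUE)[[1]][1]
  perGene <- sapply(strsplit(rec$categories, ";"), function(x)
    length(unique(vapply(x[nzchar(x)], rootOf, character(1)))))
  expect_equal(sum(roll$topLevel$n_genes), sum(perGene))

  expect_error(catalogRollup(data.frame(unique_id = "g", categories = "9.9"),
                             cat), "absent")
  tooMany <- data.frame(unique_id = "g",
                        categories = paste(rep("1.1", 8), collapse = ";"))
  expect_error(catalogRollup(tooMany, cat), "more than 7")
})

test_that("rollup counts agree with a brute-force hierarchy walk", {
  cat <- readCategoryCatalog(system.file("extdata", "synthetic_catalog.tsv",
                                         package = "geneRecon"))
  tab <- catalogTable(cat)
  set.seed(92)
  n <- 40
  rec <- data.frame(
    unique_id = sprintf("g%02d", 1:n),
    categories = vapply(1:n, function(i)
      paste(sample(tab$code, sample(0:4, 1)), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  roll <- catalogRollup(rec, cat)
  # independent walk: for each category, count genes whose assigned codes
  # contain it or any of its descendants
  descend <- function(code) {
    kids <- tab$code[!is.na(tab$parent_code) & tab$parent_code == code]
    c(code, unlist(lapply(kids, descend)))
  }
  assigned <- strsplit(rec$categories, ";")
  for (i in seq_len(nrow(tab))) {
    fam <- descend(tab$code[i])
    expected <- sum(vapply(assigned, function(a) any(a %in% fam),
                           logical(1)))
    expect_equal(roll$counts$n_genes[roll$counts$code == tab$code[i]],
                 expected, info = tab$code[i])
  }
})
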