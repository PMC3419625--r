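# shared fixture builders and independent oracles

randomDna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

substituteAt <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  nmut <- rbinom(1, length(chars), rate)
  if (nmut > 0) {
    pos <- sample.int(length(chars), nmut)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# a small simulation exercising every event type quickly
smallSimConfig <- function(seed = 1, ...) {
  defaults <- list(chromosomes = 1, genesPerChromosome = 60,
                   nSplitInB = 3, nMergeInB = 3, nTandemExpandInB = 3,
                   nChimeraInB = 3, nChimeraTripleInB = 1, nChimeraInA = 3,
                   nInvertBlocks = 1, invertBlockSize = c(4, 6),
                   nRelocate = 0, nUnplaceInA = 3,
                   nDropFromA = 2, nDropFromB = 2, seed = seed)
  do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

# a hit row in the canonical 12-column layout
makeHit <- function(query = "q", subject = "s", identity = 99,
                    len = 500, qs = 1, qe = 500, ss = 1, se = 500,
                    evalue = 1e-50, bits = 800) {
  data.frame(query_id = query, subject_id = subject,
             pct_identity = identity, aln_length = len,
             mismatches = round(len * (100 - identity) / 100),
             gap_opens = 0, q_start = qs, q_end = qe,
             s_start = ss, s_end = se, e_value = evalue,
             bit_score = bits, stringsAsFactors = FALSE)
}

emptyHitsFixture <- function() makeHit()[0, ]

# a GeneSet of n equal-length genes laid out along one chromosome
lineGeneSet <- function(ids, version, chrom = "chr1", geneLen = 1000,
                        gap = 500, start = 1) {
  n <- length(ids)
  starts <- start + (seq_len(n) - 1) * (geneLen + gap)
  GeneSet(chromosome = rep(chrom, n), start = starts,
          end = starts + geneLen - 1, strand = rep("+", n),
          gene_id = ids, versionLabel = version)
}

# independent DP identity oracle (quadratic local alignment, same scoring
# scale as the seed-and-extend aligner)
dpIdentity <- function(q, s) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 10, gapExtension = 4)
  100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# brute-force neighbor-consistency oracle: direct definition, quadratic scan
bruteNeighbor <- function(pairs, genesA, genesB, skip = 1) {
  tabA <- geneTable(genesA); tabB <- geneTable(genesB)
  ordOn <- function(tab) {
    tab <- tab[order(tab$chromosome, tab$start), ]
    split(tab$gene_id, tab$chromosome)
  }
  byA <- ordOn(tabA); byB <- ordOn(tabB)
  partner <- setNames(pairs$id_a, pairs$id_b)
  matchedA <- pairs$id_a; matchedB <- pairs$id_b
  adjA <- function(a1, a2) {
    for (genes in byA) {
      i <- match(a1, genes); j <- match(a2, genes)
      if (!is.na(i) && !is.na(j) && i != j) {
        lo <- min(i, j); hi <- max(i, j)
        if (hi - lo == 1) return(TRUE)
        between <- genes[(lo + 1):(hi - 1)]
        return(!any(between %in% matchedA) && (hi - lo - 1) <= skip)
      }
    }
    FALSE
  }
  res <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    b <- pairs$id_b[r]; a <- pairs$id_a[r]
    genes <- NULL
    for (g in byB) if (b %in% g) genes <- g
    i <- match(b, genes)
    nb <- character(0)
    for (dir in c(-1, 1)) {
      j <- i; unseen <- 0
      repeat {
        j <- j + dir
        if (j < 1 || j > length(genes)) break
        if (genes[j] %in% matchedB) { nb <- c(nb, genes[j]); break }
        unseen <- unseen + 1
        if (unseen > skip) break
      }
    }
    if (!length(nb)) { res[r] <- "untestable"; next }
    ok <- any(vapply(nb, function(b2) adjA(a, partner[[b2]]), logical(1)))
    res[r] <- if (ok) "consistent" else "inconsistent"
  }
  res
}
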