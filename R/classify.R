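#' Cardinality classification policy
#'
#' Tunable fractions behind the cardinality taxonomy. \code{samePortion}
#' gives the reciprocal-overlap fraction (of the shorter hub-side interval)
#' above which two edges are deemed to cover the same portion of their hub
#' gene. A hub region "matches a distinct protein" when a protein-evidence
#' hit covers at least \code{proteinCoverMin} of that protein's length and
#' the regions claimed by different proteins overlap by less than
#' \code{partOverlapMax} (of the shorter region); a "single protein spans"
#' the hub when one hit covers at least \code{proteinCoverMin} of the union
#' of the matched intervals. \code{flaggedEvidenceOnly} restricts evidence
#' to proteins whose existence is demonstrated at the protein level.
#' \code{lowScoreQuantile} sets the floor below which a neighbor-inconsistent
#' one-to-one pair is tagged \code{low_score}: the floor is that quantile of
#' the length-normalised scores of the neighbor-consistent one-to-one pairs.
#'
#' @param samePortion reciprocal-overlap threshold (default 0.5).
#' @param proteinCoverMin protein/union coverage fraction (default 0.6).
#' @param partOverlapMax maximum overlap between regions claimed by distinct
#'   proteins (default 0.2).
#' @param flaggedEvidenceOnly use only protein-level-flagged evidence
#'   (default TRUE).
#' @param lowScoreQuantile quantile for the low-score floor (default 0.05).
#' @return a \code{classifyPolicy} list.
#' @export
classifyPolicy <- function(samePortion = 0.5, proteinCoverMin = 0.6,
                           partOverlapMax = 0.2, flaggedEvidenceOnly = TRUE,
                           lowScoreQuantile = 0.05) {
  structure(list(samePortion = samePortion,
                 proteinCoverMin = proteinCoverMin,
                 partOverlapMax = partOverlapMax,
                 flaggedEvidenceOnly = flaggedEvidenceOnly,
                 lowScoreQuantile = lowScoreQuantile),
            class = "classifyPolicy")
}

#' @rdname classifyCardinality
#' @export
cardinalityCallLevels <- c("OK", "OK_split", "redundant", "overlap", "split",
                           "merged", "to_split", "multiple", "low_score",
                           "unmatched", "unresolved")

# protein-evidence decision for a hub gene matched on different portions.
# parts: data.frame(owner, start, end) of the partner intervals on the hub.
# Returns list(status = "distinct"/"single"/"none", parts = parts with
# protein_id attached when status == "distinct").
.evidenceDecision <- function(hubGene, hubVersion, parts, evidence, policy) {
  none <- list(status = "none", parts = NULL)
  if (is.null(evidence) || !nrow(evidence)) return(none)
  ev <- evidence[evidence$gene_id == hubGene &
                 evidence$version == hubVersion, , drop = FALSE]
  if (policy$flaggedEvidenceOnly && "flagged" %in% colnames(ev))
    ev <- ev[ev$flagged, , drop = FALSE]
  if (!nrow(ev)) return(none)
  ev$cover <- (ev$p_end - ev$p_start + 1) / ev$protein_length

  # order parts by position along the hub
  parts <- parts[order(parts$start, parts$end), , drop = FALSE]

  # (1) does every part match its own protein?
  good <- ev[ev$cover >= policy$proteinCoverMin, , drop = FALSE]
  assigned <- rep(NA_character_, nrow(parts))
  aStart <- aEnd <- rep(NA_real_, nrow(parts))
  if (nrow(good)) {
    for (i in seq_len(nrow(parts))) {
      ov <- .ovlen(good$g_start, good$g_end, parts$start[i], parts$end[i])
      if (any(ov > 0)) {
        j <- which.max(ov)
        assigned[i] <- good$protein_id[j]
        aStart[i] <- good$g_start[j]; aEnd[i] <- good$g_end[j]
      }
    }
  }
  if (!anyNA(assigned) && !anyDuplicated(assigned)) {
    distinctRegions <- TRUE
    for (i in seq_len(nrow(parts) - 1L)) {
      for (j in (i + 1L):nrow(parts)) {
        ov <- .ovlen(aStart[i], aEnd[i], aStart[j], aEnd[j])
        shorter <- min(aEnd[i] - aStart[i] + 1, aEnd[j] - aStart[j] + 1)
        if (ov >= policy$partOverlapMax * shorter) distinctRegions <- FALSE
      }
    }
    if (distinctRegions) {
      parts$protein_id <- assigned
      return(list(status = "distinct", parts = parts))
    }
  }

  # (2) does a single protein span the union of the matched intervals?
  uLo <- min(parts$start); uHi <- max(parts$end)
  spanCover <- .ovlen(ev$g_start, ev$g_end, uLo, uHi) / (uHi - uLo + 1)
  if (any(spanCover >= policy$proteinCoverMin))
    return(list(status = "single", parts = NULL))
  none
}

#' Classify every gene into the cardinality taxonomy
#'
#' Walks the connected components of the match graph and assigns each
#' non-repeat-track gene of both versions exactly one cardinality call:
#' \describe{
#'   \item{OK / low_score}{one-to-one components. A pair is \code{OK} when
#'     neighbor-consistent, or inconsistent but above the low-score floor;
#'     \code{low_score} otherwise ("Ls": low score between matches that
#'     nevertheless seem correct).}
#'   \item{redundant}{several B genes matching the same portion of one A
#'     gene (typically tandem repeats collapsed in A).}
#'   \item{overlap}{several B genes matching different portions of one A
#'     gene while a single evidence protein spans the union: B incorrectly
#'     split the locus and the models should be reassembled.}
#'   \item{split}{several B genes matching different portions of one A gene,
#'     each supported by its own protein: the split in B is correct and the
#'     A gene was an artificial merge.}
#'   \item{merged}{one B gene matching several A genes on different portions
#'     of itself with one protein spanning it: the merge in B is correct.}
#'   \item{to_split}{one B gene whose different portions each match a
#'     distinct protein: an artificial chimera; a split proposal is
#'     attached.}
#'   \item{multiple}{components combining at least two of the situations
#'     above (including all many-to-many topologies).}
#'   \item{unresolved}{a one-to-many component on different portions whose
#'     protein evidence is missing or ambiguous; the structural call is not
#'     guessed.}
#'   \item{unmatched}{degree-zero genes ("XX").}
#' }
#' Several A genes matching one B gene on the \emph{same} portion are not
#' interpreted as redundancy in A: the B gene keeps its best-scoring partner
#' as a one-to-one pair and the remaining partners are called unmatched.
#'
#' Split proposals for \code{to_split} hubs are attached as
#' \code{attr(calls, "splitParts")} and consumed by
#' \code{\link{proposeSplits}}.
#'
#' @param graph a \linkS4class{MatchGraph}.
#' @param genesA,genesB the two \linkS4class{GeneSet}s.
#' @param evidence protein-evidence hits: data.frame with columns
#'   \code{protein_id}, \code{gene_id}, \code{version}, \code{p_start},
#'   \code{p_end}, \code{g_start}, \code{g_end}, \code{protein_length} and
#'   optionally \code{flagged}; or NULL when no evidence is available.
#' @param policy a \code{\link{classifyPolicy}}.
#' @param rule a \code{\link{neighborRule}} for the one-to-one pass.
#' @return data.frame with one row per gene and columns \code{gene_id},
#'   \code{version}, \code{call}, \code{degree}, \code{partners}
#'   (comma-joined), \code{evidence} (\code{protein-single} /
#'   \code{protein-multiple} / \code{none}), \code{unresolved},
#'   \code{neighbor}, \code{component}.
#' @export
classifyCardinality <- function(graph, genesA, genesB, evidence = NULL,
                                policy = classifyPolicy(),
                                rule = neighborRule()) {
  stopifnot(is(graph, "MatchGraph"), inherits(policy, "classifyPolicy"))
  edges <- matchEdges(graph)
  vA <- graph@versionA; vB <- graph@versionB

  callRow <- function(gene, version, call, degree, partners,
                      evid = "none", unresolved = FALSE, component = NA_integer_) {
    data.frame(gene_id = gene, version = version, call = call,
               degree = degree,
               partners = paste(partners, collapse = ","),
               evidence = evid, unresolved = unresolved,
               neighbor = NA_character_, component = component,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  onePairs <- list()    # candidate one-to-one pairs for the second pass
  splitParts <- list()
  droppedA <- character(0)  # A partners dropped by the not-considered rule

  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("A|", edges$id_a),
                 to = paste0("B|", edges$id_b)), directed = FALSE)
    comp <- igraph::components(g)$membership
    edgeComp <- comp[paste0("A|", edges$id_a)]
    for (ci in sort(unique(edgeComp))) {
      sub <- edges[edgeComp == ci, , drop = FALSE]
      aIds <- unique(sub$id_a); bIds <- unique(sub$id_b)
      nA <- length(aIds); nB <- length(bIds)
      degA <- table(sub$id_a); degB <- table(sub$id_b)

      if (nA == 1L && nB == 1L) {
        onePairs[[length(onePairs) + 1L]] <-
          data.frame(id_a = aIds, id_b = bIds, bit_score = max(sub$bit_score),
                     component = ci, stringsAsFactors = FALSE)
      } else if (nA == 1L && nB >= 2L) {
        portion <- samePortion(sub$a_start, sub$a_end,
                               threshold = policy$samePortion)
        if (portion == "same") {
          for (b in bIds)
            rows[[length(rows) + 1L]] <- callRow(b, vB, "redundant",
                                                 1L, aIds, component = ci)
          rows[[length(rows) + 1L]] <- callRow(aIds, vA, "redundant",
                                               nB, bIds, component = ci)
        } else if (portion == "different") {
          parts <- data.frame(owner = sub$id_b, start = sub$a_start,
                              end = sub$a_end, stringsAsFactors = FALSE)
          dec <- .evidenceDecision(aIds, vA, parts, evidence, policy)
          if (dec$status == "distinct") {
            for (b in bIds)
              rows[[length(rows) + 1L]] <- callRow(b, vB, "split", 1L, aIds,
                                                   "protein-multiple",
                                                   component = ci)
            rows[[length(rows) + 1L]] <- callRow(aIds, vA, "split", nB, bIds,
                                                 "protein-multiple",
                                                 component = ci)
          } else if (dec$status == "single") {
            for (b in bIds)
              rows[[length(rows) + 1L]] <- callRow(b, vB, "overlap", 1L,
                                                   aIds, "protein-single",
                                                   component = ci)
            rows[[length(rows) + 1L]] <- callRow(aIds, vA, "overlap", nB,
                                                 bIds, "protein-single",
                                                 component = ci)
          } else {
            for (b in bIds)
              rows[[length(rows) + 1L]] <- callRow(b, vB, "unresolved", 1L,
                                                   aIds, "none", TRUE, ci)
            rows[[length(rows) + 1L]] <- callRow(aIds, vA, "unresolved", nB,
                                                 bIds, "none", TRUE, ci)
          }
        } else {
          for (b in bIds)
            rows[[length(rows) + 1L]] <- callRow(b, vB, "multiple", 1L, aIds,
                                                 component = ci)
          rows[[length(rows) + 1L]] <- callRow(aIds, vA, "multiple", nB,
                                               bIds, component = ci)
        }
      } else if (nB == 1L && nA >= 2L) {
        portion <- samePortion(sub$b_start, sub$b_end,
                               threshold = policy$samePortion)
        if (portion == "same") {
          # redundancy on the A side is not interpreted: keep the best edge
          best <- order(-sub$bit_score, sub$id_a)[1]
          onePairs[[length(onePairs) + 1L]] <-
            data.frame(id_a = sub$id_a[best], id_b = bIds,
                       bit_score = sub$bit_score[best], component = ci,
                       stringsAsFactors = FALSE)
          droppedA <- c(droppedA, setdiff(aIds, sub$id_a[best]))
        } else if (portion == "different") {
          parts <- data.frame(owner = sub$id_a, start = sub$b_start,
                              end = sub$b_end, stringsAsFactors = FALSE)
          dec <- .evidenceDecision(bIds, vB, parts, evidence, policy)
          if (dec$status == "distinct") {
            rows[[length(rows) + 1L]] <- callRow(bIds, vB, "to_split", nA,
                                                 aIds, "protein-multiple",
                                                 component = ci)
            for (a in aIds)
              rows[[length(rows) + 1L]] <- callRow(a, vA, "to_split", 1L,
                                                   bIds, "protein-multiple",
                                                   component = ci)
            splitParts[[length(splitParts) + 1L]] <- data.frame(
              source_gene = bIds, part_index = seq_len(nrow(dec$parts)),
              g_start = dec$parts$start, g_end = dec$parts$end,
              partner = dec$parts$owner, protein_id = dec$parts$protein_id,
              stringsAsFactors = FALSE)
          } else if (dec$status == "single") {
            rows[[length(rows) + 1L]] <- callRow(bIds, vB, "merged", nA,
                                                 aIds, "protein-single",
                                                 component = ci)
            for (a in aIds)
              rows[[length(rows) + 1L]] <- callRow(a, vA, "merged", 1L,
                                                   bIds, "protein-single",
                                                   component = ci)
          } else {
            rows[[length(rows) + 1L]] <- callRow(bIds, vB, "unresolved", nA,
                                                 aIds, "none", TRUE, ci)
            for (a in aIds)
              rows[[length(rows) + 1L]] <- callRow(a, vA, "unresolved", 1L,
                                                   bIds, "none", TRUE, ci)
          }
        } else {
          rows[[length(rows) + 1L]] <- callRow(bIds, vB, "multiple", nA,
                                               aIds, component = ci)
          for (a in aIds)
            rows[[length(rows) + 1L]] <- callRow(a, vA, "multiple", 1L,
                                                 bIds, component = ci)
        }
      } else {
        # many-to-many or compound: at least two situations combine
        for (a in aIds)
          rows[[length(rows) + 1L]] <- callRow(a, vA, "multiple",
                                               as.integer(degA[[a]]),
                                               sub$id_b[sub$id_a == a],
                                               component = ci)
        for (b in bIds)
          rows[[length(rows) + 1L]] <- callRow(b, vB, "multiple",
                                               as.integer(degB[[b]]),
                                               sub$id_a[sub$id_b == b],
                                               component = ci)
      }
    }
  }

  # one-to-one pass: neighbor consistency and the low-score floor
  if (length(onePairs)) {
    op <- do.call(rbind, onePairs)
    op <- neighborConsistency(op, genesA, genesB, rule)
    lenOf <- function(gs, ids) {
      seqs <- geneSequences(gs)
      if (length(seqs) && all(ids %in% names(seqs)))
        return(Biostrings::width(seqs)[match(ids, names(seqs))])
      gr <- geneRanges(gs)
      GenomicRanges::width(gr)[match(ids, geneIds(gs))]
    }
    minLen <- pmin(lenOf(genesA, op$id_a), lenOf(genesB, op$id_b))
    perfectBits <- (.alnDefaults$lambda * minLen -
                      log(.alnDefaults$kParam)) / log(2)
    normScore <- op$bit_score / perfectBits
    consistent <- op$neighbor == "consistent"
    floor <- if (any(consistent))
      stats::quantile(normScore[consistent], policy$lowScoreQuantile,
                      names = FALSE)
    else -Inf
    isLow <- op$neighbor == "inconsistent" & normScore < floor
    for (i in seq_len(nrow(op))) {
      call <- if (isLow[i]) "low_score" else "OK"
      ra <- callRow(op$id_a[i], vA, call, 1L, op$id_b[i],
                    component = op$component[i])
      ra$neighbor <- op$neighbor[i]
      rb <- callRow(op$id_b[i], vB, call, 1L, op$id_a[i],
                    component = op$component[i])
      rb$neighbor <- op$neighbor[i]
      rows[[length(rows) + 1L]] <- ra
      rows[[length(rows) + 1L]] <- rb
    }
  }

  calls <- if (length(rows)) do.call(rbind, rows) else
    callRow(character(0), character(0), character(0), integer(0),
            character(0))[0, ]

  # degree-zero genes
  seenA <- calls$gene_id[calls$version == vA]
  seenB <- calls$gene_id[calls$version == vB]
  unA <- c(setdiff(graph@nodesA, seenA))
  unB <- setdiff(graph@nodesB, seenB)
  unA <- unique(c(unA, droppedA))
  if (length(unA) || length(unB)) {
    extra <- rbind(
      if (length(unA)) callRow(unA, vA, "unmatched", 0L, character(0)),
      if (length(unB)) callRow(unB, vB, "unmatched", 0L, character(0)))
    extra$partners <- ""
    calls <- rbind(calls, extra)
  }
  calls <- calls[order(calls$version, calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "splitParts") <- if (length(splitParts))
    do.call(rbind, splitParts) else NULL
  calls
}

#' Extract the validated one-to-one pairs from a call table
#'
#' @param calls output of \code{\link{classifyCardinality}}.
#' @param accept call labels treated as one-to-one (default OK, OK_split and
#'   low_score).
#' @return data.frame with columns \code{id_a}, \code{id_b}.
#' @export
okPairs <- function(calls, accept = c("OK", "OK_split", "low_score")) {
  vA <- sort(unique(calls$version))[1]
  sub <- calls[calls$call %in% accept & calls$version == vA &
               calls$degree == 1L, , drop = FALSE]
  data.frame(id_a = sub$gene_id, id_b = sub$partners,
             stringsAsFactors = FALSE)
}

#' Propose split corrections for chimeric gene models
#'
#' Each \code{to_split} call (an artificial chimera whose k regions each
#' match a distinct evidence protein) is turned into a split proposal: the
#' first part keeps the source gene id and every further part becomes a new
#' gene record suffixed \code{"_2"}, \code{"_3"}, ... A k-part chimera thus
#' yields k - 1 new gene records. Proposals whose part intervals overlap
#' beyond the tolerance are rejected and the source downgraded to
#' unresolved-ambiguous rather than guessed.
#'
#' @param calls output of \code{\link{classifyCardinality}} (used for its
#'   \code{splitParts} attribute), or any data.frame of to-split calls when
#'   \code{parts} is supplied explicitly.
#' @param parts data.frame with columns \code{source_gene},
#'   \code{part_index}, \code{g_start}, \code{g_end}, \code{protein_id}.
#' @param overlapTolerance parts overlapping by at least this fraction of
#'   the shorter part invalidate their proposal (default 0.2).
#' @return a list of class \code{splitProposals}: \code{proposals} (one row
#'   per part with its \code{new_id}), \code{summary} (with
#'   \code{n_genes_split}, \code{n_triple}, \code{n_new}) and
#'   \code{rejected} (source ids downgraded).
#' @examples
#' parts <- data.frame(source_gene = "g1", part_index = 1:2,
#'                     g_start = c(1, 501), g_end = c(500, 900),
#'                     protein_id = c("p1", "p2"))
#' proposeSplits(parts = parts)$summary$n_new   # one new "_2" record
#' @export
proposeSplits <- function(calls = NULL, parts = attr(calls, "splitParts"),
                          overlapTolerance = 0.2) {
  if (is.null(parts) || !nrow(parts)) {
    return(structure(list(
      proposals = data.frame(source_gene = character(),
                             part_index = integer(), g_start = numeric(),
                             g_end = numeric(), protein_id = character(),
                             new_id = character(), stringsAsFactors = FALSE),
      summary = list(n_genes_split = 0L, n_triple = 0L, n_new = 0L),
      rejected = character(0)), class = "splitProposals"))
  }
  need <- c("source_gene", "part_index", "g_start", "g_end", "protein_id")
  stopifnot(all(need %in% colnames(parts)))
  out <- list(); rejected <- character(0); nTriple <- 0L; nNew <- 0L
  for (src in unique(parts$source_gene)) {
    p <- parts[parts$source_gene == src, , drop = FALSE]
    p <- p[order(p$g_start, p$g_end), , drop = FALSE]
    if (nrow(p) < 2L) {
      rejected <- c(rejected, src)
      next
    }
    bad <- FALSE
    for (i in seq_len(nrow(p) - 1L)) {
      for (j in (i + 1L):nrow(p)) {
        ov <- .ovlen(p$g_start[i], p$g_end[i], p$g_start[j], p$g_end[j])
        shorter <- min(p$g_end[i] - p$g_start[i] + 1,
                       p$g_end[j] - p$g_start[j] + 1)
        if (ov >= overlapTolerance * shorter) bad <- TRUE
      }
    }
    if (bad) {
      rejected <- c(rejected, src)
      next
    }
    p$part_index <- seq_len(nrow(p))
    p$new_id <- ifelse(p$part_index == 1L, src,
                       paste0(src, "_", p$part_index))
    out[[length(out) + 1L]] <- p
    nNew <- nNew + nrow(p) - 1L
    if (nrow(p) == 3L) nTriple <- nTriple + 1L
  }
  proposals <- if (length(out)) do.call(rbind, out) else
    parts[0, c(need)]
  rownames(proposals) <- NULL
  structure(list(proposals = proposals,
                 summary = list(n_genes_split = length(out),
                                n_triple = nTriple, n_new = nNew),
                 rejected = rejected),
            class = "splitProposals")
}

#' @export
print.splitProposals <- function(x, ...) {
  cat("Split proposals: ", x$summary$n_genes_split, " chimeric genes (",
      x$summary$n_triple, " triple) -> ", x$summary$n_new,
      " proposed new gene records; ", length(x$rejected),
      " rejected\n", sep = "")
  invisible(x)
}

#' Enumerate candidate resolutions of the two-by-two compound topology
#'
#' The recurrent compound ("multiple situations") case: two genes of the
#' newer set (call them A and B) align to different regions of one older-set
#' gene C, while a further portion of B also matches a second older-set gene
#' D. Three correct answers are possible and are enumerated, each annotated
#' with the protein evidence that would decide it: keep A and B separate (no
#' change); transfer a portion of B to A; or merge A and B.
#'
#' @param x a \linkS4class{MatchGraph} whose edges form exactly this
#'   topology, or the edge data.frame itself (columns as in
#'   \code{\link{matchEdges}}).
#' @return data.frame with one row per candidate resolution: columns
#'   \code{hypothesis}, \code{description}, \code{decisive_evidence}.
#' @examples
#' edges <- data.frame(id_a = c("C", "C", "D"), id_b = c("bA", "bB", "bB"),
#'                     a_start = c(1, 600, 1), a_end = c(500, 1100, 400),
#'                     b_start = c(1, 1, 520), b_end = c(500, 500, 900),
#'                     direction = "both", bit_score = 900,
#'                     pct_identity = 99)
#' nrow(enumerateResolutions(edges))   # 3
#' @export
enumerateResolutions <- function(x) {
  edges <- if (is(x, "MatchGraph")) matchEdges(x) else x
  aIds <- unique(edges$id_a); bIds <- unique(edges$id_b)
  degA <- table(edges$id_a); degB <- table(edges$id_b)
  ok <- length(aIds) == 2L && length(bIds) == 2L && nrow(edges) == 3L &&
    all(sort(as.integer(degA)) == c(1L, 2L)) &&
    all(sort(as.integer(degB)) == c(1L, 2L))
  if (!ok)
    stop("component does not match the two-by-two compound topology ",
         "(two newer-set genes on one older-set gene plus a second ",
         "older-set partner)")
  hubA <- names(degA)[degA == 2L]   # gene C
  hubB <- names(degB)[degB == 2L]   # gene B
  otherB <- setdiff(bIds, hubB)     # gene A
  otherA <- setdiff(aIds, hubA)     # gene D
  # the two newer-set genes must sit on different regions of C
  onC <- edges[edges$id_a == hubA, , drop = FALSE]
  if (nrow(onC) == 2L &&
      samePortion(onC$a_start, onC$a_end) == "same")
    stop("the two newer-set genes cover the same portion of the shared ",
         "older-set gene; not the compound topology")
  data.frame(
    hypothesis = c("no_change", "transfer_portion", "merge"),
    description = c(
      sprintf("keep %s and %s as separate genes", otherB, hubB),
      sprintf("transfer the %s-matching portion of %s to %s",
              hubA, hubB, otherB),
      sprintf("merge %s and %s into a single gene", otherB, hubB)),
    decisive_evidence = c(
      sprintf("two distinct proteins, one per gene, covering %s and %s",
              otherB, hubB),
      sprintf("a protein spanning %s plus the %s-matching portion of %s",
              otherB, hubA, hubB),
      sprintf("a single protein spanning both %s and %s", otherB, hubB)),
    stringsAsFactors = FALSE)
}
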