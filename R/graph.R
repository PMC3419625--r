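#' Build the bipartite cross-version match graph
#'
#' Merges the two directional filtered hit sets (A-as-query and B-as-query)
#' into one edge per (gene in A, gene in B) pair. Hits of both directions
#' contribute to the same edge; the matched intervals on each gene are merged
#' to their hull and the best bit score and identity are retained, together
#' with a flag recording which direction(s) supported the edge. Repeat-track
#' genes are excluded from the node sets (and any edges touching them
#' dropped) unless \code{includeRepeat = TRUE}.
#'
#' @param hitsAB filtered hits with version-A genes as query and version-B
#'   genes as subject (may be a zero-row table).
#' @param hitsBA filtered hits in the opposite direction.
#' @param genesA,genesB the two \linkS4class{GeneSet}s.
#' @param includeRepeat keep repeat-track genes in the graph (default FALSE).
#' @return a \linkS4class{MatchGraph}.
#' @export
buildMatchGraph <- function(hitsAB, hitsBA, genesA, genesB,
                            includeRepeat = FALSE) {
  stopifnot(is(genesA, "GeneSet"), is(genesB, "GeneSet"))
  idsA <- geneIds(genesA)
  idsB <- geneIds(genesB)
  checkIds <- function(hits, qids, sids, dir) {
    if (!nrow(hits)) return(invisible())
    badq <- setdiff(unique(hits$query_id), qids)
    bads <- setdiff(unique(hits$subject_id), sids)
    if (length(badq) || length(bads))
      stop("hits (", dir, ") reference unknown gene id(s): ",
           paste(utils::head(c(badq, bads), 5), collapse = ", "))
  }
  checkIds(hitsAB, idsA, idsB, "A->B")
  checkIds(hitsBA, idsB, idsA, "B->A")

  norm <- function(hits, flip) {
    if (!nrow(hits)) {
      return(data.frame(id_a = character(), id_b = character(),
                        a_start = numeric(), a_end = numeric(),
                        b_start = numeric(), b_end = numeric(),
                        direction = character(), bit_score = numeric(),
                        pct_identity = numeric(), stringsAsFactors = FALSE))
    }
    qs <- pmin(hits$q_start, hits$q_end); qe <- pmax(hits$q_start, hits$q_end)
    ss <- pmin(hits$s_start, hits$s_end); se <- pmax(hits$s_start, hits$s_end)
    if (flip) {
      data.frame(id_a = hits$subject_id, id_b = hits$query_id,
                 a_start = ss, a_end = se, b_start = qs, b_end = qe,
                 direction = "BA", bit_score = hits$bit_score,
                 pct_identity = hits$pct_identity, stringsAsFactors = FALSE)
    } else {
      data.frame(id_a = hits$query_id, id_b = hits$subject_id,
                 a_start = qs, a_end = qe, b_start = ss, b_end = se,
                 direction = "AB", bit_score = hits$bit_score,
                 pct_identity = hits$pct_identity, stringsAsFactors = FALSE)
    }
  }
  all <- rbind(norm(hitsAB, FALSE), norm(hitsBA, TRUE))

  if (!includeRepeat) {
    repA <- idsA[track(genesA) == "repeat"]
    repB <- idsB[track(genesB) == "repeat"]
    idsA <- setdiff(idsA, repA)
    idsB <- setdiff(idsB, repB)
    if (nrow(all))
      all <- all[!(all$id_a %in% repA) & !(all$id_b %in% repB), ,
                 drop = FALSE]
  }

  if (nrow(all)) {
    key <- paste(all$id_a, all$id_b, sep = "\r")
    agg <- lapply(split(seq_len(nrow(all)), key), function(ix) {
      sub <- all[ix, , drop = FALSE]
      data.frame(id_a = sub$id_a[1], id_b = sub$id_b[1],
                 a_start = min(sub$a_start), a_end = max(sub$a_end),
                 b_start = min(sub$b_start), b_end = max(sub$b_end),
                 direction = if (length(unique(sub$direction)) > 1L) "both"
                             else sub$direction[1],
                 bit_score = max(sub$bit_score),
                 pct_identity = max(sub$pct_identity),
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, agg)
    edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- all
  }
  new("MatchGraph", edges = edges, nodesA = idsA, nodesB = idsB,
      versionA = versionLabel(genesA), versionB = versionLabel(genesB))
}

#' Do edges sharing a hub gene cover the same portion of it?
#'
#' Multiple genes of one version matching a single gene of the other version
#' fall into two very different situations: they may align to the
#' \emph{same} portion of the hub (typically collapsed tandem repeats) or to
#' \emph{different} portions (a split/merge or chimera situation). The
#' decision is based on pairwise reciprocal overlap of the hub-side
#' intervals: \code{"same"} when every pair of intervals overlaps by at
#' least \code{threshold} of the shorter interval, \code{"different"} when
#' every pair overlaps by less than that, and \code{"mixed"} otherwise.
#'
#' @param starts,ends numeric vectors (>= 2 intervals) of the hub-side
#'   interval bounds of the edges.
#' @param threshold overlap fraction of the shorter interval (default 0.5).
#' @return \code{"same"}, \code{"different"} or \code{"mixed"}.
#' @examples
#' samePortion(c(1, 10), c(500, 490))      # "same"
#' samePortion(c(1, 600), c(400, 1000))    # "different"
#' @export
samePortion <- function(starts, ends, threshold = 0.5) {
  stopifnot(length(starts) == length(ends), length(starts) >= 2L)
  np <- length(starts)
  sameCount <- 0L; diffCount <- 0L
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      ov <- .ovlen(starts[i], ends[i], starts[j], ends[j])
      shorter <- min(ends[i] - starts[i] + 1, ends[j] - starts[j] + 1)
      if (ov >= threshold * shorter) sameCount <- sameCount + 1L
      else diffCount <- diffCount + 1L
    }
  }
  if (diffCount == 0L) "same" else if (sameCount == 0L) "different"
  else "mixed"
}
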