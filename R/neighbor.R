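#' Neighbor-gene consistency rule
#'
#' Putative identities between two gene sets are validated by local gene
#' order rather than absolute coordinates (chromosome sequences differ too
#' much between assembly versions for absolute positions to be comparable):
#' a candidate pair is accepted when it and at least one adjacent pair map
#' consecutively on both sides, i.e. at least two consecutively positioned
#' genes of version B hit two consecutive genes of version A.
#'
#' @param window number of adjacent matched genes examined on each side of a
#'   pair (default 1).
#' @param minConsecutivePairs minimum number of consecutive pairs required
#'   (>= 2; the pair itself plus \code{minConsecutivePairs - 1} neighbors).
#' @param skip number of intervening unmatched genes tolerated between
#'   "adjacent" genes (default 1); an intervening \emph{matched} gene always
#'   breaks adjacency.
#' @return a \code{neighborRule} list.
#' @export
neighborRule <- function(window = 1L, minConsecutivePairs = 2L, skip = 1L) {
  stopifnot(minConsecutivePairs >= 2L, window >= 1L, skip >= 0L)
  structure(list(window = as.integer(window),
                 minConsecutivePairs = as.integer(minConsecutivePairs),
                 skip = as.integer(skip)),
            class = "neighborRule")
}

# per-chromosome order index of every gene (by start coordinate)
.geneOrder <- function(geneSet) {
  df <- geneTable(geneSet)
  ord <- stats::ave(df$start, df$chromosome, FUN = rank)
  data.frame(gene_id = df$gene_id, chromosome = df$chromosome,
             order = ord, stringsAsFactors = FALSE)
}

#' Validate candidate one-to-one pairs by neighbor-gene consistency
#'
#' For each candidate pair (a, b), the matched genes adjacent to b in the
#' B gene order (up to \code{rule$window} on each side, tolerating up to
#' \code{rule$skip} intervening unmatched genes) are inspected; the pair is
#' \code{"consistent"} when at least one of those neighbors' A partners is
#' adjacent (same skip rule) to a in the A gene order, \code{"inconsistent"}
#' when testable neighbors exist but none agrees, and \code{"untestable"}
#' when b has no matched neighbor within reach (e.g. a gene alone on its
#' scaffold).
#'
#' @param pairs data.frame with columns \code{id_a}, \code{id_b} (candidate
#'   one-to-one pairs; at most one pair per gene on each side).
#' @param genesA,genesB the two \linkS4class{GeneSet}s.
#' @param rule a \code{\link{neighborRule}}.
#' @return \code{pairs} with an added \code{neighbor} column.
#' @export
neighborConsistency <- function(pairs, genesA, genesB,
                                rule = neighborRule()) {
  stopifnot(inherits(rule, "neighborRule"),
            all(c("id_a", "id_b") %in% colnames(pairs)))
  if (!nrow(pairs)) {
    pairs$neighbor <- character(0)
    return(pairs)
  }
  ordA <- .geneOrder(genesA)
  ordB <- .geneOrder(genesB)
  matchedB <- pairs$id_b
  partnerOfB <- stats::setNames(pairs$id_a, pairs$id_b)
  chromA <- stats::setNames(ordA$chromosome, ordA$gene_id)
  posA <- stats::setNames(ordA$order, ordA$gene_id)

  # adjacency in A with the skip rule: same chromosome, no matched gene in
  # between, at most `skip` unmatched genes in between
  matchedAset <- unique(pairs$id_a)
  isMatchedA <- stats::setNames(ordA$gene_id %in% matchedAset, ordA$gene_id)
  byChromA <- split(ordA[order(ordA$order), ], ordA$chromosome[order(ordA$order)])

  adjacentInA <- function(a1, a2) {
    if (is.na(a1) || is.na(a2) || a1 == a2) return(FALSE)
    if (chromA[[a1]] != chromA[[a2]]) return(FALSE)
    genes <- byChromA[[chromA[[a1]]]]$gene_id
    i <- match(a1, genes); j <- match(a2, genes)
    lo <- min(i, j); hi <- max(i, j)
    if (hi - lo == 1L) return(TRUE)
    between <- genes[(lo + 1L):(hi - 1L)]
    if (any(isMatchedA[between])) return(FALSE)
    (hi - lo - 1L) <= rule$skip
  }

  # matched neighbors of b in B order, within window and skip
  byChromB <- split(ordB[order(ordB$order), ], ordB$chromosome[order(ordB$order)])
  isMatchedB <- stats::setNames(ordB$gene_id %in% matchedB, ordB$gene_id)

  neighborsOfB <- function(b) {
    genes <- byChromB[[ordB$chromosome[match(b, ordB$gene_id)]]]$gene_id
    i <- match(b, genes)
    found <- character(0)
    for (dir in c(-1L, 1L)) {
      j <- i; unmatchedSeen <- 0L; got <- 0L
      while (got < rule$window) {
        j <- j + dir
        if (j < 1L || j > length(genes)) break
        g <- genes[j]
        if (isMatchedB[[g]]) {
          found <- c(found, g)
          got <- got + 1L
        } else {
          unmatchedSeen <- unmatchedSeen + 1L
          if (unmatchedSeen > rule$skip) break
        }
      }
    }
    found
  }

  res <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    b <- pairs$id_b[r]; a <- pairs$id_a[r]
    nb <- neighborsOfB(b)
    if (!length(nb)) {
      res[r] <- "untestable"
      next
    }
    agree <- vapply(nb, function(b2) adjacentInA(a, partnerOfB[[b2]]),
                    logical(1))
    # the pair itself plus (minConsecutivePairs - 1) agreeing neighbors
    res[r] <- if (sum(agree) >= rule$minConsecutivePairs - 1L)
      "consistent" else "inconsistent"
  }
  pairs$neighbor <- res
  pairs
}
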