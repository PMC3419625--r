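#' Normalise matched pairs to relative chromosomal positions
#'
#' Because chromosome sequences are revised between assembly versions,
#' absolute coordinates are not comparable; each gene is therefore placed at
#' the midpoint of its model expressed as a percentage of the total length
#' of its chromosome. Chromosome lengths are taken from \code{chromLengthsA}
#' / \code{chromLengthsB} when supplied and otherwise inferred as the
#' maximum gene end on each chromosome.
#'
#' @param pairs data.frame with columns \code{id_a}, \code{id_b} (e.g. from
#'   \code{\link{okPairs}}).
#' @param genesA,genesB the two \linkS4class{GeneSet}s.
#' @param chromLengthsA,chromLengthsB optional named numeric vectors of
#'   chromosome lengths.
#' @return data.frame with one row per pair: \code{id_a}, \code{id_b},
#'   \code{chrom_a}, \code{chrom_b}, \code{pos_a_pct}, \code{pos_b_pct},
#'   \code{placement_a}, \code{placement_b}.
#' @examples
#' gsA <- GeneSet("chr1", 100, 300, "+", "a1", versionLabel = "A")
#' gsB <- GeneSet("chr1", 100, 300, "+", "b1", versionLabel = "B")
#' normalizePositions(data.frame(id_a = "a1", id_b = "b1"), gsA, gsB,
#'                    chromLengthsA = c(chr1 = 1000),
#'                    chromLengthsB = c(chr1 = 1000))$pos_a_pct  # 20
#' @export
normalizePositions <- function(pairs, genesA, genesB,
                               chromLengthsA = NULL, chromLengthsB = NULL) {
  stopifnot(all(c("id_a", "id_b") %in% colnames(pairs)))
  side <- function(gs, ids, lens) {
    df <- geneTable(gs)
    if (is.null(lens)) {
      lens <- tapply(df$end, df$chromosome, max)
    }
    if (any(lens <= 0)) stop("zero-length chromosome")
    i <- match(ids, df$gene_id)
    if (anyNA(i))
      stop("pair references unknown gene id(s): ",
           paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
    mid <- (df$start[i] + df$end[i]) / 2
    chrom <- df$chromosome[i]
    list(chrom = chrom, pct = 100 * mid / as.numeric(lens[chrom]),
         placement = df$placement[i])
  }
  a <- side(genesA, pairs$id_a, chromLengthsA)
  b <- side(genesB, pairs$id_b, chromLengthsB)
  data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
             chrom_a = a$chrom, chrom_b = b$chrom,
             pos_a_pct = a$pct, pos_b_pct = b$pct,
             placement_a = a$placement, placement_b = b$placement,
             stringsAsFactors = FALSE)
}

#' Categorize matched pairs by their cross-version location
#'
#' Each pair receives exactly one of three categories:
#' \code{same_chrom} (same chromosome, both placed),
#' \code{unknown_involved} (on the unknown chromosome in at least one
#' version; takes precedence) and \code{different_or_random} (two different
#' chromosomes, or random placement in at least one version).
#'
#' @param positions output of \code{\link{normalizePositions}}.
#' @return \code{positions} with an added \code{pair_category} column; the
#'   per-category counts are attached as \code{attr(, "counts")}.
#' @export
categorizePairs <- function(positions) {
  unknown <- positions$placement_a == "unknown" |
    positions$placement_b == "unknown"
  same <- positions$chrom_a == positions$chrom_b &
    positions$placement_a == "placed" & positions$placement_b == "placed"
  cat <- ifelse(unknown, "unknown_involved",
                ifelse(same, "same_chrom", "different_or_random"))
  positions$pair_category <- cat
  counts <- c(same_chrom = sum(cat == "same_chrom"),
              unknown_involved = sum(cat == "unknown_involved"),
              different_or_random = sum(cat == "different_or_random"))
  attr(positions, "counts") <- counts
  positions
}

#' Detect placement modifications between the versions
#'
#' Labels each categorized pair with the modification the newer assembly
#' made to the gene's placement:
#' \code{newly_placed_from_unknown} (unknown chromosome in A, placed in B),
#' \code{newly_placed_from_random} (random chromosome in A, placed on the
#' same base chromosome in B), \code{reassigned} (placed or random in A,
#' placed on a different chromosome in B), or \code{none}.
#'
#' @param positions output of \code{\link{categorizePairs}}.
#' @param randomSuffix suffix of random-chromosome names.
#' @return \code{positions} with an added \code{modification} column; a
#'   summary (counts per type and per chromosome flow of reassignments) is
#'   attached as \code{attr(, "summary")}.
#' @export
detectModifications <- function(positions, randomSuffix = "_random") {
  pa <- positions$placement_a; pb <- positions$placement_b
  baseA <- .baseChrom(positions$chrom_a, randomSuffix)
  mod <- rep("none", nrow(positions))
  mod[pa == "unknown" & pb == "placed"] <- "newly_placed_from_unknown"
  mod[pa == "random" & pb == "placed" &
        baseA == positions$chrom_b] <- "newly_placed_from_random"
  mod[pa %in% c("placed", "random") & pb == "placed" &
        baseA != positions$chrom_b] <- "reassigned"
  positions$modification <- mod
  flows <- positions[mod == "reassigned", c("chrom_a", "chrom_b")]
  flowTab <- if (nrow(flows))
    stats::aggregate(list(n = seq_len(nrow(flows))), flows, FUN = length)
  else data.frame(chrom_a = character(), chrom_b = character(),
                  n = integer())
  attr(positions, "summary") <- list(counts = table(mod), flows = flowTab)
  positions
}

#' Detect inverted blocks from gene-order runs
#'
#' Within each chromosome shared by both versions, pairs are sorted by their
#' position in version B; a maximal contiguous run of at least
#' \code{minRun} pairs whose version-A order is strictly decreasing (the
#' negative-correlation pattern of an inverted assembly segment) is reported
#' as an inversion run. Unmatched genes do not interrupt contiguity because
#' only matched pairs enter the scan, and a globally reversed coordinate
#' system is not an inversion: reversing both versions' orders leaves the
#' scan invariant.
#'
#' @param positions output of \code{\link{categorizePairs}} (only
#'   \code{same_chrom} pairs are scanned).
#' @param minRun minimum number of genes in a run (default 3).
#' @return a list: \code{runs} (data.frame with \code{chromosome},
#'   \code{length}, \code{orientation_score} and a \code{members}
#'   list-column of pair ids in B order) and \code{positions}, the input
#'   with \code{modification} set to \code{inverted_block_member} for run
#'   members.
#' @export
detectInversionRuns <- function(positions, minRun = 3L) {
  if (!"modification" %in% colnames(positions))
    positions$modification <- "none"
  sub <- positions[positions$pair_category == "same_chrom", , drop = FALSE]
  runsOut <- list()
  members <- character(0)
  for (chrom in unique(sub$chrom_b)) {
    cc <- sub[sub$chrom_b == chrom, , drop = FALSE]
    cc <- cc[order(cc$pos_b_pct), , drop = FALSE]
    if (nrow(cc) < minRun) next
    dec <- diff(cc$pos_a_pct) < 0
    # maximal stretches of consecutive decreasing steps
    r <- rle(dec)
    idx <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      runLen <- r$lengths[k] + 1L       # steps -> genes
      if (runLen < minRun) next
      lo <- idx[k]; hi <- idx[k] + r$lengths[k]
      ids <- cc$id_b[lo:hi]
      members <- c(members, ids)
      runsOut[[length(runsOut) + 1L]] <- data.frame(
        chromosome = chrom, length = runLen,
        orientation_score = -1,
        stringsAsFactors = FALSE)
      runsOut[[length(runsOut)]]$members <- I(list(ids))
    }
  }
  runs <- if (length(runsOut)) do.call(rbind, runsOut) else
    data.frame(chromosome = character(), length = integer(),
               orientation_score = numeric(),
               members = I(list()))
  positions$modification[positions$id_b %in% members] <-
    "inverted_block_member"
  list(runs = runs, positions = positions)
}

#' Scatter plot of relative gene positions between versions
#'
#' Reproduces the classic cross-version position scatter: one panel per
#' pair category, x = relative position in version A, y = relative position
#' in version B, colored by version-B chromosome. Purely a display: the
#' conventional display scalings for random chromosomes (1/10 size) and the
#' unknown chromosome (magnified) are never applied to the computed
#' percentages.
#'
#' @param positions output of \code{\link{categorizePairs}}.
#' @param category which pair category to plot.
#' @param ... passed to \code{plot}.
#' @return invisibly, the plotted subset.
#' @export
plotPairPositions <- function(positions,
                              category = c("same_chrom", "unknown_involved",
                                           "different_or_random"),
                              ...) {
  category <- match.arg(category)
  sub <- positions[positions$pair_category == category, , drop = FALSE]
  chroms <- sort(unique(sub$chrom_b))
  cols <- grDevices::rainbow(max(length(chroms), 1L))
  graphics::plot(sub$pos_a_pct, sub$pos_b_pct,
                 col = cols[match(sub$chrom_b, chroms)],
                 pch = ifelse(match(sub$chrom_b, chroms) %% 2L == 0L, 1, 8),
                 xlab = "relative position in version A (%)",
                 ylab = "relative position in version B (%)",
                 main = category, ...)
  invisible(sub)
}
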