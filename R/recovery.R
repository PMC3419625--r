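#' Protein-evidence hits against selected genes
#'
#' Aligns the evidence sequences against the given genes with the internal
#' aligner, filters the hits at the supplied stringency, and reshapes them
#' into the evidence table consumed by \code{\link{classifyCardinality}}.
#'
#' @param proteins named sequences (\code{DNAStringSet} or character).
#' @param flags named logical: protein-level existence flags (proteins
#'   missing from it are unflagged).
#' @param geneSet the \linkS4class{GeneSet} the genes belong to.
#' @param geneIds ids of the genes to align against (e.g. the hub genes of
#'   one-to-many components).
#' @param policy a \code{\link{filterPolicy}} applied to the raw hits.
#' @return evidence data.frame (see \code{\link{classifyCardinality}}).
#' @export
computeEvidenceHits <- function(proteins, flags, geneSet, geneIds,
                                policy = filterPolicy()) {
  seqs <- geneSequences(geneSet)
  geneIds <- intersect(geneIds, names(seqs))
  if (!length(geneIds) || !length(proteins)) {
    return(data.frame(protein_id = character(), gene_id = character(),
                      version = character(), p_start = numeric(),
                      p_end = numeric(), g_start = numeric(),
                      g_end = numeric(), protein_length = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  hits <- alignSets(proteins, seqs[geneIds])
  hits <- filterHits(hits, policy)
  plen <- stats::setNames(nchar(as.character(proteins)),
                          names(as.character(proteins)))
  fl <- rep(FALSE, nrow(hits))
  if (!is.null(flags)) {
    got <- flags[hits$query_id]
    fl <- !is.na(got) & got
  }
  data.frame(protein_id = hits$query_id, gene_id = hits$subject_id,
             version = versionLabel(geneSet),
             p_start = hits$q_start, p_end = hits$q_end,
             g_start = pmin(hits$s_start, hits$s_end),
             g_end = pmax(hits$s_start, hits$s_end),
             protein_length = as.numeric(plen[hits$query_id]),
             flagged = fl, stringsAsFactors = FALSE)
}

#' Run the full reconciliation pipeline on two gene sets
#'
#' Convenience wrapper chaining the pipeline end to end: align (or accept
#' externally computed tabular hits), filter at high stringency in both
#' directions, build the match graph, align protein evidence against the
#' one-to-many hub genes, classify every gene, propose splits, and run the
#' positional analysis on the validated one-to-one pairs.
#'
#' @param genesA,genesB the two \linkS4class{GeneSet}s (sequences attached
#'   unless hits are supplied).
#' @param proteins,proteinFlags optional protein-evidence sequences and
#'   protein-level flags (see \code{\link{computeEvidenceHits}}).
#' @param hitsAB,hitsBA optional externally computed tabular hits (A as
#'   query / B as query); when supplied they take precedence over the
#'   internal aligner.
#' @param filter a \code{\link{filterPolicy}}.
#' @param policy a \code{\link{classifyPolicy}}.
#' @param rule a \code{\link{neighborRule}}.
#' @param minRun minimum inversion-run length.
#' @param includeRepeat keep repeat-track genes in the graph.
#' @return list with elements \code{hitsAB}, \code{hitsBA} (filtered),
#'   \code{graph}, \code{evidence}, \code{calls}, \code{proposals},
#'   \code{positions}, \code{inversionRuns}.
#' @export
reconcilePair <- function(genesA, genesB, proteins = NULL,
                          proteinFlags = NULL, hitsAB = NULL, hitsBA = NULL,
                          filter = filterPolicy(),
                          policy = classifyPolicy(), rule = neighborRule(),
                          minRun = 3L, includeRepeat = FALSE) {
  if (is.null(hitsAB) || is.null(hitsBA)) {
    sa <- geneSequences(genesA); sb <- geneSequences(genesB)
    if (!length(sa) || !length(sb))
      stop("either tabular hits or sequences for both versions ",
           "must be supplied")
    if (is.null(hitsAB)) hitsAB <- alignSets(sa, sb)
    if (is.null(hitsBA)) hitsBA <- alignSets(sb, sa)
  }
  fAB <- filterHits(hitsAB, filter)
  fBA <- filterHits(hitsBA, filter)
  graph <- buildMatchGraph(fAB, fBA, genesA, genesB,
                           includeRepeat = includeRepeat)
  evidence <- NULL
  if (!is.null(proteins)) {
    ed <- matchEdges(graph)
    hubsA <- names(which(table(ed$id_a) >= 2L))
    hubsB <- names(which(table(ed$id_b) >= 2L))
    evidence <- rbind(
      computeEvidenceHits(proteins, proteinFlags, genesA, hubsA, filter),
      computeEvidenceHits(proteins, proteinFlags, genesB, hubsB, filter))
  }
  calls <- classifyCardinality(graph, genesA, genesB, evidence = evidence,
                               policy = policy, rule = rule)
  proposals <- proposeSplits(calls)
  pairs <- okPairs(calls)
  positions <- NULL; runs <- NULL
  if (nrow(pairs)) {
    positions <- categorizePairs(normalizePositions(pairs, genesA, genesB))
    positions <- detectModifications(positions,
                                     randomSuffix = genesA@randomSuffix)
    inv <- detectInversionRuns(positions, minRun = minRun)
    positions <- inv$positions
    runs <- inv$runs
  }
  list(hitsAB = fAB, hitsBA = fBA, graph = graph, evidence = evidence,
       calls = calls, proposals = proposals, positions = positions,
       inversionRuns = runs)
}

#' Ground-truth cardinality calls of a simulated pair
#'
#' Derives, from the planted events, the cardinality call every emitted
#' gene should receive from a perfect classifier.
#'
#' @param sim a \linkS4class{SimulatedGenePair}.
#' @return data.frame with columns \code{gene_id}, \code{version},
#'   \code{truth}.
#' @export
truthCardinalityCalls <- function(sim) {
  stopifnot(is(sim, "SimulatedGenePair"))
  tr <- simTruth(sim)
  labelOf <- c(none = "OK", split_in_B = "overlap", merge_in_B = "merged",
               tandem_expand_in_B = "redundant", chimera_in_B = "to_split",
               chimera_in_A = "split", invert_block = "OK",
               relocate = "OK", unplace_in_A = "OK", mutate = "OK",
               drop_from_A = "unmatched", drop_from_B = "unmatched",
               compound = "multiple")
  rows <- list()
  vA <- versionLabel(simGenesA(sim)); vB <- versionLabel(simGenesB(sim))
  for (i in seq_len(nrow(tr))) {
    lab <- labelOf[[tr$event[i]]]
    idsA <- strsplit(tr$ids_A[i], ",", fixed = TRUE)[[1]]
    idsB <- strsplit(tr$ids_B[i], ",", fixed = TRUE)[[1]]
    # a gene present in only one version is unmatched there
    labA <- if (tr$event[i] == "drop_from_B") "unmatched" else lab
    labB <- if (tr$event[i] == "drop_from_A") "unmatched" else lab
    if (length(idsA))
      rows[[length(rows) + 1L]] <- data.frame(gene_id = idsA, version = vA,
                                              truth = labA,
                                              stringsAsFactors = FALSE)
    if (length(idsB))
      rows[[length(rows) + 1L]] <- data.frame(gene_id = idsB, version = vB,
                                              truth = labB,
                                              stringsAsFactors = FALSE)
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Ground-truth positional modifications of a simulated pair
#'
#' @param sim a \linkS4class{SimulatedGenePair}.
#' @return data.frame with columns \code{id_b} (version-B gene id of the
#'   expected one-to-one pair) and \code{truth} (expected modification
#'   label).
#' @export
truthPositionLabels <- function(sim) {
  tr <- simTruth(sim)
  labelOf <- c(invert_block = "inverted_block_member",
               relocate = "reassigned",
               unplace_in_A = "newly_placed_from_unknown")
  sub <- tr[tr$event %in% names(labelOf), , drop = FALSE]
  data.frame(id_b = sub$ids_B, truth = labelOf[sub$event],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score pipeline output against the planted ground truth
#'
#' Joins predicted cardinality calls (and, optionally, positional
#' modification labels) with the truth derived from the event log and
#' reports per-class true/false positives and negatives, precision and
#' recall.
#'
#' @param calls output of \code{\link{classifyCardinality}} (or the
#'   \code{calls} element of \code{\link{reconcilePair}}).
#' @param sim the \linkS4class{SimulatedGenePair} the calls were computed
#'   on.
#' @param positions optional positions table (with \code{modification}) to
#'   score the positional classes as well.
#' @return data.frame with columns \code{class}, \code{n_truth}, \code{tp},
#'   \code{fp}, \code{fn}, \code{precision}, \code{recall}.
#' @export
scoreRecovery <- function(calls, sim, positions = NULL) {
  truth <- truthCardinalityCalls(sim)
  key <- paste(truth$version, truth$gene_id)
  predKey <- paste(calls$version, calls$gene_id)
  pred <- calls$call[match(key, predKey)]
  classes <- sort(unique(c(truth$truth, pred)))
  tally <- function(cls, truthVec, predVec) {
    tp <- sum(truthVec == cls & predVec == cls, na.rm = TRUE)
    fp <- sum(truthVec != cls & predVec == cls, na.rm = TRUE)
    fn <- sum(truthVec == cls & (is.na(predVec) | predVec != cls))
    data.frame(class = cls, n_truth = sum(truthVec == cls), tp = tp,
               fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(classes, tally, truthVec = truth$truth,
                               predVec = pred))
  if (!is.null(positions)) {
    ptruth <- truthPositionLabels(sim)
    # positional truth is defined on the genes expected to form OK pairs
    pv <- stats::setNames(rep("none", nrow(positions)), positions$id_b)
    pv[] <- positions$modification
    tv <- stats::setNames(rep("none", nrow(positions)), positions$id_b)
    tv[ptruth$id_b[ptruth$id_b %in% names(tv)]] <-
      ptruth$truth[ptruth$id_b %in% names(tv)]
    # genes expected to pair but absent from positions are misses
    missing <- setdiff(ptruth$id_b, names(tv))
    for (cls in unique(ptruth$truth)) {
      tp <- sum(tv == cls & pv == cls)
      fp <- sum(tv != cls & pv == cls)
      fn <- sum(tv == cls & pv != cls) +
        sum(ptruth$truth[ptruth$id_b %in% missing] == cls)
      out <- rbind(out, data.frame(
        class = cls, n_truth = sum(ptruth$truth == cls), tp = tp, fp = fp,
        fn = fn,
        precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
        recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
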