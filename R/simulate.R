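#' Configuration for the synthetic assembly-pair generator
#'
#' Defines the conditions under which a pair of gene-set "versions" is
#' derived from a common ancestral gene complement. Defaults describe a
#' desk-scale genome of 2 chromosomes x 250 genes with 20 planted events per
#' structural class (5 of the 20 B-side chimeras fusing three genes),
#' 3 inverted blocks, 10 chromosome relocations, 30 genes unplaced in
#' version A, 10 genes private to each version, no sequence divergence and
#' full protein-level evidence.
#'
#' Event semantics (A is the older version, B the newer):
#' \describe{
#'   \item{split_in_B}{one real gene, predicted as one gene in A but
#'     incorrectly split into two models in B (downstream truth: overlap).}
#'   \item{merge_in_B}{one real gene, incorrectly split in A, correctly
#'     merged in B (truth: merged).}
#'   \item{tandem_expand_in_B}{tandem copies collapsed into a single gene in
#'     A, resolved as identical adjacent copies in B (truth: redundant).}
#'   \item{chimera_in_B}{2-3 adjacent real genes incorrectly fused into one
#'     B model (truth: to_split, an artificial chimera).}
#'   \item{chimera_in_A}{2-3 adjacent real genes fused in A, correctly
#'     separate in B (truth: split).}
#'   \item{invert_block}{a contiguous run of genes whose order (and strand)
#'     is reversed in B.}
#'   \item{relocate}{a gene assigned to a different chromosome in B.}
#'   \item{unplace_in_A}{a gene sitting on the unknown chromosome in A and
#'     placed in B.}
#'   \item{drop_from_A / drop_from_B}{genes private to one version.}
#'   \item{mutate}{genes carrying extra point divergence in B.}
#'   \item{compound}{three adjacent genes realising the two-by-two compound
#'     topology (fused differently in the two versions; truth: multiple).}
#' }
#'
#' @param chromosomes,genesPerChromosome genome shape.
#' @param nSplitInB,nMergeInB,nTandemExpandInB,nChimeraInB,nChimeraTripleInB,nChimeraInA,nRelocate,nUnplaceInA,nDropFromA,nDropFromB,nMutate,nCompound
#'   per-event counts; \code{nChimeraTripleInB} of the \code{nChimeraInB}
#'   chimeras fuse three genes instead of two.
#' @param nInvertBlocks,invertBlockSize number of inverted blocks and the
#'   inclusive range their gene count is drawn from.
#' @param divergence point-substitution rate d applied to every version-B
#'   sequence (0 <= d < 0.05; substitutions only, so expected identity is
#'   100(1 - d)).
#' @param mutateRate extra substitution rate for \code{mutate}-event genes.
#' @param evidenceRate probability that an ancestral gene's cognate evidence
#'   protein is emitted.
#' @param tandemCopies copies per tandem expansion.
#' @param geneLengthRange gene lengths are drawn log-uniformly from this
#'   range (bp).
#' @param minPartLength minimum length of a split part (bp); breakpoints are
#'   drawn at least this far from each gene end.
#' @param spacingRange uniform inter-gene spacing range (bp).
#' @param unknownChrom,randomSuffix placement naming conventions.
#' @param versionA,versionB labels of the emitted versions.
#' @param seed RNG seed; identical config + seed gives byte-identical
#'   output.
#' @return a \code{simulationConfig} list.
#' @export
simulationConfig <- function(chromosomes = 2L, genesPerChromosome = 250L,
                             nSplitInB = 20L, nMergeInB = 20L,
                             nTandemExpandInB = 20L,
                             nChimeraInB = 20L, nChimeraTripleInB = 5L,
                             nChimeraInA = 20L,
                             nInvertBlocks = 3L,
                             invertBlockSize = c(5L, 12L),
                             nRelocate = 10L, nUnplaceInA = 30L,
                             nDropFromA = 10L, nDropFromB = 10L,
                             nMutate = 0L, mutateRate = 0.04,
                             nCompound = 0L,
                             divergence = 0, evidenceRate = 1,
                             tandemCopies = 2L,
                             geneLengthRange = c(300L, 3000L),
                             minPartLength = 150L,
                             spacingRange = c(200L, 2000L),
                             unknownChrom = "chrUn",
                             randomSuffix = "_random",
                             versionA = "A", versionB = "B",
                             seed = 1L) {
  stopifnot(divergence >= 0, divergence < 0.05,
            evidenceRate > 0, evidenceRate <= 1,
            nChimeraTripleInB <= nChimeraInB,
            geneLengthRange[1] >= 2 * minPartLength,
            tandemCopies >= 2L)
  cfg <- as.list(environment())
  class(cfg) <- "simulationConfig"
  cfg
}

.randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutateSeq <- function(seq, d) {
  if (d <= 0) return(seq)
  L <- nchar(seq)
  nMut <- stats::rbinom(1L, L, d)
  if (nMut == 0L) return(seq)
  pos <- sample.int(L, nMut)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Emit the cross-species protein-evidence set
#'
#' Each ancestral gene's cognate evidence sequence is emitted with
#' probability \code{evidenceRate} and flagged as having existence
#' demonstrated at the protein level. Downstream chimera resolution uses
#' only flagged evidence by default.
#'
#' @param ancestral named \code{\link[Biostrings]{DNAStringSet}} (or named
#'   character vector) of ancestral gene sequences.
#' @param evidenceRate emission probability (0 < rate <= 1).
#' @return list with \code{sequences} (a \code{DNAStringSet} named
#'   \code{p_<anc_id>}) and \code{flags} (named logical, all TRUE).
#' @export
makeProteinEvidence <- function(ancestral, evidenceRate = 1) {
  stopifnot(evidenceRate > 0, evidenceRate <= 1)
  seqs <- if (is.character(ancestral)) ancestral else as.character(ancestral)
  keep <- stats::runif(length(seqs)) < evidenceRate
  out <- seqs[keep]
  names(out) <- paste0("p_", names(seqs)[keep])
  list(sequences = Biostrings::DNAStringSet(out),
       flags = stats::setNames(rep(TRUE, sum(keep)), names(out)))
}

#' Simulate a pair of assembly versions with known edit events
#'
#' Generates an ancestral gene complement, plants the configured edit
#' events on disjoint gene sets, and emits the two resulting gene-set
#' versions together with the protein-evidence set and a complete event
#' log / truth map. With zero divergence, every gene untouched by an event
#' has an identical sequence in both versions; chimera genes concatenate
#' their parts, split genes partition the ancestral sequence at a
#' breakpoint at least \code{minPartLength} from each end, inverted blocks
#' reverse gene order and strand within a contiguous run, and unplace
#' events move the gene to the unknown chromosome in version A only.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{SimulatedGenePair}.
#' @examples
#' sim <- simulateAssemblyPair(simulationConfig(
#'   chromosomes = 1, genesPerChromosome = 30, nSplitInB = 2, nMergeInB = 2,
#'   nTandemExpandInB = 1, nChimeraInB = 1, nChimeraTripleInB = 0,
#'   nChimeraInA = 1, nInvertBlocks = 1, invertBlockSize = c(3, 4),
#'   nRelocate = 0, nUnplaceInA = 2, nDropFromA = 1, nDropFromB = 1,
#'   seed = 7))
#' sim
#' @export
simulateAssemblyPair <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  cfg <- config
  set.seed(cfg$seed)

  nc <- cfg$chromosomes
  gpc <- cfg$genesPerChromosome
  n <- nc * gpc
  chromName <- paste0("chr", seq_len(nc))
  ancChrom <- rep(chromName, each = gpc)
  ancOrder <- rep(seq_len(gpc), times = nc)
  ancId <- sprintf("anc%05d", seq_len(n))
  lens <- round(10^stats::runif(n, log10(cfg$geneLengthRange[1]),
                                log10(cfg$geneLengthRange[2])))
  ancSeq <- vapply(lens, .randomSeq, character(1))
  names(ancSeq) <- ancId

  # ---- event planning on disjoint gene sets ------------------------------
  ev <- rep("none", n)
  evId <- rep(NA_integer_, n)
  groupLeader <- rep(NA_integer_, n)  # index of the first gene of a group
  events <- list()
  nextEvent <- 0L

  addEvent <- function(type, idx, params = "") {
    nextEvent <<- nextEvent + 1L
    ev[idx] <<- type
    evId[idx] <<- nextEvent
    groupLeader[idx] <<- idx[1]
    events[[nextEvent]] <<- data.frame(
      event_id = nextEvent, type = type,
      anc_ids = paste(ancId[idx], collapse = ","),
      params = params, stringsAsFactors = FALSE)
  }

  pickRun <- function(len) {
    free <- which(ev == "none")
    starts <- free[ancOrder[free] <= gpc - len + 1L]
    starts <- starts[vapply(starts, function(s)
      all(ev[s:(s + len - 1L)] == "none"), logical(1))]
    if (!length(starts)) stop("infeasible configuration: no room left for ",
                              "a run of ", len, " genes")
    s <- starts[sample.int(length(starts), 1L)]
    s:(s + len - 1L)
  }
  pickSingles <- function(k, eligible = rep(TRUE, n)) {
    free <- which(ev == "none" & eligible)
    if (length(free) < k)
      stop("infeasible configuration: more event genes than genes")
    if (k == 0L) return(integer(0))
    free[sample.int(length(free), k)]
  }

  needed <- cfg$nSplitInB + cfg$nMergeInB + cfg$nTandemExpandInB +
    2L * (cfg$nChimeraInB - cfg$nChimeraTripleInB) +
    3L * cfg$nChimeraTripleInB + 2L * cfg$nChimeraInA +
    cfg$nInvertBlocks * cfg$invertBlockSize[2] + cfg$nRelocate +
    cfg$nUnplaceInA + cfg$nDropFromA + cfg$nDropFromB + cfg$nMutate +
    3L * cfg$nCompound
  if (needed > n)
    stop("infeasible configuration: ", needed,
         " event genes requested but only ", n, " genes simulated")

  for (i in seq_len(cfg$nInvertBlocks)) {
    len <- sample(seq(cfg$invertBlockSize[1], cfg$invertBlockSize[2]), 1L)
    addEvent("invert_block", pickRun(len), params = paste0("len=", len))
  }
  for (i in seq_len(cfg$nCompound))
    addEvent("compound", pickRun(3L))
  chimKs <- c(rep(3L, cfg$nChimeraTripleInB),
              rep(2L, cfg$nChimeraInB - cfg$nChimeraTripleInB))
  for (k in chimKs)
    addEvent("chimera_in_B", pickRun(k), params = paste0("k=", k))
  for (i in seq_len(cfg$nChimeraInA))
    addEvent("chimera_in_A", pickRun(2L), params = "k=2")
  for (i in seq_len(cfg$nSplitInB))
    addEvent("split_in_B", pickSingles(1L))
  for (i in seq_len(cfg$nMergeInB))
    addEvent("merge_in_B", pickSingles(1L))
  for (i in seq_len(cfg$nTandemExpandInB))
    addEvent("tandem_expand_in_B", pickSingles(1L),
             params = paste0("copies=", cfg$tandemCopies))
  for (i in seq_len(cfg$nRelocate)) {
    idx <- pickSingles(1L)
    target <- if (nc > 1L)
      sample(setdiff(chromName, ancChrom[idx]), 1L) else chromName
    addEvent("relocate", idx, params = paste0("target=", target))
  }
  for (i in seq_len(cfg$nUnplaceInA))
    addEvent("unplace_in_A", pickSingles(1L))
  for (i in seq_len(cfg$nDropFromA)) addEvent("drop_from_A", pickSingles(1L))
  for (i in seq_len(cfg$nDropFromB)) addEvent("drop_from_B", pickSingles(1L))
  for (i in seq_len(cfg$nMutate))
    addEvent("mutate", pickSingles(1L),
             params = paste0("rate=", cfg$mutateRate))

  eventsDf <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = integer(), type = character(),
               anc_ids = character(), params = character())

  # per-gene split/merge breakpoints (fraction of length, drawn up front so
  # both versions agree on merge_in_B partitions)
  breakAt <- function(L) {
    sample(seq(cfg$minPartLength, L - cfg$minPartLength), 1L)
  }

  idsA <- stats::setNames(vector("list", n), ancId)
  idsB <- stats::setNames(vector("list", n), ancId)

  # ---- version A emission plan -------------------------------------------
  counterA <- 0L
  newIdA <- function() {
    counterA <<- counterA + 1L
    sprintf("%s%05d", cfg$versionA, counterA)
  }
  planA <- list()   # entries: chrom, id, seq, strand, anc (vector)
  addA <- function(chrom, idx, seq, strand = "+") {
    id <- newIdA()
    for (i in idx) idsA[[i]] <<- c(idsA[[i]], id)
    planA[[length(planA) + 1L]] <<- list(chrom = chrom, id = id, seq = seq,
                                         strand = strand)
  }
  consumedA <- rep(FALSE, n)
  for (g in seq_len(n)) {
    if (consumedA[g]) next
    type <- ev[g]
    if (type == "drop_from_A") next
    if (type == "unplace_in_A") {
      addA(cfg$unknownChrom, g, ancSeq[[g]])
    } else if (type %in% c("chimera_in_A", "compound") &&
               groupLeader[g] == g) {
      members <- which(evId == evId[g])
      if (type == "chimera_in_A") {
        addA(ancChrom[g], members, paste(ancSeq[members], collapse = ""))
      } else {
        # compound: A fuses genes 1+2; gene 3 stays separate
        addA(ancChrom[g], members[1:2],
             paste(ancSeq[members[1:2]], collapse = ""))
        addA(ancChrom[g], members[3], ancSeq[[members[3]]])
      }
      consumedA[members] <- TRUE
    } else if (type == "merge_in_B") {
      bp <- breakAt(lens[g])
      s <- ancSeq[[g]]
      addA(ancChrom[g], g, substr(s, 1L, bp))
      addA(ancChrom[g], g, substr(s, bp + 1L, lens[g]))
    } else {
      addA(ancChrom[g], g, ancSeq[[g]])
    }
  }

  # ---- version B emission plan -------------------------------------------
  counterB <- 0L
  newIdB <- function() {
    counterB <<- counterB + 1L
    sprintf("%s%05d", cfg$versionB, counterB)
  }
  planB <- list()
  relocated <- list()
  addB <- function(chrom, idx, seq, strand = "+", defer = FALSE) {
    id <- newIdB()
    for (i in idx) idsB[[i]] <<- c(idsB[[i]], id)
    entry <- list(chrom = chrom, id = id, seq = seq, strand = strand)
    if (defer) relocated[[length(relocated) + 1L]] <<- entry
    else planB[[length(planB) + 1L]] <<- entry
  }
  consumedB <- rep(FALSE, n)
  for (g in seq_len(n)) {
    if (consumedB[g]) next
    type <- ev[g]
    if (type == "drop_from_B") next
    if (type == "invert_block" && groupLeader[g] == g) {
      members <- rev(which(evId == evId[g]))
      for (m in members) addB(ancChrom[m], m, ancSeq[[m]], strand = "-")
      consumedB[members] <- TRUE
    } else if (type %in% c("chimera_in_B", "compound") &&
               groupLeader[g] == g) {
      members <- which(evId == evId[g])
      if (type == "chimera_in_B") {
        addB(ancChrom[g], members, paste(ancSeq[members], collapse = ""))
      } else {
        # compound: B keeps gene 1 separate and fuses genes 2+3
        addB(ancChrom[g], members[1], ancSeq[[members[1]]])
        addB(ancChrom[g], members[2:3],
             paste(ancSeq[members[2:3]], collapse = ""))
      }
      consumedB[members] <- TRUE
    } else if (type == "split_in_B") {
      bp <- breakAt(lens[g])
      s <- ancSeq[[g]]
      addB(ancChrom[g], g, substr(s, 1L, bp))
      addB(ancChrom[g], g, substr(s, bp + 1L, lens[g]))
    } else if (type == "tandem_expand_in_B") {
      for (cp in seq_len(cfg$tandemCopies))
        addB(ancChrom[g], g, ancSeq[[g]])
    } else if (type == "relocate") {
      target <- sub("^target=", "",
                    eventsDf$params[eventsDf$event_id == evId[g]])
      addB(target, g, ancSeq[[g]], defer = TRUE)
    } else {
      addB(ancChrom[g], g, ancSeq[[g]])
    }
  }
  planB <- c(planB, relocated)

  # divergence (and per-gene extra mutation) applied to emitted B sequences
  mutateExtra <- ancId[ev == "mutate"]
  if (cfg$divergence > 0 || length(mutateExtra)) {
    idsOfMutated <- unlist(idsB[mutateExtra], use.names = FALSE)
    for (i in seq_along(planB)) {
      d <- cfg$divergence +
        if (planB[[i]]$id %in% idsOfMutated) cfg$mutateRate else 0
      planB[[i]]$seq <- .mutateSeq(planB[[i]]$seq, d)
    }
  }

  # ---- coordinate layout --------------------------------------------------
  layout <- function(plan, versionLabel) {
    chroms <- vapply(plan, `[[`, character(1), "chrom")
    starts <- ends <- integer(length(plan))
    cursor <- stats::setNames(rep(0L, length(unique(chroms))),
                              unique(chroms))
    for (i in seq_along(plan)) {
      spc <- round(stats::runif(1, cfg$spacingRange[1], cfg$spacingRange[2]))
      st <- cursor[[chroms[i]]] + spc
      en <- st + nchar(plan[[i]]$seq) - 1L
      cursor[[chroms[i]]] <- en
      starts[i] <- st; ends[i] <- en
    }
    seqs <- stats::setNames(vapply(plan, `[[`, character(1), "seq"),
                            vapply(plan, `[[`, character(1), "id"))
    GeneSet(chromosome = chroms, start = starts, end = ends,
            strand = vapply(plan, `[[`, character(1), "strand"),
            gene_id = names(seqs), versionLabel = versionLabel,
            sequences = Biostrings::DNAStringSet(seqs),
            unknownChrom = cfg$unknownChrom, randomSuffix = cfg$randomSuffix)
  }
  genesA <- layout(planA, cfg$versionA)
  genesB <- layout(planB, cfg$versionB)

  evidence <- makeProteinEvidence(ancSeq, cfg$evidenceRate)

  truth <- data.frame(
    anc_id = ancId, chromosome = ancChrom, order_index = ancOrder,
    length = lens, event = ev, event_id = evId,
    ids_A = vapply(idsA, function(x) paste(x, collapse = ","), character(1)),
    ids_B = vapply(idsB, function(x) paste(x, collapse = ","), character(1)),
    protein_id = ifelse(paste0("p_", ancId) %in% names(evidence$flags),
                        paste0("p_", ancId), ""),
    stringsAsFactors = FALSE)

  new("SimulatedGenePair", genesA = genesA, genesB = genesB,
      ancestral = Biostrings::DNAStringSet(ancSeq),
      proteins = evidence$sequences, proteinFlags = evidence$flags,
      events = eventsDf, truth = truth, config = unclass(cfg),
      seed = as.integer(cfg$seed))
}
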