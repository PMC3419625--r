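#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' GeneSet: the gene complement of one assembly version
#'
#' A \code{GeneSet} holds the predicted gene models of a single assembly
#' version: their genomic coordinates as a \link[GenomicRanges]{GRanges}
#' (with metadata columns \code{gene_id}, \code{placement} and \code{track}),
#' optionally their nucleotide sequences, and the naming conventions used to
#' recognise the unplaced pseudo-chromosomes of that assembly.
#'
#' Placement is derived from the chromosome name: a gene on the designated
#' unknown chromosome (default \code{"chrUn"}, an artificial concatenation of
#' unassigned scaffolds) has \code{placement == "unknown"}; a gene on a
#' chromosome whose name carries the random suffix (default \code{"_random"},
#' scaffolds assigned to a chromosome but not positioned within it) has
#' \code{placement == "random"}; all other genes are \code{"placed"}.
#'
#' The \code{track} column distinguishes the main annotation track from a
#' repeat track of masked, speculative gene models; repeat-track genes are
#' loaded but excluded from cross-version matching by default.
#'
#' @slot genes a \code{GRanges} with metadata columns \code{gene_id}
#'   (character, unique), \code{placement}
#'   (\code{"placed"}/\code{"random"}/\code{"unknown"}) and \code{track}
#'   (\code{"main"}/\code{"repeat"}).
#' @slot versionLabel single character naming the assembly version.
#' @slot sequences a \code{DNAStringSet} named by \code{gene_id}
#'   (possibly empty when only coordinates are available).
#' @slot unknownChrom chromosome label meaning "unknown placement".
#' @slot randomSuffix chromosome-name suffix meaning "random placement".
#'
#' @seealso \code{\link{GeneSet}} (constructor), \code{\link{readGeneTable}}
#' @aliases GeneSet-class
#' @exportClass GeneSet
setClass("GeneSet",
  representation(
    genes = "GRanges",
    versionLabel = "character",
    sequences = "DNAStringSet",
    unknownChrom = "character",
    randomSuffix = "character"
  )
)

setValidity("GeneSet", function(object) {
  msg <- character()
  gr <- object@genes
  mc <- S4Vectors::mcols(gr)
  need <- c("gene_id", "placement", "track")
  if (!all(need %in% colnames(mc))) {
    return(paste("genes must carry metadata columns:",
                 paste(need, collapse = ", ")))
  }
  if (length(object@versionLabel) != 1L || is.na(object@versionLabel))
    msg <- c(msg, "versionLabel must be a single non-NA string")
  ids <- mc$gene_id
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate gene_id within version: ",
                         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                               collapse = ", ")))
  if (length(gr) && any(GenomicRanges::start(gr) < 1L))
    msg <- c(msg, "gene start coordinates must be >= 1")
  if (!all(mc$placement %in% c("placed", "random", "unknown")))
    msg <- c(msg, "placement must be one of placed/random/unknown")
  if (!all(mc$track %in% c("main", "repeat")))
    msg <- c(msg, "track must be one of main/repeat")
  # placement must agree with the chromosome naming convention
  if (length(gr)) {
    expected <- placementFromChrom(as.character(GenomicRanges::seqnames(gr)),
                                   object@unknownChrom, object@randomSuffix)
    bad <- which(expected != mc$placement)
    if (length(bad))
      msg <- c(msg, paste0("placement inconsistent with chromosome label for gene(s): ",
                           paste(utils::head(ids[bad], 3), collapse = ", ")))
  }
  if (length(object@sequences)) {
    if (is.null(names(object@sequences)) ||
        !all(names(object@sequences) %in% ids))
      msg <- c(msg, "sequences must be named by gene_id present in the gene table")
  }
  if (length(msg)) msg else TRUE
})

#' MatchGraph: the bipartite cross-version match graph
#'
#' Nodes are the (non-repeat-track, unless configured otherwise) gene ids of
#' the two versions; edges summarise the filtered, direction-merged alignment
#' hits between one gene of version A and one gene of version B, with the
#' matched interval hull on each gene.
#'
#' @slot edges data.frame with one row per (id_a, id_b) pair and columns
#'   \code{id_a}, \code{id_b}, \code{a_start}, \code{a_end}, \code{b_start},
#'   \code{b_end}, \code{direction} (\code{"AB"}, \code{"BA"} or
#'   \code{"both"}), \code{bit_score}, \code{pct_identity}.
#' @slot nodesA,nodesB character vectors of the gene ids considered on each
#'   side (matched or not).
#' @slot versionA,versionB the version labels of the two sides.
#'
#' @seealso \code{\link{buildMatchGraph}}, \code{\link{classifyCardinality}}
#' @aliases MatchGraph-class
#' @exportClass MatchGraph
setClass("MatchGraph",
  representation(
    edges = "data.frame",
    nodesA = "character",
    nodesB = "character",
    versionA = "character",
    versionB = "character"
  )
)

setValidity("MatchGraph", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("id_a", "id_b", "a_start", "a_end", "b_start", "b_end",
            "direction", "bit_score", "pct_identity")
  if (!all(need %in% colnames(ed)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(ed)) {
    if (!all(ed$id_a %in% object@nodesA))
      msg <- c(msg, "edge id_a not among nodesA")
    if (!all(ed$id_b %in% object@nodesB))
      msg <- c(msg, "edge id_b not among nodesB")
    if (anyDuplicated(paste(ed$id_a, ed$id_b, sep = "\r")))
      msg <- c(msg, "at most one edge per (id_a, id_b) pair")
    if (!all(ed$direction %in% c("AB", "BA", "both")))
      msg <- c(msg, "direction must be AB/BA/both")
  }
  if (length(msg)) msg else TRUE
})

#' CategoryCatalog: a hierarchical functional-category catalog
#'
#' A catalog of plant-physiology-oriented functional categories with dotted
#' numeric codes, up to eight levels of detail, and optional cross-references
#' to GO terms and MIPS funcat codes. The hierarchy is encoded by
#' \code{parent_code}; a node's level is one more than its parent's, root
#' nodes have level 1.
#'
#' @slot table data.frame with columns \code{code}, \code{name}, \code{level},
#'   \code{go_id}, \code{go_name}, \code{mips_code}, \code{mips_name},
#'   \code{network}, \code{parent_code}, \code{n_genes}.
#'
#' @seealso \code{\link{readCategoryCatalog}}, \code{\link{catalogRollup}}
#' @aliases CategoryCatalog-class
#' @exportClass CategoryCatalog
setClass("CategoryCatalog", representation(table = "data.frame"))

setValidity("CategoryCatalog", function(object) {
  tab <- object@table
  need <- c("code", "name", "level", "parent_code")
  if (!all(need %in% colnames(tab)))
    return(paste("catalog must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(tab$code))
    msg <- c(msg, "category codes must be unique")
  if (any(tab$level < 1L) || any(tab$level > 8L))
    msg <- c(msg, "levels must lie in 1..8")
  hasParent <- !is.na(tab$parent_code) & nzchar(tab$parent_code)
  orphan <- hasParent & !(tab$parent_code %in% tab$code)
  if (any(orphan))
    msg <- c(msg, "every parent_code must exist in the catalog")
  if (any(!hasParent & tab$level != 1L))
    msg <- c(msg, "root categories (no parent) must have level 1")
  chk <- hasParent & !orphan
  if (any(chk)) {
    plev <- tab$level[match(tab$parent_code[chk], tab$code)]
    if (any(tab$level[chk] != plev + 1L))
      msg <- c(msg, "a category's level must equal its parent's level + 1")
  }
  if (length(msg)) msg else TRUE
})

#' SimulatedGenePair: a synthetic assembly pair with ground truth
#'
#' The output of \code{\link{simulateAssemblyPair}}: two \code{GeneSet}
#' versions derived from a common ancestral gene complement by planted edit
#' events, the cross-species protein-evidence set, and the event log /
#' truth map that makes every downstream classification scoreable.
#'
#' @slot genesA,genesB the two simulated versions.
#' @slot ancestral DNAStringSet of ancestral gene sequences (named by anc_id).
#' @slot proteins DNAStringSet of emitted evidence sequences (named by
#'   protein id).
#' @slot proteinFlags named logical; TRUE means "existence demonstrated at the
#'   protein level".
#' @slot events data.frame of planted edit events (event_id, type, anc_ids,
#'   params).
#' @slot truth data.frame mapping each ancestral gene to its emitted ids in A
#'   and B and its planted event.
#' @slot config the resolved simulation configuration (list).
#' @slot seed the seed used.
#'
#' @seealso \code{\link{simulateAssemblyPair}}, \code{\link{scoreRecovery}}
#' @aliases SimulatedGenePair-class
#' @exportClass SimulatedGenePair
setClass("SimulatedGenePair",
  representation(
    genesA = "GeneSet",
    genesB = "GeneSet",
    ancestral = "DNAStringSet",
    proteins = "DNAStringSet",
    proteinFlags = "logical",
    events = "data.frame",
    truth = "data.frame",
    config = "list",
    seed = "integer"
  )
)
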