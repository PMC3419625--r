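#' Derive placement status from chromosome names
#'
#' @param chrom character vector of chromosome names.
#' @param unknownChrom label of the unknown chromosome.
#' @param randomSuffix suffix marking random chromosomes.
#' @return character vector, one of \code{"placed"}, \code{"random"},
#'   \code{"unknown"}.
#' @examples
#' placementFromChrom(c("chr1", "chrUn", "chr16_random"))
#' @export
placementFromChrom <- function(chrom, unknownChrom = "chrUn",
                               randomSuffix = "_random") {
  out <- rep("placed", length(chrom))
  out[chrom == unknownChrom] <- "unknown"
  out[endsWith(chrom, randomSuffix) & chrom != unknownChrom] <- "random"
  out
}

#' Construct a GeneSet
#'
#' @param chromosome,start,end,strand,gene_id per-gene vectors (recycled by
#'   \code{GRanges} rules are not allowed; all must have equal length).
#' @param track per-gene track, \code{"main"} or \code{"repeat"}.
#' @param versionLabel single character naming the assembly version.
#' @param sequences optional \code{DNAStringSet} (or named character vector)
#'   keyed by \code{gene_id}.
#' @param unknownChrom,randomSuffix naming conventions for unplaced
#'   pseudo-chromosomes (see \linkS4class{GeneSet}).
#' @return a validated \linkS4class{GeneSet}.
#' @examples
#' gs <- GeneSet(chromosome = c("chr1", "chrUn"), start = c(100, 1),
#'               end = c(250, 400), strand = c("+", "+"),
#'               gene_id = c("g1", "g2"), versionLabel = "A")
#' placement(gs)
#' @export
GeneSet <- function(chromosome, start, end, strand, gene_id,
                    track = "main", versionLabel = "A", sequences = NULL,
                    unknownChrom = "chrUn", randomSuffix = "_random") {
  n <- length(gene_id)
  stopifnot(length(chromosome) == n, length(start) == n, length(end) == n,
            length(strand) == n)
  if (length(track) == 1L) track <- rep(track, n)
  if (n && any(end < start))
    stop("gene end must be >= start")
  if (n && any(start < 1))
    stop("gene start must be >= 1")
  gr <- GenomicRanges::GRanges(
    seqnames = chromosome,
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)),
    strand = strand
  )
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  S4Vectors::mcols(gr)$placement <-
    placementFromChrom(as.character(chromosome), unknownChrom, randomSuffix)
  S4Vectors::mcols(gr)$track <- as.character(track)
  if (is.null(sequences)) {
    seqs <- Biostrings::DNAStringSet()
  } else if (is.character(sequences)) {
    seqs <- Biostrings::DNAStringSet(sequences)
  } else {
    seqs <- sequences
  }
  new("GeneSet", genes = gr, versionLabel = versionLabel, sequences = seqs,
      unknownChrom = unknownChrom, randomSuffix = randomSuffix)
}

#' @rdname GeneSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname GeneSet-accessors
#' @export
setGeneric("versionLabel", function(x) standardGeneric("versionLabel"))
#' @rdname GeneSet-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname GeneSet-accessors
#' @export
setGeneric("geneSequences", function(x) standardGeneric("geneSequences"))
#' @rdname GeneSet-accessors
#' @export
setGeneric("placement", function(x) standardGeneric("placement"))
#' @rdname GeneSet-accessors
#' @export
setGeneric("track", function(x) standardGeneric("track"))

#' Accessors for GeneSet objects
#'
#' \code{geneIds} returns the gene identifiers; \code{versionLabel} the
#' assembly version label; \code{geneRanges} the underlying \code{GRanges};
#' \code{geneSequences} the \code{DNAStringSet}; \code{placement} and
#' \code{track} the per-gene status vectors (named by gene id).
#'
#' @param x a \linkS4class{GeneSet}.
#' @name GeneSet-accessors
#' @aliases geneIds versionLabel geneRanges geneSequences placement track
NULL

#' @rdname GeneSet-accessors
setMethod("geneIds", "GeneSet", function(x)
  S4Vectors::mcols(x@genes)$gene_id)

#' @rdname GeneSet-accessors
setMethod("versionLabel", "GeneSet", function(x) x@versionLabel)

#' @rdname GeneSet-accessors
setMethod("geneRanges", "GeneSet", function(x) x@genes)

#' @rdname GeneSet-accessors
setMethod("geneSequences", "GeneSet", function(x) x@sequences)

#' @rdname GeneSet-accessors
setMethod("placement", "GeneSet", function(x) {
  out <- S4Vectors::mcols(x@genes)$placement
  names(out) <- geneIds(x)
  out
})

#' @rdname GeneSet-accessors
setMethod("track", "GeneSet", function(x) {
  out <- S4Vectors::mcols(x@genes)$track
  names(out) <- geneIds(x)
  out
})

setMethod("length", "GeneSet", function(x) length(x@genes))

setMethod("show", "GeneSet", function(object) {
  tr <- S4Vectors::mcols(object@genes)$track
  cat("GeneSet, version '", object@versionLabel, "': ",
      length(object@genes), " genes (",
      sum(tr == "repeat"), " on repeat track) on ",
      length(unique(as.character(GenomicRanges::seqnames(object@genes)))),
      " chromosome(s); ",
      length(object@sequences), " sequences attached\n", sep = "")
})

#' Gene table of a GeneSet as a data.frame
#'
#' Flat per-gene table (one row per gene) used by the writers and by
#' positional normalisation.
#'
#' @param x a \linkS4class{GeneSet}.
#' @return data.frame with columns chromosome, start, end, strand, gene_id,
#'   placement, track.
#' @export
geneTable <- function(x) {
  stopifnot(is(x, "GeneSet"))
  gr <- x@genes
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = S4Vectors::mcols(gr)$gene_id,
    placement = S4Vectors::mcols(gr)$placement,
    track = S4Vectors::mcols(gr)$track,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "MatchGraph", function(object) {
  cat("MatchGraph ", object@versionA, " <-> ", object@versionB, ": ",
      length(object@nodesA), " + ", length(object@nodesB), " genes, ",
      nrow(object@edges), " merged edges\n", sep = "")
})

#' @rdname matchEdges
#' @export
setGeneric("matchEdges", function(x) standardGeneric("matchEdges"))

#' Edge table of a MatchGraph
#'
#' @param x a \linkS4class{MatchGraph}.
#' @return the edge data.frame (see \linkS4class{MatchGraph}).
#' @name matchEdges
#' @export
setMethod("matchEdges", "MatchGraph", function(x) x@edges)

setMethod("show", "CategoryCatalog", function(object) {
  cat("CategoryCatalog: ", nrow(object@table), " categories, levels 1..",
      max(object@table$level), "\n", sep = "")
})

#' @rdname catalogTable
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' Table of a CategoryCatalog
#'
#' @param x a \linkS4class{CategoryCatalog}.
#' @return the catalog data.frame.
#' @name catalogTable
#' @export
setMethod("catalogTable", "CategoryCatalog", function(x) x@table)

setMethod("show", "SimulatedGenePair", function(object) {
  cat("SimulatedGenePair (seed ", object@seed, "): ",
      length(object@ancestral), " ancestral genes -> ",
      length(object@genesA), " in version '", versionLabel(object@genesA),
      "', ", length(object@genesB), " in version '",
      versionLabel(object@genesB), "'; ",
      nrow(object@events), " planted events; ",
      length(object@proteins), " evidence sequences\n", sep = "")
})

#' Accessors for SimulatedGenePair
#'
#' @param x a \linkS4class{SimulatedGenePair}.
#' @return \code{simGenesA}/\code{simGenesB}: the two \code{GeneSet}s;
#'   \code{simEvents}: the planted-event data.frame; \code{simTruth}: the
#'   ancestral-to-emitted truth map; \code{simProteins}: the evidence
#'   \code{DNAStringSet}; \code{simProteinFlags}: named logical protein-level
#'   evidence flags.
#' @name SimulatedGenePair-accessors
#' @export
simGenesA <- function(x) x@genesA
#' @rdname SimulatedGenePair-accessors
#' @export
simGenesB <- function(x) x@genesB
#' @rdname SimulatedGenePair-accessors
#' @export
simEvents <- function(x) x@events
#' @rdname SimulatedGenePair-accessors
#' @export
simTruth <- function(x) x@truth
#' @rdname SimulatedGenePair-accessors
#' @export
simProteins <- function(x) x@proteins
#' @rdname SimulatedGenePair-accessors
#' @export
simProteinFlags <- function(x) x@proteinFlags
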