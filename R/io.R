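#' Read a gene table (GFF3 or 6/7-column TSV) into a GeneSet
#'
#' Two dialects are accepted. Files ending in \code{.gff} or \code{.gff3} are
#' read with \pkg{rtracklayer}; rows of type \code{gene} become gene models,
#' the \code{ID} attribute is the gene id and, when present, a \code{track}
#' attribute of \code{"repeat"} puts the gene on the repeat track. Any other
#' file is read as a headerless tab-separated table with columns
#' chromosome, type, start, end, strand, gene_id and an optional seventh
#' column track (\code{main}/\code{repeat}).
#'
#' Malformed coordinates (non-numeric, start < 1, end < start) and duplicate
#' gene ids within the version are rejected with the offending row number;
#' nothing is silently coerced.
#'
#' @param path file to read.
#' @param versionLabel assembly version label to record.
#' @param unknownChrom,randomSuffix placement naming conventions
#'   (see \linkS4class{GeneSet}).
#' @param sequences optional \code{DNAStringSet} named by gene id (e.g. from
#'   \code{\link[Biostrings]{readDNAStringSet}}).
#' @return a \linkS4class{GeneSet}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("chr1\tgene\t100\t250\t+\tgeneA1", tf)
#' readGeneTable(tf, versionLabel = "A")
#' @export
readGeneTable <- function(path, versionLabel,
                          unknownChrom = "chrUn", randomSuffix = "_random",
                          sequences = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    if ("type" %in% colnames(S4Vectors::mcols(gr)))
      gr <- gr[as.character(S4Vectors::mcols(gr)$type) == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) stop("GFF3 gene rows must carry an ID attribute")
    trk <- S4Vectors::mcols(gr)$track
    if (is.null(trk)) trk <- rep("main", length(gr))
    trk[is.na(trk)] <- "main"
    df <- data.frame(
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = as.character(ids), track = as.character(trk),
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             colClasses = "character",
                             quote = "", comment.char = "#")
    if (ncol(raw) < 6L)
      stop("gene table must have at least 6 tab-separated columns")
    start <- suppressWarnings(as.numeric(raw[[3]]))
    end <- suppressWarnings(as.numeric(raw[[4]]))
    bad <- which(is.na(start) | is.na(end) | start < 1 | end < start)
    if (length(bad))
      stop("malformed coordinates at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    trk <- if (ncol(raw) >= 7L) raw[[7]] else rep("main", nrow(raw))
    trk[is.na(trk) | !nzchar(trk)] <- "main"
    df <- data.frame(chromosome = raw[[1]], start = start, end = end,
                     strand = raw[[5]], gene_id = raw[[6]], track = trk,
                     stringsAsFactors = FALSE)
  }
  dup <- which(duplicated(df$gene_id))
  if (length(dup))
    stop("duplicate gene_id within version at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  GeneSet(chromosome = df$chromosome, start = df$start, end = df$end,
          strand = df$strand, gene_id = df$gene_id, track = df$track,
          versionLabel = versionLabel, sequences = sequences,
          unknownChrom = unknownChrom, randomSuffix = randomSuffix)
}

#' Write a GeneSet to disk
#'
#' Writes GFF3 through \pkg{rtracklayer} when \code{path} ends in
#' \code{.gff}/\code{.gff3} (gene rows with \code{ID} and \code{track}
#' attributes), otherwise the 7-column TSV dialect of
#' \code{\link{readGeneTable}}. Reading the written file back reproduces the
#' gene table field for field.
#'
#' @param x a \linkS4class{GeneSet}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGeneTable <- function(x, path) {
  stopifnot(is(x, "GeneSet"))
  df <- geneTable(x)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- x@genes
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = rep("gene", length(gr)),
      ID = S4Vectors::mcols(gr)$gene_id,
      track = S4Vectors::mcols(gr)$track)
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    out <- data.frame(df$chromosome, "gene", df$start, df$end, df$strand,
                      df$gene_id, df$track)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

.hitCols <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "e_value", "bit_score")

#' Read 12-column tabular alignment hits
#'
#' Parses the standard 12-column tab-separated alignment format (query,
#' subject, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score). Rows are returned
#' unfiltered; \code{s_start > s_end} is preserved as minus-strand evidence.
#'
#' @param path file to read (an empty file yields a zero-row table).
#' @return data.frame with the canonical hit columns.
#' @examples
#' tf <- tempfile()
#' writeLines("g1\th1\t97.1\t500\t10\t2\t1\t500\t1\t498\t1e-50\t800", tf)
#' readTabularHits(tf)
#' @export
readTabularHits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(emptyHits())
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character",
                           quote = "", comment.char = "#")
  if (ncol(raw) != 12L)
    stop("expected 12 tab-separated columns, found ", ncol(raw))
  num <- lapply(raw[3:12], function(col) suppressWarnings(as.numeric(col)))
  badrows <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(badrows))
    stop("non-numeric value at row(s): ",
         paste(utils::head(badrows, 5), collapse = ", "))
  hits <- data.frame(raw[[1]], raw[[2]], num, stringsAsFactors = FALSE)
  names(hits) <- .hitCols
  bad <- which(hits$pct_identity < 0 | hits$pct_identity > 100 |
               hits$aln_length < 1 | hits$e_value < 0 |
               hits$q_start > hits$q_end)
  if (length(bad))
    stop("out-of-range hit values at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  hits
}

#' Write tabular alignment hits
#'
#' @param hits data.frame with the canonical 12 hit columns.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTabularHits <- function(hits, path) {
  stopifnot(all(.hitCols %in% colnames(hits)))
  utils::write.table(format(hits[, .hitCols], trim = TRUE, scientific = 10,
                            digits = 12),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

emptyHits <- function() {
  out <- data.frame(query_id = character(), subject_id = character(),
                    pct_identity = numeric(), aln_length = numeric(),
                    mismatches = numeric(), gap_opens = numeric(),
                    q_start = numeric(), q_end = numeric(),
                    s_start = numeric(), s_end = numeric(),
                    e_value = numeric(), bit_score = numeric(),
                    stringsAsFactors = FALSE)
  out
}

.corrFixed <- c("unique_id", "cardinality_comment", "track",
                "functional_annotation", "categories", "needs_review")

#' Write / read the correspondence table
#'
#' The correspondence table is the flat deliverable of the reconciliation:
#' one row per unified gene with its id in every source
#' (\code{id_in_<source>} columns), its chromosome position per source
#' (\code{chromosome_position_<source>}, formatted
#' \code{chromosome_start_end}), the cardinality comment (\code{OK} for a
#' one-to-one relationship, \code{XX} for no match, etc.), track, functional
#' annotation, semicolon-joined category codes and a re-review flag. The
#' writer and reader round-trip field for field.
#'
#' @param records data.frame with at least the fixed columns
#'   \code{unique_id}, \code{cardinality_comment}, \code{track},
#'   \code{functional_annotation}, \code{categories}, \code{needs_review},
#'   plus any \code{id_in_*} / \code{chromosome_position_*} columns.
#' @param path file to write to / read from.
#' @return \code{writeCorrespondenceTable}: invisibly, \code{path};
#'   \code{readCorrespondenceTable}: the records data.frame.
#' @export
writeCorrespondenceTable <- function(records, path) {
  miss <- setdiff(.corrFixed, colnames(records))
  if (length(miss))
    stop("records lack required column(s): ", paste(miss, collapse = ", "))
  idcols <- grep("^(id_in_|chromosome_position_)", colnames(records),
                 value = TRUE)
  out <- records[, c("unique_id", idcols,
                     setdiff(.corrFixed, "unique_id"))]
  out$needs_review <- ifelse(out$needs_review, "yes", "no")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeCorrespondenceTable
#' @param maxCategories maximum number of categories tolerated per gene
#'   (default 7); a row with more is rejected, not truncated.
#' @export
readCorrespondenceTable <- function(path, maxCategories = 7L) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  miss <- setdiff(.corrFixed, colnames(out))
  if (length(miss))
    stop("correspondence table lacks column(s): ",
         paste(miss, collapse = ", "))
  out$needs_review <- out$needs_review == "yes"
  ncat <- vapply(strsplit(out$categories, ";", fixed = TRUE),
                 function(x) sum(nzchar(x)), integer(1))
  if (any(ncat > maxCategories))
    stop("more than ", maxCategories, " categories at row(s): ",
         paste(utils::head(which(ncat > maxCategories), 5), collapse = ", "))
  out
}

#' Read a functional-category catalog
#'
#' The catalog TSV mirrors the published schema: columns
#' \code{category_name}, \code{code}, \code{level}, \code{go_name},
#' \code{go_id}, \code{network}, \code{mips_name}, \code{mips_code},
#' \code{n_genes}. The parent of a category is derived from its dotted code
#' (dropping the last segment) unless a \code{parent_code} column is given.
#' Levels beyond 8, duplicate codes, orphan parents and level gaps are
#' rejected by the class validity check.
#'
#' @param path TSV file with a header row.
#' @return a \linkS4class{CategoryCatalog}.
#' @examples
#' cat <- readCategoryCatalog(system.file("extdata",
#'   "synthetic_catalog.tsv", package = "geneRecon"))
#' cat
#' @export
readCategoryCatalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  need <- c("category_name", "code", "level")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  grab <- function(col) if (col %in% colnames(raw)) raw[[col]] else
    rep(NA_character_, nrow(raw))
  parent <- grab("parent_code")
  if (all(is.na(parent))) {
    parent <- vapply(strsplit(raw$code, ".", fixed = TRUE), function(p) {
      if (length(p) <= 1L) NA_character_ else
        paste(p[-length(p)], collapse = ".")
    }, character(1))
  }
  tab <- data.frame(
    code = raw$code, name = raw$category_name,
    level = as.integer(raw$level),
    go_id = grab("go_id"), go_name = grab("go_name"),
    mips_code = grab("mips_code"), mips_name = grab("mips_name"),
    network = grab("network"), parent_code = parent,
    n_genes = suppressWarnings(as.integer(grab("n_genes"))),
    stringsAsFactors = FALSE)
  if (anyNA(tab$level))
    stop("non-integer level at row(s): ",
         paste(utils::head(which(is.na(tab$level)), 5), collapse = ", "))
  new("CategoryCatalog", table = tab)
}

#' @rdname readCategoryCatalog
#' @param catalog a \linkS4class{CategoryCatalog} to write.
#' @export
writeCategoryCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "CategoryCatalog"))
  tab <- catalogTable(catalog)
  out <- data.frame(category_name = tab$name, code = tab$code,
                    level = tab$level, go_name = tab$go_name,
                    go_id = tab$go_id, network = tab$network,
                    mips_name = tab$mips_name, mips_code = tab$mips_code,
                    n_genes = tab$n_genes, parent_code = tab$parent_code)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
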