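#' Build the unified non-redundant gene set across sources
#'
#' Constructs one correspondence record per equivalence group of genes
#' across two or more sources (assembly-version predictions, transcript
#' sets, ...). Groups are seeded by the genes of the highest-priority
#' source; genes of every further source join the group of any gene they
#' were matched to, and the genes of each successive source that were not
#' identified in any higher-priority source are appended as new records.
#' The unique id of a record is the id from the highest-priority source
#' present in the group.
#'
#' @param geneSets named list of \linkS4class{GeneSet}s, one per source.
#' @param crossMatches data.frame of equivalence links with columns
#'   \code{source_a}, \code{id_a}, \code{source_b}, \code{id_b} (typically
#'   the one-to-one pairs between the top-priority source and each other
#'   source); may have zero rows.
#' @param priority character vector of source names, highest priority first
#'   (must name every element of \code{geneSets}, no duplicates).
#' @param splitProposals optional \code{\link{proposeSplits}} result whose
#'   new suffixed gene records are appended.
#' @return data.frame with one row per unified gene: \code{unique_id},
#'   \code{source_rank}, one \code{id_in_<source>} and one
#'   \code{chromosome_position_<source>} column per source (comma-joined
#'   when a group holds several genes of one source; positions formatted
#'   \code{chromosome_start_end}), plus empty \code{cardinality_comment},
#'   \code{track}, \code{functional_annotation}, \code{categories} and
#'   \code{needs_review} columns ready for
#'   \code{\link{transferAnnotation}} and
#'   \code{\link{writeCorrespondenceTable}}.
#' @export
unifyGeneSets <- function(geneSets, crossMatches = NULL, priority,
                          splitProposals = NULL) {
  stopifnot(is.list(geneSets), length(geneSets) >= 1L)
  if (anyDuplicated(priority)) stop("duplicate sources in priority order")
  if (!setequal(priority, names(geneSets)))
    stop("priority must name exactly the sources of geneSets")
  geneSets <- geneSets[priority]

  key <- function(src, id) paste(src, id, sep = "\r")
  allKeys <- unlist(lapply(priority, function(src)
    key(src, geneIds(geneSets[[src]]))), use.names = FALSE)
  parent <- stats::setNames(seq_along(allKeys), allKeys)
  findRoot <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (!is.null(crossMatches) && nrow(crossMatches)) {
    need <- c("source_a", "id_a", "source_b", "id_b")
    stopifnot(all(need %in% colnames(crossMatches)))
    ka <- key(crossMatches$source_a, crossMatches$id_a)
    kb <- key(crossMatches$source_b, crossMatches$id_b)
    unknown <- setdiff(c(ka, kb), allKeys)
    if (length(unknown))
      stop("crossMatches reference unknown gene(s): ",
           paste(sub("\r", ":", utils::head(unknown, 5)), collapse = ", "))
    for (i in seq_along(ka)) {
      ra <- findRoot(match(ka[i], allKeys))
      rb <- findRoot(match(kb[i], allKeys))
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_along(allKeys), findRoot, integer(1))
  groups <- split(seq_along(allKeys), root)

  srcOf <- sub("\r.*", "", allKeys)
  idOf <- sub(".*\r", "", allKeys)
  posTables <- lapply(geneSets, geneTable)
  posOf <- function(src, ids) {
    tab <- posTables[[src]]
    i <- match(ids, tab$gene_id)
    paste0(tab$chromosome[i], "_", tab$start[i], "_", tab$end[i])
  }
  trackTables <- lapply(geneSets, track)

  rows <- lapply(groups, function(ix) {
    srcs <- srcOf[ix]; ids <- idOf[ix]
    rank <- min(match(srcs, priority))
    topSrc <- priority[rank]
    uid <- sort(ids[srcs == topSrc])[1]
    rec <- list(unique_id = uid, source_rank = rank)
    for (src in priority) {
      sel <- sort(ids[srcs == src])
      rec[[paste0("id_in_", src)]] <- paste(sel, collapse = ",")
      rec[[paste0("chromosome_position_", src)]] <-
        paste(posOf(src, sel), collapse = ",")
    }
    trk <- unlist(lapply(priority, function(src)
      trackTables[[src]][ids[srcs == src]]))
    rec$track <- if (any(trk == "repeat")) "repeat" else "main"
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  records$cardinality_comment <- ""
  records$functional_annotation <- ""
  records$categories <- ""
  records$needs_review <- FALSE

  if (!is.null(splitProposals)) {
    stopifnot(inherits(splitProposals, "splitProposals"))
    pp <- splitProposals$proposals
    pp <- pp[pp$part_index > 1L, , drop = FALSE]
    if (nrow(pp)) {
      newRec <- records[rep(NA_integer_, nrow(pp)), , drop = FALSE]
      newRec[] <- lapply(newRec, function(col)
        if (is.character(col)) "" else if (is.logical(col)) TRUE else NA)
      newRec$unique_id <- pp$new_id
      newRec$source_rank <- 1L
      newRec$track <- "main"
      newRec$cardinality_comment <- "To split (new)"
      newRec$needs_review <- TRUE
      records <- rbind(records, newRec)
    }
  }
  ord <- order(records$source_rank, records$unique_id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Set-overlap membership counts (Venn regions)
#'
#' Counts the unified records falling in every non-empty membership
#' signature across the sources (which \code{id_in_<source>} columns are
#' non-empty). The signature counts always sum to the number of records.
#'
#' @param records output of \code{\link{unifyGeneSets}}.
#' @return named integer vector; names are \code{"+"}-joined source subsets.
#' @export
vennMembership <- function(records) {
  idcols <- grep("^id_in_", colnames(records), value = TRUE)
  if (!length(idcols)) stop("records carry no id_in_* columns")
  sources <- sub("^id_in_", "", idcols)
  present <- sapply(idcols, function(cn) nzchar(records[[cn]]))
  if (is.null(dim(present))) present <- matrix(present, nrow = 1L)
  sig <- apply(present, 1L, function(p)
    paste(sources[p], collapse = "+"))
  out <- table(sig)
  stats::setNames(as.integer(out), names(out))
}

#' Transfer prior functional annotation across the correspondence
#'
#' Copies the functional annotation attached to the prior (older-version)
#' gene ids onto the unified records. Records whose cardinality call is a
#' clean one-to-one (\code{OK}, \code{OK_split}) inherit the annotation
#' as-is; any gene presenting cardinality issues (redundant, overlap,
#' split, merged, to-split, multiple, unresolved, low score) keeps the
#' prior annotation only provisionally and is flagged for independent
#' re-review; unmatched genes are flagged with an empty annotation.
#'
#' @param records output of \code{\link{unifyGeneSets}}.
#' @param priorAnnotations named character vector: prior gene id ->
#'   annotation text.
#' @param calls output of \code{\link{classifyCardinality}}.
#' @param priorSource name of the source whose ids key
#'   \code{priorAnnotations} (its \code{id_in_<priorSource>} column is used).
#' @param newSource name of the source whose genes the calls describe on the
#'   newer side; defaults to the version label found in \code{calls} that is
#'   not \code{priorSource}.
#' @return \code{records} with \code{functional_annotation},
#'   \code{cardinality_comment} and \code{needs_review} filled in.
#' @export
transferAnnotation <- function(records, priorAnnotations, calls,
                               priorSource, newSource = NULL) {
  okCalls <- c("OK", "OK_split")
  if (is.null(newSource)) {
    vs <- setdiff(unique(calls$version), priorSource)
    newSource <- vs[1]
  }
  callOf <- stats::setNames(calls$call, paste(calls$version, calls$gene_id))
  idPrior <- records[[paste0("id_in_", priorSource)]]
  idNew <- records[[paste0("id_in_", newSource)]]
  if (is.null(idPrior) || is.null(idNew))
    stop("records lack id_in_ columns for the requested sources")
  for (r in seq_len(nrow(records))) {
    newIds <- strsplit(idNew[r], ",", fixed = TRUE)[[1]]
    priorIds <- strsplit(idPrior[r], ",", fixed = TRUE)[[1]]
    thisCalls <- callOf[paste(newSource, newIds)]
    thisCalls <- thisCalls[!is.na(thisCalls)]
    call <- if (length(thisCalls)) {
      # the most problematic call in the group wins
      bad <- setdiff(thisCalls, okCalls)
      if (length(bad)) bad[1] else thisCalls[1]
    } else if (!length(newIds)) {
      NA_character_          # gene absent from the newer source
    } else {
      "unmatched"
    }
    ann <- ""
    if (length(priorIds)) {
      hit <- priorAnnotations[priorIds]
      hit <- hit[!is.na(hit)]
      if (length(hit)) ann <- hit[1]
    }
    if (!is.na(call) && call %in% okCalls) {
      records$functional_annotation[r] <- ann
      records$needs_review[r] <- FALSE
      records$cardinality_comment[r] <-
        if (call == "OK") "OK" else "OK (Split)"
    } else if (!is.na(call) && call == "unmatched") {
      records$functional_annotation[r] <- ""
      records$needs_review[r] <- TRUE
      records$cardinality_comment[r] <- "XX"
    } else {
      records$functional_annotation[r] <- ann    # provisional
      records$needs_review[r] <- TRUE
      if (!is.na(call))
        records$cardinality_comment[r] <- switch(call,
          low_score = "Ls", to_split = "To split",
          redundant = "redundant", overlap = "Overlap",
          split = "Split", merged = "merge", multiple = "multiple",
          unresolved = "unresolved", call)
    }
  }
  records
}

#' Classify genes into the four functional-assignment groups
#'
#' Based on each gene's best protein hit against other species, genes fall
#' into four mutually exclusive, exhaustive groups: matching a sequence of
#' known function; matching a sequence of unknown function; matching viral
#' or transposable elements or related sequences; or matching nothing.
#'
#' @param records output of \code{\link{unifyGeneSets}}.
#' @param bestHits named character vector: unique_id -> description of the
#'   best protein hit; genes absent from it (or with NA) have no hit.
#' @param teKeywords keywords marking viral/transposable-element hits
#'   (matched case-insensitively against the description).
#' @param unknownKeywords keywords marking uncharacterized hits.
#' @return \code{records} with an added \code{four_group} column, one of
#'   \code{known_function}, \code{unknown_function}, \code{viral_te},
#'   \code{no_hit}.
#' @export
assignFourGroup <- function(records, bestHits,
                            teKeywords = c("transposon", "retrotransposon",
                                           "transposase", "gag", "pol",
                                           "polyprotein", "integrase",
                                           "reverse transcriptase",
                                           "viral", "virus"),
                            unknownKeywords = c("unknown", "uncharacterized",
                                                "hypothetical",
                                                "unnamed")) {
  desc <- bestHits[records$unique_id]
  grp <- rep("no_hit", nrow(records))
  has <- !is.na(desc) & nzchar(desc)
  matchAny <- function(x, kw) {
    hit <- rep(FALSE, length(x))
    for (k in kw)
      hit <- hit | grepl(k, x, ignore.case = TRUE, fixed = FALSE)
    hit
  }
  te <- has & matchAny(desc, paste0("\\b", teKeywords, "\\b"))
  unk <- has & !te & matchAny(desc, unknownKeywords)
  grp[has] <- "known_function"
  grp[unk] <- "unknown_function"
  grp[te] <- "viral_te"
  records$four_group <- grp
  records
}

#' Roll gene category assignments up the catalog hierarchy
#'
#' Validates each gene's category codes against the catalog (unknown codes
#' and more than \code{maxCategories} codes per gene are rejected), then
#' counts genes per category at every level, propagating each assignment to
#' all its ancestors. A gene counts once per distinct ancestor: two assigned
#' categories sharing a root contribute a single count at that root.
#'
#' @param records output of \code{\link{unifyGeneSets}} (the
#'   \code{categories} column holds semicolon-joined codes).
#' @param catalog a \linkS4class{CategoryCatalog}.
#' @param maxCategories maximum categories per gene (default 7).
#' @return a list: \code{counts} (data.frame code, name, level, n_genes),
#'   \code{topLevel} (the level-1 rows of \code{counts}),
#'   \code{nMultiCategory} (genes assigned to two or more distinct
#'   categories) and \code{nAssigned} (genes with at least one category).
#' @export
catalogRollup <- function(records, catalog, maxCategories = 7L) {
  stopifnot(is(catalog, "CategoryCatalog"))
  tab <- catalogTable(catalog)
  parent <- stats::setNames(tab$parent_code, tab$code)
  ancestorsOf <- function(code) {
    out <- code
    while (!is.na(parent[[code]]) && nzchar(parent[[code]])) {
      code <- parent[[code]]
      out <- c(out, code)
    }
    out
  }
  ancCache <- lapply(stats::setNames(tab$code, tab$code), ancestorsOf)

  rawAssigned <- strsplit(records$categories, ";", fixed = TRUE)
  rawAssigned <- lapply(rawAssigned, function(x) x[nzchar(x)])
  assigned <- lapply(rawAssigned, unique)
  ncat <- lengths(assigned)
  if (any(lengths(rawAssigned) > maxCategories))
    stop("more than ", maxCategories, " categories for record(s): ",
         paste(utils::head(
           records$unique_id[lengths(rawAssigned) > maxCategories], 5),
           collapse = ", "))
  unknown <- setdiff(unlist(assigned), tab$code)
  if (length(unknown))
    stop("category code(s) absent from catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  geneAnc <- lapply(assigned, function(codes)
    unique(unlist(ancCache[codes], use.names = FALSE)))
  counts <- table(unlist(geneAnc, use.names = FALSE))
  out <- data.frame(code = tab$code, name = tab$name, level = tab$level,
                    n_genes = as.integer(counts[tab$code]),
                    stringsAsFactors = FALSE)
  out$n_genes[is.na(out$n_genes)] <- 0L
  list(counts = out,
       topLevel = out[out$level == 1L, , drop = FALSE],
       nMultiCategory = sum(ncat >= 2L),
       nAssigned = sum(ncat >= 1L))
}
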