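## Internal small-scale nucleotide aligner.
##
## Exact k-mer seeds select (query, subject, strand, diagonal) candidates;
## each candidate diagonal is then scanned for its maximal-scoring ungapped
## segment (reward/penalty scoring, equivalent to an X-drop extension run to
## optimality on that diagonal). The e-value is a Karlin-Altschul-style
## surrogate computed from fixed (lambda, K) parameters -- it is not a
## Megablast statistic, only a comparable stringency scale.

.alnDefaults <- list(k = 16L, stride = 8L, minScore = 40,
                     reward = 1, penalty = -2,
                     lambda = 1.28, kParam = 0.46, maxKmerOcc = 16L)

# maximal-scoring contiguous segment of a logical match vector
# (Kadane on reward/penalty scores); returns c(start, end, score, matches)
maxSegment <- function(m, reward, penalty) {
  x <- ifelse(m, reward, penalty)
  cs <- cumsum(x)
  prefix <- c(0, cs[-length(cs)])
  pm <- cummin(prefix)
  gain <- cs - pm
  j <- which.max(gain)
  i <- which.max(prefix[seq_len(j)] == pm[j])
  c(i, j, gain[j], sum(m[i:j]))
}

.asCharSeqs <- function(x, what) {
  if (is(x, "XStringSet")) x <- as.character(x)
  if (is(x, "XString")) x <- as.character(x)
  if (!is.character(x)) stop(what, " must be character or (DNA)StringSet")
  if (is.null(names(x)) && length(x) > 1L)
    stop(what, " sequences must be named")
  if (is.null(names(x))) names(x) <- what
  toupper(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.kmerTable <- function(seqs, k, stride = 1L) {
  rows <- lapply(names(seqs), function(id) {
    L <- nchar(seqs[[id]])
    if (L < k) return(NULL)
    pos <- seq.int(1L, L - k + 1L, by = stride)
    if (pos[length(pos)] != L - k + 1L) pos <- c(pos, L - k + 1L)
    data.table::data.table(kmer = substring(seqs[[id]], pos, pos + k - 1L),
                           id = id, pos = pos)
  })
  data.table::rbindlist(rows)
}

#' Align two sequence sets with the internal seed-and-extend aligner
#'
#' Workhorse behind \code{\link{alignSmall}} and the hit-free entry of
#' \code{\link{reconcilePair}}. Finds local ungapped alignments between every
#' query and subject sequence that share an exact k-mer, on both strands.
#' Intended for desk-scale gene complements; supply externally computed
#' tabular hits for anything larger.
#'
#' @param query,subject named character vectors or
#'   \code{\link[Biostrings]{DNAStringSet}}s.
#' @param k seed length (exact match).
#' @param stride sampling stride of query seed positions.
#' @param minScore minimum raw segment score to report.
#' @param reward,penalty match reward and mismatch penalty.
#' @param lambda,kParam fixed Karlin-Altschul-style parameters of the
#'   bit-score / e-value surrogate.
#' @param maxKmerOcc seeds occurring more often than this in the subject
#'   index are dropped (low-complexity guard).
#' @return data.frame of hits in the canonical 12-column layout
#'   (see \code{\link{readTabularHits}}); minus-strand hits have
#'   \code{s_start > s_end}.
#' @export
alignSets <- function(query, subject,
                      k = .alnDefaults$k, stride = .alnDefaults$stride,
                      minScore = .alnDefaults$minScore,
                      reward = .alnDefaults$reward,
                      penalty = .alnDefaults$penalty,
                      lambda = .alnDefaults$lambda,
                      kParam = .alnDefaults$kParam,
                      maxKmerOcc = .alnDefaults$maxKmerOcc) {
  qs <- .asCharSeqs(query, "query")
  ss <- .asCharSeqs(subject, "subject")
  if (!length(qs) || !length(ss)) return(emptyHits())
  dbLen <- sum(as.numeric(nchar(ss)))

  idxPlus <- .kmerTable(ss, k)
  idxMinus <- .kmerTable(stats::setNames(.revcomp(ss), names(ss)), k)
  idxPlus[, strand := "+"]
  idxMinus[, strand := "-"]
  idx <- data.table::rbindlist(list(idxPlus, idxMinus))
  if (!nrow(idx)) return(emptyHits())
  idx <- idx[, n := .N, by = kmer][n <= maxKmerOcc][, n := NULL]
  data.table::setkey(idx, kmer)

  qk <- .kmerTable(qs, k, stride = stride)
  if (!nrow(qk)) return(emptyHits())
  data.table::setnames(qk, c("id", "pos"), c("qid", "qpos"))

  seeds <- idx[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(seeds)) return(emptyHits())
  cand <- unique(seeds[, .(qid, sid = id, strand, diag = qpos - pos)])

  qraw <- lapply(qs, charToRaw)
  sraw <- list("+" = lapply(ss, charToRaw),
               "-" = lapply(stats::setNames(.revcomp(ss), names(ss)),
                            charToRaw))
  qlen <- nchar(qs)
  slen <- nchar(ss)

  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    qid <- cand$qid[i]; sid <- cand$sid[i]
    strand <- cand$strand[i]; dg <- cand$diag[i]
    Lq <- qlen[[qid]]; Ls <- slen[[sid]]
    qlo <- max(1L, 1L + dg)
    qhi <- min(Lq, Ls + dg)
    if (qhi - qlo + 1L < k) next
    m <- qraw[[qid]][qlo:qhi] == sraw[[strand]][[sid]][(qlo - dg):(qhi - dg)]
    seg <- maxSegment(m, reward, penalty)
    if (seg[3] < minScore) next
    qstart <- qlo + seg[1] - 1L
    qend <- qlo + seg[2] - 1L
    len <- qend - qstart + 1L
    nmatch <- seg[4]
    s1 <- qstart - dg
    s2 <- qend - dg
    if (strand == "-") { tmp <- s1; s1 <- Ls - s1 + 1L; s2 <- Ls - s2 + 1L }
    bits <- (lambda * seg[3] - log(kParam)) / log(2)
    ev <- as.numeric(Lq) * dbLen * 2^(-bits)
    out[[i]] <- data.frame(
      query_id = qid, subject_id = sid,
      pct_identity = 100 * nmatch / len, aln_length = len,
      mismatches = len - nmatch, gap_opens = 0,
      q_start = qstart, q_end = qend, s_start = s1, s_end = s2,
      e_value = ev, bit_score = bits, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(emptyHits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$query_id, -hits$bit_score, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Align one query sequence against one subject sequence
#'
#' Small-scale local alignment via \code{\link{alignSets}} with a dense seed
#' stride, for use as an internal stand-in when no external tabular hits are
#' supplied. A self-alignment of a 1 kb sequence yields a single full-length
#' hit at identity 100; aligning against the reverse complement yields a
#' minus-strand hit with \code{s_start > s_end}.
#'
#' @param query,subject single sequences (character or
#'   \code{\link[Biostrings]{DNAString}}).
#' @param lengthCap sequences longer than this are rejected with instructions
#'   to supply external tabular hits.
#' @param minScore minimum raw segment score to report.
#' @param ... passed on to \code{\link{alignSets}}.
#' @return data.frame of hits, best first.
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
#'            collapse = "")
#' alignSmall(s, s)$pct_identity
#' @export
alignSmall <- function(query, subject, lengthCap = 50000L, minScore = 30,
                       ...) {
  q <- .asCharSeqs(stats::setNames(as.character(query)[1], "query"), "query")
  s <- .asCharSeqs(stats::setNames(as.character(subject)[1], "subject"),
                   "subject")
  if (nchar(q) > lengthCap || nchar(s) > lengthCap)
    stop("sequence longer than ", lengthCap,
         " bp: supply externally computed tabular hits instead")
  alignSets(q, s, stride = 2L, minScore = minScore, ...)
}
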