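#' High-stringency hit filter policy
#'
#' Encodes the stringency rules applied to cross-version alignment hits:
#' percent identity strictly above \code{minIdentity}, e-value strictly below
#' \code{maxEvalue}, and per query only the \code{topK} best hits by bit
#' score. In EST mode (\code{mode = "est"}) an additional minimum alignment
#' length compensates for the inability to use neighbor-gene context when
#' matching transcript evidence. Both inequalities are strict: a hit at
#' exactly the identity or e-value threshold is rejected.
#'
#' @param minIdentity percent identity bound (default 95, strict).
#' @param maxEvalue e-value bound (default 1e-20, strict).
#' @param topK number of best hits kept per query (default 4).
#' @param mode \code{"genomic"} or \code{"est"}.
#' @param minAlnLengthEst minimum alignment length in EST mode (default
#'   100 bp, inclusive).
#' @return a \code{filterPolicy} list.
#' @examples
#' filterPolicy()
#' filterPolicy(mode = "est")
#' @export
filterPolicy <- function(minIdentity = 95, maxEvalue = 1e-20, topK = 4L,
                         mode = c("genomic", "est"),
                         minAlnLengthEst = 100L) {
  mode <- match.arg(mode)
  stopifnot(topK >= 1L, minIdentity >= 0, minIdentity <= 100, maxEvalue >= 0)
  structure(list(minIdentity = minIdentity, maxEvalue = maxEvalue,
                 topK = as.integer(topK), mode = mode,
                 minAlnLengthEst = as.integer(minAlnLengthEst)),
            class = "filterPolicy")
}

#' Filter alignment hits at high stringency
#'
#' Applies a \code{\link{filterPolicy}} to a table of tabular hits: retains
#' hits with \code{pct_identity > minIdentity} and \code{e_value < maxEvalue}
#' (and, in EST mode, \code{aln_length >= minAlnLengthEst}), then keeps per
#' query only the \code{topK} hits by descending bit score. Ties in bit score
#' are broken by higher identity, longer alignment, then lexicographic
#' subject id, so the truncation is deterministic. Within a query, surviving
#' hits keep a stable order; no hit fields are mutated, and the operation is
#' idempotent.
#'
#' @param hits data.frame of hits (see \code{\link{readTabularHits}}).
#' @param policy a \code{\link{filterPolicy}}.
#' @return the retained subset of \code{hits}.
#' @examples
#' h <- alignSmall(paste(rep("ACGT", 100), collapse = ""),
#'                 paste(rep("ACGT", 100), collapse = ""))
#' nrow(filterHits(h, filterPolicy()))
#' @export
filterHits <- function(hits, policy = filterPolicy()) {
  stopifnot(inherits(policy, "filterPolicy"))
  if (!nrow(hits)) return(hits)
  keep <- hits$pct_identity > policy$minIdentity &
    hits$e_value < policy$maxEvalue
  if (policy$mode == "est")
    keep <- keep & hits$aln_length >= policy$minAlnLengthEst
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id,
               -hits$bit_score, -hits$pct_identity, -hits$aln_length,
               hits$subject_id)
  rank <- stats::ave(seq_along(ord), hits$query_id[ord],
                     FUN = seq_along)
  keepIdx <- sort(ord[rank <= policy$topK])
  out <- hits[keepIdx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
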