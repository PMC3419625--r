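.datatable.aware <- TRUE

utils::globalVariables(c(
  "kmer", "n", "id", "pos", "qid", "qpos", "sid", "strand", "diag",
  ".N", ".", "J"
))

# interval overlap length (1-based inclusive); 0 when disjoint
.ovlen <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# strip the random suffix off a chromosome name
.baseChrom <- function(chrom, randomSuffix = "_random") {
  sub(paste0(randomSuffix, "$"), "", chrom)
}
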