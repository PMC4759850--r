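# shared helpers: tiny alignments, brute-force oracles

make_aln <- function(seqs, locus_id = "test-locus") {
  locus_alignment(locus_id, names(seqs), unname(seqs))
}

# brute-force group distance: explicit double loop over the pair list,
# independent of the distance_table/group_distance path
brute_group_distance <- function(aln, group_a, group_b, correction = 0.95,
                                 min_overlap = 1) {
  vals <- c()
  for (a in intersect(group_a, aln$taxa)) {
    for (b in intersect(group_b, aln$taxa)) {
      sa <- strsplit(aln$sequences[[a]], "")[[1]]
      sb <- strsplit(aln$sequences[[b]], "")[[1]]
      ok <- !(sa %in% c("N", "-", "?")) & !(sb %in% c("N", "-", "?"))
      if (sum(ok) >= min_overlap)
        vals <- c(vals, (sum(sa[ok] != sb[ok]) / sum(ok)) / correction)
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# brute-force type-7 quantile: sort and linearly interpolate at h = (n-1)p
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h) + 1
    hi <- ceiling(h) + 1
    x[lo] + (h - (lo - 1)) * (x[hi] - x[lo])
  }, numeric(1))
}

# synthetic distance_table built directly from a full distance matrix
fake_distance_table <- function(d, locus_id = "fake") {
  structure(list(locus_id = locus_id, taxa = rownames(d),
                 distance = d,
                 overlap = matrix(1000L, nrow(d), ncol(d),
                                  dimnames = dimnames(d)),
                 min_overlap = 1),
            class = "distance_table")
}
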