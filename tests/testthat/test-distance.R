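test_that("p_distance handles identity, mismatches, pairwise deletion and overlap", {
  expect_equal(p_distance("ACGT", "ACGT", min_overlap = 1),
               list(distance = 0, overlap = 4))
  expect_equal(p_distance("ACGT", "ACGA", min_overlap = 1),
               list(distance = 0.25, overlap = 4))
  expect_equal(p_distance("AC-T", "ACGA", min_overlap = 1),
               list(distance = 1 / 3, overlap = 3))
  r <- p_distance("NNNN", "ACGT", min_overlap = 1)
  expect_true(is.na(r$distance))
  expect_equal(r$overlap, 0)
  # below min_overlap the distance is undefined, not noisy
  r <- p_distance("ACGT", "ACGA", min_overlap = 5)
  expect_true(is.na(r$distance))
  expect_equal(r$overlap, 4)
  # symmetry and case invariance
  expect_equal(p_distance("acgt", "ACGA", min_overlap = 1)$distance, 0.25)
  expect_equal(p_distance("ACGA", "ACGT", min_overlap = 1)$distance,
               p_distance("ACGT", "ACGA", min_overlap = 1)$distance)
  # '?' behaves as missing
  expect_equal(p_distance("?CGT", "ACGT", min_overlap = 1)$overlap, 3)
  expect_error(p_distance("ACGT", "ACGTA"), "length")
})

test_that("correct_saturation is d/c, monotone, identity at c = 1", {
  expect_equal(correct_saturation(0, 0.95), 0)
  expect_equal(correct_saturation(0.19, 0.95), 0.2)
  expect_equal(correct_saturation(0.3, 1), 0.3)
  expect_true(is.na(correct_saturation(NA_real_, 0.95)))
  expect_error(correct_saturation(0.1, 0), "correction")
  expect_error(correct_saturation(0.1, -1), "correction")
  expect_error(correct_saturation(1.2, 0.95), "\\[0, 1\\]")
})

test_that("group_distance averages corrected cross-group pairs", {
  aln <- make_aln(c(a = paste(rep("A", 100), collapse = ""),
                    b = paste(c(rep("A", 81), rep("C", 19)), collapse = "")))
  tb <- distance_table(aln, min_overlap = 1)
  g <- group_distance(tb, "a", "b", correction = 0.95)
  expect_equal(g$distance, 0.2)   # 0.19 / 0.95
  expect_equal(g$n_pairs, 1)
  expect_error(group_distance(tb, c("a", "b"), "b"), "overlap")
  expect_error(group_distance(tb, character(0), "b"), "non-empty")
  # mean over two pairs at c = 1
  aln <- make_aln(c(
    a = paste(c(rep("A", 90), rep("C", 10)), collapse = ""),
    b = paste(c(rep("A", 70), rep("C", 30)), collapse = ""),
    c = paste(rep("A", 100), collapse = "")))
  tb <- distance_table(aln, min_overlap = 1)
  g <- group_distance(tb, c("a", "b"), "c", correction = 1)
  expect_equal(g$distance, 0.2)
  expect_equal(g$n_pairs, 2)
  # group entirely absent from the locus -> undefined with zero pairs
  g <- group_distance(tb, "a", "zebra", correction = 1)
  expect_true(is.na(g$distance))
  expect_equal(g$n_pairs, 0)
})

test_that("group_distance equals the brute-force average over the pair list", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 6
    taxa <- letters[1:n]
    seqs <- vapply(taxa, function(t)
      paste(sample(c("A", "C", "G", "T", "N", "-"), 120, replace = TRUE,
                   prob = c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05)),
            collapse = ""), "")
    aln <- make_aln(seqs)
    tb <- distance_table(aln, min_overlap = 10)
    ga <- sample(taxa, 2); gb <- setdiff(taxa, ga)[1:2]
    got <- group_distance(tb, ga, gb, correction = 0.95)$distance
    want <- brute_group_distance(aln, ga, gb, correction = 0.95,
                                 min_overlap = 10)
    expect_equal(got, want)
  }
})

test_that("distance_table agrees with ape's raw pairwise-deletion distances", {
  set.seed(13)
  taxa <- paste0("t", 1:5)
  seqs <- vapply(taxa, function(t)
    paste(sample(c("a", "c", "g", "t", "n", "-"), 200, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.02, 0.02)),
          collapse = ""), "")
  aln <- make_aln(seqs)
  tb <- distance_table(aln, min_overlap = 1)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(tb$distance[taxa, taxa]), unname(ref[taxa, taxa]),
               tolerance = 1e-12)
})
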