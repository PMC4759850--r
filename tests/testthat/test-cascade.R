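test_that("estimate_locus_age implements the strict-clock ratio and the filter rule", {
  r <- estimate_locus_age(0.17, 0.17, 85)
  expect_equal(r$age, 85)
  expect_equal(r$status, "clock_like")   # equality passes the filter
  r <- estimate_locus_age(0.10, 0.17, 85)
  expect_equal(r$age, 50)
  expect_equal(r$status, "clock_like")
  r <- estimate_locus_age(0.20, 0.17, 85)
  expect_equal(r$age, 100)
  expect_equal(r$status, "non_clock_like")
  r <- estimate_locus_age(0.10, NA, 85)
  expect_true(is.na(r$age))
  expect_equal(r$status, "missing_outgroup")
  r <- estimate_locus_age(NA, 0.17, 85)
  expect_equal(r$status, "undefined")
  r <- estimate_locus_age(0.1, 0, 85)
  expect_equal(r$status, "undefined")
  expect_error(estimate_locus_age(0.1, 0.2, 0), "positive")
  expect_error(estimate_locus_age(0.1, 0.2, -5), "positive")
})

test_that("summarize_clade: order statistics, counting, and the quantile oracle", {
  recs <- data.frame(clade = "X",
                     age_estimate = c(10, 20, 30, 40, 50),
                     status = "clock_like")
  sm <- summarize_clade(recs)
  expect_equal(unname(sm$five_number), c(10, 20, 30, 40, 50))
  expect_equal(sm$point_estimate, 30)

  recs <- data.frame(clade = "X",
                     age_estimate = c(1, 2, NA, NA),
                     status = c("clock_like", "clock_like",
                                "non_clock_like", "missing_outgroup"))
  sm <- summarize_clade(recs)
  expect_equal(unname(sm$fractions), c(0.5, 0.25, 0.25))
  expect_equal(sm$n_loci_attempted, 4)

  # declared interpolation rule on [1,2,3,4]
  sm <- summarize_clade(data.frame(clade = "X", age_estimate = 1:4,
                                   status = "clock_like"))
  expect_equal(sm$five_number[["q1"]], 1.75)
  expect_equal(sm$five_number[["q3"]], 3.25)

  # brute-force interpolation oracle on random inputs
  set.seed(3)
  for (rep in 1:10) {
    x <- runif(sample(2:40, 1), 0, 100)
    sm <- summarize_clade(data.frame(clade = "X", age_estimate = x,
                                     status = "clock_like"))
    expect_equal(unname(sm$five_number),
                 brute_quantile7(x, c(0, 0.25, 0.5, 0.75, 1)))
  }
  # mean point estimator behind the switch
  sm <- summarize_clade(data.frame(clade = "X", age_estimate = c(1, 2, 9),
                                   status = "clock_like"),
                        point_estimator = "mean")
  expect_equal(sm$point_estimate, 4)
})

test_that("schedule validation refuses forward references and overlapping daughters", {
  expect_error(cascade_schedule("A", "B", 10, list(
    list(clade = "x", a = "A", b = "B", source = "later"))),
    "does not appear earlier")
  expect_error(cascade_schedule("A", "B", 10, list(
    list(clade = "x", a = c("A", "C"), b = c("C", "B"), source = "ROOT"))),
    "overlap")
  expect_error(cascade_schedule("A", c("B", "A"), 10, list()), "overlap")
})

test_that("the root-calibration split returns exactly the calibration age per locus", {
  cfg <- sim_config(n_loci = 25, seed = 5)
  ds <- simulate_dataset(cfg)
  res <- run_cascade(ds$loci)
  dr <- res$records[res$records$clade == "Draconinae", ]
  defined <- dr$status == "clock_like"
  expect_gt(sum(defined), 0)
  expect_true(all(dr$age_estimate[defined] == 85))
  expect_true(all(dr$status %in% c("clock_like", "missing_outgroup",
                                   "undefined")))
  expect_equal(res$summaries$Draconinae$point_estimate, 85)
})

test_that("age estimates are invariant to the saturation correction factor", {
  cfg <- sim_config(n_loci = 30, seed = 8)
  ds <- simulate_dataset(cfg)
  r1 <- run_cascade(ds$loci, correction = 0.95)
  r2 <- run_cascade(ds$loci, correction = 1)
  expect_equal(r1$records$age_estimate, r2$records$age_estimate)
  expect_identical(r1$records$status, r2$records$status)
  for (nm in names(r1$summaries))
    expect_equal(r1$summaries[[nm]]$point_estimate,
                 r2$summaries[[nm]]$point_estimate)
})

test_that("clock filter guarantee: no clock-like age exceeds its calibration; cascade is monotone", {
  cfg <- sim_config(n_loci = 60, seed = 21)
  ds <- simulate_dataset(cfg)
  res <- run_cascade(ds$loci)
  pe <- vapply(res$summaries, `[[`, 0, "point_estimate")
  tcal <- vapply(res$summaries, function(s) s$calibration_used$t_cal, 0)
  src <- vapply(res$summaries, function(s) s$calibration_used$source, "")
  for (nm in names(res$summaries)) {
    cl <- res$records[res$records$clade == nm &
                        res$records$status == "clock_like", ]
    expect_true(all(cl$age_estimate <= tcal[[nm]] + 1e-12))
    expect_lte(pe[[nm]], tcal[[nm]])
    # child point estimate never exceeds its parent's
    if (src[[nm]] != "ROOT") expect_lte(pe[[nm]], pe[[src[[nm]]]])
  }
})

test_that("identical sequences across taxa starve the cascade with a named error", {
  seqs <- setNames(rep(paste(rep("ACGT", 50), collapse = ""), 17),
                   build_fixture_tree()$phy$tip.label)
  loci <- list(make_aln(seqs, "uce-00001"), make_aln(seqs, "uce-00002"))
  expect_error(run_cascade(loci), "cascade starvation.*NonMantheyus")
})
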