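test_that("sim_config validates its invariants", {
  expect_error(sim_config(missing_individual_prob = 0.5), "25%")
  expect_error(sim_config(ils_mode = "msc", pop_size = 0), "pop_size")
  expect_error(sim_config(ils_mode = "msc", pop_size = -1), "pop_size")
  expect_error(sim_config(site_rate = -1), "site_rate")
  expect_error(sim_config(missing_fraction_mean = 0.01,
                          missing_fraction_sd = 0.4), "Beta")
  expect_error(sim_config(clock_mode = "branch_multipliers"),
               "branch_multipliers")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("identical (config, seed) give identical datasets; seeds differ otherwise", {
  cfg <- sim_config(n_loci = 5, seed = 3, ils_mode = "msc", pop_size = 0.5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(lapply(d1$loci, `[[`, "sequences"),
                   lapply(d2$loci, `[[`, "sequences"))
  expect_identical(lapply(d1$gene_trees, ape::write.tree),
                   lapply(d2$gene_trees, ape::write.tree))
  d3 <- simulate_dataset(sim_config(n_loci = 5, seed = 4, ils_mode = "msc",
                                    pop_size = 0.5))
  expect_false(identical(d1$loci[[1]]$sequences, d3$loci[[1]]$sequences))
})

test_that("zero site rate gives identical sequences; gene trees equal species tree without ILS", {
  cfg <- sim_config(n_loci = 2, seed = 1, site_rate = 0,
                    missing_individual_prob = 0,
                    missing_fraction_mean = 0, missing_fraction_sd = 0)
  ds <- simulate_dataset(cfg)
  expect_length(unique(unname(ds$loci[[1]]$sequences)), 1)
  gt <- simulate_gene_tree(ds$species_tree, cfg, 1)
  expect_identical(ape::write.tree(gt), ape::write.tree(ds$species_tree$phy))
})

test_that("MSC gene trees: determinism, age ordering, and the small-population limit", {
  tr <- build_fixture_tree()
  cfg <- sim_config(n_loci = 3, seed = 17, ils_mode = "msc", pop_size = 2)
  g1 <- simulate_gene_tree(tr, cfg, 2)
  g2 <- simulate_gene_tree(tr, cfg, 2)
  expect_identical(ape::write.tree(g1), ape::write.tree(g2))
  expect_setequal(g1$tip.label, tr$phy$tip.label)
  # coalescence happens at or above the species divergence: gene-tree root
  # is at least as old as the species root
  depth <- max(ape::node.depth.edgelength(g1))
  expect_gte(depth, tr$root_age - 1e-8)

  # population size -> 0: gene-tree ages converge on species-tree ages
  cfg0 <- sim_config(n_loci = 3, seed = 17, ils_mode = "msc",
                     pop_size = 1e-8)
  g0 <- simulate_gene_tree(tr, cfg0, 2)
  mrca_age <- function(phy, taxa) {
    depths <- ape::node.depth.edgelength(phy)
    max(depths) - depths[ape::getMRCA(phy, taxa)]
  }
  for (nm in c("NonMantheyus", "Group4", "SriLanka"))
    expect_equal(mrca_age(g0, clade_taxa(tr, nm)), clade_age(tr, nm),
                 tolerance = 1e-4)
})

test_that("locus lengths follow the clamped normal and sequences follow the JC expectation", {
  cfg <- sim_config(n_loci = 400, seed = 23, missing_individual_prob = 0,
                    missing_fraction_mean = 0, missing_fraction_sd = 0)
  ds <- simulate_dataset(cfg)
  len <- ds$truth$lengths
  expect_true(all(len >= cfg$length_min))
  # 400 loci: mean within 4 standard errors of the configured mean
  expect_lt(abs(mean(len) - 644.7), 4 * 249.7 / sqrt(400))

  # mean pairwise p-distance vs the closed-form JC expectation, two depths
  pd <- function(a, b) vapply(ds$loci, function(aln)
    p_distance(aln$sequences[[a]], aln$sequences[[b]], min_overlap = 1)$distance,
    numeric(1))
  p_root <- mean(pd("Mantheyus", "Draco"))
  expect_equal(p_root, jc_expected_p(85, cfg$site_rate), tolerance = 0.02)
  p_shallow <- mean(pd("Salea", "Calotes"))
  expect_equal(p_shallow, jc_expected_p(56, cfg$site_rate), tolerance = 0.03)
})

test_that("parsimony-informative fraction sits in the calibration band around 10.5%", {
  cfg <- sim_config(n_loci = 150, seed = 31)
  ds <- simulate_dataset(cfg)
  pis <- mean(vapply(ds$loci, pis_fraction, numeric(1)))
  expect_gt(pis, 0.055)
  expect_lt(pis, 0.155)
})

test_that("missingness injection: no-op at zero, cap enforcement, moment recovery", {
  cfg <- sim_config(n_loci = 4, seed = 2, missing_individual_prob = 0,
                    missing_fraction_mean = 0, missing_fraction_sd = 0)
  ds <- simulate_dataset(cfg)
  expect_true(all(vapply(ds$loci, function(a)
    !any(grepl("[N?-]", a$sequences)), TRUE)))
  expect_length(ds$loci[[1]]$taxa, 17)

  # cap: even at the maximum drop probability no locus loses > 25% of taxa
  cfg <- sim_config(n_loci = 60, seed = 6, missing_individual_prob = 0.25,
                    missing_fraction_mean = 0, missing_fraction_sd = 0)
  ds <- simulate_dataset(cfg)
  lost <- vapply(ds$truth$missing, function(x) length(x$dropped), 0L)
  expect_true(all(lost <= floor(0.25 * 17)))

  # moment recovery at reduced n: realized mean within 2 SE of target
  cfg <- sim_config(n_loci = 800, seed = 12)
  ds <- simulate_dataset(cfg)
  fr <- vapply(ds$truth$missing, `[[`, 0, "realized_fraction")
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.236), 2 * se + 1e-3)
  # per-sequence missingness never exceeds the 95% cap (no all-missing rows)
  worst <- max(vapply(ds$loci, function(a) {
    max(vapply(strsplit(unname(a$sequences), ""), function(s)
      mean(s %in% c("N", "-", "?")), 0))
  }, 0))
  expect_lte(worst, 0.95)
})
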