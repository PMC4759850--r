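#' Simulation configuration for synthetic UCE datasets
#'
#' Defaults emulate the published UCE matrix the pipeline was designed
#' for: locus lengths drawn from a normal with mean 644.7 bp and SD
#' 249.7 bp (clamped at `length_min`); a per-site substitution rate of
#' 6.31e-4 substitutions/site/MY, the Jukes-Cantor rate at which the
#' expected p-distance across the 85-MYA root split is 0.10 (matching the
#' mild divergence implied by ~10.5 % parsimony-informative sites); a
#' per-locus missing-data fraction drawn from a Beta distribution
#' moment-matched to mean 23.6 % and SD 19.4 %, realized as terminal runs
#' of `N` (ragged ends, as in capture data); and whole individuals dropped
#' per locus with probability 0.1, never exceeding 25 % of the taxa at a
#' locus.
#'
#' @param n_loci Number of loci.
#' @param length_mean,length_sd,length_min Locus-length distribution (bp);
#'   draws below `length_min` are clamped to it.
#' @param subst_model `"JC"` or `"HKY"`.
#' @param kappa Transition/transversion rate ratio (HKY only).
#' @param base_freqs Base frequencies A,C,G,T (HKY only).
#' @param site_rate Substitutions/site/MY on every branch (strict clock
#'   baseline).
#' @param clock_mode `"strict"`, `"per_locus_lognormal"` (per-locus rate
#'   factor, lognormal with mean 1 and `clock_sdlog`), or
#'   `"branch_multipliers"` (deterministic per-clade rate factors).
#' @param clock_sdlog Log-SD of the per-locus rate factor.
#' @param branch_multipliers Named numeric vector: clade name -> rate
#'   factor applied to every branch within that clade's crown group.
#' @param ils_mode `"none"` (gene trees equal the species tree) or
#'   `"msc"` (one gene tree per locus under the multispecies coalescent).
#' @param pop_size Coalescent population-size parameter in MY: the
#'   expected time for two lineages to coalesce within a population.
#'   Must be > 0; as it approaches 0, gene trees converge on the species
#'   tree.
#' @param missing_individual_prob Per-locus, per-taxon drop probability;
#'   must not exceed 0.25, and at most 25 % of a locus's taxa are ever
#'   removed.
#' @param missing_fraction_mean,missing_fraction_sd Moments of the
#'   per-locus missing-data fraction (measured over the sequences present
#'   at the locus).
#' @param missing_fraction_max Hard cap on the per-locus fraction
#'   (default 0.95; also caps any single sequence's missingness).
#' @param seed Master seed (integer below 2^31); every locus uses a
#'   substream derived from `(seed, locus_index)`, so subsets are
#'   reproducible.
#' @param tree Optional [dated_tree] species tree; default is the
#'   Draconinae fixture ([build_fixture_tree()]).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 100,
                       length_mean = 644.7, length_sd = 249.7,
                       length_min = 100,
                       subst_model = c("JC", "HKY"),
                       kappa = 2, base_freqs = rep(0.25, 4),
                       site_rate = 6.31e-4,
                       clock_mode = c("strict", "per_locus_lognormal",
                                      "branch_multipliers"),
                       clock_sdlog = 0.25,
                       branch_multipliers = numeric(0),
                       ils_mode = c("none", "msc"),
                       pop_size = 1,
                       missing_individual_prob = 0.1,
                       missing_fraction_mean = 0.236,
                       missing_fraction_sd = 0.194,
                       missing_fraction_max = 0.95,
                       seed = 1,
                       tree = NULL) {
  subst_model <- match.arg(subst_model)
  clock_mode <- match.arg(clock_mode)
  ils_mode <- match.arg(ils_mode)
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (length_sd < 0 || length_min < 1 || length_mean <= 0)
    stop("invalid length parameters")
  if (site_rate < 0) stop("site_rate must be >= 0")
  if (ils_mode == "msc" && pop_size <= 0)
    stop("pop_size must be > 0 under ils_mode = 'msc'")
  if (missing_individual_prob < 0 || missing_individual_prob > 0.25)
    stop("missing_individual_prob must lie in [0, 0.25] ",
         "(at most 25% of individuals may be missing at a locus)")
  m <- missing_fraction_mean; s <- missing_fraction_sd
  if (m < 0 || m >= 1 || s < 0)
    stop("invalid missing-fraction parameters")
  if (s > 0 && (m <= 0 || s^2 >= m * (1 - m)))
    stop("missing_fraction_sd too large for a Beta distribution with mean ",
         m)
  if (missing_fraction_max <= 0 || missing_fraction_max > 0.95)
    stop("missing_fraction_max must lie in (0, 0.95]")
  if (clock_mode == "branch_multipliers" && length(branch_multipliers) == 0L)
    stop("clock_mode 'branch_multipliers' needs a named branch_multipliers vector")
  if (length(branch_multipliers) &&
      (is.null(names(branch_multipliers)) || any(branch_multipliers <= 0)))
    stop("branch_multipliers must be a named vector of positive factors")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer")
  if (!is.null(tree)) stopifnot(inherits(tree, "dated_tree"))
  structure(list(n_loci = as.integer(n_loci), length_mean = length_mean,
                 length_sd = length_sd, length_min = as.integer(length_min),
                 subst_model = subst_model, kappa = kappa,
                 base_freqs = base_freqs, site_rate = site_rate,
                 clock_mode = clock_mode, clock_sdlog = clock_sdlog,
                 branch_multipliers = branch_multipliers,
                 ils_mode = ils_mode, pop_size = pop_size,
                 missing_individual_prob = missing_individual_prob,
                 missing_fraction_mean = m, missing_fraction_sd = s,
                 missing_fraction_max = missing_fraction_max,
                 seed = seed, tree = tree),
            class = "sim_config")
}

# deterministic per-locus RNG substream: distinct for every
# (seed, locus_index, stage) at fixed seed; stays below 2^31 - 1
locus_seed <- function(seed, locus_index, stage) {
  as.integer(((seed %% 1000000) * 1009 + locus_index * 131 + stage * 17) %%
               2147483647)
}

# seed the RNG for one locus/stage; an intermediate draw scrambles the
# generator state so that substreams from adjacent raw seeds are
# decorrelated (nearby Mersenne-Twister seeds share early-state structure)
set_locus_stream <- function(seed, locus_index, stage) {
  set.seed(locus_seed(seed, locus_index, stage))
  set.seed(sample.int(2147483646, 1))
  invisible(NULL)
}

#' Simulate one gene tree within the species tree
#'
#' Under `ils_mode = "none"` the gene tree is the species tree itself.
#' Under `"msc"` one genealogy is drawn under the multispecies coalescent
#' (one haploid sample per tip): lineages entering each species-tree
#' branch coalesce at rate `k(k-1)/2 / pop_size` until the branch's parent
#' node, with free coalescence above the root. Reproducible from
#' `(seed, locus_index)`.
#'
#' @param species_tree A [dated_tree].
#' @param config A [sim_config].
#' @param locus_index Locus index (1-based).
#' @return An `ape::phylo` gene tree with branch lengths in MY.
#' @export
simulate_gene_tree <- function(species_tree, config, locus_index) {
  stopifnot(inherits(species_tree, "dated_tree"),
            inherits(config, "sim_config"))
  if (config$ils_mode == "none") return(species_tree$phy)
  if (config$pop_size <= 0) stop("pop_size must be > 0")
  set_locus_stream(config$seed, locus_index, 1L)
  msc_sim(species_tree$phy, species_tree$ages, config$pop_size)
}

# multispecies-coalescent genealogy: recursion over species-tree nodes,
# building a newick string; lineage = list(label, height in MY)
msc_sim <- function(phy, ages, pop_size) {
  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  coalesce_interval <- function(lins, t_start, t_end) {
    t <- t_start
    while (length(lins) >= 2L) {
      k <- length(lins)
      w <- rexp(1, rate = k * (k - 1) / 2 / pop_size)
      if (t + w > t_end) break
      t <- t + w
      pair <- sample.int(k, 2L)
      merged <- list(
        label = sprintf("(%s:%.10g,%s:%.10g)",
                        lins[[pair[1]]]$label, t - lins[[pair[1]]]$height,
                        lins[[pair[2]]]$label, t - lins[[pair[2]]]$height),
        height = t)
      lins <- c(lins[-pair], list(merged))
    }
    lins
  }
  survive_to_parent <- function(node) {
    if (node <= ntip)
      return(list(list(label = phy$tip.label[node], height = 0)))
    lins <- list()
    for (ch in children[[as.character(node)]])
      lins <- c(lins,
                coalesce_interval(survive_to_parent(ch), ages[ch], ages[node]))
    lins
  }
  root <- ntip + 1L
  lins <- survive_to_parent(root)
  lins <- coalesce_interval(lins, ages[root], Inf)
  stopifnot(length(lins) == 1L)
  ape::read.tree(text = paste0(lins[[1]]$label, ";"))
}

# scale the branches inside each multiplier clade's crown group
scale_branch_multipliers <- function(phy, multiplier_sets) {
  for (s in multiplier_sets) {
    tips <- match(intersect(s$taxa, phy$tip.label), phy$tip.label)
    if (length(tips) == 0L) next
    mrca <- if (length(tips) > 1L) ape::getMRCA(phy, tips) else -1L
    child <- phy$edge[, 2]
    inside <- vapply(seq_along(child), function(e) {
      nd <- child[e]
      if (nd == mrca) return(FALSE)            # stem edge of the crown
      desc <- unlist(phangorn::Descendants(phy, nd, type = "tips"))
      all(desc %in% tips)
    }, logical(1))
    phy$edge.length[inside] <- phy$edge.length[inside] * s$factor
  }
  phy
}

#' Simulate one locus alignment along a gene tree
#'
#' The locus length is drawn from the configured (clamped) normal; sites
#' evolve independently under the configured substitution model with
#' effective branch rate `site_rate` times the clock-mode multipliers.
#' Reproducible from `(seed, locus_index)`.
#'
#' @param gene_tree `phylo` gene tree with branch lengths in MY.
#' @param config A [sim_config].
#' @param locus_index Locus index (1-based); also names the locus.
#' @param multiplier_sets Internal: list of `list(taxa, factor)` resolved
#'   from `config$branch_multipliers` against the species tree.
#' @return A [locus_alignment] with attribute `rate_factor` (the per-locus
#'   clock factor).
#' @export
simulate_locus <- function(gene_tree, config, locus_index,
                           multiplier_sets = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(config, "sim_config"))
  set_locus_stream(config$seed, locus_index, 2L)
  L <- max(config$length_min,
           as.integer(round(rnorm(1, config$length_mean, config$length_sd))))
  factor <- if (config$clock_mode == "per_locus_lognormal")
    rlnorm(1, meanlog = -config$clock_sdlog^2 / 2, sdlog = config$clock_sdlog)
  else 1
  phy <- gene_tree
  if (length(multiplier_sets))
    phy <- scale_branch_multipliers(phy, multiplier_sets)
  phy$edge.length <- phy$edge.length * config$site_rate * factor
  dat <- if (config$subst_model == "HKY")
    phangorn::simSeq(phy, l = L, Q = c(1, config$kappa, 1, 1, config$kappa, 1),
                     bf = config$base_freqs, type = "DNA")
  else phangorn::simSeq(phy, l = L, type = "DNA")
  m <- toupper(as.character(dat))
  aln <- locus_alignment(sprintf("uce-%05d", locus_index),
                         rownames(m),
                         apply(m, 1, paste, collapse = ""))
  attr(aln, "rate_factor") <- factor
  aln
}

#' Inject the empirical missing-data profile into simulated loci
#'
#' Two channels, per locus: (i) whole individuals are dropped
#' independently with `missing_individual_prob`, never more than 25 % of
#' the locus's taxa; (ii) a target missing fraction is drawn from the
#' moment-matched Beta distribution (capped at `missing_fraction_max`) and
#' realized by replacing terminal runs of sites with `N` for randomly
#' chosen taxa - ragged ends, as produced by sequence capture. A truth
#' table of everything removed is returned alongside the loci.
#'
#' @param loci List of [locus_alignment] objects.
#' @param config A [sim_config].
#' @return List with `loci` (modified alignments) and `truth` (per-locus
#'   list: `dropped` taxa, `target_fraction`, `realized_fraction`,
#'   `n_masked` sites per retained taxon).
#' @export
inject_missingness <- function(loci, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$missing_fraction_mean; s <- config$missing_fraction_sd
  use_beta <- s > 0
  if (use_beta) {
    shape_sum <- m * (1 - m) / s^2 - 1
    alpha <- m * shape_sum; beta <- (1 - m) * shape_sum
  }
  out <- vector("list", length(loci))
  truth <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    aln <- loci[[i]]
    set_locus_stream(config$seed, i, 3L)
    n0 <- length(aln$taxa)
    drop_flag <- runif(n0) < config$missing_individual_prob
    cap <- floor(0.25 * n0)
    if (sum(drop_flag) > cap) {
      keep_drops <- sample(which(drop_flag), cap)
      drop_flag <- seq_len(n0) %in% keep_drops
    }
    dropped <- aln$taxa[drop_flag]
    taxa <- aln$taxa[!drop_flag]
    seqs <- aln$sequences[!drop_flag]
    L <- aln$length
    np <- length(taxa)
    f <- if (use_beta) rbeta(1, alpha, beta) else m
    f <- min(max(f, 0), config$missing_fraction_max)
    chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    cur <- rowSums(matrix(chars %in% MISSING_CHARS, nrow = np))
    target <- round(f * np * L)
    extra <- max(0, target - sum(cur))
    caps <- pmax(0, floor(config$missing_fraction_max * L) - cur)
    alloc <- integer(np)
    if (extra > 0 && sum(caps) > 0) {
      extra <- min(extra, sum(caps))
      u <- runif(np)
      alloc <- pmin(as.integer(floor(u / sum(u) * extra)), caps)
      rem <- extra - sum(alloc)
      while (rem > 0) {
        slack <- which(alloc < caps)
        if (length(slack) == 0L) break
        pick <- if (length(slack) == 1L) slack else sample(slack, 1L)
        add <- min(rem, caps[pick] - alloc[pick])
        alloc[pick] <- alloc[pick] + add
        rem <- rem - add
      }
      for (j in which(alloc > 0)) {
        run <- seq_len(alloc[j])
        if (runif(1) < 0.5) run <- L - run + 1L   # tail instead of head
        chars[j, run] <- "N"
      }
      seqs <- apply(chars, 1, paste, collapse = "")
    }
    realized <- sum(chars %in% MISSING_CHARS) / (np * L)
    out[[i]] <- locus_alignment(aln$locus_id, taxa, seqs)
    attr(out[[i]], "rate_factor") <- attr(aln, "rate_factor")
    truth[[i]] <- list(locus_id = aln$locus_id, dropped = dropped,
                       target_fraction = f, realized_fraction = realized,
                       n_masked = setNames(alloc, taxa))
  }
  names(out) <- names(loci)
  list(loci = out, truth = truth)
}

#' Simulate a complete synthetic UCE dataset with ground truth
#'
#' Composes the stages: species tree (the Draconinae fixture unless
#' `config$tree` is given), per-locus gene trees, sequence evolution, and
#' missing-data injection. Identical `(config, seed)` give identical
#' datasets.
#'
#' @param config A [sim_config].
#' @return Object of class `uce_dataset`: `loci` (named list of
#'   [locus_alignment]), `species_tree`, `gene_trees` (list of `phylo`, or
#'   `NULL` under `ils_mode = "none"`, where every gene tree equals the
#'   species tree), `truth` (per-locus lengths, rate factors and
#'   missing-data records), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$tree %||% build_fixture_tree()
  msets <- NULL
  if (length(config$branch_multipliers)) {
    msets <- lapply(names(config$branch_multipliers), function(nm) {
      taxa <- if (nm %in% names(tree$clades)) clade_taxa(tree, nm)
              else if (nm %in% tree$phy$tip.label) nm
              else stop("branch_multipliers: unknown clade or taxon '", nm, "'")
      list(taxa = taxa, factor = unname(config$branch_multipliers[[nm]]))
    })
  }
  loci <- vector("list", config$n_loci)
  gene_trees <- if (config$ils_mode == "msc") vector("list", config$n_loci)
                else NULL
  for (i in seq_len(config$n_loci)) {
    gt <- simulate_gene_tree(tree, config, i)
    if (!is.null(gene_trees)) gene_trees[[i]] <- gt
    loci[[i]] <- simulate_locus(gt, config, i, msets)
  }
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  inj <- inject_missingness(loci, config)
  structure(list(loci = inj$loci, species_tree = tree,
                 gene_trees = gene_trees,
                 truth = list(
                   lengths = vapply(loci, `[[`, 0L, "length"),
                   rate_factors = vapply(loci, function(a)
                     attr(a, "rate_factor"), numeric(1)),
                   missing = inj$truth),
                 config = config),
            class = "uce_dataset")
}

#' @export
print.uce_dataset <- function(x, ...) {
  cat("<uce_dataset> ", length(x$loci), " loci, ",
      length(x$species_tree$phy$tip.label), " taxa, ils_mode=",
      x$config$ils_mode, ", clock_mode=", x$config$clock_mode, "\n", sep = "")
  invisible(x)
}

#' Fraction of parsimony-informative sites in an alignment
#'
#' A site is parsimony-informative when at least two states each occur in
#' at least two sequences, missing characters excluded.
#'
#' @param aln A [locus_alignment].
#' @return Fraction in `[0, 1]`.
#' @export
pis_fraction <- function(aln) {
  m <- aln_matrix(aln)
  m[m %in% MISSING_CHARS] <- NA
  mean(apply(m, 2, function(col) {
    tb <- table(col)
    sum(tb >= 2) >= 2
  }))
}

#' Expected Jukes-Cantor p-distance between two tips
#'
#' Closed form for two lineages that diverged `t_split` MY ago under a
#' strict clock at `site_rate` substitutions/site/MY:
#' `3/4 * (1 - exp(-8 * site_rate * t_split / 3))`.
#'
#' @param t_split Divergence time in MY.
#' @param site_rate Substitutions/site/MY.
#' @return Expected p-distance.
#' @export
jc_expected_p <- function(t_split, site_rate) {
  0.75 * (1 - exp(-8 * site_rate * t_split / 3))
}
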