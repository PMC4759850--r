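#' Simulate a dataset and write it to disk
#'
#' Writes one FASTA per locus under `loci/`, the dated species tree
#' (`species_tree.nwk`), the clade table (`clade_table.tsv`), gene trees
#' (`gene_trees.nwk`, under `ils_mode = "msc"`), a per-locus truth table
#' (`locus_truth.tsv`: length, rate factor, dropped taxa, realized missing
#' fraction), and a provenance record (`provenance.json`: config echo,
#' seed, package version). Output is deterministic: rerunning with the
#' same config produces identical bytes.
#'
#' @param out_dir Output directory (created; must be writable).
#' @param config A [sim_config].
#' @return The simulated [simulate_dataset()] object, invisibly.
#' @export
cmd_simulate <- function(out_dir, config) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(out_dir, "loci"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "loci")))
    stop("cannot create output directory: ", out_dir)
  ds <- simulate_dataset(config)
  for (aln in ds$loci)
    write_locus_fasta(aln, file.path(out_dir, "loci",
                                     paste0(aln$locus_id, ".fasta")))
  write_dated_newick(ds$species_tree, file.path(out_dir, "species_tree.nwk"))
  write_clade_table(ds$species_tree$clades,
                    file.path(out_dir, "clade_table.tsv"))
  if (!is.null(ds$gene_trees)) {
    txt <- vapply(ds$gene_trees, ape::write.tree, "")
    writeLines(txt, file.path(out_dir, "gene_trees.nwk"))
  }
  tt <- data.frame(
    locus_id = names(ds$loci),
    length = unname(ds$truth$lengths),
    rate_factor = unname(ds$truth$rate_factors),
    dropped = vapply(ds$truth$missing, function(x)
      paste(x$dropped, collapse = ","), ""),
    missing_fraction = vapply(ds$truth$missing, `[[`, 0,
                              "realized_fraction"),
    stringsAsFactors = FALSE)
  utils::write.table(tt, file.path(out_dir, "locus_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_provenance(out_dir, config = config_as_list(config),
                   seed = config$seed)
  invisible(ds)
}

config_as_list <- function(config) {
  x <- unclass(config)
  x$tree <- if (is.null(x$tree)) "fixture" else "user-supplied"
  x$branch_multipliers <- as.list(x$branch_multipliers)
  x
}

write_provenance <- function(dir, ...) {
  rec <- c(list(package = "uceclock",
                version = as.character(utils::packageVersion("uceclock"))),
           list(...))
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

#' Date a dataset with the cascade pipeline and write results
#'
#' Accepts either a dataset directory written by [cmd_simulate] (loci are
#' read from `loci/`, or from FASTA files directly in `input`) or a
#' `uce_dataset` object. Runs [run_cascade] and writes per-locus records,
#' clade summaries (via [write_results]) and a provenance record into
#' `out_dir`. Per-level calibrations and discard counts are logged to
#' standard error.
#'
#' @param input Dataset directory or `uce_dataset`.
#' @param out_dir Results directory.
#' @param schedule A [cascade_schedule] or a path to a schedule file
#'   (default [default_schedule()]).
#' @param correction,min_overlap,point_estimator,shift_threshold,reference_ages
#'   Passed to [run_cascade].
#' @param quiet Suppress log messages.
#' @return The `cascade_result`, invisibly.
#' @export
cmd_date <- function(input, out_dir, schedule = default_schedule(),
                     correction = 0.95, min_overlap = 100,
                     point_estimator = "median", shift_threshold = 0.05,
                     reference_ages = NULL, quiet = FALSE) {
  if (is.character(schedule)) schedule <- read_cascade_schedule(schedule)
  loci <- if (inherits(input, "uce_dataset")) input$loci
  else {
    d <- if (dir.exists(file.path(input, "loci"))) file.path(input, "loci")
         else input
    read_locus_dir(d)
  }
  res <- run_cascade(loci, schedule, correction = correction,
                     min_overlap = min_overlap,
                     point_estimator = point_estimator,
                     shift_threshold = shift_threshold,
                     reference_ages = reference_ages, verbose = !quiet)
  write_results(res$records, res$summaries, out_dir)
  write_provenance(out_dir,
                   parameters = list(correction = correction,
                                     min_overlap = min_overlap,
                                     point_estimator = point_estimator,
                                     shift_threshold = shift_threshold),
                   n_loci = length(loci))
  invisible(res)
}

#' Render a human-readable per-clade report
#'
#' One row per clade: point estimate, five-number summary, status
#' percentages, rate-shift call and calibration. If reference ages are
#' present (supplied to [run_cascade] or [cmd_date], or given here) a
#' comparison column with absolute differences is added. Clades with no
#' clock-like loci are rendered with `NA` values and trigger a warning.
#'
#' @param results Results directory written by [cmd_date]/[write_results],
#'   or a `cascade_result`.
#' @param reference_ages Optional named numeric vector of comparison ages
#'   (MYA).
#' @return The report data frame (also printed).
#' @export
cmd_report <- function(results, reference_ages = NULL) {
  summaries <- if (inherits(results, "cascade_result")) results$summaries
  else {
    if (!dir.exists(results)) stop("results not found: ", results)
    read_results(results)$summaries
  }
  if (length(summaries) == 0L) stop("no clade summaries to report")
  rows <- lapply(summaries, function(sm) {
    fn <- sm$five_number
    rs <- sm$rate_shift
    data.frame(
      clade = sm$clade,
      point_estimate = sm$point_estimate %||% NA_real_,
      min = fn[["min"]], q1 = fn[["q1"]], median = fn[["median"]],
      q3 = fn[["q3"]], max = fn[["max"]],
      pct_clock_like = 100 * sm$fractions[["clock_like"]],
      pct_non_clock_like = 100 * sm$fractions[["non_clock_like"]],
      pct_missing_outgroup = 100 * sm$fractions[["missing_outgroup"]],
      rate_shift = if (is.null(rs) || is.null(rs$call) || is.na(rs$call))
        NA_character_ else rs$call,
      t_cal = sm$calibration_used$t_cal,
      calibration_source = sm$calibration_used$source,
      reference_age = sm$reference_age %||% NA_real_,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(reference_ages)) {
    idx <- match(df$clade, names(reference_ages))
    df$reference_age <- ifelse(is.na(idx), df$reference_age,
                               unname(reference_ages[idx]))
  }
  if (all(is.na(df$reference_age))) df$reference_age <- NULL
  else df$abs_difference <- abs(df$point_estimate - df$reference_age)
  empty <- is.na(df$point_estimate)
  if (any(empty))
    warning("no clock-like loci for clade(s): ",
            paste(df$clade[empty], collapse = ", "))
  print(df, digits = 4, row.names = FALSE)
  invisible(df)
}
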