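#' Write per-locus records and clade summaries to a results directory
#'
#' Writes (i) `per_locus_ages.tsv`, one row per (locus, clade) attempted -
#' including discarded loci with their status - with the fixed column order
#' `locus_id`, `clade`, `raw_distance_target`, `raw_distance_calibration`,
#' `age_estimate`, `status` (status vocabulary: `clock_like`,
#' `non_clock_like`, `missing_outgroup`, `undefined`); and (ii)
#' `clade_summaries.json`, one object per clade holding the five-number
#' summary, status fractions, point estimate, rate-shift call and the
#' calibration source and value.
#'
#' @param records Data frame of per-locus records (as in
#'   [run_cascade()]`$records`).
#' @param summaries Non-empty named list of clade summaries (as in
#'   [run_cascade()]`$summaries`).
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_results <- function(records, summaries, dir) {
  if (length(summaries) == 0L) stop("summaries must be non-empty")
  cols <- c("locus_id", "clade", "raw_distance_target",
            "raw_distance_calibration", "age_estimate", "status")
  stopifnot(is.data.frame(records), all(cols %in% names(records)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create results directory: ", dir)
  tsv <- file.path(dir, "per_locus_ages.tsv")
  jsn <- file.path(dir, "clade_summaries.json")
  utils::write.table(records[, cols], tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summaries <- lapply(summaries, function(sm) {
    sm$five_number <- as.list(sm$five_number)
    sm$fractions <- as.list(sm$fractions)
    sm
  })
  jsonlite::write_json(summaries, jsn, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(c(tsv, jsn))
}

#' Read back a results directory written by [write_results]
#'
#' @param dir Results directory.
#' @return List with `records` (data frame) and `summaries` (named list;
#'   numeric values round-trip exactly).
#' @export
read_results <- function(dir) {
  tsv <- file.path(dir, "per_locus_ages.tsv")
  jsn <- file.path(dir, "clade_summaries.json")
  if (!file.exists(tsv) || !file.exists(jsn))
    stop("results files not found in ", dir)
  records <- utils::read.table(tsv, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  summaries <- jsonlite::read_json(jsn, simplifyVector = FALSE)
  summaries <- lapply(summaries, function(sm) {
    sm$five_number <- vapply(sm$five_number,
                             function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                             numeric(1))
    sm$fractions <- vapply(sm$fractions, as.numeric, numeric(1))
    if (!is.null(sm$point_estimate)) sm$point_estimate <- as.numeric(sm$point_estimate)
    else sm$point_estimate <- NA_real_
    sm
  })
  list(records = records, summaries = summaries)
}

#' Read a cascade schedule from a plain-text file
#'
#' Tab-separated, comments with `#`. The first data line is
#' `ROOT<TAB>age<TAB>taxaA<TAB>taxaB`; each further line is
#' `clade<TAB>taxaA<TAB>taxaB<TAB>source` with comma-separated taxon
#' lists.
#'
#' @param path File path.
#' @return A [cascade_schedule].
#' @export
read_cascade_schedule <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 2L) stop(path, ": schedule needs a ROOT line and >= 1 level")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (parts[[1]][1] != "ROOT" || length(parts[[1]]) != 4L)
    stop(path, ": first line must be 'ROOT<TAB>age<TAB>taxaA<TAB>taxaB'")
  split_taxa <- function(s) trimws(strsplit(s, ",")[[1]])
  root_age <- as.numeric(parts[[1]][2])
  levels <- lapply(parts[-1], function(p) {
    if (length(p) != 4L)
      stop(path, ": malformed schedule line: ", paste(p, collapse = "\t"))
    list(clade = p[1], a = split_taxa(p[2]), b = split_taxa(p[3]),
         source = p[4])
  })
  cascade_schedule(split_taxa(parts[[1]][3]), split_taxa(parts[[1]][4]),
                   root_age, levels)
}

#' Write a cascade schedule to a plain-text file
#'
#' @param schedule A [cascade_schedule].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "cascade_schedule"))
  j <- function(x) paste(x, collapse = ",")
  lines <- c(
    "# cascade schedule: ROOT<TAB>age<TAB>taxaA<TAB>taxaB, then clade<TAB>taxaA<TAB>taxaB<TAB>source",
    paste("ROOT", format(schedule$root$age, digits = 15),
          j(schedule$root$a), j(schedule$root$b), sep = "\t"),
    vapply(schedule$levels, function(lv)
      paste(lv$clade, j(lv$a), j(lv$b), lv$source, sep = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}
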