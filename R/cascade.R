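#' Build a cascade calibration schedule
#'
#' The cascade anchors at a single root calibration (a split and an age in
#' MYA) and lists, in order, the clades to date. Each level names the clade,
#' its two daughter taxon sets (the split whose between-group distance
#' operationalizes the clade's TMRCA), and a calibration source: `"ROOT"`
#' or the name of an earlier level, whose filtered point estimate supplies
#' the calibration age and whose own split supplies the per-locus
#' calibration distance.
#'
#' @param root_a,root_b Taxon sets of the two sides of the root-calibration
#'   split.
#' @param root_age Root calibration age in MYA (> 0).
#' @param levels List of levels; each is a list with fields `clade`
#'   (character), `a`, `b` (disjoint taxon vectors) and `source`
#'   (`"ROOT"` or an earlier level's clade name).
#' @return Object of class `cascade_schedule`.
#' @export
cascade_schedule <- function(root_a, root_b, root_age, levels) {
  if (!is.numeric(root_age) || root_age <= 0) stop("root_age must be > 0")
  if (length(intersect(root_a, root_b)))
    stop("root split sides overlap")
  seen <- character(0)
  for (i in seq_along(levels)) {
    lv <- levels[[i]]
    if (!all(c("clade", "a", "b", "source") %in% names(lv)))
      stop("level ", i, ": needs fields clade, a, b, source")
    if (length(intersect(lv$a, lv$b)))
      stop("level ", lv$clade, ": daughter sets overlap")
    if (length(lv$a) == 0L || length(lv$b) == 0L)
      stop("level ", lv$clade, ": empty daughter set")
    if (!identical(lv$source, "ROOT") && !lv$source %in% seen)
      stop("level ", lv$clade, ": calibration source '", lv$source,
           "' is not ROOT and does not appear earlier in the schedule")
    seen <- c(seen, lv$clade)
  }
  if (anyDuplicated(seen)) stop("duplicated clade names in schedule")
  structure(list(root = list(a = root_a, b = root_b, age = root_age),
                 levels = levels),
            class = "cascade_schedule")
}

#' @export
print.cascade_schedule <- function(x, ...) {
  cat("<cascade_schedule> root calibration ", format(x$root$age),
      " MYA; ", length(x$levels), " levels:\n", sep = "")
  for (lv in x$levels)
    cat("  ", lv$clade, " (", length(lv$a), "|", length(lv$b),
        " taxa) <- ", lv$source, "\n", sep = "")
  invisible(x)
}

#' The default Draconinae cascade schedule
#'
#' Anchored at the 85 MYA root calibration (Mantheyus vs all other genera)
#' and cascading: root -> non-Mantheyus crown; non-Mantheyus ->
#' Draco+Ptyctolaemus and the groups 1-4 crown; groups 1-4 -> group 1
#' (Acanthosaura vs the Pseudocalotes lineage) and the groups 2/3/4
#' ancestor; groups 2/3/4 -> Salea|Calotes and the group 4 crown;
#' group 4 -> the Aphaniotis/Bronchocela/Gonocephalus node and the Sri
#' Lankan crown. The root-calibration split itself is included as the first
#' level ("Draconinae"), whose estimate is identically the calibration age
#' for every defined locus.
#'
#' @param tree A [dated_tree] carrying the fixture clades (default
#'   [build_fixture_tree()]).
#' @param root_age Root calibration in MYA (default 85).
#' @return A [cascade_schedule].
#' @export
default_schedule <- function(tree = build_fixture_tree(), root_age = 85) {
  ct <- function(nm) clade_taxa(tree, nm)
  lev <- function(clade, a, b, source) list(clade = clade, a = a, b = b,
                                            source = source)
  cascade_schedule(
    root_a = "Mantheyus", root_b = ct("NonMantheyus"), root_age = root_age,
    levels = list(
      lev("Draconinae", "Mantheyus", ct("NonMantheyus"), "ROOT"),
      lev("NonMantheyus", ct("DracoPtyctolaemus"), ct("Groups1to4"), "ROOT"),
      lev("DracoPtyctolaemus", "Draco", "Ptyctolaemus", "NonMantheyus"),
      lev("Groups1to4", ct("Group1"), ct("Groups234"), "NonMantheyus"),
      lev("Group1", "Acanthosaura", setdiff(ct("Group1"), "Acanthosaura"),
          "Groups1to4"),
      lev("Groups234", ct("SaleaCalotes"), ct("Group4"), "Groups1to4"),
      lev("SaleaCalotes", "Salea", "Calotes", "Groups234"),
      lev("Group4", ct("ABG"), ct("SriLanka"), "Groups234"),
      lev("ABG", "Aphaniotis", c("Bronchocela", "Gonocephalus"), "Group4"),
      lev("SriLanka", "Ceratophora", c("Lyriocephalus", "Cophotis"), "Group4")
    ))
}

#' Naive strict-clock age of one locus for one clade
#'
#' Under a strict clock, distance ratios equal age ratios: the locus's age
#' estimate is `T_cal * d_target / d_calibration`. Loci whose estimate
#' exceeds the calibration age are non-clock-like (discarded downstream as
#' likely affected by incomplete lineage sorting or rate variation); an
#' undefined calibration-side distance gives status `missing_outgroup`, an
#' undefined target-side distance (or a zero calibration distance, where no
#' rate is estimable) gives `undefined`. Ages exactly equal to the
#' calibration are clock-like, so the calibration split itself always
#' passes.
#'
#' @param d_target Corrected between-daughter distance for the clade
#'   (fraction, or `NA`).
#' @param d_calibration Corrected distance across the calibration split
#'   (fraction, or `NA`).
#' @param t_cal Calibration age in MYA (> 0).
#' @return List with `age` (MYA or `NA`) and `status` (one of
#'   `clock_like`, `non_clock_like`, `missing_outgroup`, `undefined`).
#' @examples
#' estimate_locus_age(0.10, 0.17, 85)  # 50 MYA, clock_like
#' @export
estimate_locus_age <- function(d_target, d_calibration, t_cal) {
  if (!is.numeric(t_cal) || length(t_cal) != 1L || is.na(t_cal) || t_cal <= 0)
    stop("calibration age must be a positive number")
  if (is.na(d_calibration))
    return(list(age = NA_real_, status = "missing_outgroup"))
  if (is.na(d_target) || d_calibration == 0)
    return(list(age = NA_real_, status = "undefined"))
  # ratio first: the calibration split itself then yields t_cal exactly
  age <- t_cal * (d_target / d_calibration)
  list(age = age,
       status = if (age <= t_cal) "clock_like" else "non_clock_like")
}

#' Summarize per-locus age records for one clade
#'
#' Five-number summary (minimum, lower quartile, median, upper quartile,
#' maximum) over the clock-like ages, with linear-interpolation quantiles
#' (type 7); status fractions over all attempted loci; point estimate =
#' median (or mean) of the clock-like ages.
#'
#' @param records Data frame of per-locus records for a single clade, with
#'   columns `age_estimate` and `status` (and `clade`).
#' @param point_estimator `"median"` (default) or `"mean"`.
#' @return List with `clade`, `n_loci_attempted`, `five_number`,
#'   `fractions` (`clock_like`, `non_clock_like`, `missing_outgroup`),
#'   and `point_estimate` (`NA` when no locus is clock-like).
#' @export
summarize_clade <- function(records, point_estimator = c("median", "mean")) {
  point_estimator <- match.arg(point_estimator)
  stopifnot(is.data.frame(records),
            all(c("age_estimate", "status") %in% names(records)))
  if ("clade" %in% names(records) && length(unique(records$clade)) > 1L)
    stop("records span more than one clade")
  n <- nrow(records)
  ages <- records$age_estimate[records$status == "clock_like"]
  five <- if (length(ages))
    stats::quantile(ages, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  else rep(NA_real_, 5)
  names(five) <- c("min", "q1", "median", "q3", "max")
  fr <- c(clock_like = if (n) mean(records$status == "clock_like") else 0,
          non_clock_like = if (n) mean(records$status == "non_clock_like") else 0,
          missing_outgroup = if (n) mean(records$status == "missing_outgroup") else 0)
  pe <- if (length(ages) == 0L) NA_real_
        else if (point_estimator == "median") stats::median(ages)
        else mean(ages)
  list(clade = if ("clade" %in% names(records) && n) records$clade[1] else NA_character_,
       n_loci_attempted = n,
       five_number = five,
       fractions = fr,
       point_estimate = pe)
}

#' Classify a lineage rate shift by outgroup triangulation
#'
#' Per locus, the mean root-to-tip path length on each side of the
#' ingroup/outgroup node is estimated by triangulation: the mean outgroup
#' depth is half the mean within-outgroup corrected distance, and the mean
#' ingroup depth is the mean cross ingroup-outgroup corrected distance
#' minus the outgroup depth. Depths are averaged over loci where both are
#' defined. Ingroup paths shorter than outgroup paths by more than
#' `threshold` (relative to the outgroup depth) indicate a rate slow-down;
#' longer, a speed-up.
#'
#' With a single outgroup taxon triangulation is impossible; if
#' `b_out_fallback` (per-locus outgroup depths, e.g. half the calibration
#' split's cross distance) is supplied it is used instead and the call is
#' flagged approximate, otherwise the call is `undefined`.
#'
#' @param tables List of [distance_table] objects (one per locus).
#' @param ingroup,outgroup Disjoint taxon sets; the outgroup needs at least
#'   two taxa for exact triangulation.
#' @param correction Saturation correction factor.
#' @param threshold Relative-difference threshold for a call (default
#'   0.05).
#' @param b_out_fallback Optional numeric vector (one per locus) of
#'   outgroup depths to use when the outgroup has a single taxon.
#' @return List with `call` (`slow_down`, `speed_up`, `none` or
#'   `undefined`), `b_ingroup`, `b_outgroup`, `relative_difference`,
#'   `n_loci` (loci contributing) and `approximate` (logical).
#' @export
classify_rate_shift <- function(tables, ingroup, outgroup, correction = 0.95,
                                threshold = 0.05, b_out_fallback = NULL) {
  if (length(intersect(ingroup, outgroup)))
    stop("ingroup and outgroup overlap")
  if (length(ingroup) < 1L || length(outgroup) < 1L)
    stop("ingroup and outgroup must each contain at least one taxon")
  single_out <- length(outgroup) == 1L
  if (single_out && is.null(b_out_fallback))
    return(list(call = "undefined", b_ingroup = NA_real_,
                b_outgroup = NA_real_, relative_difference = NA_real_,
                n_loci = 0L, approximate = TRUE))
  b_i <- b_o <- rep(NA_real_, length(tables))
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    cross <- group_distance(tb, ingroup, outgroup, correction)$distance
    if (is.na(cross)) next
    bo <- if (single_out) b_out_fallback[k] else {
      og <- intersect(outgroup, tb$taxa)
      if (length(og) < 2L) NA_real_ else {
        w <- tb$distance[og, og, drop = FALSE]
        w <- w[upper.tri(w)]
        w <- w[!is.na(w)]
        if (length(w) == 0L) NA_real_
        else mean(correct_saturation(w, correction)) / 2
      }
    }
    if (is.na(bo) || bo <= 0) next
    b_o[k] <- bo
    b_i[k] <- cross - bo
  }
  ok <- is.finite(b_i) & is.finite(b_o)
  if (!any(ok))
    return(list(call = "undefined", b_ingroup = NA_real_,
                b_outgroup = NA_real_, relative_difference = NA_real_,
                n_loci = 0L, approximate = TRUE))
  bi <- mean(b_i[ok]); bo <- mean(b_o[ok])
  rel <- (bi - bo) / bo
  call <- if (rel > threshold) "speed_up"
          else if (rel < -threshold) "slow_down"
          else "none"
  list(call = call, b_ingroup = bi, b_outgroup = bo,
       relative_difference = rel, n_loci = sum(ok),
       approximate = single_out)
}

# mean raw (uncorrected) cross-split distance per locus for one split
split_distance_vec <- function(tables, a, b) {
  vapply(tables, function(tb) group_distance(tb, a, b, correction = 1)$distance,
         numeric(1))
}

#' Run the cascade strict-clock dating pipeline
#'
#' Processes the schedule's levels in order. For each level and locus, the
#' target distance is the mean corrected distance between the clade's two
#' daughter sets and the calibration distance is the mean corrected
#' distance across the calibration source's defining split; the locus age
#' is `T_cal * d_target / d_calibration` with `T_cal` the source's filtered
#' (clock-like-only) point estimate (the root calibration age for
#' `"ROOT"`). Loci with ages above their calibration are flagged
#' non-clock-like and excluded from summaries; a level whose calibration
#' source retained no clock-like locus aborts with a "cascade starvation"
#' error. Each level also receives a rate-shift call, triangulated against
#' the sister taxa on the other side of its calibration split.
#'
#' The uniform saturation correction cancels in the age ratio, so
#' estimates are invariant to `correction`; raw (uncorrected) distances are
#' what the per-locus records store.
#'
#' @param loci List of [locus_alignment] objects (or of [distance_table]
#'   objects, which skips distance computation).
#' @param schedule A [cascade_schedule] (default [default_schedule()]).
#' @param correction Saturation correction factor (default 0.95).
#' @param min_overlap Minimum compared sites per pair (default 100).
#' @param point_estimator `"median"` (default) or `"mean"`.
#' @param shift_threshold Relative-difference threshold for rate-shift
#'   calls (default 0.05).
#' @param reference_ages Optional named numeric vector of externally
#'   supplied comparison ages (MYA) attached to matching clade summaries;
#'   annotations only, never used in computation.
#' @param verbose Log per-level calibrations and discard counts via
#'   `message()`.
#' @return Object of class `cascade_result`: `records` (data frame with
#'   columns `locus_id`, `clade`, `raw_distance_target`,
#'   `raw_distance_calibration`, `age_estimate`, `status`), `summaries`
#'   (named list of per-clade summaries), `schedule`, `correction`.
#' @export
run_cascade <- function(loci, schedule = default_schedule(),
                        correction = 0.95, min_overlap = 100,
                        point_estimator = c("median", "mean"),
                        shift_threshold = 0.05, reference_ages = NULL,
                        verbose = FALSE) {
  point_estimator <- match.arg(point_estimator)
  if (length(loci) == 0L) stop("no loci supplied")
  stopifnot(inherits(schedule, "cascade_schedule"))
  tables <- lapply(loci, function(x) {
    if (inherits(x, "distance_table")) x else distance_table(x, min_overlap)
  })
  locus_ids <- vapply(tables, `[[`, "", "locus_id")

  # raw cross distances per unique split, cached
  split_cache <- new.env(parent = emptyenv())
  split_key <- function(a, b)
    paste(paste(sort(a), collapse = ","), paste(sort(b), collapse = ","),
          sep = "||")
  get_split <- function(a, b) {
    key <- split_key(a, b)
    if (is.null(split_cache[[key]]))
      split_cache[[key]] <- split_distance_vec(tables, a, b)
    split_cache[[key]]
  }

  splits <- list(ROOT = list(a = schedule$root$a, b = schedule$root$b))
  point_est <- c(ROOT = schedule$root$age)
  records <- list()
  summaries <- list()

  for (lv in schedule$levels) {
    src <- splits[[lv$source]]
    if (is.null(src))
      stop("level ", lv$clade, ": unknown calibration source ", lv$source)
    t_cal <- point_est[[lv$source]]
    if (is.na(t_cal))
      stop("cascade starvation at level ", lv$clade,
           ": calibration source ", lv$source, " has no clock-like loci")
    d_t <- get_split(lv$a, lv$b)
    d_c <- get_split(src$a, src$b)
    est <- mapply(function(dt, dc) {
      # correction cancels in the ratio; apply it anyway for fidelity
      r <- estimate_locus_age(correct_saturation(dt, correction),
                              correct_saturation(dc, correction), t_cal)
      c(r$age, match(r$status, c("clock_like", "non_clock_like",
                                 "missing_outgroup", "undefined")))
    }, ifelse(is.na(d_t), NA_real_, d_t), ifelse(is.na(d_c), NA_real_, d_c))
    status <- c("clock_like", "non_clock_like", "missing_outgroup",
                "undefined")[est[2, ]]
    recs <- data.frame(locus_id = locus_ids, clade = lv$clade,
                       raw_distance_target = d_t,
                       raw_distance_calibration = d_c,
                       age_estimate = est[1, ], status = status,
                       stringsAsFactors = FALSE, row.names = NULL)
    records[[lv$clade]] <- recs
    sm <- summarize_clade(recs, point_estimator)
    sm$clade <- lv$clade
    sm$calibration_used <- list(source = lv$source, t_cal = unname(t_cal))

    # rate shift vs the sister side of the calibration split
    target_taxa <- c(lv$a, lv$b)
    src_all <- c(src$a, src$b)
    out <- if (all(target_taxa %in% src$a)) src$b
           else if (all(target_taxa %in% src$b)) src$a
           else setdiff(src_all, target_taxa)
    if (length(out) == 0L || setequal(target_taxa, src_all)) {
      sm$rate_shift <- list(call = NA_character_, approximate = NA)
    } else {
      fallback <- if (length(out) == 1L) correct_saturation(d_c, correction) / 2
                  else NULL
      sm$rate_shift <- classify_rate_shift(tables, target_taxa, out,
                                           correction, shift_threshold,
                                           b_out_fallback = fallback)
    }
    if (!is.null(reference_ages) && lv$clade %in% names(reference_ages))
      sm$reference_age <- unname(reference_ages[[lv$clade]])
    summaries[[lv$clade]] <- sm

    splits[[lv$clade]] <- list(a = lv$a, b = lv$b)
    point_est[[lv$clade]] <- sm$point_estimate
    if (verbose)
      message(sprintf(
        "level %s: T_cal=%.3f (from %s); point=%.3f; discarded %d/%d non-clock-like",
        lv$clade, t_cal, lv$source,
        if (is.na(sm$point_estimate)) NA else sm$point_estimate,
        sum(status == "non_clock_like"), length(status)))
  }

  structure(list(records = do.call(rbind, c(records, make.row.names = FALSE)),
                 summaries = summaries, schedule = schedule,
                 correction = correction),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result> ", length(x$summaries), " clades, ",
      length(unique(x$records$locus_id)), " loci\n", sep = "")
  for (sm in x$summaries)
    cat(sprintf("  %-18s point %7.2f MYA  (T_cal %7.2f from %s; %3.0f%% clock-like)\n",
                sm$clade,
                if (is.na(sm$point_estimate)) NA else sm$point_estimate,
                sm$calibration_used$t_cal, sm$calibration_used$source,
                100 * sm$fractions[["clock_like"]]))
  invisible(x)
}
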