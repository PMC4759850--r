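#' Pairwise Hamming distance with pairwise deletion
#'
#' Sites at which either sequence carries a missing character (`N`, `-` or
#' `?`) are excluded; the distance is the fraction of remaining (compared)
#' sites at which the two sequences differ. If fewer than `min_overlap`
#' sites remain the distance is undefined (`NA`) rather than noisy.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (strings or
#'   character vectors of single characters); case-insensitive.
#' @param min_overlap Minimum number of compared sites for a defined
#'   distance (default 100).
#' @return List with `distance` (fraction in `[0, 1]`, or `NA`) and
#'   `overlap` (number of compared sites).
#' @examples
#' p_distance("ACGT", "ACGA", min_overlap = 1)  # 0.25 over 4 sites
#' @export
p_distance <- function(seq_a, seq_b, min_overlap = 100) {
  a <- to_char_vec(seq_a)
  b <- to_char_vec(seq_b)
  if (length(a) != length(b))
    stop("sequences differ in length (", length(a), " vs ", length(b), ")")
  p_distance_chars(a, b, min_overlap)
}

to_char_vec <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "", fixed = TRUE)[[1]]
  s <- toupper(s)
  s[s == "?"] <- "N"
  s
}

# core kernel; assumes upper-case vectors of single characters
p_distance_chars <- function(a, b, min_overlap) {
  ok <- !(a %in% MISSING_CHARS) & !(b %in% MISSING_CHARS)
  overlap <- sum(ok)
  if (overlap < min_overlap)
    return(list(distance = NA_real_, overlap = overlap))
  list(distance = sum(a[ok] != b[ok]) / overlap, overlap = overlap)
}

#' Saturation correction of an observed distance
#'
#' Inflates an observed p-distance by a uniform multiplicative factor,
#' `d / c`, to compensate for unobserved multiple substitutions. Because
#' the strict-clock age estimator uses distance ratios, a uniform factor
#' cancels and cannot bias age estimates (asserted as a property test).
#'
#' @param d Observed distance(s) in `[0, 1]`; `NA` passes through.
#' @param c Correction factor in `(0, 1]`; default 0.95; `c = 1` is the
#'   identity.
#' @return Corrected distance(s).
#' @export
correct_saturation <- function(d, c = 0.95) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0 || c > 1)
    stop("correction factor must be a number in (0, 1]")
  if (any(d < 0 | d > 1, na.rm = TRUE)) stop("distances must lie in [0, 1]")
  d / c
}

#' Per-locus pairwise distance table
#'
#' Computes the full symmetric matrix of pairwise Hamming distances (with
#' pairwise deletion) and overlaps for one locus alignment.
#'
#' @param aln A [locus_alignment].
#' @param min_overlap Minimum compared sites per pair (default 100).
#' @return Object of class `distance_table`: `locus_id`, `taxa`,
#'   `distance` (matrix, `NA` where undefined), `overlap` (integer matrix).
#' @export
distance_table <- function(aln, min_overlap = 100) {
  stopifnot(inherits(aln, "locus_alignment"))
  m <- aln_matrix(aln)
  miss <- matrix(m %in% MISSING_CHARS, nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(NA_real_, n, n, dimnames = list(aln$taxa, aln$taxa))
  ov <- matrix(0L, n, n, dimnames = list(aln$taxa, aln$taxa))
  diag(d) <- 0
  diag(ov) <- as.integer(rowSums(!miss))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ok <- !miss[i, ] & !miss[j, ]
        no <- sum(ok)
        ov[i, j] <- ov[j, i] <- no
        if (no >= min_overlap) {
          dij <- sum(m[i, ok] != m[j, ok]) / no
          d[i, j] <- d[j, i] <- dij
        }
      }
    }
  }
  structure(list(locus_id = aln$locus_id, taxa = aln$taxa,
                 distance = d, overlap = ov, min_overlap = min_overlap),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("<distance_table> ", x$locus_id, ": ", length(x$taxa), " taxa, ",
      sum(is.na(x$distance[upper.tri(x$distance)])),
      " undefined pairs\n", sep = "")
  invisible(x)
}

#' Mean corrected distance between two taxon groups
#'
#' Averages the saturation-corrected pairwise distance over all defined
#' cross-group pairs present at the locus. Undefined (with `n_pairs = 0`)
#' when no cross-group pair has a defined distance - e.g. when one group is
#' entirely absent from the locus, the "missing outgroup" situation
#' downstream.
#'
#' @param table A [distance_table].
#' @param group_a,group_b Disjoint, non-empty character vectors of taxa.
#' @param correction Saturation correction factor (see
#'   [correct_saturation]).
#' @return List with `distance` (mean corrected cross-group distance or
#'   `NA`) and `n_pairs` (number of contributing pairs).
#' @export
group_distance <- function(table, group_a, group_b, correction = 0.95) {
  stopifnot(inherits(table, "distance_table"))
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  a <- intersect(group_a, table$taxa)
  b <- intersect(group_b, table$taxa)
  if (length(a) == 0L || length(b) == 0L)
    return(list(distance = NA_real_, n_pairs = 0L))
  vals <- table$distance[a, b, drop = FALSE]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    return(list(distance = NA_real_, n_pairs = 0L))
  list(distance = mean(correct_saturation(vals, correction)),
       n_pairs = length(vals))
}
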