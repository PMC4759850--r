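#' Construct a per-locus alignment object
#'
#' A `locus_alignment` holds one UCE locus: an identifier, the taxa present
#' at the locus, and their aligned sequences. Sequences are normalized to
#' upper case and `?` is mapped to `N`; the missing-data characters are
#' `N`, `-` and `?`, and all three are treated identically downstream.
#'
#' @param locus_id Character scalar naming the locus.
#' @param taxa Character vector of unique taxon labels.
#' @param sequences Character vector of aligned sequences (same order as
#'   `taxa`), all of identical length, over `A,C,G,T,N,-,?` (any case).
#' @return An object of class `locus_alignment` with fields `locus_id`,
#'   `taxa`, `sequences` (named by taxon) and `length`.
#' @examples
#' aln <- locus_alignment("uce-1", c("a", "b"), c("ACGT", "AC-T"))
#' aln$length
#' @export
locus_alignment <- function(locus_id, taxa, sequences) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L)
  taxa <- as.character(taxa)
  sequences <- toupper(as.character(sequences))
  sequences <- gsub("?", "N", sequences, fixed = TRUE)
  if (length(taxa) != length(sequences))
    stop("locus ", locus_id, ": taxa and sequences differ in length")
  if (anyDuplicated(taxa))
    stop("locus ", locus_id, ": duplicated taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  widths <- nchar(sequences)
  if (length(widths) == 0L || widths[1] < 1L)
    stop("locus ", locus_id, ": empty alignment")
  if (length(unique(widths)) != 1L) {
    off <- taxa[widths != widths[1]]
    stop("locus ", locus_id, ": ragged sequence lengths (taxa: ",
         paste(off, collapse = ", "), ")")
  }
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("locus ", locus_id, ": invalid characters in sequences of: ",
         paste(taxa[bad], collapse = ", "))
  allmiss <- !grepl("[ACGT]", sequences)
  if (any(allmiss))
    stop("locus ", locus_id, ": all-missing sequence for present taxa: ",
         paste(taxa[allmiss], collapse = ", "))
  structure(list(locus_id = locus_id, taxa = taxa,
                 sequences = setNames(sequences, taxa),
                 length = widths[1]),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_id, ": ", length(x$taxa), " taxa, ",
      x$length, " aligned sites\n", sep = "")
  invisible(x)
}

# alignment as a character matrix (taxa x sites)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(m) <- aln$taxa
  m
}

#' Read one UCE locus alignment from a FASTA file
#'
#' Mixed case is normalized to upper case and `?` to `N`. Ragged sequence
#' lengths are an error (inputs must be aligned).
#'
#' @param path Path to a FASTA file holding one aligned locus.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @return A [locus_alignment].
#' @export
read_locus_fasta <- function(path, locus_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L)
    stop(path, ": malformed FASTA, empty file (line 1)")
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop(path, ": malformed FASTA, expected '>' header at line ", nonempty[1])
  is_seq <- !startsWith(trimws(lines), ">") & nzchar(trimws(lines))
  bad <- which(is_seq & grepl("[^ACGTNacgtn?[:space:]-]", lines))
  if (length(bad))
    stop(path, ": malformed FASTA, invalid sequence characters at line ", bad[1])
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(path, ": malformed FASTA, no records")
  taxa <- sub("\\s.*$", "", names(set))
  locus_id <- locus_id %||% tools::file_path_sans_ext(basename(path))
  locus_alignment(locus_id, taxa, as.character(set))
}

#' Write a locus alignment to FASTA
#'
#' @param aln A [locus_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "locus_alignment"))
  set <- Biostrings::BStringSet(aln$sequences)
  names(set) <- aln$taxa
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Read a directory of per-locus FASTA files
#'
#' @param dir Directory containing one FASTA file per locus.
#' @param pattern File-name regexp for locus files.
#' @return Named list of [locus_alignment] objects (sorted by file name).
#' @export
read_locus_dir <- function(dir, pattern = "\\.(fa|fas|fasta)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no FASTA files found in ", dir)
  loci <- lapply(files, read_locus_fasta)
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  loci
}
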