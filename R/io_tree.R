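#' Construct a dated, rooted, ultrametric tree with named clades
#'
#' Wraps an `ape::phylo` tree whose branch lengths are durations in MYA.
#' Node ages are computed from the tips (age 0, all taxa extant) upward;
#' a root stem edge, if present, is ignored. Named clades map clade labels
#' to monophyletic taxon sets and are checked against the topology.
#'
#' @param phy A rooted `phylo` object with branch lengths in MYA.
#' @param clades Named list of character vectors: taxon sets per clade name.
#' @param tol Relative tolerance for the ultrametricity check (largest
#'   root-to-tip depth spread divided by tree depth).
#' @return Object of class `dated_tree`: fields `phy`, `root_age`, `ages`
#'   (per node, tips first as in `phylo` numbering), `clades`,
#'   `clade_nodes`.
#' @export
dated_tree <- function(phy, clades = list(), tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)   # root = 0
  tipd <- depth[seq_len(ntip)]
  root_age <- max(tipd)
  spread <- (max(tipd) - min(tipd)) / root_age
  if (spread > tol) {
    worst <- c(phy$tip.label[which.max(tipd)], phy$tip.label[which.min(tipd)])
    stop(sprintf(
      "tree is not ultrametric (relative depth spread %.3g > %.3g); worst tip pair: %s, %s",
      spread, tol, worst[1], worst[2]))
  }
  ages <- root_age - depth
  ages[seq_len(ntip)] <- 0
  clade_nodes <- integer(0)
  if (length(clades)) {
    if (is.null(names(clades)) || any(!nzchar(names(clades))))
      stop("clades must be a named list")
    clade_nodes <- vapply(names(clades), function(nm) {
      taxa <- clades[[nm]]
      miss <- setdiff(taxa, phy$tip.label)
      if (length(miss))
        stop("clade ", nm, ": taxa not in tree: ", paste(miss, collapse = ", "))
      if (length(taxa) < 2L)
        stop("clade ", nm, ": needs at least two taxa")
      node <- ape::getMRCA(phy, taxa)
      desc <- ape::extract.clade(phy, node)$tip.label
      if (!setequal(desc, taxa))
        stop("clade ", nm, " is not monophyletic: MRCA also contains ",
             paste(setdiff(desc, taxa), collapse = ", "))
      node
    }, integer(1))
  }
  structure(list(phy = phy, root_age = root_age, ages = ages,
                 clades = clades, clade_nodes = clade_nodes),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("<dated_tree> ", length(x$phy$tip.label), " tips, root age ",
      format(x$root_age), " MYA, ", length(x$clades), " named clades\n",
      sep = "")
  invisible(x)
}

#' Age of a named clade
#'
#' @param tree A [dated_tree].
#' @param clade Clade name.
#' @return Crown age of the clade in MYA.
#' @export
clade_age <- function(tree, clade) {
  stopifnot(inherits(tree, "dated_tree"))
  if (!clade %in% names(tree$clade_nodes)) stop("unknown clade: ", clade)
  unname(tree$ages[tree$clade_nodes[[clade]]])
}

#' Taxa of a named clade
#'
#' @inheritParams clade_age
#' @return Character vector of taxon labels.
#' @export
clade_taxa <- function(tree, clade) {
  stopifnot(inherits(tree, "dated_tree"))
  if (!clade %in% names(tree$clades)) stop("unknown clade: ", clade)
  tree$clades[[clade]]
}

#' Read a dated Newick tree
#'
#' Branch lengths are interpreted as durations in MYA; node ages are
#' computed from tip depth 0 upward, so a stem length on the root is
#' ignored. An accompanying clade table (see [read_clade_table]) attaches
#' named clades.
#'
#' @param path Newick file path.
#' @param clade_table Optional path to a clade table, or a named list of
#'   taxon vectors.
#' @param tol Relative ultrametricity tolerance.
#' @return A [dated_tree].
#' @export
read_dated_newick <- function(path, clade_table = NULL, tol = 1e-6) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop(path, ": could not parse Newick")
  clades <- list()
  if (!is.null(clade_table)) {
    clades <- if (is.character(clade_table)) read_clade_table(clade_table)
              else clade_table
  }
  dated_tree(phy, clades, tol)
}

#' Write a dated tree as Newick
#'
#' @param tree A [dated_tree].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dated_newick <- function(tree, path) {
  stopifnot(inherits(tree, "dated_tree"))
  ape::write.tree(tree$phy, file = path)
  invisible(path)
}

#' Read a clade table
#'
#' Plain-text format, one clade per line:
#' `clade_name<TAB>taxon1,taxon2,...`
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_clade_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad))
    stop(path, ": malformed clade table at line ", bad[1],
         " (expected 'name<TAB>taxa')")
  nm <- vapply(parts, `[[`, "", 1L)
  setNames(lapply(parts, function(p) trimws(strsplit(p[2], ",")[[1]])), nm)
}

#' Write a clade table
#'
#' @param clades Named list of taxon vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_table <- function(clades, path) {
  lines <- vapply(names(clades), function(nm)
    paste0(nm, "\t", paste(clades[[nm]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}
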