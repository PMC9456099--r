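#' Read a species tree, honouring PAML-style foreground marks
#'
#' Reads a newick tree with `ape` and interprets `#1` suffixes on tip or
#' internal node labels as foreground-branch marks (the branch leading to the
#' labelled node). Branch lengths are expected substitutions per codon site.
#'
#' @param path newick file; alternatively pass `text`.
#' @param text newick string (used when `path` is `NULL`).
#' @return an `ape::phylo` with an extra logical component `foreground` of
#'   length `nrow(tree$edge)` (all `FALSE` when no labels are present).
#' @export
read_species_tree <- function(path = NULL, text = NULL) {
  tr <- if (is.null(path)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick input")
  marks <- logical(nrow(tr$edge))
  ntip <- length(tr$tip.label)
  marked_nodes <- integer(0)
  hit <- grepl("#\\d+$", tr$tip.label)
  if (any(hit)) {
    marked_nodes <- c(marked_nodes, which(hit))
    tr$tip.label <- sub("#\\d+$", "", tr$tip.label)
  }
  if (!is.null(tr$node.label)) {
    nhit <- grepl("#\\d+$", tr$node.label)
    if (any(nhit)) {
      marked_nodes <- c(marked_nodes, ntip + which(nhit))
      tr$node.label <- sub("#\\d+$", "", tr$node.label)
    }
  }
  marks[match(marked_nodes, tr$edge[, 2L])] <- TRUE
  tr$foreground <- marks
  tr
}

#' Mark foreground branches on a tree
#'
#' The foreground may be given either as a character vector of leaf names
#' (their terminal branches are marked) or left as already embedded
#' `#1` marks from [read_species_tree()]. Both styles yield identical marks
#' for equivalent specifications.
#'
#' @param tree an `ape::phylo` (with or without a `foreground` component).
#' @param foreground character vector of leaf names; must be non-empty and
#'   all present in the tree.
#' @return the tree with its `foreground` logical edge component set.
#' @export
mark_foreground <- function(tree, foreground) {
  if (length(foreground) == 0L) stop("empty foreground set")
  miss <- setdiff(foreground, tree$tip.label)
  if (length(miss) > 0L)
    stop("foreground taxa not in tree: ", paste(miss, collapse = ", "))
  tips <- match(foreground, tree$tip.label)
  marks <- logical(nrow(tree$edge))
  marks[match(tips, tree$edge[, 2L])] <- TRUE
  tree$foreground <- marks
  tree
}

#' Logical foreground edge vector of a tree
#'
#' @param tree an `ape::phylo`, optionally carrying `foreground` marks.
#' @return logical vector over edges (all `FALSE` when unmarked).
#' @export
foreground_edges <- function(tree) {
  if (is.null(tree$foreground)) return(logical(nrow(tree$edge)))
  tree$foreground
}

#' Prune a marked tree to the taxa of an alignment
#'
#' Drops tips absent from `taxa` while preserving path lengths between the
#' retained leaves and remapping foreground marks (marks on removed or
#' collapsed branches are transferred to the merged branch when its retained
#' child was marked; marks whose entire subtree is dropped disappear).
#'
#' @param tree a marked `ape::phylo`.
#' @param taxa character vector of taxa to keep.
#' @return the pruned, marked tree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss) > 0L)
    stop("alignment taxa not in tree: ", paste(miss, collapse = ", "))
  drop <- setdiff(tree$tip.label, taxa)
  if (length(drop) == 0L) return(tree)
  fg_tips <- tree$tip.label[tree$edge[tree$foreground %||% logical(nrow(tree$edge)), 2L]]
  fg_tips <- fg_tips[!is.na(fg_tips)]
  ## internal foreground marks cannot be carried safely through pruning;
  ## re-derive marks from retained foreground tips.
  pruned <- ape::drop.tip(tree, drop)
  keep_fg <- intersect(fg_tips, pruned$tip.label)
  pruned$foreground <- logical(nrow(pruned$edge))
  if (length(keep_fg) > 0L) pruned <- mark_foreground(pruned, keep_fg)
  pruned
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tree with PAML-style foreground marks
#'
#' @param tree a marked `ape::phylo`.
#' @param path output newick file.
#' @export
write_species_tree <- function(tree, path) {
  tr <- tree
  fg <- foreground_edges(tr)
  ntip <- length(tr$tip.label)
  nodes <- tr$edge[fg, 2L]
  tipn <- nodes[nodes <= ntip]
  intn <- nodes[nodes > ntip]
  if (length(tipn) > 0L)
    tr$tip.label[tipn] <- paste0(tr$tip.label[tipn], "#1")
  if (length(intn) > 0L) {
    if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
    tr$node.label[intn - ntip] <- paste0(tr$node.label[intn - ntip], "#1")
  }
  tr$foreground <- NULL
  ape::write.tree(tr, file = path)
  invisible(path)
}
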