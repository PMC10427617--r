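#' Read phylogenies from Newick or NEXUS
#'
#' Thin wrapper over the `ape` readers that sniffs the format (a file whose
#' first non-blank characters are `#NEXUS` is NEXUS; otherwise Newick) and
#' always returns either a single `phylo` or a `multiPhylo` sample.
#'
#' @param file Path to a tree file.
#' @param format `"auto"` (default), `"newick"`, or `"nexus"`.
#' @return A `phylo` or `multiPhylo` object.
#' @export
read_trees <- function(file, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) "nexus"
              else "newick"
  }
  tr <- switch(format,
               newick = ape::read.tree(file),
               nexus = ape::read.nexus(file))
  if (is.null(tr)) stop("could not parse any tree from ", file)
  tr
}

#' Write a phylogeny to Newick or NEXUS
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param file Destination path.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return `file`, invisibly.
#' @export
write_tree <- function(tree, file, format = c("newick", "nexus")) {
  format <- match.arg(format)
  switch(format,
         newick = ape::write.tree(tree, file = file),
         nexus = ape::write.nexus(tree, file = file))
  invisible(file)
}

# Clades of a rooted tree as sorted tip-label signatures (one per internal
# node, including the root). Label-based, so signatures are comparable
# across trees whose internal tip orderings differ.
clade_signatures <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "\r"),
         character(1))
}

#' Maximum clade credibility tree of a sample
#'
#' Scores every member of a tree sample by the sum over its clades of the
#' log of that clade's frequency in the sample, and returns the
#' highest-scoring member with its own branch lengths retained
#' (TreeAnnotator-style selection; node heights are not re-summarized).
#' Per-clade support values (sample frequencies) are attached as node
#' labels.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) over one common tip set.
#' @return The selected `phylo`, with `node.label` set to clade support
#'   frequencies and attributes `mcc_score` (the log-credibility sum) and
#'   `mcc_index` (position of the selected tree in the sample).
#' @export
mcc_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0L) stop("empty tree sample")
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tipsets, identical, logical(1), tipsets[[1]]))) {
    stop("all trees in the sample must share one tip set")
  }
  sigs <- lapply(trees, clade_signatures)
  counts <- table(unlist(sigs))
  n <- length(trees)
  scores <- vapply(sigs, function(s) sum(log(counts[s] / n)), numeric(1))
  best <- which.max(scores)
  out <- trees[[best]]
  support <- as.numeric(counts[sigs[[best]]]) / n
  # prop.part lists internal nodes in increasing node-number order
  out$node.label <- format(support, digits = 3)
  attr(out, "clade_support") <- support
  attr(out, "mcc_score") <- scores[best]
  attr(out, "mcc_index") <- best
  out
}

#' Prune a tree to one representative species per genus
#'
#' Drops congeners until a single tip per genus remains, suppressing the
#' resulting unary nodes and summing their branch lengths (via
#' `ape::drop.tip`), so root-to-tip depths of surviving tips are unchanged.
#'
#' @param tree A `phylo`.
#' @param genus_map Named character vector mapping every tip label to its
#'   genus.
#' @param keep `"most_media"` (default; requires `media_counts`) or
#'   `"alphabetical"`. Ties under `"most_media"` are broken alphabetically.
#' @param media_counts Named numeric vector of media counts per tip label;
#'   required for `keep = "most_media"`. Tips missing from it count 0.
#' @return The pruned `phylo`; chosen representatives are recorded in the
#'   attribute `representatives` (genus -> tip).
#' @export
prune_to_one_per_genus <- function(tree, genus_map,
                                   keep = c("most_media", "alphabetical"),
                                   media_counts = NULL) {
  keep <- match.arg(keep)
  unmapped <- setdiff(tree$tip.label, names(genus_map))
  if (length(unmapped)) {
    stop("tips with no genus mapping: ", paste(head(unmapped, 5), collapse = ", "))
  }
  if (keep == "most_media" && is.null(media_counts)) {
    stop("keep = \"most_media\" requires media_counts")
  }
  genera <- genus_map[tree$tip.label]
  reps <- vapply(split(tree$tip.label, genera), function(tips) {
    tips <- sort(tips)
    if (keep == "most_media") {
      cnt <- media_counts[tips]
      cnt[is.na(cnt)] <- 0
      tips <- tips[order(-cnt, tips)]
    }
    tips[1]
  }, character(1))
  drop <- setdiff(tree$tip.label, reps)
  out <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  attr(out, "representatives") <- reps
  out
}

# Height of every node above the tips of an ultrametric tree.
node_heights_above_tips <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Graft a new tip at the midpoint of a clade's stem edge
#'
#' Attaches a taxon of unresolved position to an ultrametric tree the way
#' missing families are placed from coarse phylogenetic knowledge: the
#' attachment point is the midpoint of the branch subtending the given
#' clade, and the new tip's pendant branch is set so the tree remains
#' ultrametric.
#'
#' @param tree An ultrametric `phylo`.
#' @param new_tip Label of the taxon to add.
#' @param attachment Character vector of tip labels spanning the attachment
#'   clade (their MRCA), or a single tip label.
#' @param tol Relative ultrametricity tolerance (default 1e-6).
#' @return The `phylo` with one extra tip.
#' @export
graft_at_midpoint <- function(tree, new_tip, attachment, tol = 1e-6) {
  if (!ape::is.ultrametric(tree, tol = tol * max(node_heights_above_tips(tree)))) {
    stop("tree is not ultrametric within tolerance")
  }
  if (new_tip %in% tree$tip.label) stop("tip ", new_tip, " already present")
  missing <- setdiff(attachment, tree$tip.label)
  if (length(missing)) {
    stop("attachment tips not in tree: ", paste(missing, collapse = ", "))
  }
  node <- if (length(attachment) == 1L) {
    match(attachment, tree$tip.label)
  } else {
    ape::getMRCA(tree, attachment)
  }
  root <- ape::Ntip(tree) + 1L
  if (node == root) stop("attachment clade is the root: no stem edge to split")
  stem <- which(tree$edge[, 2] == node)
  stem_len <- tree$edge.length[stem]
  h <- node_heights_above_tips(tree)
  attach_height <- h[node] + stem_len / 2
  out <- phytools::bind.tip(tree, new_tip, edge.length = attach_height,
                            where = node, position = stem_len / 2)
  out
}
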