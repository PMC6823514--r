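#' Time-calibrated species trees with explicit units and lineage tags
#'
#' A `species_tree` is an [ape::read.tree()]-style `phylo` object carrying two
#' extra pieces of metadata: the unit of its branch lengths (`"myr"`, millions
#' of years, or `"subs"`, expected substitutions per site) and an optional map
#' from tip labels to lineage tags (e.g. `"snake"`, `"agamid"`,
#' `"pleurodont"`, `"outgroup"`). Units are carried explicitly and never
#' inferred from magnitudes.
#'
#' @param phy a rooted `phylo` object with non-negative branch lengths.
#' @param units `"myr"` or `"subs"`.
#' @param lineages optional named character vector: `names()` are tip labels,
#'   values are lineage tags. Tips absent from the map are untagged.
#' @return `phy` with attributes `units` and `lineages`, class unchanged
#'   (`phylo`) so all ape machinery keeps working.
#' @export
species_tree <- function(phy, units = c("myr", "subs"), lineages = NULL) {
  units <- match.arg(units)
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object")
  ## treated as rooted at the phylo root node; basal polytomies are allowed
  if (sum(!(unique(phy$edge[, 1]) %in% phy$edge[, 2])) != 1L)
    stop("tree must have a single root")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (!is.null(lineages)) {
    bad <- setdiff(names(lineages), phy$tip.label)
    if (length(bad) > 0)
      stop("lineage map names absent from tree: ", paste(bad, collapse = ", "))
  }
  attr(phy, "units") <- units
  attr(phy, "lineages") <- lineages
  phy
}

#' @rdname species_tree
#' @param file path to a newick file (branch lengths mandatory).
#' @export
read_species_tree <- function(file, units = c("myr", "subs"), lineages = NULL) {
  species_tree(ape::read.tree(file), units = units, lineages = lineages)
}

#' @rdname species_tree
#' @param tree a `species_tree`.
#' @export
tree_units <- function(tree) {
  u <- attr(tree, "units")
  if (is.null(u)) stop("tree carries no unit flag; build it with species_tree()")
  u
}

#' @rdname species_tree
#' @export
tree_lineages <- function(tree) attr(tree, "lineages")

#' Tips belonging to a lineage tag (or a single tip named directly)
#'
#' @param tree a `species_tree`.
#' @param lineage a lineage tag present in the tree's lineage map, or a tip
#'   label.
#' @return character vector of tip labels.
#' @export
lineage_tips <- function(tree, lineage) {
  lin <- tree_lineages(tree)
  if (!is.null(lin) && lineage %in% lin) return(names(lin)[lin == lineage])
  if (lineage %in% tree$tip.label) return(lineage)
  stop("lineage '", lineage, "' matches no lineage tag and no tip label")
}

#' Convert a time tree (Myr) to expected substitutions per site
#'
#' Multiplies every branch by `mu * 1e6` (substitutions/site per Myr) and
#' flips the unit flag. The original Myr lengths are retained as an attribute
#' so that scenario windows, which are defined on the time axis, can still be
#' located on the transformed tree.
#'
#' @param tree a `species_tree` in Myr units.
#' @param calib a [rate_calibration()].
#' @return a `species_tree` in `"subs"` units with attribute `myr_lengths`.
#' @export
myr_to_substitutions <- function(tree, calib = rate_calibration()) {
  if (tree_units(tree) != "myr") stop("tree is not in Myr units")
  myr <- tree$edge.length
  tree$edge.length <- myr * calib$mu * 1e6
  attr(tree, "units") <- "subs"
  attr(tree, "myr_lengths") <- myr
  tree
}

## Internal: edge indices on the path root -> tip, ordered tip-upwards.
path_edges_to_root <- function(tree, node) {
  e <- tree$edge
  root <- ape::Ntip(tree) + 1L
  out <- integer(0)
  cur <- node
  while (cur != root) {
    i <- which(e[, 2] == cur)
    if (length(i) != 1L) stop("malformed tree edge matrix")
    out <- c(out, i)
    cur <- e[i, 1]
  }
  out
}

node_id <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(label, tree$node.label)
    if (!is.na(j)) return(ape::Ntip(tree) + j)
  }
  stop("node '", label, "' not found in tree")
}

#' Cumulative branch length from an ancestor down to a leaf
#'
#' Sums branch lengths on the path from `ancestor` (exclusive) to `leaf`
#' (inclusive), i.e. the total length accumulated by the leaf since that
#' ancestor. Used to make per-species estimates comparable when groups share
#' a common ancestor ("from the last common ancestor until the present").
#'
#' @param tree a `species_tree` (any units).
#' @param leaf tip label.
#' @param ancestor internal node: a node label, or an integer node id, or
#'   `"root"`.
#' @return numeric scalar.
#' @export
cumulative_length <- function(tree, leaf, ancestor) {
  tip <- match(leaf, tree$tip.label)
  if (is.na(tip)) stop("leaf '", leaf, "' not found")
  anc <- if (identical(ancestor, "root")) ape::Ntip(tree) + 1L
         else if (is.numeric(ancestor)) as.integer(ancestor)
         else node_id(tree, ancestor)
  path <- path_edges_to_root(tree, tip)          # tip-upwards
  parents <- tree$edge[path, 1]
  if (anc == ape::Ntip(tree) + 1L) {
    keep <- path
  } else {
    hit <- match(anc, parents)
    if (is.na(hit)) stop("ancestor is not on the root-to-leaf path of '", leaf, "'")
    keep <- path[seq_len(hit)]
  }
  sum(tree$edge.length[keep])
}

#' Most recent common ancestor node id of a set of tips
#'
#' @param tree a `species_tree`.
#' @param tips character vector of tip labels (length >= 1).
#' @return integer node id (a tip's parent if a single tip is given).
#' @export
mrca_node <- function(tree, tips) {
  ids <- match(tips, tree$tip.label)
  if (anyNA(ids)) stop("unknown tips: ", paste(tips[is.na(ids)], collapse = ", "))
  if (length(ids) == 1L) return(tree$edge[tree$edge[, 2] == ids, 1])
  ape::getMRCA(tree, ids)
}
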