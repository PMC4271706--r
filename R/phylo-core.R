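# Dated-tree utilities. Trees are ape "phylo" objects throughout; ages are
# Myr before present, with the deepest tip defining age 0 (extant taxa sit
# at age 0 on an ultrametric tree).

#' Parse a Newick string into a dated phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is
#' an `ape` `phylo` object that has passed [validate_dated_tree()]: every
#' branch has a finite non-negative length and tip labels are unique. Node
#' ages (Myr before present) are derived on demand by [node_ages()].
#' Square-bracket comments are ignored and internal node labels are kept as
#' metadata, following common Newick practice.
#'
#' @param text A single character string holding one well-formed Newick
#'   description with branch lengths.
#' @return A `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single Newick string")
  text <- gsub("\\[[^]]*\\]", "", text)
  n_open <- nchar(gsub("[^(]", "", text))
  n_close <- nchar(gsub("[^)]", "", text))
  if (n_open != n_close)
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')') in ", substr(text, 1, 60))
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error near: ", substr(text, 1, 60))
  validate_dated_tree(tr)
}

#' Validate a dated phylogeny
#'
#' Checks the invariants every downstream stage relies on: a single root,
#' finite non-negative branch lengths on every edge, and unique tip labels.
#' Parent age strictly exceeds child age on every positive-length branch by
#' construction of [node_ages()].
#'
#' @param tree A `phylo` object.
#' @param require_ultrametric If `TRUE`, additionally require all tips at
#'   age 0 (within `tol`). Stages that need extant-only trees set this.
#' @param tol Numerical tolerance for the ultrametricity check.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_dated_tree <- function(tree, require_ultrametric = FALSE,
                                tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; dated trees require them")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("non-finite or missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  ntab <- tabulate(tree$edge[, 2], nbins = max(tree$edge))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(root)) != 1L) stop("tree must have exactly one root")
  if (any(ntab[unique(tree$edge[, 2])] > 1L))
    stop("a node has more than one parent")
  if (require_ultrametric) {
    ages <- node_ages(tree)
    if (any(abs(ages[seq_len(ape::Ntip(tree))]) > tol))
      stop("tree is not ultrametric: extinct or non-contemporaneous tips")
  }
  invisible(tree)
}

#' Node ages in Myr before present
#'
#' Ages are root-to-node depths subtracted from the total tree depth, so the
#' deepest tip sits at age 0 and the root at the crown age. On an
#' ultrametric tree all tips have age 0.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric vector of ages indexed by ape node number
#'   (tips `1..n`, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Root age (crown age) of a dated tree
#' @param tree A `phylo` object.
#' @return Age of the root in Myr.
#' @export
root_age <- function(tree) max(ape::node.depth.edgelength(tree))

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the path joining two tips through their most
#' recent common ancestor. Symmetric; zero for a tip against itself.
#'
#' @param tree A `phylo` object.
#' @param a,b Tip labels.
#' @return Path length in Myr.
#' @export
patristic_distance <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("unknown tip label: ", a)
  if (is.na(ib)) stop("unknown tip label: ", b)
  if (ia == ib) return(0)
  d <- ape::dist.nodes(tree)
  unname(d[ia, ib])
}

#' Drop tips from a dated tree
#'
#' Removes the named tips, suppressing the degree-2 nodes this creates and
#' merging their branch lengths, so the ages of all retained nodes are
#' unchanged.
#'
#' @param tree A `phylo` object.
#' @param drop Character vector of tip labels to remove (labels not present
#'   are ignored). At least two tips must remain.
#' @return The pruned `phylo` object.
#' @export
prune_tips <- function(tree, drop) {
  drop <- intersect(drop, tree$tip.label)
  if (length(drop) == 0L) return(tree)
  keep <- setdiff(tree$tip.label, drop)
  if (length(keep) < 2L)
    stop("pruning would leave fewer than 2 tips")
  ape::keep.tip(tree, keep)
}

#' Write a tree (or list of trees) as Newick text
#' @param tree A `phylo` object or list of them.
#' @param path Optional file path; if `NULL` the Newick string(s) are
#'   returned.
#' @return Character vector of Newick strings (invisibly when writing).
#' @export
write_newick <- function(tree, path = NULL) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  txt <- vapply(tree, function(t) ape::write.tree(t), character(1))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a tree ensemble from a multi-tree Newick file
#'
#' One tree per line (the usual bootstrap-ensemble format). Every tree is
#' validated and all trees must share one tip-label universe; the ensemble
#' is the unit of uncertainty for downstream summaries.
#'
#' @param path File of Newick strings, one per line.
#' @return A list of `phylo` objects with class `tree_ensemble`.
#' @export
read_tree_ensemble <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ensemble file: ", path)
  trees <- lapply(lines, parse_newick)
  as_tree_ensemble(trees)
}

#' Assemble a validated tree ensemble
#' @param trees List of `phylo` objects sharing one tip-label set.
#' @return The list, classed `tree_ensemble`.
#' @export
as_tree_ensemble <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("ensemble must contain at least one tree")
  lapply(trees, validate_dated_tree)
  labs <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), labs))
      stop("tree ", i, " does not share the ensemble tip-label universe")
  }
  structure(trees, class = c("tree_ensemble", "list"))
}

# parent of each node (0 for root), indexed by node number
parent_vector <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# nodes on the path root -> node, inclusive
root_path <- function(tree, node) {
  p <- parent_vector(tree)
  path <- node
  while (p[node] != 0L) {
    node <- p[node]
    path <- c(node, path)
  }
  path
}

# descendant tip indices of a node
descendant_tips <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}
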