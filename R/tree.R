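## Rooted-phylogeny utilities: Newick I/O, validation, edge bookkeeping,
## BLADJ-style node dating, and patristic distances.  Trees are ape "phylo"
## objects throughout; an "edge" is a row index into tree$edge.

#' Read a rooted phylogeny from Newick
#'
#' Thin wrapper around [ape::read.tree()] adding the validation the
#' downstream metrics rely on: a single root, unique tip labels, and
#' non-negative branch lengths.  Spaces in labels are replaced by
#' underscores (the Phylomatic convention), so community tables and trees
#' match on the same strings.
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text a Newick string.
#' @return an object of class `"phylo"`.
#' @export
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)  # 5
read_newick <- function(file = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(file = file) else ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick input")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree")
  tr$tip.label <- gsub(" ", "_", tr$tip.label, fixed = TRUE)
  if (!is.null(tr$node.label)) tr$node.label <- gsub(" ", "_", tr$node.label, fixed = TRUE)
  validate_tree(tr)
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree a `"phylo"` object.
#' @param file output path; when `NULL` the Newick string is returned.
#' @return the file path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(file)
}

## Structural invariants shared by all metrics.  ape guarantees most of the
## edge-table structure; we re-check what user-supplied trees can break.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  nt <- length(tree$tip.label)
  parents <- tabulate(tree$edge[, 2], nbins = nt + tree$Nnode)
  if (any(parents > 1)) stop("node with more than one parent")
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(roots)) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

root_node <- function(tree) length(tree$tip.label) + 1L

## For every node, the index of the edge leading into it (0 for the root).
incoming_edge <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  inc <- integer(n)
  inc[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  inc
}

## List, per tip, of the edge indices on the root-to-tip path.
tip_edge_paths <- function(tree) {
  inc <- incoming_edge(tree)
  root <- root_node(tree)
  parent <- integer(length(inc))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_along(tree$tip.label), function(tip) {
    path <- integer(0)
    v <- tip
    while (v != root) {
      e <- inc[v]
      path <- c(path, e)
      v <- parent[v]
    }
    path
  })
}

## Sparse edges x tips incidence: 1 when the edge lies on the root-to-tip
## path.  The workhorse behind PD, PhyloSorenson, WPE and AED.
edge_tip_incidence <- function(tree) {
  paths <- tip_edge_paths(tree)
  Matrix::sparseMatrix(
    i = unlist(paths),
    j = rep(seq_along(paths), lengths(paths)),
    x = 1,
    dims = c(nrow(tree$edge), length(tree$tip.label)),
    dimnames = list(NULL, tree$tip.label)
  )
}

#' Edges spanning a set of taxa
#'
#' Returns the union of edges on the root-to-tip paths of the given taxa:
#' the minimum spanning path connecting the taxa to the root.  The total
#' branch length over these edges is Faith's PD.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param taxa character vector of tip names (non-empty).
#' @return integer vector of edge indices (rows of `tree$edge`).
#' @export
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' sum(tr$edge.length[spanning_edges(tr, c("A", "B"))])  # 3
spanning_edges <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("empty taxa set")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  idx <- match(taxa, tree$tip.label)
  paths <- tip_edge_paths(tree)
  sort(unique(unlist(paths[idx])))
}

#' Patristic distance matrix
#'
#' Pairwise path-length distances between all tips, in the tip-label order
#' of the tree.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
tip_distance_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Node ages of a dated tree
#'
#' Ages (time before present) for all nodes, computed from root-to-node path
#' lengths; only meaningful for ultrametric (dated) trees, for which all tip
#' ages are zero.
#'
#' @param tree a dated `"phylo"` object.
#' @return numeric vector over tips then internal nodes (ape node numbering).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' BLADJ-style node dating
#'
#' Assigns ages to undated internal nodes by spacing them evenly (in age)
#' between their nearest dated ancestor and nearest dated descendant, then
#' recomputes every branch length as parent age minus child age.  Tips have
#' age zero; the root must be calibrated.  Nodes are processed root-ward
#' first (preorder), so ages are always interpolated below an already-dated
#' parent and branch lengths come out non-negative.
#'
#' @param tree a `"phylo"` object whose internal nodes carry labels
#'   (`tree$node.label`) for the calibrated nodes.
#' @param calibrations data frame with columns `node_label` and `age`
#'   (ages in Myr; see [read_calibrations()]).
#' @return the tree with new `edge.length` and a `node.ages` component
#'   (ages over tips then internal nodes).
#' @export
bladj_date <- function(tree, calibrations) {
  stopifnot(is.data.frame(calibrations),
            all(c("node_label", "age") %in% names(calibrations)))
  if (any(calibrations$age < 0)) stop("calibration ages must be non-negative")
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  if (is.null(tree$node.label)) stop("tree has no internal node labels")
  lab2node <- match(calibrations$node_label, tree$node.label)
  if (anyNA(lab2node))
    stop("calibration labels not found in tree: ",
         paste(calibrations$node_label[is.na(lab2node)], collapse = ", "))
  age <- rep(NA_real_, nt + nn)
  age[seq_len(nt)] <- 0
  fixed <- c(rep(TRUE, nt), rep(FALSE, nn))  # tips are dated at 0
  age[nt + lab2node] <- calibrations$age
  fixed[nt + lab2node] <- TRUE
  root <- root_node(tree)
  if (!fixed[root]) stop("root must be calibrated")

  ## children lists and a preorder of internal nodes
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(nt + nn)))
  preorder <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v > nt) {
      preorder <- c(preorder, v)
      stack <- c(stack, kids[[v]])
    }
  }

  ## ancestry consistency of the calibrations themselves
  parent <- integer(nt + nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  for (v in preorder) {
    if (v == root || !fixed[v] || is.na(age[v])) next
    a <- parent[v]
    while (a != root && !fixed[a]) a <- parent[a]
    if (fixed[a] && !is.na(age[a]) && age[a] <= age[v] && a != v)
      stop("calibration violates ancestry: node aged ", age[v],
           " below ancestor aged ", age[a])
  }

  ## nearest dated descendant (fewest edges, ties to the older age)
  nearest_dated_below <- function(v) {
    frontier <- kids[[v]]
    steps <- 1L
    repeat {
      dated <- frontier[fixed[frontier]]
      if (length(dated))
        return(list(age = max(age[dated]), steps = steps))
      frontier <- unlist(kids[frontier], use.names = FALSE)
      if (!length(frontier)) stop("internal node with no dated descendant")
      steps <- steps + 1L
    }
  }

  for (v in preorder) {
    if (fixed[v]) next
    p_age <- age[parent[v]]
    nd <- nearest_dated_below(v)
    est <- p_age - (p_age - nd$age) / (nd$steps + 1)
    age[v] <- min(est, p_age)  # guard against age inversion
  }

  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  tree$node.ages <- age
  tree
}

#' Read a node-age calibration table
#'
#' Two-column CSV (`node_label`, `age`) mapping internal-node labels to fixed
#' ages in Myr; tips are implicitly aged zero.
#'
#' @param file CSV path.
#' @return a data frame with columns `node_label` and `age`.
#' @export
read_calibrations <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop("calibration table needs two columns (node_label, age)")
  names(x)[1:2] <- c("node_label", "age")
  x$age <- as.numeric(x$age)
  if (anyNA(x$age)) stop("non-numeric calibration ages")
  x[, c("node_label", "age")]
}
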