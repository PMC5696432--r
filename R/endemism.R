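## Weighted phylogenetic endemism, abundance-weighted evolutionary
## distinctiveness, and imbalance of abundances at clade level.

#' Clade range sizes
#'
#' For every edge of the tree, the number of spatial units (plots, or 0.5
#' degree grid cells when coordinates are supplied) occupied by at least one
#' individual of any tip descending from that edge.  Ranges are monotonically
#' non-decreasing root-ward.
#'
#' @param tree a `"phylo"` object, aligned with `cm`.
#' @param cm community matrix.
#' @param unit `"plot"` or `"grid"`.
#' @param coords plot coordinates (data frame with `lon`, `lat`, rownames =
#'   plot IDs); required when `unit = "grid"`.
#' @param cell_size grid cell size in degrees.
#' @return integer vector of range sizes, one per edge (rows of `tree$edge`).
#' @export
clade_ranges <- function(tree, cm, unit = c("plot", "grid"), coords = NULL,
                         cell_size = 0.5) {
  unit <- match.arg(unit)
  cm <- as_community(cm)[, tree$tip.label, drop = FALSE]
  p01 <- (cm > 0) * 1
  if (unit == "grid") {
    if (is.null(coords)) stop("coordinates required when unit = \"grid\"")
    coords <- coords[rownames(cm), , drop = FALSE]
    cellid <- paste(floor(coords$lon / cell_size), floor(coords$lat / cell_size))
    p01 <- rowsum(p01, cellid) > 0
    p01 <- p01 * 1
  }
  E <- spanning_by_plot(edge_tip_incidence(tree), p01)
  as.integer(rowSums(E))
}

#' Weighted phylogenetic endemism
#'
#' Faith's PD with every branch down-weighted by the geographic range of the
#' clade it subtends: `WPE(plot) = sum over spanning edges of
#' branch_length / clade_range`.  High values flag concentrations of
#' range-restricted lineages.  `WPE <= PD` always, with equality when every
#' range equals one unit.
#'
#' @param tree a `"phylo"` object, aligned with `cm`.
#' @param cm community matrix.
#' @param ranges per-edge range sizes from [clade_ranges()]; computed with
#'   plot units when omitted.
#' @return named numeric vector, one WPE value per plot.
#' @export
weighted_phylogenetic_endemism <- function(tree, cm, ranges = NULL) {
  cm <- as_community(cm)[, tree$tip.label, drop = FALSE]
  if (is.null(ranges)) ranges <- clade_ranges(tree, cm)
  if (length(ranges) != nrow(tree$edge)) stop("ranges must cover all edges")
  E <- spanning_by_plot(edge_tip_incidence(tree), (cm > 0) * 1)
  w <- ifelse(ranges > 0, tree$edge.length / ranges, 0)
  setNames(colSums(E * w), rownames(cm))
}

#' Abundance-weighted evolutionary distinctiveness
#'
#' Apportions each branch on the path from a species to the root equally
#' among the individuals (in the focal plot) descending from that branch:
#' `AED_i = sum over path edges e of branch_length_e / n_e`, with `n_e` the
#' number of individuals below edge `e`.  Summing `n_i * AED_i` over species
#' recovers the plot's Faith PD exactly (each branch is partitioned across
#' precisely its descendants).
#'
#' @param tree a `"phylo"` object, aligned with `cm`.
#' @param cm community matrix.
#' @param plot plot identifier (rowname of `cm`).
#' @param per_species logical; divide branches by descendant *species*
#'   counts instead of individuals (an incidence-based variant).
#' @return named numeric vector of AED values for species present.
#' @export
aed <- function(tree, cm, plot, per_species = FALSE) {
  cm <- as_community(cm)[, tree$tip.label, drop = FALSE]
  if (!plot %in% rownames(cm)) stop("unknown plot: ", plot)
  n <- cm[plot, ]
  present <- which(n > 0)
  if (!length(present)) stop("plot has zero individuals")
  inc <- edge_tip_incidence(tree)
  weightvec <- if (per_species) (n > 0) * 1 else as.numeric(n)
  n_e <- as.numeric(inc %*% weightvec)          # individuals below each edge
  contrib <- ifelse(n_e > 0, tree$edge.length / n_e, 0)
  vals <- as.numeric(Matrix::crossprod(inc[, present, drop = FALSE], contrib))
  setNames(vals, colnames(cm)[present])
}

#' Imbalance of abundances at clade level
#'
#' Compares a plot's species abundances with the expectation that
#' individuals split evenly at every node of the plot-pruned tree: the
#' expected abundance of species i is `N * prod(1/d_k)` over the internal
#' nodes k on its root path, with `d_k` the number of daughter lineages
#' (polytomies split `1/d_k`).  IAC is the mean absolute deviation per
#' internal node: `sum |n_i - nhat_i| / v`.
#'
#' @param tree a `"phylo"` object, aligned with `cm`.
#' @param cm community matrix.
#' @param plot plot identifier.
#' @return IAC (individuals per node); `NA` for single-species plots, which
#'   have no internal splits.
#' @export
iac <- function(tree, cm, plot) {
  cm <- as_community(cm)[, tree$tip.label, drop = FALSE]
  if (!plot %in% rownames(cm)) stop("unknown plot: ", plot)
  n <- cm[plot, ]
  sp <- colnames(cm)[n > 0]
  if (!length(sp)) stop("plot has zero individuals")
  if (length(sp) == 1L) return(NA_real_)
  sub <- ape::keep.tip(tree, sp)                # collapses single-child nodes
  N <- sum(n)
  nt <- length(sub$tip.label)
  n_child <- tabulate(sub$edge[, 1], nbins = nt + sub$Nnode)
  paths <- tip_edge_paths(sub)                  # edges on each root path
  nhat <- vapply(seq_len(nt), function(tip) {
    parents <- sub$edge[paths[[tip]], 1]        # internal nodes crossed
    N / prod(n_child[parents])
  }, numeric(1))
  sum(abs(n[sub$tip.label] - nhat)) / sub$Nnode
}

#' Per-plot endemism summary
#'
#' Convenience wrapper computing WPE, IAC and the mean AED of species
#' present, for every plot.
#'
#' @param tree a `"phylo"` object, aligned with `cm`.
#' @param cm community matrix.
#' @param ranges optional precomputed [clade_ranges()].
#' @return data frame: `plot_id`, `WPE`, `IAC`, `mean_AED`.
#' @export
endemism_table <- function(tree, cm, ranges = NULL) {
  cm <- as_community(cm)[, tree$tip.label, drop = FALSE]
  wpe <- weighted_phylogenetic_endemism(tree, cm, ranges)
  iacv <- vapply(rownames(cm), function(p) iac(tree, cm, p), numeric(1))
  maed <- vapply(rownames(cm), function(p) mean(aed(tree, cm, p)), numeric(1))
  data.frame(plot_id = rownames(cm), WPE = wpe, IAC = iacv, mean_AED = maed,
             row.names = NULL, stringsAsFactors = FALSE)
}
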