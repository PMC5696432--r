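## Pairwise taxonomic and phylogenetic dissimilarity (1-Sorenson,
## 1-PhyloSorenson) and the independent-swap null expectation for the latter.
## Dissimilarity matrices are plain symmetric matrices in [0,1] with a zero
## diagonal and a "metric" attribute.

dissim <- function(m, metric) {
  diag(m) <- 0
  m[m < 0] <- 0       # clip numerical fuzz
  m[m > 1] <- 1
  attr(m, "metric") <- metric
  m
}

#' Taxonomic dissimilarity (1 - Sorenson)
#'
#' Incidence-based: for two plots sharing `a` species with `b` and `c`
#' unique, dissimilarity is `1 - 2a / (2a + b + c)`.
#'
#' @param cm community matrix (plots x species).
#' @return symmetric plot x plot matrix, metric `"TBD"`.
#' @export
sorenson_matrix <- function(cm) {
  cm <- as_community(cm)
  if (nrow(cm) < 2) stop("need at least 2 plots")
  p <- (cm > 0) * 1
  if (any(rowSums(p) == 0)) stop("plot with zero species")
  a <- tcrossprod(p)                       # shared species counts
  s <- rowSums(p)
  dissim(1 - 2 * a / outer(s, s, "+"), "TBD")
}

#' Abundance-based Bray-Curtis dissimilarity
#'
#' Provided as a labelled extra alongside the incidence-based indices.
#'
#' @param cm community matrix.
#' @return symmetric plot x plot matrix, metric `"BC"`.
#' @export
bray_curtis_matrix <- function(cm) {
  d <- as.matrix(vegan::vegdist(as_community(cm), method = "bray"))
  dissim(d, "BC")
}

## Edges x plots spanning incidence (logical) given a sparse edge-tip
## incidence and a binary plot matrix; shared branch length falls out of one
## crossprod.
spanning_by_plot <- function(inc, p01) {
  as.matrix(inc %*% t(p01)) > 0
}

phylosor_from_spanning <- function(E, lengths) {
  M <- E * sqrt(lengths)                   # rows = edges
  shared <- crossprod(M)                   # shared branch length
  bl <- colSums(E * lengths)
  1 - 2 * shared / outer(bl, bl, "+")
}

#' Phylogenetic dissimilarity (1 - PhyloSorenson)
#'
#' For plots k and l with spanning branch lengths `BL_k`, `BL_l` and shared
#' spanning branch length `BL_shared`, dissimilarity is
#' `1 - 2 BL_shared / (BL_k + BL_l)`.
#'
#' @param tree a `"phylo"` object, aligned with `cm`
#'   (see [align_tree_community()]).
#' @param cm community matrix.
#' @return symmetric plot x plot matrix, metric `"PBD"`.
#' @export
phylosor_matrix <- function(tree, cm) {
  cm <- as_community(cm)[, tree$tip.label, drop = FALSE]
  if (nrow(cm) < 2) stop("need at least 2 plots")
  inc <- edge_tip_incidence(tree)
  E <- spanning_by_plot(inc, (cm > 0) * 1)
  m <- phylosor_from_spanning(E, tree$edge.length)
  dimnames(m) <- list(rownames(cm), rownames(cm))
  dissim(m, "PBD")
}

#' Null-model expectation of phylogenetic dissimilarity
#'
#' Mean PhyloSorenson dissimilarity over `n_null` independent-swap
#' randomizations of the presence/absence matrix (species occurrence
#' frequencies and plot richness preserved; one randomization per replicate
#' shared by all pairs).  Deviations above zero mean more phylogenetic
#' turnover than expected from taxonomic turnover alone.
#'
#' @param tree a `"phylo"` object, aligned with `cm`.
#' @param cm community matrix.
#' @param n_null number of null replicates (at least 99).
#' @param seed optional integer seed.
#' @return list: `observed`, `expected` (metric `"nullPBD"`), `deviation`
#'   (= observed - expected), and `quantile` (rank of the observed value in
#'   the null, per pair, with the +1 correction).
#' @export
null_phylosor <- function(tree, cm, n_null = 999, seed = NULL) {
  if (n_null < 99) stop("n_null must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  cm <- as_community(cm)[, tree$tip.label, drop = FALSE]
  inc <- edge_tip_incidence(tree)
  lengths <- tree$edge.length
  p01 <- (cm > 0) * 1L
  storage.mode(p01) <- "integer"
  obs <- phylosor_from_spanning(spanning_by_plot(inc, p01), lengths)
  nsw <- 10L * sum(p01)
  acc <- matrix(0, nrow(cm), nrow(cm))
  lesseq <- matrix(0, nrow(cm), nrow(cm))
  for (r in seq_len(n_null)) {
    rnd <- .swap_chain(p01, nsw, 100000L)$matrix
    m <- phylosor_from_spanning(spanning_by_plot(inc, rnd), lengths)
    acc <- acc + m
    lesseq <- lesseq + (m <= obs + 1e-12)
  }
  expected <- acc / n_null
  qtl <- (lesseq + 1) / (n_null + 1)
  dn <- list(rownames(cm), rownames(cm))
  dimnames(obs) <- dimnames(expected) <- dimnames(qtl) <- dn
  dev <- obs - expected
  diag(dev) <- 0
  diag(qtl) <- NA
  list(observed = dissim(obs, "PBD"),
       expected = dissim(expected, "nullPBD"),
       deviation = dev,
       quantile = qtl)
}

#' Per-plot mean dissimilarity
#'
#' Mean of each plot's off-diagonal row entries: the plot's average
#' dissimilarity to every other plot in the network, the quantity
#' interpolated over the map grid.
#'
#' @param D symmetric dissimilarity matrix.
#' @return named numeric vector, one value per plot.
#' @export
mean_row_dissimilarity <- function(D) {
  if (nrow(D) < 2) stop("need at least 2 plots")
  (rowSums(D) - diag(D)) / (nrow(D) - 1)
}
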