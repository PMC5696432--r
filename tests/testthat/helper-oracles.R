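## Brute-force oracles, independent of the package internals: edge
## membership comes from phangorn's Descendants/Ancestors rather than the
## package's own incidence machinery.

## Tip labels descending from each edge (list over edge rows).
oracle_edge_tips <- function(tree) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

## Faith PD by marking every edge whose descendant tip set meets the plot.
oracle_pd <- function(tree, taxa) {
  et <- oracle_edge_tips(tree)
  on_path <- vapply(et, function(tips) any(tips %in% taxa), logical(1))
  sum(tree$edge.length[on_path])
}

oracle_spanning <- function(tree, taxa) {
  et <- oracle_edge_tips(tree)
  which(vapply(et, function(tips) any(tips %in% taxa), logical(1)))
}

oracle_phylosor <- function(tree, taxa1, taxa2) {
  e1 <- oracle_spanning(tree, taxa1)
  e2 <- oracle_spanning(tree, taxa2)
  shared <- sum(tree$edge.length[intersect(e1, e2)])
  1 - 2 * shared / (sum(tree$edge.length[e1]) + sum(tree$edge.length[e2]))
}

## WPE with ranges counted by direct occupancy enumeration.
oracle_wpe <- function(tree, cm, plot) {
  et <- oracle_edge_tips(tree)
  ranges <- vapply(et, function(tips)
    sum(rowSums(cm[, tips, drop = FALSE] > 0) > 0), numeric(1))
  taxa <- colnames(cm)[cm[plot, ] > 0]
  e <- oracle_spanning(tree, taxa)
  sum(tree$edge.length[e] / ranges[e])
}

## AED by explicit root-path walks (phangorn::Ancestors).
oracle_aed <- function(tree, abund) {
  et <- oracle_edge_tips(tree)
  n_e <- vapply(et, function(tips) sum(abund[tips]), numeric(1))
  present <- names(abund)[abund > 0]
  out <- setNames(numeric(length(present)), present)
  for (sp in present) {
    tip <- match(sp, tree$tip.label)
    nodes <- c(tip, phangorn::Ancestors(tree, tip, "all"))
    edges <- match(nodes[-length(nodes)], tree$edge[, 2])
    out[sp] <- sum(tree$edge.length[edges] / n_e[edges])
  }
  out
}

## IAC by explicit recursion over the plot-pruned tree.
oracle_iac <- function(tree, abund) {
  sp <- names(abund)[abund > 0]
  if (length(sp) < 2) return(NA_real_)
  sub <- ape::keep.tip(tree, sp)
  N <- sum(abund)
  nhat <- setNames(numeric(length(sub$tip.label)), sub$tip.label)
  for (tip in seq_along(sub$tip.label)) {
    anc <- phangorn::Ancestors(sub, tip, "all")
    dk <- vapply(anc, function(v) sum(sub$edge[, 1] == v), numeric(1))
    nhat[tip] <- N / prod(dk)
  }
  sum(abs(abund[sub$tip.label] - nhat)) / sub$Nnode
}

## Exhaustive MRPP over every distinct relabelling, written independently
## (combn-based bipartition enumeration for the two-group case).
oracle_mrpp_two_groups <- function(D, groups) {
  n <- nrow(D)
  g1 <- unique(groups)[1]
  k <- sum(groups == g1)
  delta_of <- function(idx) {
    within <- function(i) {
      m <- D[i, i]
      mean(m[lower.tri(m)])
    }
    (k / n) * within(idx) + ((n - k) / n) * within(setdiff(seq_len(n), idx))
  }
  combos <- combn(n, k)
  deltas <- apply(combos, 2, delta_of)
  d_obs <- delta_of(which(groups == g1))
  list(delta_obs = d_obs, delta_exp = mean(deltas),
       A = 1 - d_obs / mean(deltas),
       p = mean(deltas <= d_obs + 1e-12))
}

## Exhaustive Mantel by direct loop over every permutation.
oracle_mantel <- function(D1, D2) {
  n <- nrow(D1)
  lt <- lower.tri(D1)
  r_obs <- cor(D1[lt], D2[lt])
  perms <- gtools_perms(n)
  rs <- apply(perms, 1, function(p) cor(D1[lt], D2[p, p][lt]))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

## All permutations, rows = permutations (recursive, small n only).
gtools_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos)
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1L)))))
}

## Random community fixture over a random tree.
random_fixture <- function(n_tips = 8, n_plots = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_tips)
  cm <- matrix(rpois(n_plots * n_tips, 2), n_plots, n_tips,
               dimnames = list(paste0("p", seq_len(n_plots)), tr$tip.label))
  ## ensure every plot has at least 2 species
  for (i in seq_len(n_plots))
    while (sum(cm[i, ] > 0) < 2) cm[i, sample(n_tips, 1)] <- 1 + cm[i, sample(n_tips, 1)]
  list(tree = tr, comm = cm)
}

## Chain tree: root R above k undated internal nodes above one tip.
chain_tree <- function(k) {
  n <- k + 1L
  edge <- cbind(2:(1 + n), c(3:(1 + n), 1L))
  structure(list(edge = edge, Nnode = n, tip.label = "t",
                 node.label = c("R", if (k > 0) paste0("X", seq_len(k))),
                 edge.length = rep(1, nrow(edge))),
            class = "phylo")
}
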