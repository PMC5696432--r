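## Per-plot phylogenetic alpha diversity: Faith's PD, mean pairwise distance,
## and standardized effect sizes under the independent-swap null model.

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimum spanning path connecting a set of
#' species to the root of the tree.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param species character vector of tip names, or a named abundance vector
#'   (species with positive abundance are used).
#' @return PD in the tree's branch-length units (Myr for dated trees).
#' @export
faith_pd <- function(tree, species) {
  species <- species_set(species)
  sum(tree$edge.length[spanning_edges(tree, species)])
}

species_set <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("abundance vectors must be named by species")
    names(x)[x > 0]
  } else as.character(x)
}

#' Mean pairwise phylogenetic distance
#'
#' Unweighted: mean patristic distance over unordered pairs of species
#' present.  Abundance-weighted: sum of `n_i * n_j * d(i,j)` over ordered
#' pairs `i != j`, divided by the matching sum of `n_i * n_j`.
#'
#' @param tree a `"phylo"` object (ignored when `dmat` is supplied).
#' @param x character vector of species present, or named abundance vector.
#' @param weighted logical; abundance-weight the average.
#' @param dmat optional precomputed patristic distance matrix.
#' @return mean pairwise distance.
#' @export
mpd <- function(tree, x, weighted = FALSE, dmat = NULL) {
  if (is.null(dmat)) dmat <- tip_distance_matrix(tree)
  sp <- species_set(x)
  if (length(sp) < 2) stop("mpd needs at least 2 species present")
  missing <- setdiff(sp, rownames(dmat))
  if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
  d <- dmat[sp, sp]
  if (weighted && is.numeric(x)) {
    n <- x[sp]
    w <- outer(n, n)
    diag(w) <- 0
    sum(w * d) / sum(w)
  } else {
    sum(d) / (length(sp) * (length(sp) - 1))
  }
}

#' Independent-swap randomization
#'
#' Randomizes a presence/absence matrix by repeatedly flipping 2x2
#' checkerboard submatrices, which preserves every row sum (plot richness)
#' and column sum (species occurrence frequency) exactly.
#'
#' @param x binary (or abundance; positive entries become 1) matrix.
#' @param n_swaps number of successful swaps to perform; defaults to
#'   `10 * sum(x > 0)`, a standard mixing heuristic.
#' @param seed optional integer seed.
#' @param max_fail consecutive failed draws tolerated before giving up
#'   (a matrix with no checkerboard is returned unchanged with a warning).
#' @return the randomized binary matrix; attribute `gave_up` is `TRUE` if
#'   the requested number of swaps could not be completed.
#' @export
independent_swap <- function(x, n_swaps = NULL, seed = NULL, max_fail = 100000L) {
  m <- as.matrix(x)
  m[] <- as.integer(m > 0)
  storage.mode(m) <- "integer"
  if (is.null(n_swaps)) n_swaps <- 10L * sum(m)
  if (!is.null(seed)) set.seed(seed)
  res <- .swap_chain(m, as.integer(n_swaps), as.integer(max_fail))
  out <- res$matrix
  dimnames(out) <- dimnames(x)
  if (res$gave_up)
    warning("no (further) checkerboard found; completed ",
            res$swaps_done, " of ", n_swaps, " swaps")
  attr(out, "gave_up") <- res$gave_up
  attr(out, "swaps_done") <- res$swaps_done
  out
}

#' Standardized effect size of MPD under the independent-swap null
#'
#' For each plot, compares observed mean pairwise distance with its
#' distribution over `n_null` independent-swap randomizations of the
#' presence/absence matrix (each null replicate is an independent chain of
#' `10 * fill` successful swaps started from the observed matrix).
#' `ses = (obs - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation; `quantile` is the rank of the observed value within the null.
#'
#' The default classification follows the convention in which positive
#' ses.MPD beyond +1.96 is reported as phylogenetic clustering and values
#' below -1.96 as overdispersion; `convention = "standard"` inverts the
#' labels (high MPD = overdispersion), the usual NRI reading.
#'
#' @param tree a `"phylo"` object, aligned with `cm`.
#' @param cm community matrix (plots x species).
#' @param n_null number of null replicates (at least 99).
#' @param seed optional integer seed.
#' @param weighted abundance-weight the *observed* MPD (nulls are
#'   incidence-based).
#' @param convention `"paper"` or `"standard"` label orientation.
#' @param crit critical value for the two-sided classification.
#' @return data frame per plot: `plot_id`, `n_species`, `obs`, `null_mean`,
#'   `null_sd`, `ses`, `quantile`, `label`.
#' @export
ses_mpd <- function(tree, cm, n_null = 999, seed = NULL, weighted = FALSE,
                    convention = c("paper", "standard"), crit = 1.96) {
  convention <- match.arg(convention)
  if (n_null < 99) stop("n_null must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  dmat <- tip_distance_matrix(tree)
  cm <- cm[, tree$tip.label, drop = FALSE]
  p01 <- (cm > 0) * 1L
  nsw <- 10L * sum(p01)

  obs <- mpd_all_plots(cm, dmat, weighted = weighted)
  nulls <- matrix(NA_real_, n_null, nrow(cm))
  for (r in seq_len(n_null)) {
    rnd <- .swap_chain(p01, nsw, 100000L)$matrix
    nulls[r, ] <- mpd_all_plots(rnd, dmat, weighted = FALSE)
  }
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, sd)
  ses <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  qtl <- vapply(seq_len(nrow(cm)), function(i) {
    if (is.na(obs[i])) return(NA_real_)
    (sum(nulls[, i] <= obs[i]) + 1) / (n_null + 1)
  }, numeric(1))
  hi <- if (convention == "paper") "clustered" else "overdispersed"
  lo <- if (convention == "paper") "overdispersed" else "clustered"
  label <- rep("random", nrow(cm))
  label[!is.na(ses) & ses > crit] <- hi
  label[!is.na(ses) & ses < -crit] <- lo
  label[is.na(ses)] <- "undefined"
  data.frame(plot_id = rownames(cm), n_species = rowSums(cm > 0),
             obs = obs, null_mean = mu, null_sd = sdv,
             ses = ses, quantile = qtl, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Vectorized per-plot MPD: for binary rows v, sum_{i != j} d_ij v_i v_j =
## (vDv) with zero diagonal, so one matrix product covers all plots.
mpd_all_plots <- function(cm, dmat, weighted = FALSE) {
  w <- if (weighted) {
    m <- cm
    storage.mode(m) <- "double"
    m
  } else (cm > 0) * 1
  num <- rowSums((w %*% dmat) * w)          # diag(dmat) = 0
  den <- rowSums(w)^2 - rowSums(w^2)
  ifelse(rowSums(cm > 0) >= 2, num / den, NA_real_)
}
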