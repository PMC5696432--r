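## Ordination and permutation inference: NMDS (multi-start wrapper around
## vegan's monotone-regression engine), MRPP, and the Mantel test.  MRPP and
## Mantel are implemented directly so that small instances can be evaluated
## by exhaustive enumeration of permutations.

#' Non-metric multidimensional scaling
#'
#' Global NMDS minimizing Kruskal's stress-1 (monotone regression, primary
#' tie treatment), taking the best of `n_starts` configurations: the first
#' start is classical metric scaling, the rest are random.  The returned
#' configuration is centred at the origin.
#'
#' @param D symmetric dissimilarity matrix.
#' @param k number of dimensions (2 in typical use).
#' @param n_starts number of starting configurations (>= 1).
#' @param seed optional integer seed (random starts are drawn in sequence,
#'   so the best stress is non-increasing in `n_starts` at fixed seed).
#' @return object of class `"nmds_fit"`: `points` (plots x k), `stress`
#'   (Kruskal stress-1), `n_starts`, `converged`.
#' @export
nmds <- function(D, k = 2, n_starts = 50, seed = NULL) {
  D <- as.matrix(D)
  if (all(D == 0)) stop("all-zero dissimilarity matrix")
  if (n_starts < 1) stop("n_starts must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  d <- stats::as.dist(D)
  n <- nrow(D)
  init <- cmdscale(d, k = k)
  if (ncol(init) < k) init <- cbind(init, matrix(0, n, k - ncol(init)))
  best <- vegan::monoMDS(d, y = init, k = k, model = "global")
  for (s in seq_len(n_starts - 1L)) {
    y0 <- matrix(runif(n * k, -1, 1), n, k)
    fit <- vegan::monoMDS(d, y = y0, k = k, model = "global")
    if (fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress, n_starts = n_starts,
                 converged = best$icause == 3 || best$stress < 1e-4),
            class = "nmds_fit")
}

#' @method print nmds_fit
#' @export
print.nmds_fit <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$points), "sites,", ncol(x$points),
      "dimensions\nKruskal stress-1:", format(x$stress, digits = 5),
      " (best of", x$n_starts, "starts)\n")
  invisible(x)
}

## All distinct arrangements of a label vector (multiset permutations),
## as columns.  Feasible for the <=8-plot instances used with exact tests.
label_arrangements <- function(labels) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  rec <- function(remaining) {
    if (sum(remaining) == 0L) return(matrix(character(0), nrow = 0))
    out <- NULL
    for (u in seq_along(uniq)) {
      if (remaining[u] == 0L) next
      rem <- remaining
      rem[u] <- rem[u] - 1L
      sub <- rec(rem)
      block <- if (nrow(sub) == 0) matrix(uniq[u], 1, 1) else
        rbind(matrix(uniq[u], 1, ncol(sub)), sub)
      out <- cbind(out, block)
    }
    out
  }
  rec(as.integer(table(factor(labels, levels = uniq))))
}

mrpp_delta <- function(D, groups) {
  n <- length(groups)
  del <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    del <- del + (length(i) / n) * mean(D[i, i][lower.tri(D[i, i])])
  }
  del
}

#' Multi-response permutation procedure
#'
#' Tests whether within-group dissimilarity is smaller than expected under
#' random relabelling.  The statistic is the group-size weighted mean
#' within-group dissimilarity `delta = sum(n_g/N * mean within-group d)`;
#' significance comes from `n_perm` random relabellings (or exhaustive
#' enumeration of all distinct arrangements when `exact = TRUE`), with the
#' +1 correction so p is never zero.  The chance-corrected effect size is
#' `A = 1 - delta_obs / delta_exp`.
#'
#' @param D symmetric dissimilarity matrix.
#' @param groups group label per plot (length `nrow(D)`); every group needs
#'   at least 2 members.
#' @param n_perm number of random relabellings.
#' @param seed optional integer seed.
#' @param exact enumerate all distinct label arrangements instead of
#'   sampling (instances up to ~8 plots).
#' @return object of class `"mrpp_test"`: `delta_obs`, `delta_exp`, `A`,
#'   `p`, `n_perm`, `exact`.
#' @export
mrpp <- function(D, groups, n_perm = 999, seed = NULL, exact = FALSE) {
  D <- as.matrix(D)
  groups <- as.character(groups)
  if (length(groups) != nrow(D)) stop("one group label per plot required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("singleton group: ", names(sizes)[sizes < 2][1])
  d_obs <- mrpp_delta(D, groups)
  if (exact) {
    arr <- label_arrangements(groups)
    deltas <- apply(arr, 2, function(g) mrpp_delta(D, g))
    p <- mean(deltas <= d_obs + 1e-12)
    d_exp <- mean(deltas)
    n_perm <- ncol(arr)
  } else {
    if (!is.null(seed)) set.seed(seed)
    deltas <- vapply(seq_len(n_perm),
                     function(i) mrpp_delta(D, sample(groups)), numeric(1))
    p <- (sum(deltas <= d_obs + 1e-12) + 1) / (n_perm + 1)
    d_exp <- mean(deltas)
  }
  structure(list(delta_obs = d_obs, delta_exp = d_exp,
                 A = 1 - d_obs / d_exp, p = p, n_perm = n_perm,
                 exact = exact),
            class = "mrpp_test")
}

#' @method print mrpp_test
#' @export
print.mrpp_test <- function(x, ...) {
  cat("MRPP: delta_obs =", format(x$delta_obs, digits = 5),
      " delta_exp =", format(x$delta_exp, digits = 5),
      "\n      A =", format(x$A, digits = 4),
      " p =", format(x$p, digits = 4),
      if (x$exact) " (exact," else " (",
      x$n_perm, "permutations)\n")
  invisible(x)
}

#' Mantel test
#'
#' Pearson correlation between the lower triangles of two dissimilarity
#' matrices; significance by simultaneously permuting rows and columns of
#' the second matrix, one-tailed (greater), with the +1 correction
#' (exhaustive over all `n!` relabellings when `exact = TRUE`).
#'
#' @param D1,D2 symmetric dissimilarity matrices over the same plots in the
#'   same order.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @param exact enumerate all permutations (instances up to ~8 plots).
#' @return list: `r`, `p`, `n_perm`, `exact`.
#' @export
mantel <- function(D1, D2, n_perm = 999, seed = NULL, exact = FALSE) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("matrices must match")
  lt <- lower.tri(D1)
  if (sd(D1[lt]) == 0 || sd(D2[lt]) == 0)
    stop("constant dissimilarity matrix: correlation undefined")
  r_obs <- cor(D1[lt], D2[lt])
  n <- nrow(D1)
  if (exact) {
    perms <- all_permutations(n)
    rs <- apply(perms, 2, function(p) cor(D1[lt], D2[p, p][lt]))
    p <- mean(rs >= r_obs - 1e-12)
    n_perm <- ncol(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rs <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(D1[lt], D2[p, p][lt])
    }, numeric(1))
    p <- (sum(rs >= r_obs - 1e-12) + 1) / (n_perm + 1)
  }
  list(r = r_obs, p = p, n_perm = n_perm, exact = exact)
}

## All permutations of 1..n as columns (n <= 8).
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to 8 plots")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 1L
  for (pos in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      out[, col] <- append(sub[, j], n, after = pos - 1L)
      col <- col + 1L
    }
  }
  out
}
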