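## Community-matrix and coordinate I/O, tree-matrix reconciliation, and
## Fisher's log-series alpha.  A community matrix is a plain integer matrix,
## plots in rows (rownames = plot IDs), species in columns.

#' Read a plot-by-species abundance table
#'
#' First column holds plot identifiers, the header row species names, cells
#' integer stem counts; blanks become zeros.  Every plot must contain at
#' least one individual.
#'
#' @param file CSV or TSV path (delimiter sniffed from the first line).
#' @return integer matrix, plots x species.
#' @export
read_community <- function(file) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  x <- read.csv(file, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(x[[1]]))
    stop("duplicate plot ID: ", paste(unique(x[[1]][duplicated(x[[1]])]), collapse = ", "))
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  m[is.na(m)] <- 0
  storage.mode(m) <- "double"
  bad <- which(m != round(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at plot '", rownames(m)[bad[1, 1]],
         "', species '", colnames(m)[bad[1, 2]], "'")
  storage.mode(m) <- "integer"
  as_community(m)
}

## Validate and stamp a community matrix.
as_community <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("plot", seq_len(nrow(m)))
  if (anyDuplicated(colnames(m))) stop("duplicate species names")
  if (any(m < 0)) stop("negative abundances")
  empty <- rowSums(m) == 0
  if (any(empty))
    stop("plot has zero individuals: ", paste(rownames(m)[empty], collapse = ", "))
  storage.mode(m) <- "integer"
  m
}

#' Write a community matrix to CSV
#' @param cm community matrix.
#' @param file output path.
#' @export
write_community <- function(cm, file) {
  df <- data.frame(plot_id = rownames(cm), cm, check.names = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read plot coordinates
#'
#' CSV with columns `plot_id`, `lon`, `lat` (decimal degrees, WGS84).
#'
#' @param file CSV path.
#' @return data frame with rownames set to plot IDs.
#' @export
read_coordinates <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("plot_id", "lon", "lat")
  if (anyDuplicated(x$plot_id)) stop("duplicate plot ID in coordinates")
  if (any(x$lon < -180 | x$lon > 180) || any(x$lat < -90 | x$lat > 90))
    stop("coordinates outside WGS84 bounds")
  rownames(x) <- x$plot_id
  x
}

#' Drop unnamed morphospecies by name pattern
#'
#' Removes species whose names match a pattern typical of undetermined
#' material (defaults cover "sp.", "sp_", "indet").  Intended to run before
#' [align_tree_community()].
#'
#' @param cm community matrix.
#' @param pattern regular expression matched against species names.
#' @return the filtered matrix with an attribute `dropped` listing removals.
#' @export
filter_morphospecies <- function(cm, pattern = "(sp[._]|indet)") {
  drop <- grepl(pattern, colnames(cm), ignore.case = TRUE)
  out <- cm[, !drop, drop = FALSE]
  attr(out, "dropped") <- colnames(cm)[drop]
  out
}

#' Reconcile a tree and a community matrix
#'
#' Species absent from the tree are dropped from the matrix; tips absent
#' from the matrix are pruned from the tree.  The returned objects share an
#' identical species set.
#'
#' @param tree a `"phylo"` object.
#' @param cm community matrix.
#' @return list with `tree`, `comm`, and `report` (species dropped from the
#'   matrix and tips pruned from the tree).
#' @export
align_tree_community <- function(tree, cm) {
  shared <- intersect(tree$tip.label, colnames(cm))
  if (length(shared) == 0L) stop("tree and community matrix share no species")
  dropped <- setdiff(colnames(cm), shared)
  pruned <- setdiff(tree$tip.label, shared)
  if (length(pruned)) tree <- ape::keep.tip(tree, shared)
  cm <- cm[, tree$tip.label, drop = FALSE]  # column order follows the tree
  cm <- as_community(cm)
  list(tree = tree, comm = cm,
       report = list(species_dropped = dropped, tips_pruned = pruned))
}

#' Fisher's alpha from richness and abundance
#'
#' Inverts the log-series relation S = alpha * ln(1 + N/alpha) by bracketed
#' root-finding (the left side is strictly increasing in alpha), followed by
#' a Newton polish to drive the residual below 1e-9.
#'
#' @param S species count(s), `1 <= S < N`.
#' @param N individual count(s).
#' @return alpha, vectorized over `S` and `N`.
#' @export
#' @examples
#' fisher_alpha(10 * log(101), 1000)  # 10
fisher_alpha <- function(S, N) {
  n <- max(length(S), length(N))
  S <- rep_len(as.numeric(S), n)
  N <- rep_len(as.numeric(N), n)
  if (any(S < 1)) stop("S must be at least 1")
  if (any(S >= N)) stop("no finite alpha: S must be smaller than N")
  vapply(seq_len(n), function(i) {
    f <- function(a) a * log1p(N[i] / a) - S[i]
    a <- uniroot(f, c(1e-6, 1e8), tol = 1e-12)$root
    for (k in 1:5) {  # Newton polish
      fa <- f(a)
      if (abs(fa) < 1e-12) break
      da <- log1p(N[i] / a) - N[i] / (a + N[i])
      a <- a - fa / da
    }
    a
  }, numeric(1))
}
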