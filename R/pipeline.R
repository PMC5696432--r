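## End-to-end analysis: align inputs, alpha metrics, beta matrices and
## nulls, Mantel/NMDS/MRPP inference, endemism, and loess surfaces.

#' Delimit floristic districts from a plot network
#'
#' Runs the full analysis chain on an aligned (tree, community, coordinates)
#' triple: per-plot Fisher's alpha, Faith's PD and ses.MPD; taxonomic (TBD)
#' and phylogenetic (PBD) dissimilarity matrices with the independent-swap
#' null expectation of PBD; Mantel tests of TBD against PBD and against the
#' null PBD expectation; 2-D NMDS ordinations of both matrices; MRPP on
#' user-supplied group labels (or k-medoids labels derived from the TBD
#' matrix, marked as such); WPE, IAC and AED summaries; and, when
#' coordinates are given, loess surfaces of the six mapped quantities
#' (mean TBD, mean PBD, mean null-PBD, WPE, IAC, mean AED).
#'
#' @param tree a `"phylo"` object.
#' @param comm community matrix (plots x species, integer counts).
#' @param coords optional data frame with `lon`, `lat`, rownames = plot IDs;
#'   spatial stages are skipped when absent.
#' @param groups optional group label per plot for MRPP; when `NULL`,
#'   k-medoids with `k_groups` clusters on the TBD matrix provides
#'   provisional labels flagged `groups_derived`.
#' @param n_null null-model replicates for ses.MPD and null PBD.
#' @param n_perm permutations for MRPP and Mantel.
#' @param n_starts NMDS starting configurations.
#' @param run_ses compute ses.MPD (the most expensive stage).
#' @param cell_size,span,degree grid and loess parameters.
#' @param k_groups clusters for derived labels.
#' @param seed integer seed governing every randomized stage.
#' @return object of class `"phylofloristics"`.
#' @export
phylofloristics <- function(tree, comm, coords = NULL, groups = NULL,
                            n_null = 999, n_perm = 999, n_starts = 1000,
                            run_ses = TRUE, cell_size = 0.5, span = 0.75,
                            degree = 2, k_groups = 3, seed = 1) {
  set.seed(seed)
  ali <- align_tree_community(tree, comm)
  tree <- ali$tree; comm <- ali$comm
  if (!is.null(coords)) {
    coords <- coords[rownames(comm), , drop = FALSE]
    if (anyNA(coords$lon)) stop("coordinates missing for some plots")
  }

  ## --- alpha diversity -------------------------------------------------
  N <- rowSums(comm); S <- rowSums(comm > 0)
  alpha_tab <- data.frame(plot_id = rownames(comm), N = N, S = S,
                          fisher_alpha = fisher_alpha(S, N),
                          PD = vapply(rownames(comm), function(p)
                            faith_pd(tree, comm[p, ]), numeric(1)),
                          row.names = NULL, stringsAsFactors = FALSE)
  ses <- if (run_ses) ses_mpd(tree, comm, n_null = n_null) else NULL

  ## --- beta diversity --------------------------------------------------
  tbd <- sorenson_matrix(comm)
  pbd <- phylosor_matrix(tree, comm)
  nullp <- null_phylosor(tree, comm, n_null = n_null)
  mantel_tbd_pbd <- mantel(tbd, pbd, n_perm = n_perm)
  mantel_tbd_nullpbd <- mantel(tbd, nullp$expected, n_perm = n_perm)

  ## --- ordination and group tests --------------------------------------
  ord_tbd <- nmds(tbd, k = 2, n_starts = n_starts)
  ord_pbd <- nmds(pbd, k = 2, n_starts = n_starts)
  groups_derived <- is.null(groups)
  if (groups_derived) {
    groups <- paste0("g", cluster::pam(stats::as.dist(tbd), k = k_groups,
                                       diss = TRUE, cluster.only = TRUE))
    names(groups) <- rownames(comm)
  } else {
    groups <- if (is.null(names(groups))) {
      if (length(groups) != nrow(comm))
        stop("unnamed 'groups' must have one label per aligned plot")
      setNames(as.character(groups), rownames(comm))
    } else setNames(as.character(groups[rownames(comm)]), rownames(comm))
    if (anyNA(groups)) stop("group labels missing for some plots")
  }
  mrpp_tbd <- mrpp(tbd, groups, n_perm = n_perm)
  mrpp_pbd <- mrpp(pbd, groups, n_perm = n_perm)

  ## --- endemism ---------------------------------------------------------
  endem <- endemism_table(tree, comm)
  mean_tbd <- mean_row_dissimilarity(tbd)
  mean_pbd <- mean_row_dissimilarity(pbd)
  mean_nullpbd <- mean_row_dissimilarity(nullp$expected)

  ## --- spatial surfaces -------------------------------------------------
  surfaces <- NULL
  if (!is.null(coords)) {
    spec <- grid_spec_from_coords(coords, cell_size)
    panel <- list(TBD = mean_tbd, PBD = mean_pbd, nullPBD = mean_nullpbd,
                  WPE = setNames(endem$WPE, endem$plot_id),
                  IAC = setNames(endem$IAC, endem$plot_id),
                  AED = setNames(endem$mean_AED, endem$plot_id))
    surfaces <- lapply(names(panel), function(m) {
      v <- panel[[m]]
      v <- v[!is.na(v)]
      interpolate_metric_surface(v, coords, spec, span = span,
                                 degree = degree, metric = m)
    })
    names(surfaces) <- names(panel)
  }

  structure(list(alpha = alpha_tab, ses_mpd = ses,
                 tbd = tbd, pbd = pbd, null_pbd = nullp,
                 mantel = list(tbd_pbd = mantel_tbd_pbd,
                               tbd_nullpbd = mantel_tbd_nullpbd),
                 nmds = list(tbd = ord_tbd, pbd = ord_pbd),
                 groups = groups, groups_derived = groups_derived,
                 mrpp = list(tbd = mrpp_tbd, pbd = mrpp_pbd),
                 endemism = endem,
                 mean_dissim = data.frame(plot_id = rownames(comm),
                                          mean_TBD = mean_tbd,
                                          mean_PBD = mean_pbd,
                                          mean_nullPBD = mean_nullpbd,
                                          row.names = NULL),
                 surfaces = surfaces, report = ali$report,
                 params = list(n_null = n_null, n_perm = n_perm,
                               n_starts = n_starts, cell_size = cell_size,
                               span = span, degree = degree,
                               k_groups = k_groups, seed = seed)),
            class = "phylofloristics")
}

#' @method print phylofloristics
#' @export
print.phylofloristics <- function(x, ...) {
  cat("Floristic-district analysis:", nrow(x$alpha), "plots,",
      length(attr(x$tbd, "dimnames")[[1]]), "aligned plots\n")
  cat("  Fisher's alpha: median", format(median(x$alpha$fisher_alpha), digits = 4),
      " Faith PD: median", format(median(x$alpha$PD), digits = 5), "\n")
  cat("  Mantel r (TBD~PBD):", format(x$mantel$tbd_pbd$r, digits = 4),
      " p =", format(x$mantel$tbd_pbd$p, digits = 3), "\n")
  cat("  NMDS stress: TBD", format(x$nmds$tbd$stress, digits = 4),
      " PBD", format(x$nmds$pbd$stress, digits = 4), "\n")
  cat("  MRPP (", length(unique(x$groups)), if (x$groups_derived)
    "derived" else "supplied", "groups): TBD A =",
    format(x$mrpp$tbd$A, digits = 3), "p =", format(x$mrpp$tbd$p, digits = 3),
    "; PBD A =", format(x$mrpp$pbd$A, digits = 3),
    "p =", format(x$mrpp$pbd$p, digits = 3), "\n")
  if (!is.null(x$surfaces))
    cat("  Surfaces:", paste(names(x$surfaces), collapse = ", "), "\n")
  invisible(x)
}

#' @method summary phylofloristics
#' @export
summary.phylofloristics <- function(object, ...) {
  out <- list(
    alpha = object$alpha,
    mantel = data.frame(
      comparison = c("TBD~PBD", "TBD~nullPBD"),
      r = c(object$mantel$tbd_pbd$r, object$mantel$tbd_nullpbd$r),
      p = c(object$mantel$tbd_pbd$p, object$mantel$tbd_nullpbd$p)),
    mrpp = data.frame(
      matrix = c("TBD", "PBD"),
      delta_obs = c(object$mrpp$tbd$delta_obs, object$mrpp$pbd$delta_obs),
      delta_exp = c(object$mrpp$tbd$delta_exp, object$mrpp$pbd$delta_exp),
      A = c(object$mrpp$tbd$A, object$mrpp$pbd$A),
      p = c(object$mrpp$tbd$p, object$mrpp$pbd$p)),
    stress = c(TBD = object$nmds$tbd$stress, PBD = object$nmds$pbd$stress),
    endemism = object$endemism,
    pbd_below_null = mean(object$null_pbd$deviation[
      lower.tri(object$null_pbd$deviation)] < 0))
  class(out) <- "summary.phylofloristics"
  out
}

#' @method print summary.phylofloristics
#' @export
print.summary.phylofloristics <- function(x, ...) {
  cat("Mantel tests:\n"); print(x$mantel, row.names = FALSE)
  cat("\nMRPP:\n"); print(x$mrpp, row.names = FALSE)
  cat("\nNMDS stress:", paste(names(x$stress),
                              format(x$stress, digits = 4), collapse = "  "), "\n")
  cat("\nShare of plot pairs with PBD below null expectation:",
      format(x$pbd_below_null, digits = 3), "\n")
  cat("\nPer-plot metrics (first rows):\n")
  print(head(merge(x$alpha, x$endemism, by = "plot_id")), row.names = FALSE)
  invisible(x)
}

#' Plot method: ordination panels
#'
#' Draws the TBD- and PBD-based NMDS configurations coloured by group.
#'
#' @param x a `"phylofloristics"` object.
#' @param which `"ordination"` (both NMDS panels) or a surface name
#'   (e.g. `"PBD"`) to image that interpolated grid.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.phylofloristics <- function(x, which = "ordination", ...) {
  if (identical(which, "ordination")) {
    grp <- factor(x$groups)
    cols <- hcl.colors(nlevels(grp), "Dark 3")
    op <- par(mfrow = c(1, 2)); on.exit(par(op))
    for (m in c("tbd", "pbd")) {
      pts <- x$nmds[[m]]$points
      plot(pts, col = cols[grp], pch = 19,
           main = paste0(toupper(m), " NMDS (stress ",
                         format(x$nmds[[m]]$stress, digits = 3), ")"), ...)
    }
    legend("topright", legend = levels(grp), col = cols, pch = 19, bty = "n")
  } else {
    s <- x$surfaces[[which]]
    if (is.null(s)) stop("no surface named ", which)
    ix <- sort(unique(s$lon_center)); iy <- sort(unique(s$lat_center))
    z <- matrix(NA_real_, length(ix), length(iy))
    z[cbind(match(s$lon_center, ix), match(s$lat_center, iy))] <- s$value
    image(ix, iy, z, xlab = "longitude", ylab = "latitude",
          col = hcl.colors(24, "YlOrRd", rev = TRUE), ...)
    title(main = paste("Loess surface:", which))
  }
  invisible(x)
}

#' Run the pipeline from files and write all outputs
#'
#' Reads the tree, community table and (optionally) coordinates, runs
#' [phylofloristics()], and writes per-plot CSVs, dissimilarity matrices,
#' ordination and test results, surfaces, and a JSON manifest recording
#' every parameter and the seed.  A missing coordinates file skips the
#' spatial stage (noted in the manifest) rather than aborting.
#'
#' @param tree_file Newick path.
#' @param community_file CSV/TSV path.
#' @param coords_file optional CSV path.
#' @param groups optional named vector of group labels.
#' @param out_dir output directory.
#' @param ... passed to [phylofloristics()].
#' @return the fitted `"phylofloristics"` object, invisibly.
#' @export
run_pipeline <- function(tree_file, community_file, coords_file = NULL,
                         groups = NULL, out_dir, ...) {
  tree <- read_newick(tree_file)
  comm <- read_community(community_file)
  coords <- if (!is.null(coords_file) && file.exists(coords_file))
    read_coordinates(coords_file) else NULL
  fit <- phylofloristics(tree, comm, coords = coords, groups = groups, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name) write.csv(df, file.path(out_dir, name),
                                     row.names = FALSE, quote = FALSE)
  wr(fit$alpha, "alpha_metrics.csv")
  if (!is.null(fit$ses_mpd)) wr(fit$ses_mpd, "ses_mpd.csv")
  wr(fit$endemism, "endemism.csv")
  wr(fit$mean_dissim, "mean_dissimilarity.csv")
  write.csv(fit$tbd, file.path(out_dir, "tbd_matrix.csv"))
  write.csv(fit$pbd, file.path(out_dir, "pbd_matrix.csv"))
  write.csv(fit$null_pbd$expected, file.path(out_dir, "null_pbd_matrix.csv"))
  for (m in c("tbd", "pbd"))
    wr(data.frame(plot_id = rownames(fit$nmds[[m]]$points),
                  fit$nmds[[m]]$points,
                  stress = fit$nmds[[m]]$stress),
       paste0("nmds_", m, ".csv"))
  wr(data.frame(plot_id = names(fit$groups), group = fit$groups,
                derived = fit$groups_derived), "groups.csv")
  if (!is.null(fit$surfaces))
    for (m in names(fit$surfaces))
      write_surface(fit$surfaces[[m]], file.path(out_dir,
                                                 paste0("surface_", m, ".csv")))
  manifest <- list(
    inputs = list(tree = tree_file, community = community_file,
                  coords = coords_file),
    params = fit$params,
    spatial_stage = if (is.null(fit$surfaces)) "skipped (no coordinates)"
    else paste(names(fit$surfaces), collapse = ","),
    tests = list(
      mantel_tbd_pbd = fit$mantel$tbd_pbd,
      mantel_tbd_nullpbd = fit$mantel$tbd_nullpbd,
      mrpp_tbd = unclass(fit$mrpp$tbd), mrpp_pbd = unclass(fit$mrpp$pbd)),
    versions = list(package = as.character(utils::packageVersion("phylofloristics")),
                    R = R.version.string))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
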