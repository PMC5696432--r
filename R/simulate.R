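## Synthetic-landscape generator: a dated regional phylogeny, a plot network
## with log-series abundances and clade-biased district composition, and
## coordinates in geographically coherent districts.  Gives every analysis
## stage a fixture with known truth.

#' Simulation configuration
#'
#' Defaults emulate the design of a 62-plot, 1,687-species Amazonian
#' inventory network: three latitudinally coherent districts, each biased
#' toward one deep clade of the regional tree, per-plot abundances from a
#' log-series with Fisher's alpha 100 at 600 stems per hectare, inside a
#' roughly 3 x 5.5 degree window.
#'
#' @param seed integer seed.
#' @param n_species regional pool size.
#' @param n_plots number of one-hectare plots.
#' @param n_districts number of floristic districts.
#' @param birth_rate pure-birth rate for the regional tree.
#' @param alpha target Fisher's alpha per plot.
#' @param beta clade-bias strength in `[0, 1]`: probability that a plot
#'   draws a species from its district's preferred deep clade.
#' @param n_individuals stems per plot.
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` in decimal degrees.
#' @param root_age root age of the simulated tree (Myr-like units).
#' @return a list of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 1, n_species = 1687, n_plots = 62,
                              n_districts = 3, birth_rate = 0.1,
                              alpha = 100, beta = 0.9, n_individuals = 600,
                              bbox = c(-78, -75, -5, 0.5), root_age = 100) {
  stopifnot(n_species >= 4, n_plots >= n_districts, n_districts >= 1,
            beta >= 0, beta <= 1, alpha > 0, n_individuals >= 1)
  structure(list(seed = seed, n_species = n_species, n_plots = n_plots,
                 n_districts = n_districts, birth_rate = birth_rate,
                 alpha = alpha, beta = beta, n_individuals = n_individuals,
                 bbox = as.numeric(bbox), root_age = root_age),
            class = "sim_config")
}

#' Simulate a dated regional phylogeny
#'
#' Pure-birth (Yule) tree conditioned on the number of tips, rescaled so the
#' root age equals `root_age`; tips are renamed `sp0001...` and internal
#' nodes labelled `n1...` so calibration tables can reference them.
#'
#' @param n_species number of tips (>= 4).
#' @param birth_rate per-lineage speciation rate.
#' @param seed optional integer seed.
#' @param root_age root age after rescaling.
#' @return an ultrametric `"phylo"` object.
#' @export
simulate_tree <- function(n_species, birth_rate = 0.1, seed = NULL,
                          root_age = 100) {
  if (n_species < 4) stop("n_species must be at least 4")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * root_age / depth
  tr$tip.label <- sprintf("sp%04d", seq_len(n_species))
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  tr
}

## Log-series species-abundance sampler.  Fisher's model links alpha, N and
## the parameter x through N = alpha * x / (1 - x); individual species
## abundances then follow P(n) = -x^n / (n * log(1 - x)).
logseries_x <- function(alpha, N) N / (N + alpha)

rlogseries <- function(m, x, nmax = 100000L) {
  p <- -x^seq_len(nmax) / (seq_len(nmax) * log1p(-x))
  cdf <- cumsum(p)
  cdf <- cdf / cdf[length(cdf)]
  findInterval(runif(m), cdf) + 1L
}

## Deep clades for district preferences: cut the tree at the shallowest
## level yielding >= k subtrees by repeatedly splitting the subtree whose
## root is oldest; keep splitting until the k-th largest clade reaches
## min_size tips (Yule root splits are often very unbalanced, and a
## district's preferred clade must be able to hold a plot's richness).
## Returns a list of tip-name sets, largest first.
deep_clades <- function(tree, k, min_size = 1) {
  ages <- node_ages(tree)
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(nt + tree$Nnode)))
  desc_tips <- function(v) {
    tips <- integer(0); stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (u <= nt) tips <- c(tips, u) else stack <- c(stack, kids[[u]])
    }
    tips
  }
  n_desc <- function(v) if (v <= nt) 1L else length(desc_tips(v))
  roots <- kids[[root_node(tree)]]
  kth_size <- function(rs) {
    sz <- sort(vapply(rs, n_desc, integer(1)), decreasing = TRUE)
    if (length(sz) < k) 0L else sz[k]
  }
  best <- roots
  for (iter in seq_len(200)) {
    if (length(roots) >= k && kth_size(roots) >= min_size) break
    internal <- roots[roots > nt]
    if (!length(internal)) break
    split_at <- internal[which.max(ages[internal])]
    roots <- c(setdiff(roots, split_at), kids[[split_at]])
    if (kth_size(roots) >= kth_size(best)) best <- roots
  }
  if (kth_size(roots) < kth_size(best)) roots <- best
  if (length(roots) < k) stop("tree cannot be cut into ", k, " subtrees")
  sets <- lapply(roots, function(v) tree$tip.label[desc_tips(v)])
  sets[order(-lengths(sets))]
}

#' Simulate a plot network over a regional tree
#'
#' Plots sit uniformly within district-specific latitudinal bands.  Each
#' plot's species count and abundances are drawn from a log-series tuned to
#' the target Fisher's alpha at `n_individuals` stems; species identities
#' fall in the district's preferred deep clade with probability `beta` and
#' in the remainder of the pool otherwise.
#'
#' @param tree regional phylogeny (tips = species pool).
#' @param config a [simulation_config()].
#' @param seed optional integer seed (use [simulate_bundle()] for a fully
#'   seeded tree + community draw).
#' @return list of class `"synthetic_bundle"`: `tree`, `comm`
#'   (plots x all pool species), `coords`, `districts` (named integer
#'   vector), `clades` (preferred tip sets), `config`.
#' @export
simulate_communities <- function(tree, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- config$n_districts
  s_expect <- config$alpha * log1p(config$n_individuals / config$alpha)
  min_size <- min(ceiling(1.2 * s_expect),
                  floor(config$n_species / k))
  clades <- deep_clades(tree, k, min_size = min_size)[seq_len(k)]
  n_plots <- config$n_plots
  district <- rep(seq_len(k), length.out = n_plots)
  district <- sort(district)
  b <- config$bbox
  band_h <- (b[4] - b[3]) / k
  lat <- b[3] + (district - 1) * band_h + runif(n_plots) * band_h
  lon <- runif(n_plots, b[1], b[2])
  N <- config$n_individuals
  x <- logseries_x(config$alpha, N)
  pool <- tree$tip.label
  comm <- matrix(0L, n_plots, length(pool),
                 dimnames = list(sprintf("plot%02d", seq_len(n_plots)), pool))
  for (i in seq_len(n_plots)) {
    counts <- integer(0)
    while (sum(counts) < N) counts <- c(counts, rlogseries(32L, x))
    over <- sum(counts) - N
    cum <- cumsum(counts)
    counts <- counts[cum - counts < N]        # drop species entirely past N
    counts[length(counts)] <- counts[length(counts)] - (sum(counts) - N)
    if (counts[length(counts)] == 0L) counts <- counts[-length(counts)]
    S <- min(length(counts), length(pool))
    pref <- clades[[district[i]]]
    ## bias: with probability beta a species comes from the preferred deep
    ## clade, otherwise from the whole pool (so beta = 0 is uniform and the
    ## district labels carry no compositional signal)
    n_pref <- min(stats::rbinom(1, S, config$beta), length(pref))
    sp <- sample(pref, n_pref)
    sp <- c(sp, sample(setdiff(pool, sp), S - n_pref))
    comm[i, sp] <- counts[seq_len(S)]
  }
  coords <- data.frame(plot_id = rownames(comm), lon = lon, lat = lat,
                       stringsAsFactors = FALSE)
  rownames(coords) <- coords$plot_id
  structure(list(tree = tree, comm = comm, coords = coords,
                 districts = setNames(district, rownames(comm)),
                 clades = clades, config = config),
            class = "synthetic_bundle")
}

#' Simulate a complete synthetic bundle
#'
#' Seeds the RNG once and draws the tree and the plot network in a single
#' stream, so a given configuration always yields the identical bundle.
#'
#' @param config a [simulation_config()].
#' @return a `"synthetic_bundle"` (see [simulate_communities()]).
#' @export
simulate_bundle <- function(config = simulation_config()) {
  set.seed(config$seed)
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        root_age = config$root_age)
  simulate_communities(tree, config)
}

#' Write a synthetic bundle to disk
#'
#' Writes `tree.nwk`, `community.csv`, `coords.csv` and `truth.json`
#' (district labels and generating parameters).  Re-running with the same
#' configuration reproduces byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
generate_bundle <- function(config = simulation_config(), dir) {
  bundle <- simulate_bundle(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  write_community(bundle$comm, file.path(dir, "community.csv"))
  write.csv(bundle$coords, file.path(dir, "coords.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- list(districts = as.list(bundle$districts),
                config = unclass(config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
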