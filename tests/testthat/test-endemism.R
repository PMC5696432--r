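test_that("clade ranges count occupied units and grow root-ward", {
  tr <- read_newick(text = "(A:1,B:1);")
  cm <- rbind(plot1 = c(A = 2L, B = 1L), plot2 = c(A = 0L, B = 3L))
  r <- clade_ranges(tr, cm)
  ## edge order follows tr$edge; map via tip children
  tipA <- which(tr$edge[, 2] == match("A", tr$tip.label))
  tipB <- which(tr$edge[, 2] == match("B", tr$tip.label))
  expect_equal(r[tipA], 1L)
  expect_equal(r[tipB], 2L)

  all_everywhere <- rbind(p1 = c(A = 1L, B = 1L), p2 = c(A = 1L, B = 1L))
  expect_true(all(clade_ranges(tr, all_everywhere) == 2L))

  set.seed(61)
  for (i in 1:20) {
    fx <- random_fixture(n_tips = sample(5:12, 1), n_plots = 4)
    r <- clade_ranges(fx$tree, fx$comm)
    ## parent edge range >= child edge range
    for (e in seq_len(nrow(fx$tree$edge))) {
      pe <- which(fx$tree$edge[, 2] == fx$tree$edge[e, 1])
      if (length(pe)) expect_gte(r[pe], r[e])
    }
  }
})

test_that("grid-cell ranges pool plots within cells", {
  tr <- read_newick(text = "(A:1,B:1);")
  cm <- rbind(p1 = c(A = 1L, B = 1L), p2 = c(A = 0L, B = 1L),
              p3 = c(A = 0L, B = 1L))
  coords <- data.frame(lon = c(-76.1, -76.2, -75.1), lat = c(-1.1, -1.2, -0.2),
                       row.names = c("p1", "p2", "p3"))
  r <- clade_ranges(tr, cm, unit = "grid", coords = coords)
  tipB <- which(tr$edge[, 2] == match("B", tr$tip.label))
  expect_equal(r[tipB], 2L)  # p1+p2 share a cell
  expect_error(clade_ranges(tr, cm, unit = "grid"), "coordinates")
})

test_that("WPE divides branch lengths by clade range", {
  tr <- read_newick(text = "(A:1,B:1);")
  cm <- rbind(plot1 = c(A = 1L, B = 1L), plot2 = c(A = 0L, B = 2L))
  w <- weighted_phylogenetic_endemism(tr, cm)
  expect_equal(unname(w), c(1 / 1 + 1 / 2, 1 / 2))

  set.seed(67)
  for (i in 1:20) {
    fx <- random_fixture(n_tips = sample(5:10, 1), n_plots = 3)
    w <- weighted_phylogenetic_endemism(fx$tree, fx$comm)
    pd <- vapply(rownames(fx$comm), function(p)
      faith_pd(fx$tree, fx$comm[p, ]), numeric(1))
    expect_true(all(w <= pd + 1e-12))        # ranges >= 1
    expect_equal(w[["p1"]], oracle_wpe(fx$tree, fx$comm, "p1"),
                 tolerance = 1e-12)
  }

  ## single-plot landscape: WPE reduces to Faith PD
  solo <- rbind(only = c(A = 1L, B = 1L))
  expect_equal(unname(weighted_phylogenetic_endemism(tr, solo)),
               faith_pd(tr, c("A", "B")))
})

test_that("AED partitions each branch across its individuals", {
  ## cherry with a stem: root above ((A,B))
  tr <- structure(list(edge = cbind(c(3L, 4L, 4L), c(4L, 1L, 2L)),
                       Nnode = 2L, tip.label = c("A", "B"),
                       edge.length = c(1, 1, 1)), class = "phylo")
  v <- aed(tr, rbind(p = c(A = 3L, B = 1L)), "p")
  expect_equal(v[["A"]], 1 / 3 + 1 / 4)
  expect_equal(v[["B"]], 1 / 1 + 1 / 4)

  ## single species: n * AED = path length
  tr2 <- read_newick(text = "((A:1,B:1):1,C:2);")
  v2 <- aed(tr2, rbind(p = c(A = 0L, B = 0L, C = 5L)), "p")
  expect_equal(5 * v2[["C"]], 2)

  set.seed(71)
  for (i in 1:100) {
    fx <- random_fixture(n_tips = sample(4:12, 1), n_plots = 2)
    ab <- fx$comm[1, ]
    v <- aed(fx$tree, fx$comm, "p1")
    expect_equal(sum(ab[names(v)] * v), faith_pd(fx$tree, ab),
                 tolerance = 1e-9)
    expect_equal(v, oracle_aed(fx$tree, ab)[names(v)], tolerance = 1e-12)
  }
})

test_that("IAC measures deviation from even splits", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(iac(tr, rbind(p = c(A = 2L, B = 2L, C = 2L, D = 2L)), "p"), 0)
  expect_equal(iac(tr, rbind(p = c(A = 4L, B = 2L, C = 1L, D = 1L)), "p"),
               4 / 3)
  two <- read_newick(text = "(A:1,B:1);")
  expect_equal(iac(two, rbind(p = c(A = 3L, B = 1L)), "p"), 2)

  ## doubling abundances doubles IAC
  set.seed(73)
  for (i in 1:20) {
    fx <- random_fixture(n_tips = sample(4:10, 1), n_plots = 2)
    i1 <- iac(fx$tree, fx$comm, "p1")
    i2 <- iac(fx$tree, fx$comm * 2L, "p1")
    expect_equal(i2, 2 * i1, tolerance = 1e-9)
    expect_equal(i1, oracle_iac(fx$tree, fx$comm[1, ]), tolerance = 1e-12)
  }
})

test_that("endemism table assembles per-plot WPE, IAC and mean AED", {
  set.seed(79)
  fx <- random_fixture(n_tips = 10, n_plots = 4)
  tab <- endemism_table(fx$tree, fx$comm)
  expect_equal(tab$plot_id, rownames(fx$comm))
  expect_true(all(tab$WPE >= 0))
  expect_equal(tab$WPE,
               unname(weighted_phylogenetic_endemism(fx$tree, fx$comm)))
  expect_equal(tab$mean_AED[1], mean(aed(fx$tree, fx$comm, "p1")))
})
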