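test_that("Sorenson dissimilarity matches the incidence formula", {
  cm <- rbind(p1 = c(a = 2L, b = 1L, c = 1L, d = 0L),
              p2 = c(a = 1L, b = 3L, c = 0L, d = 2L))
  D <- sorenson_matrix(cm)
  expect_equal(D["p1", "p2"], 1 - 4 / 6)  # a=2 shared, b=1, c=1

  same <- rbind(p1 = c(a = 1L, b = 2L), p2 = c(a = 3L, b = 1L))
  expect_equal(sorenson_matrix(same)["p1", "p2"], 0)

  disj <- rbind(p1 = c(a = 1L, b = 1L, c = 0L, d = 0L),
                p2 = c(a = 0L, b = 0L, c = 1L, d = 1L))
  expect_equal(sorenson_matrix(disj)["p1", "p2"], 1)
  expect_true(isSymmetric(unname(sorenson_matrix(disj))))
})

test_that("PhyloSorenson dissimilarity follows shared spanning branch length", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cm <- rbind(p1 = c(A = 1L, B = 1L, C = 0L, D = 0L),
              p2 = c(A = 0L, B = 0L, C = 1L, D = 1L),
              p3 = c(A = 1L, B = 1L, C = 0L, D = 0L))
  D <- phylosor_matrix(tr, cm)
  expect_equal(D["p1", "p2"], 1)   # disjoint clades share no edges
  expect_equal(D["p1", "p3"], 0)   # identical plots
  expect_true(all(D >= 0 & D <= 1))

  ## stem edges count: spanning({A,C}) = {A, stem_AB, C, stem_CD}
  tr2 <- read_newick(text = "((A:1,B:1):1,C:2);")
  cm2 <- rbind(p1 = c(A = 1L, B = 1L, C = 0L), p2 = c(A = 1L, B = 0L, C = 1L))
  expect_equal(phylosor_matrix(tr2, cm2)["p1", "p2"], 1 - 4 / 7)
})

test_that("PhyloSorenson agrees with oracle and picante on random fixtures", {
  set.seed(43)
  for (i in 1:10) {
    fx <- random_fixture(n_tips = sample(5:10, 1), n_plots = 4)
    D <- phylosor_matrix(fx$tree, fx$comm)
    taxa <- function(p) colnames(fx$comm)[fx$comm[p, ] > 0]
    expect_equal(D["p1", "p2"],
                 oracle_phylosor(fx$tree, taxa("p1"), taxa("p2")),
                 tolerance = 1e-12)
    ref <- 1 - as.matrix(picante::phylosor(fx$comm, fx$tree))
    diag(ref) <- 0
    expect_equal(unname(D), unname(ref[rownames(D), rownames(D)]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("on a star phylogeny PhyloSorenson equals Sorenson", {
  set.seed(47)
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:12, ":1", collapse = ","), ");"))
  for (i in 1:10) {
    cm <- (matrix(runif(48), 4, 12,
                  dimnames = list(paste0("p", 1:4), star$tip.label)) > 0.4) * 1L
    for (r in 1:4) while (sum(cm[r, ]) < 1) cm[r, sample(12, 1)] <- 1L
    expect_equal(unname(phylosor_matrix(star, cm)),
                 unname(sorenson_matrix(cm)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("null PhyloSorenson has sound structure and direction", {
  set.seed(53)
  tr <- ape::rcoal(20)
  ## two disjoint 6-species clades
  desc <- phangorn::Descendants(tr, 21:39, "tips")
  sizes <- lengths(desc)
  i1 <- which(sizes >= 5 & sizes <= 8)[1]
  cl1 <- desc[[i1]]
  cand <- which(sizes >= 5 & sizes <= 8 &
                  vapply(desc, function(d) !any(d %in% cl1), logical(1)))
  cl2 <- desc[[cand[1]]]
  cm <- matrix(0L, 6, 20, dimnames = list(paste0("p", 1:6), tr$tip.label))
  for (i in 1:3) cm[i, sample(tr$tip.label[cl1], 4)] <- 1L
  for (i in 4:6) cm[i, sample(tr$tip.label[cl2], 4)] <- 1L
  nl <- null_phylosor(tr, cm, n_null = 199, seed = 3)
  expect_true(isSymmetric(unname(nl$deviation)))
  expect_equal(unname(diag(nl$deviation)), rep(0, 6))
  expect_equal(nl$deviation, nl$observed - nl$expected,
               ignore_attr = TRUE, tolerance = 1e-12)
  ## between-clade pairs: observed turnover above null expectation
  between <- nl$deviation[1:3, 4:6]
  expect_true(mean(between) > 0)
})

test_that("an uninformative star phylogeny gives observed close to null PBD", {
  set.seed(59)
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:15, ":1", collapse = ","), ");"))
  cm <- (matrix(runif(90), 6, 15,
                dimnames = list(paste0("p", 1:6), star$tip.label)) > 0.5) * 1L
  for (r in 1:6) while (sum(cm[r, ]) < 2) cm[r, sample(15, 1)] <- 1L
  nl <- null_phylosor(star, cm, n_null = 199, seed = 4)
  lt <- lower.tri(nl$deviation)
  expect_lt(abs(mean(nl$deviation[lt])), 0.05)
})

test_that("mean row dissimilarity averages off-diagonal entries", {
  D <- matrix(0, 2, 2); D[1, 2] <- D[2, 1] <- 0.4
  expect_equal(unname(mean_row_dissimilarity(D)), c(0.4, 0.4))

  D3 <- matrix(0, 3, 3)
  D3[1, 2] <- D3[2, 1] <- 0.2
  D3[1, 3] <- D3[3, 1] <- 0.4
  D3[2, 3] <- D3[3, 2] <- 0.6
  expect_equal(unname(mean_row_dissimilarity(D3)), c(0.3, 0.4, 0.5))
  expect_equal(unname(mean_row_dissimilarity(matrix(0, 4, 4))), rep(0, 4))
})
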