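test_that("Faith PD matches hand examples and picante", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, "A"), 2)
  expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length))
  expect_error(faith_pd(tr, character(0)), "empty")

  set.seed(13)
  tr <- ape::rtree(12)
  cm <- (matrix(runif(36), 3, 12,
                dimnames = list(paste0("p", 1:3), tr$tip.label)) > 0.5) * 1L
  cm[cm == 0 & col(cm) <= 2] <- 1L  # no empty plots
  mine <- vapply(rownames(cm), function(p) faith_pd(tr, cm[p, ]), numeric(1))
  ref <- picante::pd(cm, tr)$PD
  expect_equal(unname(mine), ref, tolerance = 1e-9)
})

test_that("Faith PD agrees with the edge-marking oracle on all subsets", {
  set.seed(17)
  tr <- ape::rtree(8)
  subsets <- unlist(lapply(1:8, function(k)
    combn(tr$tip.label, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets)
    expect_equal(faith_pd(tr, s), oracle_pd(tr, s), tolerance = 1e-12)
})

test_that("MPD averages patristic distances, weighted and unweighted", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(mpd(tr, c("A", "B", "C")), 10 / 3)
  expect_equal(mpd(tr, c(A = 1, B = 1, C = 0), weighted = TRUE), 2)
  expect_error(mpd(tr, "A"), "2 species")

  ## equal abundances: weighted == unweighted
  set.seed(19)
  for (i in 1:25) {
    tr <- ape::rtree(sample(4:10, 1))
    ab <- setNames(rep(3, length(tr$tip.label)), tr$tip.label)
    expect_equal(mpd(tr, ab, weighted = TRUE),
                 mpd(tr, names(ab)), tolerance = 1e-12)
  }

  ## unequal abundances cross-checked against picante, whose weighted mean
  ## keeps the zero-distance i = j pairs: rescale by the weight it adds
  tr <- ape::rtree(9)
  ab <- setNames(rpois(9, 3) + 1, tr$tip.label)
  cmat <- matrix(ab, 1, dimnames = list("p1", names(ab)))
  off_w <- sum(ab)^2 - sum(ab^2)
  expect_equal(mpd(tr, ab, weighted = TRUE) * off_w / sum(ab)^2,
               picante::mpd(cmat, tip_distance_matrix(tr),
                            abundance.weighted = TRUE),
               tolerance = 1e-9)
})

test_that("independent swap preserves margins exactly", {
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  s <- independent_swap(m, 1, seed = 1)
  expect_equal(c(s), c(0, 1, 1, 0))

  set.seed(23)
  for (i in 1:5) {
    m <- (matrix(runif(1000), 20, 50) > 0.6) * 1L
    s <- independent_swap(m, n_swaps = 10000, seed = i)
    expect_identical(rowSums(s), rowSums(m))
    expect_identical(colSums(s), colSums(m))
    expect_false(attr(s, "gave_up"))
  }

  ones <- matrix(1L, 3, 3)
  expect_warning(s <- independent_swap(ones, 5, max_fail = 500), "checkerboard")
  expect_equal(unname(s[, ]), unname(ones))
})

test_that("swap chains reach every matrix with the given margins", {
  ## 3x3 permutation-matrix margins: exactly 6 reachable states
  seed_m <- diag(1L, 3)
  seen <- character(0)
  set.seed(29)
  state <- seed_m
  for (step in 1:400) {
    state <- independent_swap(state, 1)
    seen <- union(seen, paste(state, collapse = ""))
  }
  all_states <- apply(gtools_perms(3), 1, function(p)
    paste(diag(3)[p, ], collapse = ""))
  expect_setequal(seen, unique(all_states))
})

test_that("ses.MPD flags clade-restricted communities as clustered", {
  set.seed(31)
  tr <- ape::rcoal(64)
  ## two disjoint deep clades; every plot confined to one of them, so the
  ## swap null (which mixes both) sees each plot as phylogenetically tight
  desc <- phangorn::Descendants(tr, 65:127, "tips")
  sizes <- lengths(desc)
  i1 <- which(sizes >= 12 & sizes <= 30)[1]
  cl1 <- desc[[i1]]
  i2 <- which(sizes >= 12 & sizes <= 30 &
                vapply(desc, function(d) !any(d %in% cl1), logical(1)))[1]
  cl2 <- desc[[i2]]
  n_plots <- 20
  cm <- matrix(0L, n_plots, 64, dimnames = list(paste0("p", 1:n_plots), tr$tip.label))
  for (i in 1:n_plots) {
    cl <- if (i %% 2) cl1 else cl2
    cm[i, sample(tr$tip.label[cl], 8)] <- 1L
  }
  res <- ses_mpd(tr, cm, n_null = 199, seed = 1)
  expect_true(mean(res$ses < -1.96) >= 0.9)        # low MPD vs null
  expect_true(all(res$label[res$ses < -1.96] == "overdispersed"))
  ## paper convention labels the positive tail "clustered"
  res_std <- ses_mpd(tr, cm, n_null = 99, seed = 1, convention = "standard")
  expect_true(all(res_std$label[res_std$ses < -1.96] == "clustered"))
})

test_that("ses.MPD handles degenerate plots and centres correctly", {
  set.seed(37)
  tr <- ape::rtree(10)
  cm <- matrix(rbinom(50, 1, 0.5), 5, 10,
               dimnames = list(paste0("p", 1:5), tr$tip.label))
  cm[1, ] <- 0L; cm[1, 3] <- 1L           # single-species plot
  cm[2, cm[2, ] == 0][1] <- 1L
  for (i in 3:5) while (sum(cm[i, ]) < 2) cm[i, sample(10, 1)] <- 1L
  res <- ses_mpd(tr, cm, n_null = 99, seed = 2)
  expect_equal(res$label[1], "undefined")
  expect_true(is.na(res$obs[1]))
  ok <- !is.na(res$ses)
  expect_equal(res$ses[ok],
               (res$obs[ok] - res$null_mean[ok]) / res$null_sd[ok],
               tolerance = 1e-12)
  expect_true(all(res$quantile[ok] > 0 & res$quantile[ok] <= 1))
})
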