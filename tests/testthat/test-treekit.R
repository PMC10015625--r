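# Tree building, canonical topologies, weighting, counting, quartet score.

test_that("nj_tree recovers clean splits and joins zero-distance tips", {
  # two clearly separated clusters of dosage profiles
  dos <- cbind(a1 = c(2L, 2L, 0L, 0L, 0L, 0L),
               a2 = c(2L, 2L, 0L, 0L, 0L, 1L),
               b1 = c(0L, 0L, 2L, 2L, 0L, 0L),
               b2 = c(0L, 0L, 2L, 2L, 0L, 1L))
  gm <- make_gm(dos, rep("X", 4))
  tr <- nj_tree(gm)
  id <- canonical_topology(tr, outgroup = "a1", keep_outgroup = TRUE)
  expect_equal(id, "(((b1,b2),a2),a1)")  # rooted at a1

  # duplicated columns are siblings
  dos2 <- cbind(u = c(2L, 0L, 1L), v = c(2L, 0L, 1L),
                w = c(0L, 2L, 0L), x = c(1L, 1L, 2L))
  tr2 <- nj_tree(make_gm(dos2, rep("X", 4)))
  id2 <- canonical_topology(tr2, outgroup = "w", keep_outgroup = TRUE)
  expect_true(grepl("(u,v)", id2, fixed = TRUE))

  expect_error(nj_tree(make_gm(dos2[, 1:3], rep("X", 3))), "at least 4")
})

test_that("nj_tree equals ape::nj on the hand-computed p-distance matrix", {
  set.seed(41)
  dos <- matrix(sample(c(0:2, NA), 8 * 60, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 60, 8)
  colnames(dos) <- letters[1:8]
  gm <- make_gm(dos, rep("X", 8))
  D <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  for (i in 1:7) for (j in (i + 1):8) {
    ok <- !is.na(dos[, i]) & !is.na(dos[, j])
    D[i, j] <- D[j, i] <- sum(abs(dos[ok, i] - dos[ok, j])) / (2 * sum(ok))
  }
  expect_equal(suppressWarnings(
    ape::dist.topo(ape::unroot(nj_tree(gm)), ape::unroot(ape::nj(D))))[1], 0)
})

test_that("canonical IDs are rotation-invariant and NNI-discriminating", {
  expect_equal(canonical_topology("((B,A),(D,C));"),
               canonical_topology("((C,D),(B,A));"))
  expect_false(canonical_topology("((A,B),(C,D));") ==
                 canonical_topology("((A,C),(B,D));"))
  # unrooted input needs an outgroup
  unrooted <- ape::unroot(ape::read.tree(text = "((A,B),(C,D),E);"))
  expect_error(canonical_topology(unrooted), "outgroup")
  expect_type(canonical_topology(unrooted, outgroup = "E"), "character")
})

test_that("canonical IDs agree with a pairwise isomorphism oracle", {
  set.seed(43)
  trees <- lapply(1:40, function(i) ape::rtree(7, br = NULL))
  ids <- vapply(trees, canonical_topology, "")
  iso <- function(t1, t2) {
    # isomorphism oracle: unrooted RF distance on trees augmented with a
    # dummy outgroup attached at the root keeps rooted shape information
    aug <- function(t) {
      t$root.edge <- 1
      ape::bind.tree(t, ape::read.tree(text = "(zzz_dummy:1);"),
                     position = 0.5)
    }
    suppressWarnings(ape::dist.topo(aug(t1), aug(t2)))[1] == 0
  }
  for (i in 1:15) for (j in (i + 1):16) {
    expect_equal(ids[i] == ids[j], iso(trees[[i]], trees[[j]]),
                 info = paste(i, j))
  }
})

test_that("topology counts match the double factorial and enumeration", {
  expect_equal(count_topologies(4, rooted_with_fixed_outgroup = TRUE), 3)
  expect_equal(count_topologies(5, rooted_with_fixed_outgroup = TRUE), 15)
  expect_equal(count_topologies(8, rooted_with_fixed_outgroup = TRUE), 10395)
  for (n in 2:6)
    expect_equal(count_topologies(n, rooted_with_fixed_outgroup = FALSE),
                 length(enumerate_topologies(letters[1:n])))
})

test_that("weighting is exact for one tip per group and sums to one", {
  tr <- ape::read.tree(text = "(((a1:1,b1:1):1,c1:2):1,o1:3);")
  gmap <- c(a1 = "A", b1 = "B", c1 = "C", o1 = "O")
  w <- topology_weighting(tr, gmap, outgroup_group = "O")
  expect_equal(unname(w$weights), 1)
  expect_equal(names(w$weights), "(((A,B),C),O)")

  tr2 <- ape::read.tree(text = "((((a1:1,b1:1):1,(a2:1,b2:1):1):1,c1:3):1,o1:4);")
  gmap2 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", o1 = "O")
  w2 <- topology_weighting(tr2, gmap2, outgroup_group = "O")
  expect_equal(sum(w2$weights), 1)
  expect_equal(w2$method, "exhaustive")
})

test_that("weighting is invariant to tip relabeling within a group", {
  tr <- ape::read.tree(text = "((((a1:1,b1:1):1,(a2:1,b2:1):1):1,c1:3):1,o1:4);")
  gmap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", o1 = "O")
  w1 <- topology_weighting(tr, gmap, outgroup_group = "O")
  tr2 <- tr
  tr2$tip.label[tr2$tip.label == "a1"] <- "tmp"
  tr2$tip.label[tr2$tip.label == "a2"] <- "a1"
  tr2$tip.label[tr2$tip.label == "tmp"] <- "a2"
  w2 <- topology_weighting(tr2, gmap, outgroup_group = "O")
  expect_equal(w1$weights[sort(names(w1$weights))],
               w2$weights[sort(names(w2$weights))])
})

test_that("Monte-Carlo weighting agrees with exhaustive within 3 SE", {
  set.seed(45)
  tr <- ape::rtree(9, br = NULL)
  tr$edge.length <- rep(1, nrow(tr$edge))
  gmap <- stats::setNames(rep(c("A", "B", "C", "D"), length.out = 9),
                          tr$tip.label)
  ex <- topology_weighting(tr, gmap, method = "exhaustive")
  n_mc <- 3000
  mc <- topology_weighting(tr, gmap, method = "montecarlo",
                           n_samples = n_mc, seed = 47)
  for (id in names(ex$weights)) {
    p <- ex$weights[id]
    se <- sqrt(p * (1 - p) / n_mc)
    expect_lt(abs((mc$weights[id] %||% 0) - p), 3 * se + 1e-9)
  }
  # >8 groups refused, empty group refused
  gmap9 <- stats::setNames(paste0("g", 1:9), tr$tip.label)
  expect_error(topology_weighting(tr, gmap9), "eight")
})

test_that("main topologies average window weights and apply the threshold", {
  w <- function(x) structure(list(weights = x, method = "exhaustive",
                                  n_samples = 1, groups = c("A", "B")),
                             class = "weighting_result")
  res <- main_topologies(list(w(c(T1 = 0.6, T2 = 0.4)),
                              w(c(T1 = 0.8, T3 = 0.2))),
                         freq_threshold = 0.15)
  expect_equal(res$frequency[res$topology == "T1"], 0.7)
  expect_equal(res$frequency[res$topology == "T2"], 0.2)
  expect_equal(res$frequency[res$topology == "T3"], 0.1)
  expect_equal(res$main, c(TRUE, TRUE, FALSE))
  # single window: weights are the frequencies; threshold 0 keeps all
  res1 <- main_topologies(list(w(c(T1 = 0.6, T2 = 0.4))), freq_threshold = 0)
  expect_equal(res1$frequency, c(0.6, 0.4))
  expect_true(all(res1$main))
})

test_that("quartet score is exact on agreement, monotone under NNI, and
          matches the pruning oracle", {
  sp <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
  expect_equal(quartet_score(sp, list(sp, sp))$score, 1)

  swapped <- ape::read.tree(text = "(((A:1,C:1):1,(B:1,D:1):1):1,(E:2,F:2):1);")
  expect_lt(quartet_score(sp, list(swapped))$score, 1)

  set.seed(49)
  gts <- lapply(1:20, function(i) ape::rtree(7, tip.label = paste0("t", 1:7)))
  sp7 <- ape::rtree(7, tip.label = paste0("t", 1:7))
  qs <- quartet_score(sp7, gts)
  expect_equal(qs$score, oracle_quartet_score(sp7, gts), tolerance = 1e-12)
  expect_equal(qs$n_quartets, 20 * choose(7, 4))

  # invariant to gene-tree order and branch lengths
  gts2 <- rev(lapply(gts, function(g) { g$edge.length <- runif(nrow(g$edge)); g }))
  expect_equal(quartet_score(sp7, gts2)$score, qs$score)
})

test_that("quartet score handles multi-tip species via the group map", {
  sp <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  # a1 sits with b1 (quartet matches AB|CD); a2 sits with c1 (mismatch)
  gt <- ape::read.tree(text = "((a1:1,b1:1):1,((a2:1,c1:1):1,d1:2):1);")
  gmap <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", d1 = "D")
  qs <- quartet_score(sp, list(gt), group_map = gmap)
  # one species quartet {A,B,C,D}, two tip choices for A
  expect_equal(qs$n_quartets, 2L)
  expect_equal(qs$score, 0.5)
})
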