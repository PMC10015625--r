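# ABBA-BABA machinery against hand values and brute-force oracles.

test_that("pattern counts match definitions and the per-site oracle", {
  pf <- make_pf(3, c("P1", "P2", "P3"), seed = 1)
  pf$freq[1, ] <- c(0, 1, 1)    # pure ABBA site
  pc <- pattern_counts(pf, "P1", "P2", "P3", n_blocks = 1)
  o <- oracle_abba_baba(pf$freq[, 1], pf$freq[, 2], pf$freq[, 3])
  expect_equal(pc$ABBA, unname(o["ABBA"]))
  expect_equal(pc$BABA, unname(o["BABA"]))

  pf1 <- make_pf(1, c("P1", "P2", "P3"))
  pf1$freq[1, ] <- c(0, 1, 1)
  pc1 <- pattern_counts(pf1, "P1", "P2", "P3", n_blocks = 1)
  expect_equal(pc1$ABBA, 1)
  expect_equal(pc1$BABA, 0)

  # p2 == p1 everywhere -> symmetric counts
  pf2 <- make_pf(200, c("P1", "P2", "P3"), seed = 3)
  pf2$freq[, "P2"] <- pf2$freq[, "P1"]
  pc2 <- pattern_counts(pf2, "P1", "P2", "P3")
  expect_equal(pc2$ABBA, pc2$BABA)
  expect_equal(d_statistic(pc2)$D, 0)

  # 1,000 random sites, seed 3: exact agreement with the loop oracle
  pf3 <- make_pf(1000, c("P1", "P2", "P3"), seed = 3)
  pc3 <- pattern_counts(pf3, "P1", "P2", "P3")
  o3 <- oracle_abba_baba(pf3$freq[, 1], pf3$freq[, 2], pf3$freq[, 3])
  expect_equal(pc3$ABBA, unname(o3["ABBA"]))
  expect_equal(pc3$BABA, unname(o3["BABA"]))
  expect_equal(sum(pc3$abba_blocks), pc3$ABBA)
  expect_equal(sum(pc3$baba_blocks), pc3$BABA)
})

test_that("D is antisymmetric in (P1, P2) with unchanged |Z|", {
  pf <- make_pf(500, c("P1", "P2", "P3"), seed = 5)
  d12 <- d_statistic(pattern_counts(pf, "P1", "P2", "P3"))
  d21 <- d_statistic(pattern_counts(pf, "P2", "P1", "P3"))
  expect_equal(d12$D, -d21$D)
  expect_equal(abs(d12$Z), abs(d21$Z))
  expect_equal(d12$p, d21$p)
  expect_true(abs(d12$D) <= 1)
})

test_that("jackknife variance equals an explicit leave-one-out recomputation", {
  pf <- make_pf(400, c("P1", "P2", "P3"), seed = 7)
  g <- 20
  pc <- pattern_counts(pf, "P1", "P2", "P3", n_blocks = g)
  d <- d_statistic(pc)
  # independent recomputation: drop each block of sites and recompute D
  blk <- introscape:::block_assignment(400, g)
  Dj <- sapply(seq_len(g), function(j) {
    keep <- blk != j
    o <- oracle_abba_baba(pf$freq[keep, 1], pf$freq[keep, 2], pf$freq[keep, 3])
    (o["ABBA"] - o["BABA"]) / (o["ABBA"] + o["BABA"])
  })
  se <- sqrt((g - 1) / g * sum((Dj - mean(Dj))^2))
  expect_equal(d$Z, d$D / se, tolerance = 1e-12)
})

test_that("D is undefined on zero counts and flagged", {
  pf <- make_pf(10, c("P1", "P2", "P3"))
  pf$freq[, "P3"] <- 0
  d <- d_statistic(pattern_counts(pf, "P1", "P2", "P3"))
  expect_true(d$undefined)
  expect_true(is.na(d$D))
})

test_that("d_min picks the zero arrangement for duplicated taxa and is
          permutation invariant", {
  pf <- make_pf(300, c("A", "B", "C"), seed = 9)
  pf$freq[, "B"] <- pf$freq[, "A"]
  dm <- d_min(pf, "A", "B", "C")
  expect_equal(dm$dmin$D, 0)
  expect_setequal(dm$dmin$trio[c("P1", "P2")], c("A", "B"))

  pf2 <- make_pf(200, c("A", "B", "C"), seed = 11)
  perms <- list(c("A", "B", "C"), c("C", "A", "B"), c("B", "C", "A"))
  res <- lapply(perms, function(p) d_min(pf2, p[1], p[2], p[3]))
  for (r in res[-1]) {
    expect_equal(r$dmin$D, res[[1]]$dmin$D)
    expect_equal(r$dmin$trio, res[[1]]$dmin$trio)
  }
  # brute force over the three arrangements
  arr <- list(c("A", "B", "C"), c("A", "C", "B"), c("B", "C", "A"))
  absd <- sapply(arr, function(a) {
    o <- oracle_abba_baba(pf2$freq[, a[1]], pf2$freq[, a[2]], pf2$freq[, a[3]])
    abs((o["ABBA"] - o["BABA"]) / (o["ABBA"] + o["BABA"]))
  })
  expect_equal(res[[1]]$dmin$D, min(absd), tolerance = 1e-12)
})

test_that("BH adjustment matches hand step-up results", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.02, 0.5)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("f_hom hits its closed-form limits", {
  pf <- make_pf(300, c("P1", "P2", "P3"), seed = 13)
  pf$freq[, "P2"] <- pf$freq[, "P3"]   # complete homogenization
  expect_equal(f_hom(pf, "P1", "P2", "P3"), 1)

  pf0 <- make_pf(300, c("P1", "P2", "P3"), seed = 15)
  pf0$freq[, "P2"] <- pf0$freq[, "P1"]  # no asymmetry in the numerator
  expect_equal(f_hom(pf0, "P1", "P2", "P3"), 0)

  pfz <- make_pf(5, c("P1", "P2", "P3"))
  pfz$freq[, "P3"] <- 0
  expect_warning(expect_true(is.na(f_hom(pfz, "P1", "P2", "P3"))),
                 "undefined")
})

test_that("f_hom_max aggregates the maximum over P1 choices", {
  trios <- data.frame(P1 = c("A", "B"), P2 = c("X", "X"), P3 = c("Y", "Y"),
                      f_hom = c(0.1, 0.3), stringsAsFactors = FALSE)
  out <- f_hom_max(NULL, trios)
  expect_equal(nrow(out), 1L)
  expect_equal(out$f_hom_max, 0.3)
  expect_equal(out$P1_max, "B")
})

test_that("windowed f_dM equals the straight-line per-site oracle", {
  set.seed(17)
  wt <- make_windows(c("1" = 1e5), window_len = 1e4)   # 10 windows
  pf <- make_pf(600, c("P1", "P2", "P3"), seed = 17)
  pf$sites$pos <- sort(sample.int(1e5, 600))
  tr <- f_dm_track(pf, wt, "P1", "P2", "P3", min_snps = 10)
  idx <- introscape:::site_window_index(pf$sites, wt)
  for (w in seq_len(10)) {
    s <- which(idx == w)
    if (length(s) >= 10) {
      expect_equal(tr$fdm[w],
                   oracle_fdm(pf$freq[s, 1], pf$freq[s, 2], pf$freq[s, 3]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(abs(tr$fdm[!is.na(tr$fdm)]) <= 1 + 1e-12))

  # p1 == p2 -> 0
  pfe <- make_pf(200, c("P1", "P2", "P3"), seed = 19)
  pfe$freq[, "P2"] <- pfe$freq[, "P1"]
  pfe$sites$pos <- seq_len(200) * 40L
  tre <- f_dm_track(pfe, make_windows(c("1" = 8000), 8000), "P1", "P2", "P3")
  expect_equal(tre$fdm, 0)

  # window with 9 SNPs is masked at min_snps = 10
  pf9 <- make_pf(9, c("P1", "P2", "P3"), seed = 21)
  tr9 <- f_dm_track(pf9, make_windows(c("1" = 100), 100), "P1", "P2", "P3")
  expect_true(is.na(tr9$fdm))
  expect_equal(tr9$n_snps, 9L)
})

test_that("pIR calling flags exactly the ceil(x% of defined) largest values", {
  set.seed(23)
  wt <- make_windows(c("1" = 1e6), window_len = 1e4)  # 100 windows
  wt$fdm <- runif(100)
  wt$n_snps <- rep(20L, 100)
  expect_equal(sum(call_pir(wt, 0)), 0L)
  expect_equal(sum(call_pir(wt, 100)), 100L)
  p5 <- call_pir(wt, 5)
  expect_equal(sum(p5), 5L)
  expect_setequal(which(p5), order(-wt$fdm)[1:5])
  # negative x (negative f_hom) -> empty
  expect_equal(sum(call_pir(wt, -10)), 0L)
  # ties at the cutoff resolved by genomic order, count stays exact
  wt$fdm <- rep(1, 100)
  p10 <- call_pir(wt, 10)
  expect_equal(which(p10), 1:10)
})

test_that("introgression index is the flagged fraction of defined trios", {
  pir <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
              c(FALSE, TRUE, FALSE))
  ii <- introgression_index(pir)
  expect_equal(ii$index, c(2 / 3, 2 / 3, 0))
  def <- list(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, TRUE),
              c(TRUE, FALSE, TRUE))
  ii2 <- introgression_index(pir, def)
  expect_equal(ii2$index, c(2 / 3, 1 / 2, 0))
  expect_equal(ii2$n_trios, c(3L, 2L, 3L))
})

test_that("ILS-only simulation leaves D centred on zero", {
  m <- default_demography(mu = 2e-8)
  hits <- 0
  for (r in 1:20) {
    sim <- simulate_dataset(m, window_model(150, 1e4),
                            c(P1 = 2, P2 = 2, P3 = 2, P4 = 2, O = 1),
                            seed = 500 + r)
    pf <- polarize(sim$genotypes, outgroup = "O")
    d <- d_statistic(pattern_counts(pf, "P1", "P2", "P3"))
    if (!is.na(d$p) && d$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 4)   # ~1 expected at nominal rate
})
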