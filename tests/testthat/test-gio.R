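# VCF filtering, polarization, window site statistics, gene density.

pm4 <- stats::setNames(c("X", "X", "Y", "O"), c("s1", "s2", "s3", "s4"))

test_that("site filters drop indels, multiallelics and high missingness", {
  body <- c(
    "1\t100\t.\tA\tT,G\t50\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",  # triallelic
    "1\t200\t.\tAT\tA\t50\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",   # indel
    "1\t300\t.\tA\tG\t50\tPASS\t.\tGT\t./.\t./.\t./.\t0/0",    # 75% missing
    "1\t400\t.\tC\tG\t50\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "1\t500\t.\tG\tA\t50\tPASS\t.\tGT\t0/1\t0/1\t0/0\t0/0")
  path <- write_vcf_fixture(body, names(pm4))
  gm <- read_vcf_filtered(path, pm4, outgroup = "O",
                          max_missing_fraction = 0.67)
  expect_equal(gm$sites$pos, c(400L, 500L))
  lg <- attr(gm, "filter_log")
  expect_equal(lg$multiallelic, 1)
  expect_equal(lg$indel, 1)
  expect_equal(lg$missingness, 1)

  # all filters disabled on the clean subset: nothing dropped
  gm_all <- read_vcf_filtered(path, pm4, outgroup = "O",
                              biallelic_only = FALSE,
                              max_missing_fraction = NULL,
                              min_quality = NULL, mean_depth_bounds = NULL)
  expect_equal(nrow(gm_all$sites), 4L)  # only the indel always goes
})

test_that("quality filter and unknown-sample error behave", {
  body <- c("1\t100\t.\tA\tT\t10\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
            "1\t200\t.\tA\tT\t40\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0")
  path <- write_vcf_fixture(body, names(pm4))
  gm <- read_vcf_filtered(path, pm4, min_quality = 30)
  expect_equal(gm$sites$pos, 200L)
  expect_error(read_vcf_filtered(path, pm4[-1]), "absent from the population map")
})

test_that("empty VCF body yields an empty genotype matrix", {
  path <- write_vcf_fixture(character(0), names(pm4))
  gm <- read_vcf_filtered(path, pm4)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(nrow(gm$sites), 0L)
})

test_that("polarization uses the outgroup-fixed allele and drops the rest", {
  # samples: 3 ingroup (pop X/Y) + 2 outgroup diploids
  pops <- c("X", "X", "Y", "O", "O")
  dos <- rbind(
    c(0L, 1L, 2L, 0L, 0L),  # og fixed ref: X freq (0+1)/4, Y 1
    c(0L, 1L, 2L, 2L, 2L),  # og fixed alt: derived = ref
    c(0L, 1L, 2L, 1L, 0L),  # og heterozygous -> dropped
    c(0L, 1L, 2L, NA, NA),  # og missing -> dropped
    c(2L, 2L, 0L, 0L, NA))  # og fixed ref via one sample
  gm <- make_gm(dos, pops, outgroup = "O")
  pf <- polarize(gm)
  expect_equal(nrow(pf$freq), 3L)
  expect_equal(unname(pf$dropped["outgroup_polymorphic"]), 1L)
  expect_equal(unname(pf$dropped["outgroup_missing"]), 1L)
  expect_equal(unname(pf$freq[1, ]), c(X = 0.25, Y = 1), ignore_attr = TRUE)
  # site 2: ancestral is alt, X alt freq 1/4 -> derived 3/4; Y -> 0
  expect_equal(unname(pf$freq[2, "X"]), 0.75)
  expect_equal(unname(pf$freq[2, "Y"]), 0)
})

test_that("a fixture with 2 outgroup-polymorphic sites keeps 8 of 10", {
  pops <- c("X", "X", "O", "O")
  dos <- matrix(0L, 10, 4)
  dos[, 1] <- 1L
  dos[3, 3:4] <- c(1L, 0L)   # og polymorphic
  dos[7, 3:4] <- c(2L, 1L)   # og polymorphic
  pf <- polarize(make_gm(dos, pops, outgroup = "O"))
  expect_equal(nrow(pf$freq), 8L)
})

test_that("population with no genotyped sample gets NA frequency", {
  pops <- c("X", "Y", "O")
  dos <- rbind(c(1L, NA, 0L))
  pf <- polarize(make_gm(dos, pops, outgroup = "O"))
  expect_true(is.na(pf$freq[1, "Y"]))
  expect_equal(unname(pf$freq[1, "X"]), 0.5)
})

test_that("window site stats count PIS at the allele-copy level", {
  # 4 diploid samples; singleton site (1 alt copy) vs 2/6 split site
  pops <- rep("X", 4)
  dos <- rbind(c(1L, 0L, 0L, 0L),
               c(1L, 1L, 0L, 0L))
  gm <- make_gm(dos, pops, pos = c(50L, 60L))
  wt <- make_windows(c("1" = 100), window_len = 100)
  ws <- window_site_stats(gm, wt, min_sites = 2, min_pis = 1)
  expect_equal(ws$n_sites, 2L)
  expect_equal(ws$n_pis, 1L)
  expect_true(ws$pass_flag)

  ws2 <- window_site_stats(gm, wt)  # defaults 200/20
  expect_false(ws2$pass_flag)

  # empty window
  wt0 <- make_windows(c("2" = 1000), window_len = 1000)
  ws0 <- window_site_stats(gm, wt0)
  expect_equal(ws0$n_sites, 0L)
  expect_equal(ws0$n_pis, 0L)
  expect_false(ws0$pass_flag)
})

test_that("window pass thresholds follow the 200-site / 20-PIS rule", {
  set.seed(2)
  n <- 250
  dos <- matrix(sample(0:2, n * 6, replace = TRUE), n, 6)
  gm <- make_gm(dos, rep(c("X", "Y"), 3), pos = sample.int(9999, n))
  wt <- window_site_stats(gm, make_windows(c("1" = 1e4)))
  expect_equal(wt$n_sites, n)
  expect_true(wt$n_pis >= 20)
  expect_true(wt$pass_flag)   # 250 sites, plenty of PIS
})

test_that("gene density is merged-interval coverage per window", {
  wt <- make_windows(c("1" = 3e4), window_len = 1e4)
  ann <- merge_intervals(data.frame(chrom = "1",
                                    start = c(0, 2000, 9000),
                                    end = c(3000, 6000, 21000)))
  gd <- gene_density(ann, wt)
  # [0,3000)+[2000,6000) merge to 6000 bp; window 2 fully covered; window 3
  # overlapped on [20000,21000)
  expect_equal(gd$gene_density, c(0.7, 1.0, 0.1))

  # no overlap
  gd0 <- suppressWarnings(gene_density(merge_intervals(
    data.frame(chrom = "2", start = 0, end = 100)), wt))
  expect_equal(gd0$gene_density, rep(0, 3))

  # invariance to splitting an interval into adjacent pieces
  ann_split <- merge_intervals(data.frame(
    chrom = "1", start = c(0, 1500, 2000, 4000, 9000, 15000),
    end = c(1500, 2000, 4000, 6000, 15000, 21000)))
  expect_equal(gene_density(ann_split, wt)$gene_density, gd$gene_density)
})

test_that("gff gene intervals are read and merged", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t1\t3000\t.\t+\t.\tID=g1",
    "1\tsrc\tgene\t2001\t6000\t.\t-\t.\tID=g2",
    "1\tsrc\tmRNA\t1\t9000\t.\t+\t.\tID=m1"), gff)
  ann <- read_gene_intervals(gff)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$start, 0L)
  expect_equal(ann$end, 6000L)
})

test_that("windows are disjoint, sorted, and index sites correctly", {
  wt <- make_windows(c(chr1 = 25000, chr2 = 9000), window_len = 1e4)
  expect_equal(nrow(wt), 4L)
  expect_equal(wt$end[3], 25000)
  sites <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr3"),
                      pos = c(1L, 10000L, 8999L, 5L))
  idx <- introscape:::site_window_index(sites, wt)
  # pos 10000 is 0-based 9999 -> first window [0,10000)
  expect_equal(idx, c(1L, 1L, 4L, NA))
})
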