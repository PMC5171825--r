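test_that("read counting respects bin boundaries and conserves reads", {
  g <- genome_model(c(chrA = 1000))
  b <- make_bin_boundaries(g, 10)  # width-100 bins
  # a read exactly at a bin start belongs to that bin
  r <- data.frame(chrom = "chrA", pos = c(0, 100, 100, 950))
  cc <- count_reads_in_bins(r, b)
  expect_equal(cc$counts, c(1, 2, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(cc$unassigned, 0)
  # conservation with out-of-range and unknown-chromosome reads
  set.seed(1)
  r2 <- data.frame(chrom = sample(c("chrA", "chrZ"), 500, replace = TRUE),
                   pos = round(runif(500, -50, 1100)))
  cc2 <- count_reads_in_bins(r2, b)
  expect_equal(sum(cc2$counts) + cc2$unassigned, 500)
})

test_that("ratio normalization is exact on degenerate cohorts", {
  # identical samples give all-1 profiles exactly
  m <- matrix(rep(c(5, 10, 20, 5), 3), ncol = 3)
  expect_true(all(normalize_ratios(m) == 1))
  # constant single sample
  expect_true(all(normalize_ratios(rep(7, 50)) == 1))
  # hand evaluation of the two-step formula: one sample doubles one bin
  base <- c(10, 10, 10, 10)
  m2 <- cbind(a = c(20, 10, 10, 10), b = base, c = base)
  r <- normalize_ratios(m2)
  scaled_a <- c(20, 10, 10, 10) / 12.5
  ref <- (scaled_a + 1 + 1) / 3
  expect_equal(unname(r[, "a"]), scaled_a / ref)
  expect_gt(r[1, "a"], 1)
  # cohort-mean-0 bin flagged missing
  m3 <- cbind(c(0, 5, 5), c(0, 5, 5))
  expect_true(all(is.na(normalize_ratios(m3)[1, ])))
})

test_that("GC correction removes quadratic bias and rescales to mean 1", {
  set.seed(2)
  n <- 10000
  gc <- runif(n, 0.3, 0.6)
  flat <- rnorm(n, 1, 0.05)
  out <- gc_correct(flat, gc)
  expect_lt(max(abs(out - flat / mean(flat))), 0.02)
  expect_equal(mean(out), 1, tolerance = 1e-9)
  biased <- flat * (1 - 3 * (gc - 0.45)^2) / mean(1 - 3 * (gc - 0.45)^2)
  # the injected bias is quadratic (symmetric), so measure it on that scale
  expect_gt(abs(cor(biased, (gc - 0.45)^2)), 0.3)
  corr <- gc_correct(biased, gc)
  expect_lt(abs(cor(corr, gc)), 0.05)
  expect_lt(abs(cor(corr, (gc - 0.45)^2)), 0.05)
  expect_equal(mean(corr), 1, tolerance = 1e-9)
  expect_error(gc_correct(rep(1, 5), runif(5)), "at least 10")
})

test_that("segmentation finds single steps and keeps constant tracks whole", {
  expect_equal(nrow(segment_bins(rep(1, 300), seed = 1)$segments), 1)
  set.seed(3)
  x <- c(rnorm(500, 1, 0.1), rnorm(500, 1.5, 0.1))
  sg <- segment_bins(x, seed = 4)
  expect_equal(nrow(sg$segments), 2)
  expect_lt(abs(sg$segments$end_bin[1] - 500), 2.5)
  expect_lt(abs(sg$segments$mean_ratio[2] - 1.5), 0.05)
  expect_equal(sg$segments$state[2], "amplification")
  # segment ratio constant within segments
  expect_equal(length(unique(sg$seg_ratio)), 2)
  # short chromosome becomes a single segment
  sg2 <- segment_bins(c(1, 2, 1), chrom = rep("c", 3), min_width = 3, seed = 1)
  expect_equal(nrow(sg2$segments), 1)
})

test_that("segmentation breakpoints never cross chromosomes", {
  set.seed(5)
  chrom <- rep(c("a", "b"), each = 200)
  x <- c(rnorm(200, 1, 0.05), rnorm(200, 1.6, 0.05))
  sg <- segment_bins(x, chrom = chrom, seed = 6)
  expect_true(all(table(sg$segments$chrom) == 1))
  expect_equal(sort(unique(sg$segments$chrom)), c("a", "b"))
})

test_that("MAPD equals the brute-force enumerated median", {
  expect_equal(mapd(rep(0.3, 100)), 0)
  expect_equal(mapd(c(0, 1, 0, 1)), 1)
  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(50)
    chrom <- sort(sample(c("a", "b"), 50, replace = TRUE))
    expect_identical(mapd(x, chrom), brute_mapd(x, chrom))
  }
  expect_error(mapd(c(1), chrom = "a"), ">= 2 bins")
})

test_that("MAPD filter removes cells at or above the cutoff", {
  set.seed(8)
  # iid log2 noise sd s gives MAPD about 0.954 * s
  lo <- replicate(5, rnorm(500, 0, 0.5))
  hi <- replicate(5, rnorm(500, 0, 2))
  m <- cbind(lo, hi)
  colnames(m) <- paste0("c", 1:10)
  res <- filter_cells_by_mapd(m, cutoff = 1.4)
  expect_identical(res$report$retained, rep(c(TRUE, FALSE), each = 5))
  # inclusive threshold: a cell exactly at the cutoff is removed
  x <- rep(c(0, 1.4), 100)  # every neighbour difference 1.4
  m2 <- cbind(a = x, b = rnorm(200, 0, 0.1))
  res2 <- filter_cells_by_mapd(m2, cutoff = 1.4)
  expect_false(res2$report$retained[1])
  expect_error(filter_cells_by_mapd(cbind(x), cutoff = 1.4), "all cells")
})

test_that("log2 clamping follows the stated rule and is idempotent", {
  expect_equal(clamp_log2(4), 1)
  expect_equal(clamp_log2(1), 0)
  expect_equal(clamp_log2(0.2), -1)
  expect_equal(clamp_log2(0), -1)
  x <- seq(0.1, 5, by = 0.1)
  y <- clamp_log2(x)
  expect_true(all(y >= -1 & y <= 1))
  expect_true(all(diff(y) >= 0))              # monotone
  expect_equal(clamp_log2(2^y), y)            # idempotent on the clamped scale
})

test_that("ward.D2 clustering separates simulated clones", {
  # identical profiles merge at height zero
  p <- matrix(1, 4, 10)
  hc <- cluster_cells(p)$hclust
  expect_equal(hc$height[1], 0)
  set.seed(9)
  prof <- rbind(matrix(rnorm(20 * 30, 0, 0.1), 20),
                matrix(rnorm(20 * 30, 1, 0.1), 20))
  cl <- cluster_cells(prof, k = 2)
  expect_equal(adjusted_rand_index(cl$labels, rep(1:2, each = 20)), 1)
  expect_error(cluster_cells(prof, k = 50), "exceeds")
})

test_that("false-positive region test has the stated conventions and power", {
  # identical constant regions: p = 1
  r <- rep(1, 20)
  res <- region_fp_test(r, region_a = 1:10, region_b = 11:20)
  expect_equal(res$p, 1)
  # zero variance, unequal means: p = 0
  r2 <- c(rep(1, 10), rep(2, 10))
  expect_equal(region_fp_test(r2, region_a = 1:10, region_b = 11:20)$p, 0)
  # matches the reference pooled t-test on random data
  set.seed(10)
  x <- rnorm(60)
  mine <- region_fp_test(x, region_a = 1:30, region_b = 31:60)
  ref <- t.test(x[1:30], x[31:60], var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  # strong shift is detected
  y <- c(rnorm(50, 0, 1), rnorm(50, 3, 1))
  expect_lt(region_fp_test(y, region_a = 1:50, region_b = 51:100)$p, 0.001)
  expect_error(region_fp_test(x, region_a = 1:2, region_b = 3:60),
               "at least 3")
})

test_that("pooled t-test is calibrated under the null", {
  set.seed(11)
  p <- replicate(500, {
    x <- rnorm(40)
    region_fp_test(x, region_a = 1:20, region_b = 21:40)$p
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("subclone assignment maps lost/gained loci to the five categories", {
  b <- make_bin_boundaries(default_genome(), 2000)
  mk <- function(regions_lost = list(), regions_gained = list()) {
    v <- rep(0, nrow(b))
    for (r in regions_lost) v[bins_in_region_test(b, r)] <- -1
    for (r in regions_gained) v[bins_in_region_test(b, r)] <- 1
    v
  }
  bins_in_region_test <- function(bins, r) {
    mid <- (bins$start + bins$end) / 2
    which(bins$chrom == r$chrom & mid >= r$start & mid < r$end)
  }
  rg <- default_regions()
  expect_equal(assign_subclone(mk(), b), "normal-like")
  expect_equal(assign_subclone(mk(regions_lost = rg["focal_13q"]), b),
               "focal 13q- only")
  expect_equal(assign_subclone(mk(regions_lost = rg["large_13q"]), b),
               "focal and large 13q-")
  expect_equal(assign_subclone(
    mk(regions_lost = rg[c("6q", "focal_13q")], regions_gained = rg["12q"]),
    b), "6q- and 12q+, 13q14.3-")
  expect_equal(assign_subclone(
    mk(regions_gained = rg[c("12p", "12q")]), b), "trisomy 12 only")
  expect_equal(assign_subclone(
    mk(regions_lost = rg["6q"], regions_gained = rg[c("12p", "12q")]), b),
    "other")
  bad <- c(rg, list(conflict = list(chrom = "chr13", start = 13e6, end = 20e6)))
  expect_error(assign_subclone(mk(), b, regions = bad), "contradictory")
})
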