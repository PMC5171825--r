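test_that("default clone model has the five subclone genotypes", {
  mdl <- make_default_clone_model()
  expect_length(mdl, 5)
  ids <- vapply(mdl, `[[`, character(1), "id")
  expect_setequal(ids, c("normal-like", "focal 13q- only",
                         "focal and large 13q-", "6q- and 12q+, 13q14.3-",
                         "trisomy 12 only"))
  fr <- clone_fractions(mdl)
  expect_true(all(abs(colSums(fr) - 1) < 1e-12))
  # time course: 6q-/12q+ clone vanishes late, trisomy 12 appears only late
  expect_equal(unname(fr["6q- and 12q+, 13q14.3-", c("year26", "year28")]),
               c(0, 0))
  expect_true(all(fr["trisomy 12 only", 1:4] == 0))
  expect_true(all(fr["trisomy 12 only", 5:7] > 0))
})

test_that("degenerate single-clone model is all-normal", {
  mdl <- make_default_clone_model(sim_config(n_clones = 1))
  expect_length(mdl, 1)
  expect_true(all(mdl[[1]]$fractions == 1))
  expect_equal(nrow(mdl[[1]]$events), 0)
})

test_that("clone events outside the genome are rejected", {
  expect_error(clone_population("bad",
    data.frame(chrom = "chr13", start = 0, end = 99e6, copy = 1),
    rep(1, 7)), "outside genome bounds")
  expect_error(clone_population("bad",
    data.frame(chrom = "chrNope", start = 0, end = 1e6, copy = 1),
    rep(1, 7)), "unknown chromosome")
})

test_that("bin counts follow the Poisson copy-number model", {
  mdl <- make_default_clone_model()
  b <- make_bin_boundaries(default_genome(), 2000)
  # diploid cell, no GC bias: mean count/bin within 3 s.e. of depth
  sim <- simulate_cell_bin_counts(mdl, b, data.frame(clone = 1),
                                  depth_per_bin = 50, gc_curvature = 0,
                                  seed = 1)
  m <- mean(sim$counts[, 1])
  se <- sqrt(50 / nrow(b))
  expect_lt(abs(m - 50), 3 * se)

  # trisomy cell: region mean / flanking mean close to 1.5
  sim3 <- simulate_cell_bin_counts(mdl, b, data.frame(clone = 5),
                                   depth_per_bin = 50, gc_curvature = 0,
                                   seed = 2)
  in12 <- b$chrom == "chr12"
  ratio <- mean(sim3$counts[in12, 1]) / mean(sim3$counts[!in12, 1])
  se_r <- 1.5 * sqrt(1 / (50 * sum(in12)) + 1 / (50 * sum(!in12)))
  expect_lt(abs(ratio - 1.5), 3 * se_r)

  # copy-0 region yields all-zero counts
  zero_clone <- clone_population("null13",
    data.frame(chrom = "chr13", start = 0, end = 25e6, copy = 0), rep(1, 7))
  mdl0 <- structure(list(zero_clone), timepoints = attr(mdl, "timepoints"),
                    genome = default_genome(), class = "clone_model")
  sim0 <- simulate_cell_bin_counts(mdl0, b, data.frame(clone = 1),
                                   depth_per_bin = 50, seed = 3)
  expect_true(all(sim0$counts[b$chrom == "chr13", 1] == 0))
})

test_that("simulations are bit-reproducible under a fixed seed", {
  mdl <- make_default_clone_model()
  b <- make_bin_boundaries(default_genome(), 500)
  s1 <- simulate_cell_bin_counts(mdl, b, data.frame(clone = c(1, 4)), seed = 9)
  s2 <- simulate_cell_bin_counts(mdl, b, data.frame(clone = c(1, 4)), seed = 9)
  expect_identical(s1$counts, s2$counts)
  t1 <- simulate_probe_track(0.4, "loss", seed = 9)
  t2 <- simulate_probe_track(0.4, "loss", seed = 9)
  expect_identical(t1, t2)
  m1 <- simulate_maf_sites(mdl, n_sites = 50, seed = 9)
  m2 <- simulate_maf_sites(mdl, n_sites = 50, seed = 9)
  expect_identical(m1, m2)
  e1 <- simulate_expression(n_cells_per_time = 10, seed = 9)
  e2 <- simulate_expression(n_cells_per_time = 10, seed = 9)
  expect_identical(e1$fpkm, e2$fpkm)
})

test_that("probe track BAF/LRR means follow the mixture algebra", {
  # f = 0: het BAF mean 0.5, LRR mean 0 within 3 s.e.
  tr0 <- simulate_probe_track(0, "none", n_probes = 2000, het_rate = 0.6,
                              seed = 4)
  het <- tr0$genotype == "AB"
  expect_lt(abs(mean(tr0$baf[het]) - 0.5), 3 * 0.03 / sqrt(sum(het)))
  expect_lt(abs(mean(tr0$lrr)), 3 * 0.15 / sqrt(nrow(tr0)))

  # CNLOH f = 0.5: het BAF modes at 0.25 / 0.75
  trc <- simulate_probe_track(0.5, "cnloh", n_probes = 2000,
                              region_probes = 1000, het_rate = 1,
                              baf_noise_sd = 0.01, seed = 5)
  inr <- attr(trc, "truth")$in_region
  hi <- trc$baf[inr] > 0.5
  expect_lt(abs(mean(trc$baf[inr][hi]) - 0.75), 0.01)
  expect_lt(abs(mean(trc$baf[inr][!hi]) - 0.25), 0.01)

  # full loss (f = 1): het BAF at 0/1, LRR mean -1
  trl <- simulate_probe_track(1, "loss", n_probes = 2000,
                              region_probes = 1000, het_rate = 1,
                              baf_noise_sd = 0, lrr_noise_sd = 0, seed = 6)
  inr <- attr(trl, "truth")$in_region
  expect_true(all(trl$baf[inr] %in% c(0, 1)))
  expect_equal(mean(trl$lrr[inr]), -1)
})

test_that("variant-site allele fractions track the clone fractions", {
  mdl <- make_default_clone_model()
  ms <- simulate_maf_sites(mdl, n_sites = 300, depth = 1000,
                           germline_fraction = 0.5, seed = 7)
  maf <- maf_matrix(ms)
  germ_het <- ms$sites$truth_germline & maf[, 1] < 0.9
  # germline het sites stay within a 5-sd binomial band of 0.5
  expect_true(all(abs(maf[germ_het, ] - 0.5) < 5 * sqrt(0.25 / 1000)))
  # somatic sites of the trisomy clone are exactly 0 while the clone is
  # absent (error-free mode)
  tri <- which(ms$sites$truth_clone == "trisomy 12 only")
  expect_true(all(ms$alt[tri, 1:4] == 0))
  # expected MAF is half the clone fraction
  c4 <- which(ms$sites$truth_clone == "6q- and 12q+, 13q14.3-")
  expect_lt(abs(mean(maf[c4, 1]) - 0.5 * 0.35), 0.02)
})

test_that("expression generator encodes clusters, markers and prevalences", {
  spec <- default_expression_spec()
  expect_true(all(abs(colSums(spec$prevalence) - 1) < 1e-8))
  sim <- simulate_expression(spec, n_cells_per_time = 60, seed = 8)
  expect_equal(dim(sim$fpkm), c(spec$n_genes, 300))
  # sampled composition within the multinomial band of the spec
  tab <- table(factor(sim$cells$truth_cluster, levels = LETTERS[1:6]),
               sim$cells$time)
  for (t in seq_along(spec$times)) {
    phat <- tab[, t] / 60
    p <- spec$prevalence[, t]
    expect_true(all(abs(phat - p) <= 1.96 * sqrt(p * (1 - p) / 60) + 1e-9))
  }
  # marker genes are up-shifted in their own cluster
  mk <- which(sim$genes$marker_of == "D")
  inD <- sim$cells$truth_cluster == "D"
  lfc <- log2(mean(sim$fpkm[mk, inD]) / mean(sim$fpkm[mk, !inD]))
  expect_gt(lfc, 0.5)
  # zero effect produces no cluster separation
  spec0 <- default_expression_spec(effect = 1)
  sim0 <- simulate_expression(spec0, n_cells_per_time = 30, seed = 8)
  mk0 <- which(sim0$genes$marker_of == "D")
  inD0 <- sim0$cells$truth_cluster == "D"
  lfc0 <- abs(log2(mean(sim0$fpkm[mk0, inD0]) / mean(sim0$fpkm[mk0, !inD0])))
  expect_lt(lfc0, 0.1)
  # prevalence misspecification is rejected
  bad <- spec; bad$prevalence[1, 1] <- bad$prevalence[1, 1] + 0.5
  expect_error(simulate_expression(bad, 10, seed = 1), "sum to 1")
})
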