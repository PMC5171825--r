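test_that("time-varying genes are retained and null genes near-nominal", {
  set.seed(1)
  n <- 150
  times <- rep(c(10, 20, 23), each = 50)
  ng <- 200
  fpkm <- matrix(rlnorm(ng * n, 1, 0.3), ng,
                 dimnames = list(paste0("g", 1:ng), paste0("c", 1:n)))
  de <- paste0("g", 1:30)
  for (g in 1:30) fpkm[g, ] <- fpkm[g, ] * 2^(as.numeric(factor(times)) - 1)
  # a constant gene is never retained
  fpkm["g200", ] <- 3
  sel <- de_genes_by_time(fpkm, times)
  expect_true(all(de %in% sel))
  expect_false("g200" %in% sel)
  # null retention rate near the cutoff
  null_p <- attr(sel, "p")[31:199]
  expect_lt(mean(null_p < 0.01), 0.05)
  expect_error(de_genes_by_time(fpkm, rep(10, n)), ">= 2 time points")
})

test_that("the MST matches geometry and the enumeration oracle", {
  # three collinear cells: the path runs through the middle one
  f <- matrix(0, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  f[1, ] <- c(0, 1, 3)   # log2(fpkm+1) spacing preserved through embedding
  fp <- 2^f - 1
  em <- embed_and_mst(fp, seed = 1)
  deg <- igraph::degree(em$mst)
  expect_equal(unname(deg), c(1, 2, 1))
  expect_equal(nrow(em$edges), 2)

  set.seed(2)
  for (n in c(6, 8)) {
    emb <- matrix(rnorm(2 * n), n, 2)
    fpkm <- 2^t(cbind(emb, emb[, 1] - emb[, 2])) - 1
    fpkm[fpkm < 0] <- 0
    rownames(fpkm) <- paste0("g", 1:3)
    colnames(fpkm) <- paste0("c", 1:n)
    em2 <- embed_and_mst(fpkm, method = "pca", seed = 1)
    d <- as.matrix(dist(em2$embedding))
    expect_equal(sum(em2$edges$weight), brute_mst_weight(d), tolerance = 1e-9)
    expect_equal(nrow(em2$edges), n - 1)
  }
  expect_error(embed_and_mst(matrix(1, 3, 5)), "identical")
})

test_that("ordering recovers a linear latent time", {
  set.seed(3)
  n <- 150
  tt <- sort(runif(n))
  ng <- 100
  beta <- rnorm(ng, 0, 2)
  x <- outer(beta, tt) + matrix(rnorm(ng * n, 0, 0.4), ng)
  fpkm <- 2^(x + 3) - 1
  fpkm[fpkm < 0] <- 0
  rownames(fpkm) <- paste0("g", 1:ng)
  colnames(fpkm) <- paste0("c", 1:n)
  em <- embed_and_mst(fpkm, seed = 1)
  ord <- order_cells(em, num_paths = 2)
  expect_gte(abs(cor(ord$cells$rank, tt, method = "spearman")), 0.9)
  # ranks are a permutation of 0..n-1
  expect_setequal(ord$cells$rank, 0:(n - 1))
})

test_that("a Y-shaped manifold decomposes into three trajectories", {
  set.seed(4)
  na <- 60; nb <- 45; nc2 <- 45
  emb <- rbind(cbind(seq(0, 1, length.out = na), 0),
               cbind(1 + seq(0.02, 1, length.out = nb),
                     seq(0.02, 1, length.out = nb)),
               cbind(1 + seq(0.02, 1, length.out = nc2),
                     -seq(0.02, 1, length.out = nc2)))
  emb <- emb + matrix(rnorm(2 * (na + nb + nc2), 0, 0.02), ncol = 2)
  fp <- t(2^(emb %*% matrix(rnorm(40), 2, 20) + 3))
  fp[fp < 0] <- 0
  rownames(fp) <- paste0("g", 1:20)
  colnames(fp) <- paste0("c", 1:ncol(fp))
  em <- embed_and_mst(fp, seed = 1)
  ord <- order_cells(em, num_paths = 2)
  expect_equal(sort(unique(ord$cells$trajectory)), 1:3)
  truth <- rep(1:3, c(na, nb, nc2))
  expect_gte(adjusted_rand_index(ord$cells$trajectory, truth), 0.8)
  # a pure path has no branches: warning and a single trajectory
  line <- cbind(seq(0, 1, length.out = 20), 0)
  fpl <- t(2^(line %*% matrix(c(1, 0, 0, 1, 1, 1), 2, 3) + 2))
  rownames(fpl) <- paste0("g", 1:3); colnames(fpl) <- paste0("c", 1:20)
  eml <- embed_and_mst(fpl, method = "pca", seed = 1)
  expect_warning(op <- order_cells(eml, num_paths = 2), "fewer trajectories")
  expect_equal(unique(op$cells$trajectory), 1L)
  # and with num_paths = 1 the ordering equals the path order
  o1 <- order_cells(eml, num_paths = 1)
  expect_true(all(diff(o1$cells$rank) %in% c(-19:19)))
  expect_equal(cor(o1$cells$rank, seq_len(20), method = "spearman"), 1,
               tolerance = 1e-12)
})

test_that("time anchoring reverses a backwards ordering and keeps adjacency", {
  set.seed(5)
  n <- 90
  tt <- seq_len(n)                       # latent order along the path
  # late cells come first along the path; year-10 cells spill into the
  # middle tertile so the anchoring counts are unambiguous
  times <- c(rep(28, 30), rep(23, 20), rep(10, 40))
  fp <- t(2^(cbind(tt / n * 4, rnorm(n, 0, 0.05)) %*%
               matrix(rnorm(10), 2, 5) + 3))
  fp[fp < 0] <- 0
  rownames(fp) <- paste0("g", 1:5); colnames(fp) <- paste0("c", 1:n)
  em <- embed_and_mst(fp, method = "pca", seed = 1)
  ord <- suppressWarnings(order_cells(em, num_paths = 1))
  ro <- reorder_by_time(ord, times, early = 10, late = c(23, 28))
  # anchored ordering runs from the year-10 group toward the late group
  start_cells <- ro$cells$rank < n / 3
  expect_gt(mean(times[start_cells] == 10), 0.9)
  end_cells <- ro$cells$rank >= 2 * n / 3
  expect_gt(mean(times[end_cells] %in% c(23, 28)), 0.9)
  # within-group relative order is preserved pairwise
  for (ph in unique(ord$cells$phase)) {
    idx <- which(ord$cells$phase == ph)
    expect_identical(order(ord$cells$rank[idx]), order(ro$cells$rank[idx]))
  }
  # an already-anchored ordering is unchanged
  ro2 <- reorder_by_time(ro, times, early = 10, late = c(23, 28))
  expect_identical(ro2$cells$rank, ro$cells$rank)
  # a genuine anchoring tie warns and resolves toward the original order
  times_tie <- c(rep(10, 30), rep(23, 30), rep(28, 30))
  oa <- suppressWarnings(
    reorder_by_time(ord, rev(times_tie), early = 10, late = c(23, 28)))
  expect_warning(reorder_by_time(oa, rev(times_tie), early = 10,
                                 late = c(23, 28)), "tie")
})

test_that("gene grouping finds planted high-low-high profiles", {
  set.seed(6)
  n <- 120
  ord_ranks <- 0:(n - 1)
  u <- (ord_ranks + 0.5) / n
  ng <- 60
  prof <- matrix(rnorm(ng * n, 0, 0.3), ng)
  for (g in 1:10) prof[g, ] <- 3 * (2 * (u - 0.5))^2 + rnorm(n, 0, 0.3)
  for (g in 11:20) prof[g, ] <- 3 * u + rnorm(n, 0, 0.3)
  fp <- 2^(prof + 3); fp[fp < 0] <- 0
  rownames(fp) <- paste0("g", 1:ng); colnames(fp) <- paste0("c", 1:n)
  ordering <- structure(list(cells = data.frame(
    cell = colnames(fp), pseudotime = u, rank = ord_ranks,
    trajectory = 1L, phase = "start", stringsAsFactors = FALSE)),
    class = "pseudotime_ordering")
  gg <- group_genes_along_path(fp, ordering, n_groups = 10)
  hlh_groups <- gg$groups$group[1:10]
  main <- as.integer(names(which.max(table(hlh_groups))))
  expect_gte(max(table(hlh_groups)), 9)
  expect_equal(unname(gg$patterns[as.character(main)]), "high-low-high")
  rising <- as.integer(names(which.max(table(gg$groups$group[11:20]))))
  expect_equal(unname(gg$patterns[as.character(rising)]), "rising")
  expect_error(group_genes_along_path(fp, ordering, n_groups = 100),
               "exceeds")
  # all-constant genes collapse to one flat group with a warning
  fc <- matrix(4, 5, n, dimnames = list(paste0("k", 1:5), colnames(fp)))
  expect_warning(g0 <- group_genes_along_path(fc, ordering, 3), "constant")
  expect_equal(unique(g0$groups$group), 1L)
  expect_equal(unname(g0$patterns), "flat")
})
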