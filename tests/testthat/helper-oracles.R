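# Independent oracles used across the suite.

# Brute-force MAPD: enumerate neighbour differences within chromosomes and
# take the plain median.
brute_mapd <- function(x, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("chr", length(x))
  diffs <- c()
  for (ch in unique(chrom)) {
    v <- x[chrom == ch]
    if (length(v) >= 2)
      for (i in seq_len(length(v) - 1)) diffs <- c(diffs, abs(v[i + 1] - v[i]))
  }
  median(diffs)
}

# Brute-force upper-tail hypergeometric probability via choose() sums:
# P(X >= k) with K successes in a population of N, drawing n.
brute_hyper_upper <- function(k, K, N, n) {
  j <- max(k, max(0, n - (N - K))):min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Minimum spanning tree weight by exhaustive enumeration of all labelled
# trees (Pruefer sequences); feasible for n <= 8.
brute_mst_weight <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3, n <= 8)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    deg <- rep(1L, n)
    for (v in pr) deg[v] <- deg[v] + 1L
    w <- 0
    for (v in pr) {
      leaf <- which.max(deg == 1L)          # smallest-index leaf
      w <- w + d[leaf, v]
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    left <- which(deg == 1L)
    w <- w + d[left[1], left[2]]
    if (w < best) best <- w
  }
  best
}

# Small helper: a maf_sites fixture with fully controlled flags and depths.
make_maf_fixture <- function(n_sites, n_times = 7, depth = 100, maf = 0.5,
                             flagged = rep(FALSE, n_sites)) {
  dp <- matrix(depth, n_sites, n_times,
               dimnames = list(NULL, paste0("year", seq_len(n_times))))
  if (length(maf) == 1) maf <- matrix(maf, n_sites, n_times)
  ad <- round(dp * maf)
  sites <- data.frame(
    id = sprintf("s%03d", seq_len(n_sites)),
    chrom = "chr1", pos = seq_len(n_sites) * 1000,
    ref = "A", alt = "G",
    population_af_above_cutoff = flagged,
    flagged_snp = FALSE,
    truth_germline = NA, truth_clone = NA,
    stringsAsFactors = FALSE)
  structure(list(sites = sites, depth = dp, alt = ad,
                 times = seq_len(n_times)),
            class = "maf_sites")
}
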