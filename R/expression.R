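#' Kruskal-Wallis rank sum test
#'
#' Rank-based H statistic with tie correction; the p-value comes from the
#' chi-square distribution with (groups - 1) degrees of freedom.  When every
#' value is identical the convention H = 0, p = 1 applies.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 nonempty groups).
#' @return List with `H`, `p`, `df`.
#' @export
kw_test <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(droplevels(groups)) >= 2)
  groups <- droplevels(groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  nj <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(nj * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C <= 0) return(list(H = 0, p = 1, df = nlevels(groups) - 1))
  H <- H / C
  df <- nlevels(groups) - 1
  list(H = H, p = pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Quality-control cascade for a single-cell FPKM matrix
#'
#' Applies, in order: (1) drop cells with fewer than `min_mapped` reads
#' mapped to gene regions; (2) drop suspected doublets with more than
#' `max_expressed` expressed genes (FPKM > 1); (3) keep protein-coding
#' genes; (4) define the core gene set as genes expressed (FPKM > 1) in at
#' least `core_frac` of the remaining cells — this set persists as the gene
#' filter; (5) drop cells that are BOTH below the `pct_low` quantile of
#' core-set expressed-gene count AND have mean core-set FPKM <= `mean_cut`
#' (conjunctive rule); (6) drop genes whose mean FPKM exceeds the
#' `gene_pct_high` quantile of gene means.  Counts at every step are
#' reported.
#'
#' @param fpkm genes x cells FPKM matrix.
#' @param cells data.frame with `cell` and `mapped_reads`.
#' @param genes data.frame with `gene` and `protein_coding`.
#' @param min_mapped,max_expressed,core_frac,pct_low,mean_cut,gene_pct_high
#'   thresholds as above.
#' @return List: filtered `fpkm`, `cells`, `genes`, and a `report` of
#'   per-step counts.
#' @export
qc_filter <- function(fpkm, cells, genes,
                      min_mapped = 1e6, max_expressed = 8000,
                      core_frac = 0.5, pct_low = 0.10, mean_cut = 1,
                      gene_pct_high = 0.99) {
  stopifnot(ncol(fpkm) == nrow(cells), nrow(fpkm) == nrow(genes))
  report <- list(cells_in = ncol(fpkm), genes_in = nrow(fpkm))
  fail <- function(step) stop("no cells/genes left after step: ", step)

  keep_c <- cells$mapped_reads >= min_mapped
  report$cells_dropped_low_reads <- sum(!keep_c)
  fpkm <- fpkm[, keep_c, drop = FALSE]; cells <- cells[keep_c, , drop = FALSE]
  if (ncol(fpkm) == 0) fail("mapped-read filter")

  expressed <- colSums(fpkm > 1)
  keep_c <- expressed <= max_expressed
  report$cells_dropped_doublet <- sum(!keep_c)
  fpkm <- fpkm[, keep_c, drop = FALSE]; cells <- cells[keep_c, , drop = FALSE]
  if (ncol(fpkm) == 0) fail("expressed-gene doublet filter")

  keep_g <- genes$protein_coding
  report$genes_dropped_noncoding <- sum(!keep_g)
  fpkm <- fpkm[keep_g, , drop = FALSE]; genes <- genes[keep_g, , drop = FALSE]
  if (nrow(fpkm) == 0) fail("protein-coding filter")

  core <- rowMeans(fpkm > 1) >= core_frac
  report$core_gene_set <- sum(core)
  if (!any(core)) fail("core gene set")
  core_counts <- colSums(fpkm[core, , drop = FALSE] > 1)
  core_means <- colMeans(fpkm[core, , drop = FALSE])
  thr <- quantile(core_counts, pct_low, names = FALSE)
  keep_c <- !(core_counts < thr & core_means <= mean_cut)
  report$cells_dropped_low_complexity <- sum(!keep_c)
  fpkm <- fpkm[, keep_c, drop = FALSE]; cells <- cells[keep_c, , drop = FALSE]
  if (ncol(fpkm) == 0) fail("low-complexity cell filter")

  # the core set persists as the gene filter
  fpkm <- fpkm[core, , drop = FALSE]; genes <- genes[core, , drop = FALSE]

  gm <- rowMeans(fpkm)
  hi <- quantile(gm, gene_pct_high, names = FALSE)
  keep_g <- gm <= hi
  report$genes_dropped_high_mean <- sum(!keep_g)
  fpkm <- fpkm[keep_g, , drop = FALSE]; genes <- genes[keep_g, , drop = FALSE]
  if (nrow(fpkm) == 0) fail("high-mean gene filter")

  report$cells_out <- ncol(fpkm)
  report$genes_out <- nrow(fpkm)
  list(fpkm = fpkm, cells = cells, genes = genes, report = report)
}

# log2(FPKM + 1), genes standardized across cells (sd-0 genes left centred).
log_standardize <- function(fpkm) {
  x <- log2(fpkm + 1)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s < 1e-12] <- 1
  (x - mu) / s
}

# Deterministic PCA sign: each rotation column oriented so its
# largest-|loading| entry is positive.
fix_pc_signs <- function(pc) {
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  pc
}

#' Iterative PCA / hierarchical clustering of single cells
#'
#' Each round: PCA of the current gene set (log2(FPKM+1), per-gene
#' standardized); the union of the `genes_per_pc` largest-|loading| genes of
#' the first `n_pcs` components (at most `n_pcs * genes_per_pc` genes)
#' drives ward.D2 hierarchical clustering of the cells cut at `k`; a
#' Kruskal-Wallis test per current-set gene across the k groups, BH-adjusted,
#' retains genes with q below `q_cutoff` as the next round's gene set.  The
#' final round's labels (letters by decreasing cluster size) and gene sets
#' are returned.  Fully deterministic (PCA signs fixed internally).
#'
#' @param fpkm genes x cells FPKM matrix.
#' @param n_rounds,k,n_pcs,genes_per_pc,q_cutoff procedure parameters
#'   (defaults 3, 6, 4, 20, 0.01).
#' @return List of class `iterative_cluster`: `labels` (named letter per
#'   cell), `rounds` (per-round clustering genes and selected genes),
#'   `kw` (final-round statistics), `hclust`.
#' @export
iterative_cluster <- function(fpkm, n_rounds = 3, k = 6, n_pcs = 4,
                              genes_per_pc = 20, q_cutoff = 0.01) {
  stopifnot(nrow(fpkm) >= n_pcs, ncol(fpkm) > k)
  gene_set <- rownames(fpkm) %||% as.character(seq_len(nrow(fpkm)))
  rownames(fpkm) <- gene_set
  rounds <- list()
  labels <- NULL; hc <- NULL; kw_tab <- NULL
  for (r in seq_len(n_rounds)) {
    x <- log_standardize(fpkm[gene_set, , drop = FALSE])
    x <- x[apply(x, 1, sd) > 0, , drop = FALSE]
    npc <- min(n_pcs, nrow(x) - 1, ncol(x) - 1)
    pc <- fix_pc_signs(prcomp(t(x), center = FALSE, scale. = FALSE,
                              rank. = npc))
    sel <- unique(unlist(lapply(seq_len(npc), function(j) {
      rownames(x)[order(-abs(pc$rotation[, j]))[seq_len(min(genes_per_pc,
                                                            nrow(x)))]]
    })))
    hc <- hclust(dist(t(x[sel, , drop = FALSE])), method = "ward.D2")
    grp <- cutree(hc, k = k)
    kw_tab <- data.frame(gene = rownames(x),
                         H = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    for (gi in seq_len(nrow(x))) {
      res <- kw_test(x[gi, ], grp)
      kw_tab$H[gi] <- res$H; kw_tab$p[gi] <- res$p
    }
    kw_tab$q <- p.adjust(kw_tab$p, method = "BH")
    next_set <- kw_tab$gene[kw_tab$q < q_cutoff]
    rounds[[r]] <- list(clustering_genes = sel, selected = next_set,
                        n_selected = length(next_set))
    labels <- grp
    if (r < n_rounds) {
      if (length(next_set) == 0)
        stop("no genes with q < ", q_cutoff, " after round ", r,
             " (min q = ", signif(min(kw_tab$q), 3), ")")
      gene_set <- next_set
    }
  }
  # letters by decreasing cluster size; ties by first occurrence
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- setNames(LETTERS[seq_along(ord)], names(sizes)[ord])
  labels <- setNames(relab[as.character(labels)], colnames(fpkm))
  structure(list(labels = labels, rounds = rounds, kw = kw_tab, hclust = hc),
            class = "iterative_cluster")
}

#' Hypergeometric marker genes per cluster
#'
#' A gene is "expressed" in a cell when FPKM > 1.  For each (gene, cluster)
#' pair the upper-tail hypergeometric probability of observing at least the
#' seen number of expressing cells inside the cluster — given the cluster
#' size, the total number of cells and the gene's overall expressing count —
#' is BH-adjusted across all pairs; pairs with q below the cutoff are the
#' marker calls.
#'
#' @param fpkm genes x cells FPKM matrix.
#' @param labels cluster label per cell.
#' @param q_cutoff marker significance cutoff (default 0.01).
#' @return data.frame (gene, cluster, in_cluster, cluster_size,
#'   expressing_total, n_cells, p, q, marker).
#' @export
marker_genes <- function(fpkm, labels, q_cutoff = 0.01) {
  stopifnot(ncol(fpkm) == length(labels))
  expr <- fpkm > 1
  N <- ncol(fpkm)
  K <- rowSums(expr)
  cl <- sort(unique(labels))
  cl <- cl[vapply(cl, function(c) sum(labels == c) > 0, logical(1))]
  out <- do.call(rbind, lapply(cl, function(c) {
    inc <- labels == c
    n <- sum(inc)
    kin <- rowSums(expr[, inc, drop = FALSE])
    data.frame(gene = rownames(fpkm) %||% seq_len(nrow(fpkm)),
               cluster = c, in_cluster = kin, cluster_size = n,
               expressing_total = K, n_cells = N,
               p = phyper(kin - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out$q <- p.adjust(out$p, method = "BH")
  out$marker <- out$q < q_cutoff
  rownames(out) <- NULL
  out
}

#' Cluster-by-time composition table
#'
#' Percentage of the cells of each time point falling in each cluster;
#' columns (time points) sum to 100 up to rounding.
#'
#' @param labels cluster label per cell.
#' @param times time label per cell.
#' @param digits rounding for the reported percentages (default 1).
#' @return Matrix clusters x time points of percentages.
#' @export
composition_table <- function(labels, times, digits = 1) {
  stopifnot(length(labels) == length(times))
  tab <- table(labels, times)
  round(100 * sweep(tab, 2, colSums(tab), `/`), digits)
}
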