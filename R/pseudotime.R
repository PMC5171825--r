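#' Differentially expressed genes by sampling time
#'
#' Kruskal-Wallis test per gene across the cells' time labels; genes with
#' unadjusted p below the cutoff are retained for the embedding.
#'
#' @param fpkm genes x cells FPKM matrix.
#' @param times time label per cell (>= 2 distinct values).
#' @param p_cutoff retention cutoff (default 0.01).
#' @return Character vector of retained gene ids, with attribute `p` (all
#'   per-gene p-values).
#' @export
de_genes_by_time <- function(fpkm, times, p_cutoff = 0.01) {
  if (length(unique(times)) < 2)
    stop("differential expression by time needs >= 2 time points")
  p <- vapply(seq_len(nrow(fpkm)),
              function(g) kw_test(fpkm[g, ], times)$p, numeric(1))
  ids <- rownames(fpkm) %||% as.character(seq_len(nrow(fpkm)))
  out <- ids[p < p_cutoff]
  attr(out, "p") <- setNames(p, ids)
  out
}

#' Embed cells in 2-D and build the minimum spanning tree
#'
#' Cells are embedded from log2(FPKM+1) on the selected genes either by
#' plain PCA (first two sign-fixed components; the default, which preserves
#' the relative variance of signal and noise directions and keeps the
#' spanning tree path-like) or by whitened PCA followed by seeded
#' 2-component ICA.  A Euclidean minimum spanning tree is then built over
#' the cells in the embedding.
#'
#' @param fpkm genes x cells FPKM matrix.
#' @param genes gene ids to use (default: all rows).
#' @param method "pca" (first two sign-fixed components; default) or
#'   "ica" (whitened PCA + seeded 2-component ICA).
#' @param n_whiten number of whitened components fed to ICA (default 2,
#'   i.e. ICA rotates the whitened top-2 PC plane).
#' @param seed RNG seed for the ICA initialization.
#' @return List of class `cell_embedding`: `embedding` (cells x 2), `mst`
#'   (igraph tree), `edges` (data.frame from, to, weight).
#' @export
embed_and_mst <- function(fpkm, genes = NULL, method = c("pca", "ica"),
                          n_whiten = 2, seed = 1) {
  method <- match.arg(method)
  stopifnot(ncol(fpkm) >= 3)
  x <- log2(fpkm + 1)
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  xt <- t(x)                                   # cells x genes
  if (all(apply(xt, 2, sd) < 1e-12))
    stop("cells are identical on the selected genes; cannot embed")
  pc <- fix_pc_signs(prcomp(xt, center = TRUE, scale. = FALSE))
  pos <- pc$sdev > 1e-8
  if (method == "ica") {
    d <- min(n_whiten, sum(pos), ncol(pc$x))
    white <- sweep(pc$x[, seq_len(d), drop = FALSE], 2,
                   pc$sdev[seq_len(d)], `/`)
    set.seed(seed)
    emb <- fast_ica(white, n_comp = 2)
  } else {
    emb <- pc$x[, 1:2, drop = FALSE]
  }
  rownames(emb) <- colnames(fpkm)
  colnames(emb) <- c("dim1", "dim2")
  d <- as.matrix(dist(emb))
  # complete graph built explicitly: an adjacency-matrix construction would
  # drop zero-weight edges between duplicate cells
  n_cells <- nrow(emb)
  cmb <- t(utils::combn(n_cells, 2))
  g <- igraph::graph_from_edgelist(cmb, directed = FALSE)
  igraph::E(g)$weight <- d[cmb]
  tree <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(tree, names = FALSE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      weight = igraph::E(tree)$weight)
  structure(list(embedding = emb, mst = tree, edges = edges),
            class = "cell_embedding")
}

#' Order cells along the MST into trajectories
#'
#' The backbone is the MST's weighted diameter path.  With `num_paths = 2`
#' the longest side branch off the backbone defines a second path, which
#' decomposes the cells into three trajectory segments: backbone before the
#' branch point, the branch, and backbone after the branch point.  Every
#' cell attaches to its nearest backbone/branch node by tree distance, and
#' the pseudotime rank is the geodesic distance from the backbone root
#' (ties broken by cell index).  Phase groups are pseudotime tertiles.
#'
#' @param emb a `cell_embedding` from [embed_and_mst()].
#' @param num_paths number of paths (1 = backbone only; default 2).
#' @return List of class `pseudotime_ordering`: `cells` (data.frame: cell,
#'   pseudotime, rank, trajectory, phase), `backbone`, `branch`, `root`.
#' @export
order_cells <- function(emb, num_paths = 2) {
  stopifnot(inherits(emb, "cell_embedding"), num_paths >= 1)
  tree <- emb$mst
  n <- igraph::vcount(tree)
  D <- igraph::distances(tree, weights = igraph::E(tree)$weight)
  ends <- which(D == max(D), arr.ind = TRUE)[1, ]
  root <- min(ends)
  tip <- max(ends)
  backbone <- as.integer(igraph::shortest_paths(tree, root, tip,
    weights = igraph::E(tree)$weight)$vpath[[1]])

  # nearest backbone node for every cell (tree distance)
  att_pos <- apply(D[, backbone, drop = FALSE], 1, which.min)
  att <- backbone[att_pos]

  trajectory <- rep(1L, n)
  branch <- integer(0)
  if (num_paths >= 2) {
    off <- setdiff(seq_len(n), backbone)
    depth <- if (length(off)) D[cbind(off, att[off])] else numeric(0)
    if (length(off) == 0 || max(depth) <= 0) {
      warning("no side branches available; returning fewer trajectories")
    } else {
      btip <- off[which.max(depth)]
      bpath <- as.integer(igraph::shortest_paths(tree, btip, att[btip],
        weights = igraph::E(tree)$weight)$vpath[[1]])
      branch <- setdiff(bpath, backbone)
      banchor <- att[btip]
      anchor_pos <- match(banchor, backbone)
      # assign every cell to its nearest node among backbone + branch
      skel <- c(backbone, branch)
      skel_att <- skel[apply(D[, skel, drop = FALSE], 1, which.min)]
      on_branch <- skel_att %in% branch
      before <- skel_att %in% backbone[seq_len(anchor_pos)]
      trajectory[before & !on_branch] <- 1L
      trajectory[on_branch] <- 2L
      trajectory[!before & !on_branch] <- 3L
    }
  }

  pseudotime <- D[root, ]
  rank <- order(order(pseudotime, seq_len(n))) - 1L
  phase <- cut(rank, breaks = quantile(rank, c(0, 1/3, 2/3, 1)),
               labels = c("start", "middle", "end"), include.lowest = TRUE)
  ids <- rownames(emb$embedding) %||% as.character(seq_len(n))
  cells <- data.frame(cell = ids, pseudotime = pseudotime, rank = rank,
                      trajectory = trajectory, phase = as.character(phase),
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, backbone = backbone, branch = branch,
                 root = root),
            class = "pseudotime_ordering")
}

#' Anchor the pseudotime direction on real sampling times
#'
#' Cells are taken in their three pseudotime phase groups; the group holding
#' the most cells from the earliest time point becomes the start of the
#' path and the group holding the most cells from the two designated late
#' time points becomes the end, with the remaining group in the middle.
#' Relative order within each group is preserved; ranks are reassigned by
#' concatenation.  Ties in the anchoring are broken toward preserving the
#' original group order, with a warning.
#'
#' @param ordering a `pseudotime_ordering`.
#' @param times time label per cell (same order as `ordering$cells`).
#' @param early the earliest time label (default: minimum of `times`).
#' @param late the late time labels anchoring the end (default: the two
#'   largest distinct values).
#' @return The reordered `pseudotime_ordering` (ranks and phases updated).
#' @export
reorder_by_time <- function(ordering, times, early = NULL, late = NULL) {
  stopifnot(inherits(ordering, "pseudotime_ordering"),
            length(times) == nrow(ordering$cells))
  if (is.null(early)) early <- min(times)
  if (is.null(late)) late <- tail(sort(unique(times)), 2)
  cells <- ordering$cells
  groups <- c("start", "middle", "end")
  cnt_early <- vapply(groups, function(g)
    sum(cells$phase == g & times == early), numeric(1))
  cnt_late <- vapply(groups, function(g)
    sum(cells$phase == g & times %in% late), numeric(1))
  pick <- function(cnt, exclude = character(0), prefer = c("first", "last")) {
    prefer <- match.arg(prefer)
    cand <- setdiff(groups, exclude)
    v <- cnt[cand]
    top <- cand[v == max(v)]
    if (length(top) > 1) {
      warning("tie in group anchoring; preserving original group order")
      # keep the anchor closest to its current position in the ordering
      top <- if (prefer == "first") top[1] else top[length(top)]
    }
    top
  }
  start_g <- pick(cnt_early, prefer = "first")
  end_g <- pick(cnt_late, exclude = start_g, prefer = "last")
  mid_g <- setdiff(groups, c(start_g, end_g))
  new_order <- c(which(cells$phase == start_g)[order(cells$rank[cells$phase == start_g])],
                 which(cells$phase == mid_g)[order(cells$rank[cells$phase == mid_g])],
                 which(cells$phase == end_g)[order(cells$rank[cells$phase == end_g])])
  cells$rank[new_order] <- seq_along(new_order) - 1L
  cells$phase[cells$phase == start_g] <- "_s"
  cells$phase[cells$phase == mid_g] <- "_m"
  cells$phase[cells$phase == end_g] <- "_e"
  cells$phase <- c(`_s` = "start", `_m` = "middle", `_e` = "end")[cells$phase]
  ordering$cells <- cells
  ordering
}

#' Group genes by their profile along the pseudotime path
#'
#' Each gene's expression along the ordering is smoothed with a centred
#' rolling mean (window = cells/20 by default) and standardized; the
#' profiles are clustered (Euclidean, ward.D2) into `n_groups`, and each
#' group is tagged with a coarse pattern by comparing the smoothed group
#' mean over the first, middle and last thirds of the path (for example
#' "high-low-high").
#'
#' @param fpkm genes x cells FPKM matrix.
#' @param ordering a `pseudotime_ordering`.
#' @param n_groups number of gene groups (default 10).
#' @param window rolling-mean window (default `ncol/20`).
#' @param margin pattern-call margin in standardized units (default 0.25).
#' @return List: `groups` (data.frame gene, group), `patterns` (tag per
#'   group), `profiles` (smoothed standardized genes x cells matrix in path
#'   order).
#' @export
group_genes_along_path <- function(fpkm, ordering, n_groups = 10,
                                   window = NULL, margin = 0.25) {
  stopifnot(inherits(ordering, "pseudotime_ordering"), n_groups >= 2)
  if (n_groups > nrow(fpkm))
    stop("n_groups (", n_groups, ") exceeds the number of genes")
  ord <- order(ordering$cells$rank)
  x <- log2(fpkm[, ord, drop = FALSE] + 1)
  n <- ncol(x)
  if (is.null(window)) window <- max(3, round(n / 20))
  sm <- t(apply(x, 1, rolling_mean, window = window))
  mu <- rowMeans(sm); s <- apply(sm, 1, sd)
  flat <- s < 1e-12
  s[flat] <- 1
  prof <- (sm - mu) / s
  if (all(flat)) {
    warning("all gene profiles are constant; returning a single flat group")
    return(list(groups = data.frame(gene = rownames(fpkm) %||%
                                      seq_len(nrow(fpkm)), group = 1L),
                patterns = c(`1` = "flat"), profiles = prof))
  }
  hc <- hclust(dist(prof), method = "ward.D2")
  grp <- cutree(hc, k = n_groups)
  thirds <- cut(seq_len(n), 3, labels = FALSE)
  patterns <- vapply(sort(unique(grp)), function(g) {
    m <- colMeans(prof[grp == g, , drop = FALSE])
    m3 <- tapply(m, thirds, mean)
    if (m3[2] < m3[1] - margin && m3[2] < m3[3] - margin) return("high-low-high")
    if (m3[2] > m3[1] + margin && m3[2] > m3[3] + margin) return("low-high-low")
    if (m3[3] > m3[1] + margin) return("rising")
    if (m3[1] > m3[3] + margin) return("falling")
    "flat"
  }, character(1))
  names(patterns) <- sort(unique(grp))
  list(groups = data.frame(gene = rownames(fpkm) %||% seq_len(nrow(fpkm)),
                           group = grp),
       patterns = patterns, profiles = prof)
}
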