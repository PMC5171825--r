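#' Remove annotation-flagged variant sites
#'
#' Drops sites flagged as common population polymorphisms (population allele
#' frequency above cutoff in the reference panels) or as database-flagged
#' SNPs, emulating the annotation-based removal of likely germline variants.
#'
#' @param msites a `maf_sites` object.
#' @return Filtered `maf_sites`.
#' @export
filter_annotations <- function(msites) {
  keep <- !(msites$sites$population_af_above_cutoff | msites$sites$flagged_snp)
  subset_maf_sites(msites, keep)
}

#' Keep sites deeply covered at every time point
#'
#' A site is retained only if its depth is at least `min_depth` in all
#' samples (inclusive threshold).
#'
#' @param msites a `maf_sites` object.
#' @param min_depth minimum depth (default 30).
#' @return Filtered `maf_sites`.
#' @export
filter_depth <- function(msites, min_depth = 30) {
  keep <- apply(msites$depth >= min_depth, 1, all)
  subset_maf_sites(msites, keep)
}

subset_maf_sites <- function(msites, keep) {
  structure(list(sites = msites$sites[keep, , drop = FALSE],
                 depth = msites$depth[keep, , drop = FALSE],
                 alt = msites$alt[keep, , drop = FALSE],
                 times = msites$times),
            class = "maf_sites")
}

#' Variant allele-frequency matrix of a site set
#'
#' @param msites a `maf_sites` object.
#' @return sites x time points matrix of alt/depth (direction-preserving,
#'   not folded).
#' @export
maf_matrix <- function(msites) {
  m <- msites$alt / msites$depth
  rownames(m) <- msites$sites$id
  m
}

#' PCA-based germline filter of allele-frequency trajectories
#'
#' Performs a correlation PCA of the per-site trajectories (each trajectory
#' row-centred, columns standardised, values on a percent scale) and removes
#' sites whose PC1 score is above the threshold.  The sign of PC1 is
#' oriented so that its correlation with per-site trajectory variance is
#' negative: strongly varying, somatic-like sites score low and survive the
#' `score > threshold` removal, flat germline-like sites score near zero and
#' are removed.
#'
#' @param maf sites x time points matrix of allele fractions in \[0, 1\].
#' @param threshold removal cutoff on the oriented PC1 score (default -1).
#' @param percent multiply allele fractions by 100 before the PCA so the
#'   default threshold operates on percent-like units (default TRUE).
#' @return List: `retained` (logical per site), `scores` (oriented PC1).
#' @export
pca_germline_filter <- function(maf, threshold = -1, percent = TRUE) {
  stopifnot(nrow(maf) >= 3, ncol(maf) >= 2)
  x <- if (percent) maf * 100 else maf
  xc <- x - rowMeans(x)
  csd <- apply(xc, 2, sd)
  if (all(csd < 1e-12)) {
    warning("constant trajectory matrix: all sites classified germline-like")
    return(list(retained = rep(FALSE, nrow(maf)),
                scores = rep(0, nrow(maf))))
  }
  xs <- sweep(xc, 2, pmax(csd, 1e-12), `/`)
  pc <- prcomp(xs, center = TRUE, scale. = FALSE)
  scores <- orient_pc1(pc$x[, 1], apply(x, 1, var))
  list(retained = scores <= threshold, scores = scores)
}

#' Self-organizing tree clustering of trajectories
#'
#' Divisive clustering growing a binary tree of prototype vectors: profiles
#' are presented in input order to their best-matching leaf, which moves
#' toward the profile (winner rate), dragging its parent and sibling along
#' at lower rates when the sibling is also a leaf.  After an epoch's
#' relative error change falls below `tol`, the leaf with the largest
#' resource (mean member distance) is split into two children; growth stops
#' at `n_clusters` leaves (or earlier, with a warning, when every resource
#' is zero).  Deterministic given the seed and input order.
#'
#' @param x profiles x features numeric matrix.
#' @param n_clusters number of leaf clusters to grow (default 12).
#' @param rates learning rates for winner, parent, sibling (default
#'   0.1, 0.05, 0.01).
#' @param max_epochs maximum training epochs per growth cycle.
#' @param tol relative error-change convergence tolerance.
#' @param seed optional RNG seed (controls the tiny symmetric jitter used
#'   when a node splits).
#' @return List of class `sota_fit`: `labels` (leaf id per profile, in
#'   1..n_leaves), `centroids` (leaf vectors), `resource` per leaf.
#' @export
sota_cluster <- function(x, n_clusters = 12, rates = c(0.1, 0.05, 0.01),
                         max_epochs = 100, tol = 1e-4, seed = NULL) {
  stopifnot(is.matrix(x), n_clusters >= 2)
  n <- nrow(x)
  if (n_clusters > n) stop("n_clusters (", n_clusters,
                           ") exceeds the number of profiles (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(x)
  jitter_sd <- 1e-8 * max(sd(as.vector(x)), 1e-12)

  # tree as parallel vectors; nodes never deleted, leaves tracked by flag
  vecs <- list(colMeans(x))
  parent <- c(NA_integer_)
  children <- list(integer(0))
  is_leaf <- TRUE
  split_node <- function(k) {
    for (s in 1:2) {
      vecs[[length(vecs) + 1]] <<- vecs[[k]] + rnorm(p, 0, jitter_sd)
      parent[length(vecs)] <<- k
      children[[length(vecs)]] <<- integer(0)
      is_leaf[length(vecs)] <<- TRUE
    }
    children[[k]] <<- c(length(vecs) - 1L, length(vecs))
    is_leaf[k] <<- FALSE
  }
  split_node(1L)

  repeat {
    prev_err <- Inf
    for (epoch in seq_len(max_epochs)) {
      err_sum <- 0
      for (i in seq_len(n)) {
        leaves <- which(is_leaf)
        d <- vapply(leaves, function(l) sum((x[i, ] - vecs[[l]])^2), numeric(1))
        w <- leaves[which.min(d)]
        err_sum <- err_sum + sqrt(min(d))
        vecs[[w]] <- vecs[[w]] + rates[1] * (x[i, ] - vecs[[w]])
        pa <- parent[w]
        if (!is.na(pa)) {
          sib <- setdiff(children[[pa]], w)
          if (length(sib) == 1 && is_leaf[sib]) {
            vecs[[pa]] <- vecs[[pa]] + rates[2] * (x[i, ] - vecs[[pa]])
            vecs[[sib]] <- vecs[[sib]] + rates[3] * (x[i, ] - vecs[[sib]])
          }
        }
      }
      err <- err_sum / n
      if (is.finite(prev_err) &&
          abs(prev_err - err) <= tol * max(prev_err, 1e-12)) break
      prev_err <- err
    }
    leaves <- which(is_leaf)
    if (length(leaves) >= n_clusters) break
    # resource per leaf: mean member distance
    win <- integer(n)
    for (i in seq_len(n)) {
      d <- vapply(leaves, function(l) sum((x[i, ] - vecs[[l]])^2), numeric(1))
      win[i] <- leaves[which.min(d)]
    }
    resource <- vapply(leaves, function(l) {
      m <- win == l
      if (!any(m)) return(0)
      mean(sqrt(rowSums((x[m, , drop = FALSE] -
                           matrix(vecs[[l]], sum(m), p, byrow = TRUE))^2)))
    }, numeric(1))
    if (max(resource) <= 1e-12) {
      warning("all leaf resources are zero; stopped at ", length(leaves),
              " clusters")
      break
    }
    split_node(leaves[which.max(resource)])
  }

  leaves <- which(is_leaf)
  win <- integer(n)
  for (i in seq_len(n)) {
    d <- vapply(leaves, function(l) sum((x[i, ] - vecs[[l]])^2), numeric(1))
    win[i] <- which.min(d)
  }
  resource <- vapply(seq_along(leaves), function(k) {
    m <- win == k
    if (!any(m)) return(0)
    mean(sqrt(rowSums((x[m, , drop = FALSE] -
                         matrix(vecs[[leaves[k]]], sum(m), p, byrow = TRUE))^2)))
  }, numeric(1))
  structure(list(labels = win,
                 centroids = do.call(rbind, vecs[leaves]),
                 resource = resource),
            class = "sota_fit")
}

#' Summarize trajectory clusters
#'
#' @param maf sites x time points allele-fraction matrix.
#' @param labels cluster label per site.
#' @return data.frame per cluster: size, centroid range, plus a `centroids`
#'   attribute (cluster x time matrix of member means).
#' @export
maf_cluster_summary <- function(maf, labels) {
  ids <- sort(unique(labels))
  cent <- t(vapply(ids, function(k)
    colMeans(maf[labels == k, , drop = FALSE]), numeric(ncol(maf))))
  rownames(cent) <- ids
  out <- data.frame(cluster = ids,
                    size = as.integer(table(factor(labels, levels = ids))),
                    range = apply(cent, 1, function(v) max(v) - min(v)))
  attr(out, "centroids") <- cent
  out
}

#' Prune clusters with flat centroid trajectories
#'
#' Clusters whose centroid range (max - min across time points) falls below
#' the threshold are treated as residual germline signal and removed.
#'
#' @param summary output of [maf_cluster_summary()].
#' @param range_threshold minimum centroid range in allele-fraction units
#'   (default 0.1).
#' @return The summary restricted to retained clusters (centroids attribute
#'   subset accordingly).
#' @export
prune_low_range <- function(summary, range_threshold = 0.1) {
  keep <- summary$range >= range_threshold
  out <- summary[keep, , drop = FALSE]
  attr(out, "centroids") <- attr(summary, "centroids")[keep, , drop = FALSE]
  out
}

#' Label a centroid trajectory
#'
#' Rule-based trajectory classes: "lost" = monotone decreasing (Spearman
#' rho <= -rho_cutoff) ending near zero; "increasing" = monotone increasing
#' (rho >= rho_cutoff); "transient" = an interior peak above the start with
#' the end back at or below the start; otherwise "other" (constant
#' centroids are "other").
#'
#' @param centroid numeric trajectory over time points.
#' @param rho_cutoff Spearman monotonicity cutoff (default 0.8).
#' @param near_zero "near zero" level for the lost rule (default 0.02).
#' @return One of "lost", "increasing", "transient", "other".
#' @export
label_trajectory <- function(centroid, rho_cutoff = 0.8, near_zero = 0.02) {
  k <- length(centroid)
  if (sd(centroid) < 1e-12) return("other")
  rho <- suppressWarnings(cor(centroid, seq_len(k), method = "spearman"))
  if (!is.na(rho) && rho <= -rho_cutoff && centroid[k] <= near_zero)
    return("lost")
  if (!is.na(rho) && rho >= rho_cutoff) return("increasing")
  pk <- which.max(centroid)
  if (pk > 1 && pk < k && centroid[pk] > centroid[1] + 0.05 &&
      centroid[k] <= centroid[1]) return("transient")
  "other"
}

#' Allele-frequency trajectory pipeline
#'
#' Annotation filter, depth filter, PCA germline filter, SOTA clustering,
#' low-range pruning and trajectory labelling, end to end.
#'
#' @param msites a `maf_sites` object.
#' @param min_depth depth filter threshold.
#' @param n_clusters SOTA leaf count (default 12).
#' @param pc1_threshold germline-filter cutoff.
#' @param range_threshold centroid-range pruning threshold.
#' @param seed RNG seed.
#' @return List: the filtered `maf_sites`, the retained MAF matrix, SOTA
#'   fit, cluster summary with labels, and the pruned summary.
#' @export
maf_trajectory_pipeline <- function(msites, min_depth = 30, n_clusters = 12,
                                    pc1_threshold = -1, range_threshold = 0.1,
                                    seed = NULL) {
  ms <- filter_depth(filter_annotations(msites), min_depth)
  maf <- maf_matrix(ms)
  gf <- pca_germline_filter(maf, threshold = pc1_threshold)
  ms <- subset_maf_sites(ms, gf$retained)
  maf <- maf[gf$retained, , drop = FALSE]
  fit <- sota_cluster(maf, n_clusters = min(n_clusters, max(2, nrow(maf))),
                      seed = seed)
  summ <- maf_cluster_summary(maf, fit$labels)
  pruned <- prune_low_range(summ, range_threshold)
  cents <- attr(pruned, "centroids")
  pruned$label <- apply(cents, 1, label_trajectory)
  list(sites = ms, maf = maf, fit = fit, summary = summ, pruned = pruned,
       germline_scores = gf$scores)
}
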