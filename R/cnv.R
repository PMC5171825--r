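#' Count reads into genomic bins
#'
#' Assigns each read to exactly one bin by its start coordinate (bins are
#' 0-based half-open).  Reads falling outside every bin are tallied, not
#' dropped silently.
#'
#' @param reads data.frame with columns `chrom` and `pos` (0-based read
#'   start).
#' @param bins `bin_boundaries`.
#' @return List with `counts` (integer vector along bins) and `unassigned`.
#' @export
count_reads_in_bins <- function(reads, bins) {
  stopifnot(all(c("chrom", "pos") %in% names(reads)))
  counts <- integer(nrow(bins))
  unassigned <- 0L
  for (ch in unique(bins$chrom)) {
    bsel <- which(bins$chrom == ch)
    rsel <- reads$pos[reads$chrom == ch]
    if (length(rsel) == 0) next
    edges <- c(bins$start[bsel], bins$end[bsel[length(bsel)]])
    idx <- findInterval(rsel, edges, left.open = FALSE)
    ok <- idx >= 1 & idx <= length(bsel) & rsel < edges[length(edges)]
    tab <- tabulate(idx[ok], nbins = length(bsel))
    counts[bsel] <- counts[bsel] + tab
    unassigned <- unassigned + sum(!ok)
  }
  unassigned <- unassigned + sum(!reads$chrom %in% bins$chrom)
  list(counts = counts, unassigned = unassigned)
}

#' Normalize bin counts to cohort-referenced ratios
#'
#' Two-step normalization: (1) scale each sample so its mean bin count is 1;
#' (2) divide each scaled value by that bin's mean scaled value across the
#' cohort, so the cohort-mean profile is identically 1.  Bins whose cohort
#' mean is 0 are returned as NA and must be excluded downstream.
#'
#' @param counts bins x samples numeric matrix (a vector is treated as one
#'   sample).
#' @return Matrix of normalized ratios with attribute `reference` (the
#'   per-bin cohort mean of the scaled profiles).
#' @export
normalize_ratios <- function(counts) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  stopifnot(ncol(counts) >= 1)
  tot <- colMeans(counts)
  if (any(tot <= 0)) stop("every sample must have positive total count")
  scaled <- sweep(counts, 2, tot, `/`)
  ref <- rowMeans(scaled)
  ratio <- sweep(scaled, 1, ref, `/`)
  ratio[ref == 0, ] <- NA_real_
  attr(ratio, "reference") <- ref
  ratio
}

#' GC-bias correction of bin ratios
#'
#' Divides each ratio by a locally-weighted (lowess) fit of ratio against GC
#' fraction and rescales the result to mean 1, removing smooth wave-like
#' coverage biases tied to base composition.
#'
#' @param ratios numeric vector of bin ratios (NAs allowed; passed through).
#' @param gc per-bin GC fraction in \[0, 1\].
#' @param span lowess span (default 0.3).
#' @return Corrected ratios, mean 1 over informative bins.
#' @export
gc_correct <- function(ratios, gc, span = 0.3) {
  stopifnot(length(ratios) == length(gc), all(gc >= 0 & gc <= 1, na.rm = TRUE))
  ok <- is.finite(ratios) & is.finite(gc)
  if (sum(ok) < 10) stop("need at least 10 informative bins for GC correction")
  fit <- lowess(gc[ok], ratios[ok], f = span)
  pred <- approx(fit$x, fit$y, xout = gc[ok], rule = 2, ties = mean)$y
  pred[pred <= 0] <- min(pred[pred > 0], 1e-6)
  out <- ratios
  out[ok] <- ratios[ok] / pred
  out[ok] <- out[ok] / mean(out[ok])
  out
}

# Recursive circular binary segmentation of one chromosome's ratio vector.
# Returns the sorted indices of segment right-boundaries (excluding the last
# bin).
cbs_changepoints <- function(x, alpha = 0.01, nperm = 1000, min_width = 3) {
  bp <- integer(0)
  rec <- function(lo, hi) {
    if (hi - lo + 1 < 2 * min_width) return(invisible(NULL))
    res <- .cbs_test_split(x[lo:hi], min_width, alpha, nperm)
    if (is.na(res$i) || res$p >= alpha) return(invisible(NULL))
    a <- lo + res$i       # first arc element (res$i is a 0-based offset)
    b <- lo + res$j - 1   # last arc element
    if (a == lo && b == hi) return(invisible(NULL))
    if (a > lo) bp <<- c(bp, a - 1)
    if (b < hi) bp <<- c(bp, b)
    if (a > lo) rec(lo, a - 1)
    rec(a, b)
    if (b < hi) rec(b + 1, hi)
  }
  rec(1, length(x))
  sort(unique(bp))
}

# Merge adjacent segments whose means differ by less than merge_tol.
# boundaries: right-boundary indices (excluding n); returns updated ones.
merge_close_segments <- function(x, boundaries, merge_tol) {
  repeat {
    edges <- c(0, boundaries, length(x))
    if (length(boundaries) == 0) break
    means <- vapply(seq_len(length(edges) - 1), function(s)
      mean(x[(edges[s] + 1):edges[s + 1]]), numeric(1))
    d <- abs(diff(means))
    if (all(d >= merge_tol)) break
    drop <- which.min(d)
    boundaries <- boundaries[-drop]
  }
  boundaries
}

#' Segment bin ratios by circular binary segmentation
#'
#' Recursively finds, per chromosome, the pair of breakpoints maximizing the
#' two-sample t-statistic between a circular arc and its complement, and
#' accepts a split when its permutation p-value is below `alpha`.  Adjacent
#' segments whose means differ by less than `merge_tol` are merged.  Bins in
#' the same segment share the segment ratio (the mean corrected ratio of the
#' member bins).
#'
#' @param x numeric vector of (GC-corrected) bin ratios, finite.
#' @param chrom chromosome per bin (NULL = one chromosome).
#' @param alpha permutation significance level for accepting a split.
#' @param nperm number of permutations (permutations stop early as soon as
#'   the exceedance count already implies p >= alpha).
#' @param min_width minimum segment width in bins; chromosomes with fewer
#'   than `min_width` bins become single segments.
#' @param merge_tol mean-difference threshold below which neighbouring
#'   segments are merged.
#' @param state_thresh clamped-log2 threshold for calling a segment a
#'   deletion (< -state_thresh) or amplification (> +state_thresh).
#' @param seed optional RNG seed for the permutations.
#' @return List with `segments` (data.frame: chrom, start_bin, end_bin,
#'   n_bins, mean_ratio, clamped_log2, state) and `seg_ratio` (per-bin
#'   segment ratio).
#' @export
segment_bins <- function(x, chrom = NULL, alpha = 0.01, nperm = 1000,
                         min_width = 3, merge_tol = 0.05,
                         state_thresh = 0.3, seed = NULL) {
  stopifnot(all(is.finite(x)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chrom)) chrom <- rep("chr", length(x))
  stopifnot(length(chrom) == length(x))
  seg_ratio <- numeric(length(x))
  segs <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    xi <- x[idx]
    if (length(xi) >= 2 * min_width) {
      bnd <- cbs_changepoints(xi, alpha, nperm, min_width)
      bnd <- merge_close_segments(xi, bnd, merge_tol)
    } else bnd <- integer(0)
    edges <- c(0, bnd, length(xi))
    for (s in seq_len(length(edges) - 1)) {
      span_i <- (edges[s] + 1):edges[s + 1]
      m <- mean(xi[span_i])
      seg_ratio[idx[span_i]] <- m
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start_bin = idx[span_i[1]], end_bin = idx[span_i[length(span_i)]],
        n_bins = length(span_i), mean_ratio = m, stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  segments$clamped_log2 <- clamp_log2(segments$mean_ratio)
  segments$state <- ifelse(segments$clamped_log2 > state_thresh, "amplification",
                      ifelse(segments$clamped_log2 < -state_thresh, "deletion",
                             "normal"))
  list(segments = segments, seg_ratio = seg_ratio)
}

#' Median absolute pairwise difference (MAPD)
#'
#' The median over adjacent-bin pairs of the absolute difference in log2
#' copy-number ratio; a per-cell noise metric.  Neighbour pairs are formed
#' within chromosomes only.
#'
#' @param x log2 bin ratios.
#' @param chrom chromosome per bin (NULL = one chromosome).
#' @return Non-negative scalar.
#' @export
mapd <- function(x, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("chr", length(x))
  stopifnot(length(chrom) == length(x))
  d <- unlist(lapply(unique(chrom), function(ch) abs(diff(x[chrom == ch]))),
              use.names = FALSE)
  if (length(d) == 0)
    stop("MAPD needs at least one chromosome with >= 2 bins")
  median(d)
}

#' Filter cells by MAPD
#'
#' Removes cells whose MAPD is at or above the cutoff (inclusive threshold:
#' a cell at exactly the cutoff is removed).
#'
#' @param log2_ratios bins x cells matrix of log2 ratios.
#' @param chrom chromosome per bin (NULL = one chromosome).
#' @param cutoff removal threshold (default 1.4).
#' @return List with `retained` (column-subset matrix) and `report`
#'   (data.frame: cell, mapd, retained).
#' @export
filter_cells_by_mapd <- function(log2_ratios, chrom = NULL, cutoff = 1.4) {
  stopifnot(cutoff > 0)
  m <- apply(log2_ratios, 2, mapd, chrom = chrom)
  keep <- m < cutoff
  report <- data.frame(cell = colnames(log2_ratios) %||% seq_along(m),
                       mapd = unname(m), retained = unname(keep),
                       stringsAsFactors = FALSE)
  if (!any(keep)) {
    stop("all cells removed by MAPD filter (cutoff ", cutoff, "); MAPDs: ",
         paste(sprintf("%.3g", m), collapse = ", "))
  }
  list(retained = log2_ratios[, keep, drop = FALSE], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp log2 ratios to \[-1, 1\]
#'
#' `y = min(1, max(-1, log2(ratio)))`; non-positive ratios map to -1.
#'
#' @param ratio numeric vector of (segment) ratios.
#' @return Clamped log2 values in \[-1, 1\].
#' @export
clamp_log2 <- function(ratio) {
  out <- rep(-1, length(ratio))
  pos <- is.finite(ratio) & ratio > 0
  out[pos] <- pmin(1, pmax(-1, log2(ratio[pos])))
  out[is.na(ratio)] <- NA_real_
  out
}

#' Hierarchically cluster cells on clamped copy-number profiles
#'
#' Agglomerative clustering with Euclidean distance and ward.D2 linkage
#' (Lance-Williams update on squared distances).
#'
#' @param profiles cells x features numeric matrix (one row per cell).
#' @param k number of clusters to cut (optional).
#' @param h height to cut (optional alternative).
#' @return List with `hclust` and, when `k` or `h` is given, `labels`.
#' @export
cluster_cells <- function(profiles, k = NULL, h = NULL) {
  stopifnot(nrow(profiles) >= 2)
  if (!is.null(k) && k > nrow(profiles))
    stop("k (", k, ") exceeds the number of cells (", nrow(profiles), ")")
  hc <- hclust(dist(profiles), method = "ward.D2")
  labels <- if (!is.null(k) || !is.null(h)) cutree(hc, k = k, h = h) else NULL
  list(hclust = hc, labels = labels)
}

# Indices of bins whose midpoint lies in a region list(chrom, start, end).
bins_in_region <- function(bins, region) {
  mid <- (bins$start + bins$end) / 2
  which(bins$chrom == region$chrom & mid >= region$start & mid < region$end)
}

#' Test a candidate false-positive merged segment
#'
#' Pooled-variance two-sample two-sided t-test on the raw (pre-segmentation)
#' bin ratios of two portions of one cell's profile.  A small p-value means
#' the two portions differ in level, flagging a segment that was merged
#' across a true copy-number boundary.
#'
#' @param ratios per-bin raw ratios of one cell.
#' @param bins `bin_boundaries` (or NULL if regions are index vectors).
#' @param region_a,region_b regions as `list(chrom, start, end)` or integer
#'   bin-index vectors.
#' @return List with `t`, `p` and the two region sizes.
#' @export
region_fp_test <- function(ratios, bins = NULL, region_a, region_b) {
  ia <- if (is.list(region_a)) bins_in_region(bins, region_a) else region_a
  ib <- if (is.list(region_b)) bins_in_region(bins, region_b) else region_b
  if (length(ia) < 3 || length(ib) < 3)
    stop("both regions must contain at least 3 bins")
  tt <- pooled_t_test(ratios[ia], ratios[ib])
  list(t = tt$t, p = tt$p, n_a = length(ia), n_b = length(ib))
}

#' Assign a cell's segment profile to a subclone category
#'
#' Rule-based call over diagnostic loci: a region is lost when its mean
#' clamped log2 value is at or below `-loss_thresh`, gained at or above
#' `gain_thresh`.  The combination of lost/gained loci maps to one of the
#' five subclone categories of the CLL model, or "other".
#'
#' @param clamped per-bin clamped log2 segment ratios of one cell.
#' @param bins `bin_boundaries`.
#' @param regions named region list; see [default_regions()].  Regions on
#'   one chromosome must be disjoint or nested.
#' @param loss_thresh,gain_thresh thresholds (default 0.3).
#' @return Character label.
#' @export
assign_subclone <- function(clamped, bins, regions = default_regions(),
                            loss_thresh = 0.3, gain_thresh = 0.3) {
  nm <- names(regions)
  if (anyDuplicated(nm)) stop("duplicated region names")
  # overlapping definitions must be nested, not partial
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    if (i >= j) next
    a <- regions[[i]]; b <- regions[[j]]
    if (a$chrom != b$chrom) next
    ov <- min(a$end, b$end) - max(a$start, b$start)
    if (ov > 0) {
      nested <- (a$start <= b$start && a$end >= b$end) ||
                (b$start <= a$start && b$end >= a$end)
      if (!nested) stop("overlapping contradictory region definitions: ",
                        nm[i], " vs ", nm[j])
    }
  }
  mean_val <- vapply(regions, function(r) {
    idx <- bins_in_region(bins, r)
    if (length(idx) == 0) return(NA_real_)
    mean(clamped[idx], na.rm = TRUE)
  }, numeric(1))
  lost <- !is.na(mean_val) & mean_val <= -loss_thresh
  gained <- !is.na(mean_val) & mean_val >= gain_thresh
  need <- c("6q", "12p", "12q", "focal_13q", "large_13q")
  if (!all(need %in% nm))
    stop("regions must name the diagnostic loci: ",
         paste(setdiff(need, nm), collapse = ", "))
  if (!any(lost) && !any(gained)) return("normal-like")
  if (gained["12p"] && gained["12q"] && !lost["6q"] &&
      !lost["focal_13q"] && !lost["large_13q"]) return("trisomy 12 only")
  if (lost["6q"] && gained["12q"] && lost["focal_13q"] && !gained["12p"])
    return("6q- and 12q+, 13q14.3-")
  if (lost["focal_13q"] && lost["large_13q"] && !lost["6q"] &&
      !gained["12q"] && !gained["12p"]) return("focal and large 13q-")
  if (lost["focal_13q"] && !lost["large_13q"] && !lost["6q"] &&
      !gained["12q"] && !gained["12p"]) return("focal 13q- only")
  "other"
}

#' End-to-end single-cell copy-number pipeline
#'
#' Normalizes per-cell bin counts against the cohort, GC-corrects, removes
#' noisy cells by MAPD, segments each retained cell by circular binary
#' segmentation, clamps the log2 segment ratios to \[-1, 1\] and clusters
#' the cells with ward.D2.
#'
#' @param counts bins x cells count matrix.
#' @param bins `bin_boundaries`.
#' @param k number of subclone clusters to cut.
#' @param alpha,nperm,min_width,merge_tol segmentation parameters; see
#'   [segment_bins()].
#' @param span GC-correction lowess span.
#' @param mapd_cutoff MAPD removal threshold.
#' @param seed RNG seed for the segmentation permutations.
#' @return List with `qc` (MAPD report), `clamped` (cells x bins matrix of
#'   clamped log2 segment ratios), `segments` (per-cell list), `clusters`
#'   (result of [cluster_cells()]) and `retained_cells`.
#' @export
cnv_pipeline <- function(counts, bins, k = 5, alpha = 0.01, nperm = 1000,
                         min_width = 3, merge_tol = 0.05, span = 0.3,
                         mapd_cutoff = 1.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ratios <- normalize_ratios(counts)
  ok_bin <- apply(is.finite(ratios), 1, all) & is.finite(bins$gc)
  corrected <- apply(ratios[ok_bin, , drop = FALSE], 2, gc_correct,
                     gc = bins$gc[ok_bin], span = span)
  chrom <- bins$chrom[ok_bin]
  safe_log2 <- function(r) { r[r <= 0] <- min(r[r > 0]) / 2; log2(r) }
  l2 <- apply(corrected, 2, safe_log2)
  qc <- filter_cells_by_mapd(l2, chrom = chrom, cutoff = mapd_cutoff)
  keep <- qc$report$retained
  corrected <- corrected[, keep, drop = FALSE]
  segs <- vector("list", ncol(corrected))
  clamped <- matrix(NA_real_, ncol(corrected), nrow(corrected),
                    dimnames = list(colnames(corrected), NULL))
  for (ci in seq_len(ncol(corrected))) {
    sg <- segment_bins(corrected[, ci], chrom = chrom, alpha = alpha,
                       nperm = nperm, min_width = min_width,
                       merge_tol = merge_tol)
    segs[[ci]] <- sg$segments
    clamped[ci, ] <- clamp_log2(sg$seg_ratio)
  }
  clusters <- cluster_cells(clamped, k = k)
  list(qc = qc$report, clamped = clamped, segments = segs,
       clusters = clusters, retained_cells = colnames(corrected),
       bin_index = which(ok_bin))
}
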