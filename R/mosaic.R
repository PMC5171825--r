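# Heterozygous-probe mask: genotype class when available, otherwise a BAF
# band at the track level.
het_probes <- function(track, baf_band = c(0.15, 0.85)) {
  if (!is.null(track$genotype) && !all(is.na(track$genotype))) {
    track$genotype == "AB"
  } else {
    track$baf >= baf_band[1] & track$baf <= baf_band[2]
  }
}

#' Preprocess an LRR/BAF probe track
#'
#' Drops probes with non-finite LRR (count reported as an attribute),
#' optionally quantile-maps the LRR values onto a reference distribution,
#' and residualizes LRR against local GC with a lowess fit (same contract as
#' [gc_correct()], on the log scale: the fitted trend is subtracted).  BAF
#' is left untouched.
#'
#' @param track a `probe_track` (needs `lrr`; `gc` for the GC step).
#' @param reference optional numeric vector whose empirical distribution the
#'   LRR values are mapped onto.
#' @param span lowess span.
#' @return The corrected track, with attribute `n_dropped`.
#' @export
preprocess_track <- function(track, reference = NULL, span = 0.3) {
  ok <- is.finite(track$lrr)
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no probes with finite LRR")
  track <- track[ok, , drop = FALSE]
  if (!is.null(reference)) {
    ref <- sort(reference[is.finite(reference)])
    r <- rank(track$lrr, ties.method = "average")
    # probs (r-1)/(n-1) with quantile type 7 make the map the identity when
    # the track is its own reference
    track$lrr <- quantile(ref, probs = (r - 1) / (length(r) - 1),
                          names = FALSE, type = 7)
  }
  if (!is.null(track$gc) && length(unique(track$gc)) > 2) {
    fit <- lowess(track$gc, track$lrr, f = span)
    pred <- approx(fit$x, fit$y, xout = track$gc, rule = 2, ties = mean)$y
    track$lrr <- track$lrr - pred + mean(pred)
  }
  attr(track, "n_dropped") <- n_dropped
  class(track) <- c("probe_track", "data.frame")
  track
}

#' Segment the mirrored BAF deviation of heterozygous probes
#'
#' Applies circular binary segmentation (shared with [segment_bins()]) to
#' the mirrored deviation `delta_i = |BAF_i - 0.5|` of heterozygous probes,
#' chromosome by chromosome.  Segments shorter than `min_probes` are merged
#' into their closer-mean neighbour, so every reported segment has at least
#' `min_probes` heterozygous probes; chromosomes with fewer than
#' `min_probes` heterozygous probes are reported as single unscored
#' segments.  Each segment carries its mean LRR (all probes in its span) and
#' mean deviation delta (het probes).
#'
#' @param track a `probe_track`.
#' @param min_probes minimum heterozygous probes per reported segment
#'   (default 20).
#' @param alpha,nperm segmentation permutation parameters.
#' @param seed optional RNG seed.
#' @return data.frame of mosaic segments: chrom, start, end, n_probes (het),
#'   mean_lrr, delta, scored.
#' @export
segment_baf_lrr <- function(track, min_probes = 20, alpha = 0.01,
                            nperm = 1000, seed = NULL) {
  stopifnot(min_probes >= 2)
  if (!is.null(seed)) set.seed(seed)
  het <- het_probes(track)
  segs <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch & het)
    all_ch <- which(track$chrom == ch)
    if (length(sel) < min_probes) {
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = min(track$pos[all_ch]), end = max(track$pos[all_ch]),
        n_probes = length(sel),
        mean_lrr = mean(track$lrr[all_ch]),
        delta = if (length(sel)) mean(abs(track$baf[sel] - 0.5)) else NA_real_,
        scored = FALSE, stringsAsFactors = FALSE)
      next
    }
    delta <- abs(track$baf[sel] - 0.5)
    bnd <- cbs_changepoints(delta, alpha, nperm, min_width = 2)
    # enforce the minimum segment size by absorbing short segments
    repeat {
      edges <- c(0, bnd, length(sel))
      sizes <- diff(edges)
      if (all(sizes >= min_probes) || length(bnd) == 0) break
      means <- vapply(seq_along(sizes), function(s)
        mean(delta[(edges[s] + 1):edges[s + 1]]), numeric(1))
      short <- which.min(sizes)
      # merge with the neighbour of closer mean
      cand <- c(short - 1, short)
      cand <- cand[cand >= 1 & cand <= length(bnd)]
      if (length(cand) == 2) {
        left_gap <- abs(means[short] - means[short - 1])
        right_gap <- abs(means[short] - means[short + 1])
        cand <- if (left_gap <= right_gap) short - 1 else short
      }
      bnd <- bnd[-cand[1]]
    }
    edges <- c(0, bnd, length(sel))
    for (s in seq_len(length(edges) - 1)) {
      span_i <- sel[(edges[s] + 1):edges[s + 1]]
      lo <- min(track$pos[span_i]); hi <- max(track$pos[span_i])
      in_span <- all_ch[track$pos[all_ch] >= lo & track$pos[all_ch] <= hi]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = lo, end = hi, n_probes = length(span_i),
        mean_lrr = mean(track$lrr[in_span]),
        delta = mean(abs(track$baf[span_i] - 0.5)),
        scored = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Classify a mosaic segment
#'
#' A segment whose BAF deviation delta is above the noise floor is a mosaic
#' loss when its mean LRR is below `-lrr_thresh`, a mosaic gain above
#' `+lrr_thresh`, and copy-neutral LOH when |LRR| is within the threshold.
#' Delta at the noise floor means a normal segment.
#'
#' @param mean_lrr,delta segment summaries (see [segment_baf_lrr()]).
#' @param lrr_thresh LRR threshold (default 0.05).
#' @param delta_floor BAF-deviation noise floor (default 0.03; with BAF
#'   noise sd 0.03 the null mean deviation is about 0.024).
#' @return One of "mosaic loss", "mosaic gain", "mosaic CNLOH", "normal".
#' @export
classify_mosaic <- function(mean_lrr, delta, lrr_thresh = 0.05,
                            delta_floor = 0.03) {
  stopifnot(length(mean_lrr) == length(delta))
  out <- rep("normal", length(delta))
  ab <- !is.na(delta) & delta > delta_floor
  out[ab & mean_lrr < -lrr_thresh] <- "mosaic loss"
  out[ab & mean_lrr > lrr_thresh] <- "mosaic gain"
  out[ab & abs(mean_lrr) <= lrr_thresh] <- "mosaic CNLOH"
  out
}

#' Estimate the mosaic cell fraction from the BAF deviation
#'
#' Inverts the allelic mixture algebra.  With a fraction f of aberrant cells
#' mixed into diploid cells, a heterozygous probe's BAF deviates from 1/2
#' by: loss delta = f / (2(2-f)); gain delta = f / (2(2+f)); CNLOH
#' delta = f/2.  Solving for f gives loss f = 4d/(1+2d), gain
#' f = 4d/(1-2d) (capped at 1; d >= 1/6 already implies a pure gain), CNLOH
#' f = 2d.
#'
#' @param state classification from [classify_mosaic()].
#' @param delta mean mirrored BAF deviation in \[0, 0.5\].
#' @return Estimated fraction in \[0, 1\] ("normal" gives 0).  Gains with
#'   delta >= 1/6 are capped at 1 with attribute `capped`.
#' @export
estimate_mosaic_fraction <- function(state, delta) {
  stopifnot(length(state) == length(delta),
            all(is.na(delta) | (delta >= 0 & delta <= 0.5)))
  f <- numeric(length(state))
  capped <- logical(length(state))
  for (i in seq_along(state)) {
    d <- delta[i]
    f[i] <- switch(state[i],
      "mosaic loss"  = 4 * d / (1 + 2 * d),
      "mosaic gain"  = { v <- 4 * d / (1 - 2 * d)
                         if (d >= 1 / 6) { capped[i] <- TRUE; 1 } else min(v, 1) },
      "mosaic CNLOH" = min(2 * d, 1),
      "normal"       = 0,
      stop("unknown state: ", state[i]))
  }
  attr(f, "capped") <- capped
  f
}

#' Scan a probe track for mosaic aberrations
#'
#' Convenience wrapper: segments the mirrored BAF deviation, classifies each
#' scored segment and estimates its mosaic fraction.
#'
#' @inheritParams segment_baf_lrr
#' @param lrr_thresh,delta_floor see [classify_mosaic()].
#' @return Segment data.frame with `state` and `fraction` columns.
#' @export
scan_mosaic <- function(track, min_probes = 20, alpha = 0.01, nperm = 1000,
                        lrr_thresh = 0.05, delta_floor = 0.03, seed = NULL) {
  segs <- segment_baf_lrr(track, min_probes = min_probes, alpha = alpha,
                          nperm = nperm, seed = seed)
  segs$state <- NA_character_
  segs$fraction <- NA_real_
  sc <- segs$scored
  segs$state[sc] <- classify_mosaic(segs$mean_lrr[sc], segs$delta[sc],
                                    lrr_thresh, delta_floor)
  segs$fraction[sc] <- estimate_mosaic_fraction(segs$state[sc], segs$delta[sc])
  segs
}

#' Coordinates of the focal 13q14.3 deletion (GRCh36 label)
#'
#' The targeted interval chr13:49,139,793-50,269,706 on the GRCh36 human
#' assembly, shipped as a preset label for real-data use; simulated tracks
#' use toy-genome coordinates instead.
#' @return `list(chrom, start, end, assembly)`.
#' @export
focal_13q14_region <- function() {
  list(chrom = "chr13", start = 49139793, end = 50269706, assembly = "GRCh36")
}

#' Targeted focal-region t-test
#'
#' Welch (unequal-variance) two-sided t-tests comparing, between a small
#' target region and a whole reference chromosome: (a) probe LRR, and (b)
#' the mirrored BAF deviation |BAF - 0.5| of heterozygous probes.  Designed
#' to catch a focal deletion too small for genome-wide segmentation.
#'
#' @param track a `probe_track`.
#' @param target `list(chrom, start, end)` (default: the aberrant interval
#'   of the toy genome's chr13).
#' @param reference_chrom reference chromosome (default "chr1").
#' @return List: `t_lrr`, `p_lrr`, `t_baf`, `p_baf` (BAF entries NA when
#'   the target has no heterozygous probes), probe counts.
#' @export
focal_region_ttest <- function(track,
                               target = list(chrom = "chr13", start = 12e6,
                                             end = 14e6),
                               reference_chrom = "chr1") {
  in_t <- track$chrom == target$chrom & track$pos >= target$start &
    track$pos < target$end
  in_r <- track$chrom == reference_chrom
  if (sum(in_t) < 3 || sum(in_r) < 3)
    stop("target region and reference chromosome each need >= 3 probes")
  lt <- welch_t_test(track$lrr[in_t], track$lrr[in_r])
  het <- het_probes(track)
  td <- abs(track$baf[in_t & het] - 0.5)
  rd <- abs(track$baf[in_r & het] - 0.5)
  if (length(td) >= 3 && length(rd) >= 3) {
    bt <- welch_t_test(td, rd)
    t_baf <- bt$t; p_baf <- bt$p
  } else {
    t_baf <- NA_real_; p_baf <- NA_real_
  }
  list(t_lrr = lt$t, p_lrr = lt$p, t_baf = t_baf, p_baf = p_baf,
       n_target = sum(in_t), n_reference = sum(in_r),
       n_target_het = length(td))
}
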