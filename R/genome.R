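#' Construct a genome model
#'
#' A desk-scale stand-in for a reference genome: named chromosome lengths plus
#' a deterministic, smooth GC track.  GC at a position is a sinusoid
#' `gc_base + gc_amplitude * sin(2*pi*pos/gc_period + phase)` with a
#' chromosome-specific phase, clipped to \[0, 1\].  All coordinates are
#' 0-based half-open internally; text I/O converts to 1-based inclusive.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param gc_base,gc_amplitude,gc_period GC track parameters (fraction,
#'   fraction, bp).
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes,
                         gc_base = 0.45,
                         gc_amplitude = 0.10,
                         gc_period = 7e6) {
  stopifnot(is.numeric(chromosomes), length(chromosomes) >= 1,
            !is.null(names(chromosomes)), all(chromosomes > 0),
            gc_base >= 0, gc_base <= 1, gc_amplitude >= 0, gc_period > 0)
  structure(list(chrom = names(chromosomes),
                 length = unname(as.numeric(chromosomes)),
                 gc_base = gc_base, gc_amplitude = gc_amplitude,
                 gc_period = gc_period),
            class = "genome_model")
}

#' Default toy genome
#'
#' Six chromosomes (15-60 Mb) carrying the loci relevant to the CLL subclone
#' model: chr1 (SNP-array reference), chr6 (6q deletions), chr10 (CNLOH),
#' chr12 (12q gain / trisomy), chr13 (focal and large 13q deletions), chr19
#' (filler).  Total 205 Mb.
#'
#' @return A `genome_model`.
#' @export
default_genome <- function() {
  genome_model(c(chr1 = 60e6, chr6 = 40e6, chr10 = 30e6,
                 chr12 = 35e6, chr13 = 25e6, chr19 = 15e6))
}

#' GC fraction at genomic positions
#'
#' @param genome a `genome_model`.
#' @param chrom chromosome name(s).
#' @param pos position(s), 0-based.
#' @return GC fractions in \[0, 1\].
#' @export
gc_at <- function(genome, chrom, pos) {
  idx <- match(chrom, genome$chrom)
  if (anyNA(idx)) stop("unknown chromosome: ",
                       paste(unique(chrom[is.na(idx)]), collapse = ", "))
  phase <- (idx - 1) * pi / 3
  g <- genome$gc_base +
    genome$gc_amplitude * sin(2 * pi * pos / genome$gc_period + phase)
  pmin(1, pmax(0, g))
}

#' Tile a genome into fixed-count bins
#'
#' Allocates `n_bins` bins to chromosomes proportionally to length
#' (largest-remainder rounding, at least one bin each), with equal-width bins
#' within a chromosome, and annotates each bin with the GC fraction at its
#' midpoint.  This mirrors the fixed-bin-count strategy used for low-coverage
#' copy-number calling (10,000 bins by default).
#'
#' @param genome a `genome_model`.
#' @param n_bins total number of bins (default 10000).
#' @return A data.frame of class `bin_boundaries` with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `gc`.
#' @export
make_bin_boundaries <- function(genome, n_bins = 10000) {
  stopifnot(inherits(genome, "genome_model"))
  n_chrom <- length(genome$chrom)
  if (n_bins < n_chrom)
    stop("n_bins (", n_bins, ") must be at least the number of chromosomes (",
         n_chrom, ")")
  total <- sum(genome$length)
  if (n_bins > total) stop("n_bins exceeds total genome length")
  quota <- n_bins * genome$length / total
  alloc <- pmax(1L, floor(quota))
  rem <- n_bins - sum(alloc)
  if (rem > 0) {
    frac <- quota - floor(quota)
    ord <- order(-frac, seq_along(frac))  # ties broken by chromosome order
    take <- ord[seq_len(rem)]
    alloc[take] <- alloc[take] + 1L
  } else if (rem < 0) {
    # only possible when the >=1 floor over-allocated tiny chromosomes
    ord <- order(-alloc)
    i <- 1L
    while (rem < 0) {
      if (alloc[ord[i]] > 1L) { alloc[ord[i]] <- alloc[ord[i]] - 1L; rem <- rem + 1L }
      i <- if (i == n_chrom) 1L else i + 1L
    }
  }
  out <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
    nb <- alloc[ci]
    edges <- round(seq(0, genome$length[ci], length.out = nb + 1))
    data.frame(chrom = genome$chrom[ci],
               start = edges[-(nb + 1)], end = edges[-1],
               stringsAsFactors = FALSE)
  }))
  out$gc <- gc_at(genome, out$chrom, (out$start + out$end) / 2)
  rownames(out) <- NULL
  class(out) <- c("bin_boundaries", "data.frame")
  attr(out, "genome") <- genome
  out
}
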