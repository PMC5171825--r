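#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-patient generator.  A fixed seed makes
#' every downstream simulation bit-reproducible.
#'
#' @param seed integer RNG seed.
#' @param n_clones number of subclones (5 = the default CLL model; 1 = a
#'   single normal clone).
#' @param depth_per_bin mean sequencing reads per genomic bin per cell.
#' @param cells_per_time single-cell WGS cells sampled per time point.
#' @param n_probes SNP-array probes per simulated track.
#' @param n_sites variant sites for the allele-frequency trajectories.
#' @param n_genes,markers_per_cluster,marker_effect,dropout_rate expression
#'   generator: genes, markers per expression cluster, multiplicative marker
#'   effect (2 = two-fold), dropout probability.
#' @param gc_curvature curvature of the quadratic GC bias on bin counts
#'   (0 disables the bias).
#' @param baf_noise_sd,lrr_noise_sd SNP-array noise scales.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clones = 5L,
                       depth_per_bin = 100,
                       cells_per_time = 50L,
                       n_probes = 1000L,
                       n_sites = 500L,
                       n_genes = 2000L,
                       markers_per_cluster = 100L,
                       marker_effect = 2,
                       dropout_rate = 0.02,
                       gc_curvature = 4,
                       baf_noise_sd = 0.03,
                       lrr_noise_sd = 0.15) {
  stopifnot(depth_per_bin > 0, cells_per_time > 0, n_probes > 0, n_sites > 0,
            n_genes > 0, markers_per_cluster > 0, marker_effect >= 1,
            dropout_rate >= 0, dropout_rate < 1, n_clones %in% c(1L, 5L))
  structure(list(seed = as.integer(seed), n_clones = as.integer(n_clones),
                 depth_per_bin = depth_per_bin,
                 cells_per_time = as.integer(cells_per_time),
                 n_probes = as.integer(n_probes),
                 n_sites = as.integer(n_sites),
                 n_genes = as.integer(n_genes),
                 markers_per_cluster = as.integer(markers_per_cluster),
                 marker_effect = marker_effect,
                 dropout_rate = dropout_rate,
                 gc_curvature = gc_curvature,
                 baf_noise_sd = baf_noise_sd,
                 lrr_noise_sd = lrr_noise_sd),
            class = "sim_config")
}

#' Construct a subclone
#'
#' @param id clone label.
#' @param events data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `copy` (integer copy number >= 0) and optionally `allele`
#'   ("A"/"B", the homolog retained or duplicated; relevant for LOH).
#' @param fractions numeric vector, mixture fraction of this clone at each
#'   time point (values in \[0, 1\]).
#' @param genome a `genome_model` used to validate event bounds.
#' @return An object of class `clone_population`.
#' @export
clone_population <- function(id, events, fractions, genome = default_genome()) {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), copy = integer(),
                         allele = character(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("chrom", "start", "end", "copy") %in% names(events)))
    if (is.null(events$allele)) events$allele <- "A"
    idx <- match(events$chrom, genome$chrom)
    if (anyNA(idx)) stop("event on unknown chromosome")
    if (any(events$start < 0) || any(events$end > genome$length[idx]))
      stop("event region outside genome bounds")
    if (any(events$copy < 0)) stop("copy numbers must be >= 0")
    events$copy <- as.integer(events$copy)
  }
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  structure(list(id = id, events = events, fractions = fractions),
            class = "clone_population")
}

# Diagnostic loci of the default model, in toy-genome coordinates.
# The focal 13q14.3 deletion is nested inside the large 13q14.2-14.3 region;
# chr12 is split into p and q parts so a q-arm gain and a whole-chromosome
# trisomy are distinguishable.
#' Diagnostic region definitions for subclone assignment
#' @return Named list of regions, each `list(chrom, start, end)`.
#' @export
default_regions <- function() {
  list(`6q`          = list(chrom = "chr6",  start = 20e6, end = 40e6),
       `12p`         = list(chrom = "chr12", start = 0,    end = 17.5e6),
       `12q`         = list(chrom = "chr12", start = 17.5e6, end = 35e6),
       `focal_13q`   = list(chrom = "chr13", start = 12e6, end = 14e6),
       `large_13q`   = list(chrom = "chr13", start = 8e6,  end = 16e6))
}

#' The default five-subclone longitudinal model
#'
#' Returns the five CNV-defined subclones of the CLL patient model on the toy
#' genome: normal-like; focal 13q- only; focal plus large 13q-; 6q- with 12q+
#' and focal 13q-; and trisomy 12 only.  Mixture fractions are defined on
#' seven time points (years 10, 14, 21, 23, 24, 26, 28 after presentation):
#' the 6q-/12q+ clone dominates early and vanishes after therapy, while the
#' trisomy-12 clone appears only at the late time points.
#'
#' @param config a `sim_config`; with `n_clones = 1` a single normal clone
#'   (all fractions 1) is returned.
#' @param genome a `genome_model`.
#' @return List of `clone_population`, with attributes `timepoints` (years)
#'   and `genome`.
#' @export
make_default_clone_model <- function(config = sim_config(),
                                     genome = default_genome()) {
  stopifnot(inherits(config, "sim_config"))
  times <- c(10, 14, 21, 23, 24, 26, 28)
  if (config$n_clones == 1L) {
    clones <- list(clone_population("normal-like", NULL,
                                    rep(1, length(times)), genome))
  } else {
    frac <- rbind(
      `normal-like`             = c(0.30, 0.25, 0.20, 0.20, 0.25, 0.30, 0.20),
      `focal 13q- only`         = c(0.25, 0.25, 0.25, 0.30, 0.40, 0.40, 0.35),
      `focal and large 13q-`    = c(0.10, 0.15, 0.20, 0.20, 0.20, 0.15, 0.15),
      `6q- and 12q+, 13q14.3-`  = c(0.35, 0.35, 0.35, 0.30, 0.05, 0.00, 0.00),
      `trisomy 12 only`         = c(0.00, 0.00, 0.00, 0.00, 0.10, 0.15, 0.30))
    ev <- list(
      `normal-like` = NULL,
      `focal 13q- only` = data.frame(
        chrom = "chr13", start = 12e6, end = 14e6, copy = 1L, allele = "A"),
      `focal and large 13q-` = data.frame(
        chrom = "chr13", start = 8e6, end = 16e6, copy = 1L, allele = "A"),
      `6q- and 12q+, 13q14.3-` = data.frame(
        chrom = c("chr6", "chr12", "chr13"),
        start = c(20e6, 17.5e6, 12e6),
        end   = c(40e6, 35e6, 14e6),
        copy  = c(1L, 3L, 1L), allele = "A"),
      `trisomy 12 only` = data.frame(
        chrom = "chr12", start = 0, end = 35e6, copy = 3L, allele = "A"))
    clones <- lapply(rownames(frac), function(id)
      clone_population(id, ev[[id]], frac[id, ], genome))
  }
  tot <- Reduce(`+`, lapply(clones, `[[`, "fractions"))
  stopifnot(all(abs(tot - 1) < 1e-12))
  structure(clones, timepoints = times, genome = genome,
            class = "clone_model")
}

#' Per-clone fraction matrix of a clone model
#' @param model a `clone_model`.
#' @return Matrix clones x time points.
#' @export
clone_fractions <- function(model) {
  m <- do.call(rbind, lapply(model, `[[`, "fractions"))
  rownames(m) <- vapply(model, `[[`, character(1), "id")
  colnames(m) <- paste0("year", attr(model, "timepoints"))
  m
}

# Integer copy number of clone `cl` over the bins (vector along bins).
# A bin takes the copy number of the event containing its midpoint.
clone_copy_by_bin <- function(cl, bins) {
  copy <- rep(2L, nrow(bins))
  if (nrow(cl$events) == 0) return(copy)
  mid <- (bins$start + bins$end) / 2
  for (e in seq_len(nrow(cl$events))) {
    hit <- bins$chrom == cl$events$chrom[e] &
      mid >= cl$events$start[e] & mid < cl$events$end[e]
    copy[hit] <- cl$events$copy[e]
  }
  copy
}
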