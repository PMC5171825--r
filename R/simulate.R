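#' Simulate per-cell binned read counts
#'
#' Draws one low-coverage WGS profile per cell from its clone's copy-number
#' genotype: the count in a bin is Poisson with mean
#' `depth_per_bin * copy/2 * gc_bias(gc)`, where the GC bias is the smooth
#' unimodal quadratic `max(0.1, 1 - gc_curvature * (gc - 0.45)^2)`.
#'
#' @param model a `clone_model`.
#' @param bins `bin_boundaries`.
#' @param cell_spec data.frame with one row per cell: column `clone` (index
#'   into `model`) and optional `time` (index into the model's time points,
#'   used to record metadata only).
#' @param depth_per_bin mean reads per bin for a diploid region.
#' @param gc_curvature curvature of the GC bias (0 = no bias).
#' @param seed optional RNG seed.
#' @return List with `counts` (bins x cells integer matrix), `cells`
#'   (metadata with ground-truth clone id) and `bins`.
#' @export
simulate_cell_bin_counts <- function(model, bins, cell_spec,
                                     depth_per_bin = 100,
                                     gc_curvature = 4,
                                     seed = NULL) {
  stopifnot(inherits(model, "clone_model"), inherits(bins, "bin_boundaries"),
            depth_per_bin > 0, all(cell_spec$clone >= 1),
            all(cell_spec$clone <= length(model)))
  if (!is.null(seed)) set.seed(seed)
  gc_bias <- pmax(0.1, 1 - gc_curvature * (bins$gc - 0.45)^2)
  copy <- vapply(model, clone_copy_by_bin, integer(nrow(bins)), bins = bins)
  n_cells <- nrow(cell_spec)
  counts <- matrix(0L, nrow(bins), n_cells)
  for (ci in seq_len(n_cells)) {
    lam <- depth_per_bin * copy[, cell_spec$clone[ci]] / 2 * gc_bias
    counts[, ci] <- rpois(nrow(bins), lam)
  }
  ids <- sprintf("cell%03d", seq_len(n_cells))
  colnames(counts) <- ids
  cells <- data.frame(cell = ids,
                      clone = vapply(model, `[[`, character(1), "id")[cell_spec$clone],
                      clone_index = cell_spec$clone,
                      stringsAsFactors = FALSE)
  if (!is.null(cell_spec$time)) cells$time <- cell_spec$time
  list(counts = counts, cells = cells, bins = bins)
}

#' Simulate a SNP-array probe track with a mosaic aberration
#'
#' Heterozygous probes inside the aberrant region are centred at the two
#' mirrored B-allele frequencies given by the allelic mixture of a fraction
#' `fraction` of aberrant cells with `1 - fraction` diploid cells; LRR is
#' centred at `log2((2*(1-fraction) + c*fraction)/2)` for aberrant copy
#' number `c`.  Homozygous probes stay at BAF 0/1.  Optionally a reference
#' chromosome (chr1) of normal probes is appended, as used by the targeted
#' focal-deletion test.
#'
#' @param fraction mosaic cell fraction in \[0, 1\].
#' @param aberration_type one of "none", "loss", "gain", "cnloh".
#' @param n_probes probes on the target chromosome.
#' @param region_probes number of those probes falling in the aberrant
#'   region.
#' @param reference_probes probes simulated on the diploid reference
#'   chromosome chr1 (0 = none).
#' @param het_rate probability a probe is heterozygous.
#' @param baf_noise_sd,lrr_noise_sd Gaussian noise scales (0 = noiseless).
#' @param gc_lrr_amplitude amplitude of an optional GC-linked LRR wave
#'   (used to exercise the GC residualization).
#' @param chrom target chromosome; `region` its aberrant interval (0-based).
#' @param genome a `genome_model`.
#' @param seed optional RNG seed.
#' @return A data.frame of class `probe_track` (`chrom`, `pos`, `lrr`,
#'   `baf`, `genotype`, `gc`) sorted by position, with a `truth` attribute
#'   recording region membership, fraction and type.
#' @export
simulate_probe_track <- function(fraction, aberration_type = c("none", "loss",
                                                               "gain", "cnloh"),
                                 n_probes = 1000,
                                 region_probes = round(n_probes * 0.3),
                                 reference_probes = 0,
                                 het_rate = 0.6,
                                 baf_noise_sd = 0.03,
                                 lrr_noise_sd = 0.15,
                                 gc_lrr_amplitude = 0,
                                 chrom = "chr13",
                                 region = c(12e6, 14e6),
                                 genome = default_genome(),
                                 seed = NULL) {
  aberration_type <- match.arg(aberration_type)
  stopifnot(fraction >= 0, fraction <= 1, region_probes <= n_probes)
  if (!is.null(seed)) set.seed(seed)
  f <- fraction
  copy <- switch(aberration_type, none = 2, loss = 1, gain = 3, cnloh = 2)
  len <- genome$length[match(chrom, genome$chrom)]
  if (is.na(len)) stop("unknown chromosome: ", chrom)

  pos_in <- if (region_probes > 0)
    round(seq(region[1], region[2], length.out = region_probes + 2)[-c(1, region_probes + 2)])
  else numeric(0)
  n_out <- n_probes - region_probes
  pos_out <- if (n_out > 0) {
    p <- round(seq(0, len, length.out = n_out + 2)[-c(1, n_out + 2)])
    p[p < region[1] | p >= region[2]]
  } else numeric(0)
  pos <- c(pos_in, pos_out)
  chr <- rep(chrom, length(pos))
  in_region <- c(rep(TRUE, length(pos_in)), rep(FALSE, length(pos_out)))
  if (reference_probes > 0) {
    rlen <- genome$length[match("chr1", genome$chrom)]
    rpos <- round(seq(0, rlen, length.out = reference_probes + 2))[
      -c(1, reference_probes + 2)]
    pos <- c(pos, rpos)
    chr <- c(chr, rep("chr1", reference_probes))
    in_region <- c(in_region, rep(FALSE, reference_probes))
  }

  n <- length(pos)
  geno <- sample(c("AB", "AA", "BB"), n, replace = TRUE,
                 prob = c(het_rate, (1 - het_rate) / 2, (1 - het_rate) / 2))
  # mixture BAF for heterozygous probes in the aberrant region
  baf_modes <- switch(aberration_type,
    none  = c(0.5, 0.5),
    loss  = c((1 - f) / (2 - f), 1 / (2 - f)),
    gain  = c(1 / (2 + f), (1 + f) / (2 + f)),
    cnloh = c((1 - f) / 2, (1 + f) / 2))
  baf <- numeric(n)
  het <- geno == "AB"
  pick_hi <- runif(n) < 0.5
  baf[het & !in_region] <- 0.5
  baf[het & in_region] <- ifelse(pick_hi[het & in_region],
                                 baf_modes[2], baf_modes[1])
  baf[geno == "AA"] <- 0
  baf[geno == "BB"] <- 1
  if (baf_noise_sd > 0) baf <- pmin(1, pmax(0, baf + rnorm(n, 0, baf_noise_sd)))

  lrr_mu <- ifelse(in_region, log2((2 * (1 - f) + copy * f) / 2), 0)
  gc <- gc_at(genome, chr, pos)
  if (gc_lrr_amplitude != 0) lrr_mu <- lrr_mu + gc_lrr_amplitude * (gc - mean(gc))
  lrr <- lrr_mu + if (lrr_noise_sd > 0) rnorm(n, 0, lrr_noise_sd) else 0

  ord <- order(match(chr, genome$chrom), pos)
  out <- data.frame(chrom = chr, pos = pos, lrr = lrr, baf = baf,
                    genotype = geno, gc = gc, stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  class(out) <- c("probe_track", "data.frame")
  attr(out, "truth") <- list(in_region = in_region[ord], fraction = f,
                             type = aberration_type, chrom = chrom,
                             region = region)
  out
}

#' Simulate longitudinal variant allele-depth tables
#'
#' Germline sites keep a constant allele fraction (0.5 heterozygous, 1
#' homozygous) across all time points; somatic sites are heterozygous in
#' their clone, so their expected variant allele fraction at time t is
#' `0.5 * clone_fraction(t)`.  Depths are Poisson around `depth`; variant
#' reads are binomial.  Annotation flags (population allele frequency above
#' cutoff, flagged database SNP) are set on a random subset of germline
#' sites, emulating the annotation-based removal of known polymorphisms.
#'
#' @param model a `clone_model` (its time points define the columns).
#' @param n_sites number of sites.
#' @param depth mean per-site sequencing depth.
#' @param germline_fraction fraction of sites that are germline.
#' @param hom_fraction fraction of germline sites that are homozygous.
#' @param flag_rate probability a germline site carries an annotation flag.
#' @param error_rate sequencing-error allele fraction added to every site
#'   (default 0: sites of absent clones yield exactly 0 variant reads).
#' @param seed optional RNG seed.
#' @return List of class `maf_sites`: `sites` (metadata + flags + ground
#'   truth), `depth` and `alt` (sites x time points matrices), `times`.
#' @export
simulate_maf_sites <- function(model, n_sites = 500, depth = 500,
                               germline_fraction = 0.5,
                               hom_fraction = 0.1,
                               flag_rate = 0.3,
                               error_rate = 0,
                               seed = NULL) {
  stopifnot(inherits(model, "clone_model"), n_sites > 0, depth > 0)
  if (!is.null(seed)) set.seed(seed)
  times <- attr(model, "timepoints")
  genome <- attr(model, "genome")
  nt <- length(times)
  frac <- clone_fractions(model)

  is_germ <- runif(n_sites) < germline_fraction
  n_clone <- length(model)
  clone_of <- ifelse(is_germ, NA_integer_,
                     sample(seq_len(n_clone), n_sites, replace = TRUE))
  hom <- is_germ & runif(n_sites) < hom_fraction

  p <- matrix(0, n_sites, nt)
  p[is_germ & !hom, ] <- 0.5
  p[hom, ] <- 1
  som <- which(!is_germ)
  for (i in som) p[i, ] <- 0.5 * frac[clone_of[i], ]
  if (error_rate > 0) p <- pmin(1, p + error_rate)

  dp <- matrix(pmax(1L, rpois(n_sites * nt, depth)), n_sites, nt)
  ad <- matrix(rbinom(n_sites * nt, dp, p), n_sites, nt)
  colnames(dp) <- colnames(ad) <- paste0("year", times)

  ci <- sample(seq_along(genome$chrom), n_sites, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  flag1 <- is_germ & runif(n_sites) < flag_rate
  flag2 <- is_germ & runif(n_sites) < flag_rate / 2
  sites <- data.frame(
    id = sprintf("site%04d", seq_len(n_sites)),
    chrom = genome$chrom[ci],
    pos = floor(runif(n_sites) * genome$length[ci]),
    ref = ref, alt = unname(alt),
    population_af_above_cutoff = flag1,
    flagged_snp = flag2,
    truth_germline = is_germ,
    truth_clone = ifelse(is_germ, NA_character_,
                         vapply(model, `[[`, character(1), "id")[clone_of]),
    stringsAsFactors = FALSE)
  structure(list(sites = sites, depth = dp, alt = ad, times = times),
            class = "maf_sites")
}

#' Default expression cluster specification
#'
#' Six expression clusters (A-F) over five sampling years whose prevalences
#' shift with disease course: cluster D dominates the earliest and the
#' year-26 samples, F takes over at year 20, and A/E expand at the terminal
#' time point (the composition pattern of the CLL patient's expression
#' clusters by date, normalized to sum to 1 per time point).
#'
#' @param n_genes,markers_per_cluster,effect,dropout generator knobs; see
#'   [sim_config()].
#' @param noise_sd standard deviation of per-cell log-normal expression
#'   noise (natural-log scale).
#' @return List used by [simulate_expression()].
#' @export
default_expression_spec <- function(n_genes = 2000, markers_per_cluster = 100,
                                    effect = 2, dropout = 0.02,
                                    noise_sd = 0.25) {
  prevalence <- cbind(
    year10 = c(0,    3.2,  6.5, 77,   3.2,  9.7),
    year20 = c(0,    0,    4.2,  0,   2.2, 94),
    year23 = c(11,  41,   30,   11,   6.5,  0),
    year26 = c(3.7,  0,    7.4, 82,   3.7,  3.7),
    year28 = c(36,   8.7, 20,    0,  36,    0))
  prevalence <- sweep(prevalence, 2, colSums(prevalence), `/`)
  rownames(prevalence) <- LETTERS[1:6]
  list(n_genes = n_genes, markers_per_cluster = markers_per_cluster,
       effect = effect, dropout = dropout, noise_sd = noise_sd,
       prevalence = prevalence, times = c(10, 20, 23, 26, 28),
       protein_coding_frac = 0.95)
}

#' Simulate a single-cell FPKM matrix with cluster structure
#'
#' Log-normal baseline expression per gene; each cluster's marker genes are
#' up-shifted by the multiplicative `effect` in cells of that cluster;
#' values are zeroed at the dropout rate.  Cells are assigned to clusters by
#' the time-specific prevalences of the spec, and carry mapped-read counts
#' so the QC cascade is exercisable.
#'
#' @param spec a spec from [default_expression_spec()].
#' @param n_cells_per_time cells sampled at each time point.
#' @param seed optional RNG seed.
#' @return List of class `expression_sim`: `fpkm` (genes x cells), `cells`
#'   (cell, time, mapped_reads, truth_cluster), `genes` (gene,
#'   protein_coding, marker_of).
#' @export
simulate_expression <- function(spec = default_expression_spec(),
                                n_cells_per_time = 60,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prev <- spec$prevalence
  if (any(abs(colSums(prev) - 1) > 1e-8))
    stop("cluster prevalences must sum to 1 at every time point")
  kc <- nrow(prev)
  nt <- ncol(prev)
  n_cells <- n_cells_per_time * nt
  cl_names <- rownames(prev)

  truth <- character(0); time <- numeric(0)
  for (t in seq_len(nt)) {
    truth <- c(truth, sample(cl_names, n_cells_per_time, replace = TRUE,
                             prob = prev[, t]))
    time <- c(time, rep(spec$times[t], n_cells_per_time))
  }

  ng <- spec$n_genes
  marker_of <- rep(NA_character_, ng)
  for (k in seq_len(kc)) {
    idx <- ((k - 1) * spec$markers_per_cluster + 1):(k * spec$markers_per_cluster)
    marker_of[idx] <- cl_names[k]
  }
  base_meanlog <- rnorm(ng, 1, 1)
  # markers sit comfortably above the expressed threshold so they survive
  # the core-gene-set filter
  base_meanlog[!is.na(marker_of)] <- rnorm(sum(!is.na(marker_of)), 1.5, 0.4)
  fpkm <- matrix(0, ng, n_cells)
  log_eff <- log(spec$effect)
  for (ci in seq_len(n_cells)) {
    mu <- base_meanlog + ifelse(!is.na(marker_of) & marker_of == truth[ci],
                                log_eff, 0)
    fpkm[, ci] <- exp(mu + rnorm(ng, 0, spec$noise_sd))
  }
  drop <- matrix(runif(ng * n_cells) < spec$dropout, ng, n_cells)
  fpkm[drop] <- 0

  gene_ids <- sprintf("gene%04d", seq_len(ng))
  cell_ids <- sprintf("c%03d", seq_len(n_cells))
  rownames(fpkm) <- gene_ids
  colnames(fpkm) <- cell_ids
  structure(list(
    fpkm = fpkm,
    cells = data.frame(cell = cell_ids, time = time,
                       mapped_reads = round(runif(n_cells, 2e6, 6e6)),
                       truth_cluster = truth, stringsAsFactors = FALSE),
    genes = data.frame(gene = gene_ids,
                       protein_coding = runif(ng) < spec$protein_coding_frac,
                       marker_of = marker_of, stringsAsFactors = FALSE)),
    class = "expression_sim")
}
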