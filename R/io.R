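# Text I/O for the pipeline's tabular formats.  Genomic intervals are
# 0-based half-open in memory and 1-based inclusive on disk.

#' Write per-cell bin counts as a BED-like table
#'
#' Columns: chrom, start, end (1-based inclusive on disk), gc, then one
#' count column per cell.
#'
#' @param sim output of [simulate_cell_bin_counts()] (or a list with
#'   `counts` and `bins`).
#' @param path output TSV path.
#' @export
write_bin_counts <- function(sim, path) {
  out <- data.frame(chrom = sim$bins$chrom, start = sim$bins$start + 1,
                    end = sim$bins$end, gc = sim$bins$gc,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(sim$counts))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a BED-like bin-count table
#' @param path TSV written by [write_bin_counts()].
#' @return List with `bins` (0-based half-open) and `counts` matrix.
#' @export
read_bin_counts <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  bins <- data.frame(chrom = x$chrom, start = x$start - 1, end = x$end,
                     gc = x$gc, stringsAsFactors = FALSE)
  class(bins) <- c("bin_boundaries", "data.frame")
  counts <- as.matrix(x[, setdiff(names(x), c("chrom", "start", "end", "gc")),
                        drop = FALSE])
  list(bins = bins, counts = counts)
}

#' Write / read a probe track (chrom, pos, LRR, BAF, genotype)
#' @param track a `probe_track`.
#' @param path TSV path.
#' @export
write_probe_track <- function(track, path) {
  out <- as.data.frame(track)
  out$pos <- out$pos + 1
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_probe_track
#' @export
read_probe_track <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  x$pos <- x$pos - 1
  class(x) <- c("probe_track", "data.frame")
  x
}

#' Write / read longitudinal allele-depth tables (VCF-like TSV)
#'
#' One row per site: CHROM, POS, REF, ALT, the annotation flags, then
#' per-time-point DP_* and AD_* columns.
#'
#' @param msites a `maf_sites` object.
#' @param path TSV path.
#' @export
write_maf_sites <- function(msites, path) {
  out <- data.frame(CHROM = msites$sites$chrom, POS = msites$sites$pos + 1,
                    REF = msites$sites$ref, ALT = msites$sites$alt,
                    population_af_above_cutoff =
                      msites$sites$population_af_above_cutoff,
                    flagged_snp = msites$sites$flagged_snp,
                    stringsAsFactors = FALSE)
  dp <- msites$depth; colnames(dp) <- paste0("DP_", colnames(dp))
  ad <- msites$alt; colnames(ad) <- paste0("AD_", colnames(ad))
  write.table(cbind(out, dp, ad), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname write_maf_sites
#' @export
read_maf_sites <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  dp_cols <- grep("^DP_", names(x), value = TRUE)
  ad_cols <- grep("^AD_", names(x), value = TRUE)
  times <- as.numeric(sub("^DP_year", "", dp_cols))
  sites <- data.frame(id = sprintf("site%04d", seq_len(nrow(x))),
                      chrom = x$CHROM, pos = x$POS - 1, ref = x$REF,
                      alt = x$ALT,
                      population_af_above_cutoff = x$population_af_above_cutoff,
                      flagged_snp = x$flagged_snp, stringsAsFactors = FALSE)
  dp <- as.matrix(x[, dp_cols]); colnames(dp) <- sub("^DP_", "", dp_cols)
  ad <- as.matrix(x[, ad_cols]); colnames(ad) <- sub("^AD_", "", ad_cols)
  structure(list(sites = sites, depth = dp, alt = ad, times = times),
            class = "maf_sites")
}

#' Write / read an FPKM matrix with cell metadata
#' @param sim an `expression_sim` (or list with `fpkm`, `cells`, `genes`).
#' @param prefix path prefix; writes `<prefix>_fpkm.tsv`,
#'   `<prefix>_cells.tsv`, `<prefix>_genes.tsv`.
#' @export
write_expression <- function(sim, prefix) {
  write.table(data.frame(gene = rownames(sim$fpkm), sim$fpkm,
                         check.names = FALSE),
              paste0(prefix, "_fpkm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$cells, paste0(prefix, "_cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genes, paste0(prefix, "_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' @rdname write_expression
#' @export
read_expression <- function(prefix) {
  f <- read.table(paste0(prefix, "_fpkm.tsv"), header = TRUE, sep = "\t",
                  check.names = FALSE, stringsAsFactors = FALSE)
  fpkm <- as.matrix(f[, -1, drop = FALSE])
  rownames(fpkm) <- f$gene
  list(fpkm = fpkm,
       cells = read.table(paste0(prefix, "_cells.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE),
       genes = read.table(paste0(prefix, "_genes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE))
}

#' Write per-cell segment calls as a BED-compatible table
#' @param segments segment data.frame from [segment_bins()] plus `bins`.
#' @param bins `bin_boundaries`.
#' @param path TSV path.
#' @export
write_segments <- function(segments, bins, path) {
  out <- data.frame(chrom = segments$chrom,
                    start = bins$start[segments$start_bin] + 1,
                    end = bins$end[segments$end_bin],
                    n_bins = segments$n_bins,
                    ratio = segments$mean_ratio,
                    clamped_log2 = segments$clamped_log2,
                    state = segments$state, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Export a cell dendrogram in Newick format
#' @param hc an `hclust` (e.g. from [cluster_cells()]).
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (is.null(hc$labels)) hc$labels <- as.character(seq_len(length(hc$order)))
  ape::write.tree(ape::as.phylo(hc), file = path)
}
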