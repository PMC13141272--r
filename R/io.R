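#' Read and write the interchange formats
#'
#' Coordinates on disk follow the BED convention (0-based, half-open), the
#' same convention used by the in-memory tables, so round trips are exact.
#'
#' @param genome A `genome_model`.
#' @param path File path.
#' @name k4gauge-io
NULL

#' @rdname k4gauge-io
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(genome$chromosomes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname k4gauge-io
#' @param x_name X chromosome name; if `NULL`, the unique name ending in
#'   `"X"` is used.
#' @export
read_chrom_sizes <- function(path, x_name = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("name", "length"),
                   colClasses = c("character", "numeric"))
  if (is.null(x_name)) {
    hit <- grep("X$", df$name, value = TRUE)
    if (length(hit) != 1L)
      stop("cannot infer the X chromosome; pass x_name")
    x_name <- hit
  }
  build_genome(df, x_name)
}

#' @rdname k4gauge-io
#' @param tss TSS anchor table (`name`, `chrom`, `pos`, `strand`).
#' @export
write_tss_bed <- function(tss, path) {
  if (nrow(tss) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(tss$chrom, tss$pos, tss$pos + 1, tss$name, 0L, tss$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname k4gauge-io
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(name = if (is.null(gr$name)) sprintf("tss_%d", seq_along(gr))
                    else gr$name,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             pos = GenomicRanges::start(gr) - 1,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname k4gauge-io
#' @param intervals Interval table (`name`, `chrom`, `start`, `end`).
#' @export
write_intervals_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   intervals$name, 0L, ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname k4gauge-io
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(name = if (is.null(gr$name)) sprintf("iv_%d", seq_along(gr))
                    else gr$name,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @rdname k4gauge-io
#' @param track A `coverage_track`.
#' @export
write_bedgraph <- function(track, genome, path) {
  gr <- track_to_granges(track, genome)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname k4gauge-io
#' @param bin_size Bin width of the track on disk.
#' @param normalisation Normalisation tag to attach on read.
#' @export
read_bedgraph <- function(path, genome, bin_size, normalisation = "raw") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  granges_to_track(gr, genome, bin_size, normalisation)
}

#' @rdname k4gauge-io
#' @param peaks Peak table as produced by [simulate_peaks()] or
#'   [read_broadpeak()].
#' @export
write_broadpeak <- function(peaks, path) {
  df <- peaks[, c("chrom", "start", "end", "name", "score", "strand",
                  "signalValue", "pValue_neglog10", "qValue_neglog10")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname k4gauge-io
#' @param mark,genotype Labels attached to every record on read.
#' @export
read_broadpeak <- function(path, mark = NA_character_,
                           genotype = NA_character_) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(signalValue = "numeric",
                                          pValue = "numeric",
                                          qValue = "numeric"))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = gr$name,
             score = as.integer(gr$score),
             strand = {
               s <- as.character(GenomicRanges::strand(gr))
               ifelse(s == "*", ".", s)
             },
             signalValue = gr$signalValue,
             pValue_neglog10 = gr$pValue,
             qValue_neglog10 = gr$qValue,
             mark = mark, genotype = genotype,
             stringsAsFactors = FALSE)
}

#' @rdname k4gauge-io
#' @param table A data frame (differential-expression results, spike-in
#'   counts, or Ct values).
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname k4gauge-io
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname k4gauge-io
#' @export
read_deg_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "chrom", "baseMean", "baseMeanA", "baseMeanB",
            "log2FoldChange", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("differential-expression table lacks columns: ",
         paste(miss, collapse = ", "))
  df
}

#' Write a complete synthetic fixture set
#'
#' Generates a genome, feature annotation, one raw coverage track and one
#' broadPeak table per genotype for the requested mark, a spike-in count
#' table covering all genotypes, and one differential-expression table per
#' mutant genotype, and writes everything in the plain-text interchange
#' formats.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param genome A `genome_model` (default: [default_genome()]).
#' @param n_tss,n_enh Feature counts.
#' @param mark Mark for the coverage/peak fixtures.
#' @param genotypes Genotypes to simulate (must be named in
#'   `config$mark_effects`).
#' @return Named character vector of file paths (the manifest).
#' @export
write_fixtures <- function(outdir, config = sim_config(),
                           genome = default_genome(),
                           n_tss = 200, n_enh = 100, mark = "me3",
                           genotypes = c("wt", "wdr5", "rbbp5")) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", outdir)
  feats <- simulate_features(genome, n_tss, n_enh, seed = config$seed,
                             enhancer_width = config$enhancer_width)
  manifest <- c(
    chrom_sizes = write_chrom_sizes(genome, file.path(outdir, "chrom.sizes")),
    tss = write_tss_bed(feats$tss, file.path(outdir, "tss.bed")),
    enhancers = write_intervals_bed(feats$enhancers,
                                    file.path(outdir, "enhancers.bed")))
  depl <- vapply(genotypes,
                 function(g) mean(config$mark_effects[[g]][[mark]]),
                 numeric(1))
  depl <- pmin(depl, 1)
  spike <- simulate_spikein_counts(depl,
                                   setNames(rep(config$depth,
                                                length(genotypes)),
                                            genotypes),
                                   config$spike_fraction, seed = config$seed)
  spike$genotype <- spike$sample_id
  spike$mark <- mark
  manifest["spike_counts"] <- write_tsv(
    spike[, c("sample_id", "genotype", "mark", "target_reads",
              "spike_reads")],
    file.path(outdir, "spike_counts.tsv"))
  for (g in genotypes) {
    trk <- simulate_coverage(genome, feats$tss, feats$enhancers, mark, g,
                             config, depth = spike$target_reads[
                               spike$sample_id == g])
    manifest[paste0("coverage_", g)] <-
      write_bedgraph(trk, genome, file.path(outdir,
                                            sprintf("%s_%s.bedgraph",
                                                    g, mark)))
    pk <- simulate_peaks(genome, feats$tss, feats$enhancers, mark, g, config)
    manifest[paste0("peaks_", g)] <-
      write_broadpeak(pk, file.path(outdir,
                                    sprintf("%s_%s.broadPeak", g, mark)))
  }
  for (g in setdiff(genotypes, "wt")) {
    deg <- simulate_deg_table(config, genome, label = g)
    manifest[paste0("deg_", g)] <-
      write_tsv(deg, file.path(outdir, sprintf("deg_%s.tsv", g)))
  }
  manifest
}
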