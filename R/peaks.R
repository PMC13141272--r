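#' Post-filter broad-peak calls with mark-specific thresholds
#'
#' Retains H3K4me1/me2 peaks with length >= 2000 bp and H3K4me3 peaks with
#' length >= 500 bp, in both cases requiring fold enrichment
#' `signalValue >= 3` and q <= 0.005. The q threshold is applied on the
#' broadPeak `-log10(q)` column as `qValue_neglog10 >= -log10(0.005)`
#' (~2.301), so all boundaries are inclusive. Input order is preserved.
#'
#' @param peaks Peak table with columns `chrom`, `start`, `end`,
#'   `signalValue`, `qValue_neglog10` and `mark`.
#' @param min_length_broad,min_length_me3 Length thresholds (bp) for
#'   me1/me2 and me3 peaks.
#' @param min_signal Minimum fold enrichment.
#' @param max_q Maximum q-value.
#' @return The retained subset of `peaks`.
#' @export
filter_peaks <- function(peaks, min_length_broad = 2000,
                         min_length_me3 = 500, min_signal = 3,
                         max_q = 0.005) {
  stopifnot(is.data.frame(peaks),
            all(c("start", "end", "signalValue", "qValue_neglog10",
                  "mark") %in% names(peaks)))
  bad <- setdiff(unique(peaks$mark), c("me1", "me2", "me3"))
  if (length(bad)) stop("unknown mark: ", paste(bad, collapse = ", "))
  len <- peaks$end - peaks$start
  min_len <- ifelse(peaks$mark == "me3", min_length_me3, min_length_broad)
  keep <- len >= min_len & peaks$signalValue >= min_signal &
    peaks$qValue_neglog10 >= -log10(max_q)
  peaks[keep, , drop = FALSE]
}

# 0-based half-open intervals -> GRanges (1-based closed)
.intervals_to_gr <- function(chrom, start, end, seqlevels) {
  GenomicRanges::GRanges(factor(chrom, levels = seqlevels),
                         IRanges::IRanges(start = start + 1, end = end))
}

#' Classify peaks into four mutually exclusive regulatory categories
#'
#' A peak overlapping (by any shared base) at least one promoter window
#' (TSS +/- `promoter_halfwidth`, half-open) and at least one enhancer is
#' `Promoter_Enhancer`; only a promoter, `Promoter_only`; only an enhancer,
#' `Enhancer_only`; neither, `Other`. Peaks on chromosomes absent from both
#' feature sets are classified `Other` (with a message, not an error).
#'
#' @param peaks Peak table (0-based half-open `start`, `end`).
#' @param tss TSS anchor table (`chrom`, `pos`).
#' @param enhancers Enhancer interval table (`chrom`, `start`, `end`).
#' @param promoter_halfwidth Promoter window half-width in bp; the window
#'   for a TSS at position p is `[p - hw, p + hw)`.
#' @return `peaks` with an added factor column `category` with levels
#'   `Promoter_only`, `Enhancer_only`, `Promoter_Enhancer`, `Other`.
#' @export
classify_regulatory <- function(peaks, tss, enhancers,
                                promoter_halfwidth = 1000) {
  stopifnot(is.data.frame(peaks))
  lvls <- c("Promoter_only", "Enhancer_only", "Promoter_Enhancer", "Other")
  if (nrow(peaks) == 0L) {
    peaks$category <- factor(character(), levels = lvls)
    return(peaks)
  }
  seqlv <- unique(c(peaks$chrom, tss$chrom, enhancers$chrom))
  pk <- .intervals_to_gr(peaks$chrom, peaks$start, peaks$end, seqlv)
  hits_p <- if (nrow(tss)) {
    prom <- .intervals_to_gr(tss$chrom, tss$pos - promoter_halfwidth,
                             tss$pos + promoter_halfwidth, seqlv)
    GenomicRanges::countOverlaps(pk, GenomicRanges::reduce(prom)) > 0
  } else rep(FALSE, nrow(peaks))
  hits_e <- if (nrow(enhancers)) {
    enh <- .intervals_to_gr(enhancers$chrom, enhancers$start,
                            enhancers$end, seqlv)
    GenomicRanges::countOverlaps(pk, enh) > 0
  } else rep(FALSE, nrow(peaks))
  orphan <- !peaks$chrom %in% unique(c(tss$chrom, enhancers$chrom))
  if (any(orphan))
    message(sum(orphan), " peak(s) on chromosomes absent from the feature",
            " sets; classified Other")
  category <- ifelse(hits_p & hits_e, "Promoter_Enhancer",
              ifelse(hits_p, "Promoter_only",
              ifelse(hits_e, "Enhancer_only", "Other")))
  peaks$category <- factor(category, levels = lvls)
  peaks
}

#' Summarise peak burden per regulatory category
#'
#' Exact per-(genotype, mark, category) counts, cumulative fold-enrichment
#' signal, and cumulative area (signal x width). Categories with zero peaks
#' are reported with zeros.
#'
#' @param peaks Classified peak table (needs `genotype`, `mark`,
#'   `category`, `signalValue`, `start`, `end`).
#' @return Data frame `genotype`, `mark`, `category`, `n_peaks`,
#'   `cum_signal`, `cum_area`.
#' @export
summarize_categories <- function(peaks) {
  lvls <- c("Promoter_only", "Enhancer_only", "Promoter_Enhancer", "Other")
  if (nrow(peaks) == 0L)
    return(data.frame(genotype = character(), mark = character(),
                      category = factor(character(), levels = lvls),
                      n_peaks = integer(), cum_signal = numeric(),
                      cum_area = numeric()))
  stopifnot(all(c("genotype", "mark", "category", "signalValue",
                  "start", "end") %in% names(peaks)))
  strata <- unique(peaks[, c("genotype", "mark")])
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- peaks$genotype == strata$genotype[i] &
      peaks$mark == strata$mark[i]
    cat_f <- factor(as.character(peaks$category[sel]), levels = lvls)
    width <- (peaks$end - peaks$start)[sel]
    data.frame(genotype = strata$genotype[i], mark = strata$mark[i],
               category = factor(lvls, levels = lvls),
               n_peaks = as.integer(table(cat_f)),
               cum_signal = vapply(lvls, function(l)
                 sum(peaks$signalValue[sel][cat_f == l]), numeric(1)),
               cum_area = vapply(lvls, function(l)
                 sum((peaks$signalValue[sel] * width)[cat_f == l]),
                 numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Annotate peaks across six genomic features
#'
#' Assigns each peak exactly one of `promoter-TSS`, `TTS`, `Exon_UTR`,
#' `CDS`, `intron`, `intergenic` by the location of its midpoint, with the
#' fixed precedence promoter-TSS > TTS > Exon(UTR) > CDS > intron >
#' intergenic. The TTS window mirrors the promoter window on the gene's
#' 3' end.
#'
#' @param peaks Peak table (0-based half-open).
#' @param gene_models Gene-model table as from [simulate_gene_models()]:
#'   rows of `type` `gene` (full span, used to derive the strand-aware TTS),
#'   `UTR_exon`, `CDS`, `intron`.
#' @param tss TSS anchor table (`chrom`, `pos`).
#' @param promoter_halfwidth,tts_halfwidth Window half-widths in bp.
#' @return List with `peaks` (input plus a `feature` factor column) and
#'   `percentages` (per genotype x mark, percentage of peaks per feature,
#'   summing to 100).
#' @export
annotate_six_features <- function(peaks, gene_models, tss,
                                  promoter_halfwidth = 1000,
                                  tts_halfwidth = 1000) {
  stopifnot(is.data.frame(gene_models),
            all(c("gene_id", "chrom", "start", "end", "strand", "type")
                %in% names(gene_models)))
  if (!all(gene_models$type %in% c("gene", "UTR_exon", "CDS", "intron")))
    stop("malformed gene model: unknown feature type")
  if (any(gene_models$end <= gene_models$start))
    stop("malformed gene model: empty interval")
  lvls <- c("promoter-TSS", "TTS", "Exon_UTR", "CDS", "intron", "intergenic")
  if (!"genotype" %in% names(peaks)) peaks$genotype <- "."
  if (!"mark" %in% names(peaks)) peaks$mark <- "."
  genes <- gene_models[gene_models$type == "gene", ]
  tts_pos <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  mid <- floor((peaks$start + peaks$end) / 2)
  seqlv <- unique(c(peaks$chrom, gene_models$chrom, tss$chrom))
  midgr <- .intervals_to_gr(peaks$chrom, mid, mid + 1, seqlv)
  in_set <- function(chrom, start, end) {
    if (!length(chrom)) return(rep(FALSE, nrow(peaks)))
    GenomicRanges::countOverlaps(
      midgr, .intervals_to_gr(chrom, start, end, seqlv)) > 0
  }
  in_prom <- in_set(tss$chrom, tss$pos - promoter_halfwidth,
                    tss$pos + promoter_halfwidth)
  in_tts <- in_set(genes$chrom, tts_pos - tts_halfwidth,
                   tts_pos + tts_halfwidth)
  sel <- function(tp) gene_models$type == tp
  in_utr <- in_set(gene_models$chrom[sel("UTR_exon")],
                   gene_models$start[sel("UTR_exon")],
                   gene_models$end[sel("UTR_exon")])
  in_cds <- in_set(gene_models$chrom[sel("CDS")],
                   gene_models$start[sel("CDS")],
                   gene_models$end[sel("CDS")])
  in_intron <- in_set(gene_models$chrom[sel("intron")],
                      gene_models$start[sel("intron")],
                      gene_models$end[sel("intron")])
  feature <- rep("intergenic", nrow(peaks))
  feature[in_intron] <- "intron"
  feature[in_cds] <- "CDS"
  feature[in_utr] <- "Exon_UTR"
  feature[in_tts] <- "TTS"
  feature[in_prom] <- "promoter-TSS"
  peaks$feature <- factor(feature, levels = lvls)
  strata <- unique(peaks[, c("genotype", "mark")])
  pct <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    selp <- peaks$genotype == strata$genotype[i] &
      peaks$mark == strata$mark[i]
    tab <- table(factor(as.character(peaks$feature[selp]), levels = lvls))
    data.frame(genotype = strata$genotype[i], mark = strata$mark[i],
               feature = factor(lvls, levels = lvls),
               n_peaks = as.integer(tab),
               percent = 100 * as.numeric(tab) / sum(tab),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(pct) <- NULL
  list(peaks = peaks, percentages = pct)
}
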