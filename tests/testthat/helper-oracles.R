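# Small genomes/configs for fast simulation in tests
tiny_genome <- function(chrom_length = 2e5) default_genome(chrom_length)

fast_config <- function(seed = 1L, depth = 5e4, ...) {
  sim_config(seed = seed, depth = depth, ...)
}

# Exhaustive pairwise-overlap oracle for the four-category regulatory
# classification (any shared base; promoter window [p - hw, p + hw)).
oracle_classify <- function(peaks, tss, enhancers, hw = 1000) {
  vapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$start[i]; e <- peaks$end[i]; ch <- peaks$chrom[i]
    in_prom <- FALSE
    if (nrow(tss)) {
      for (j in seq_len(nrow(tss))) {
        if (tss$chrom[j] == ch &&
            max(s, tss$pos[j] - hw) < min(e, tss$pos[j] + hw)) {
          in_prom <- TRUE; break
        }
      }
    }
    in_enh <- FALSE
    if (nrow(enhancers)) {
      for (j in seq_len(nrow(enhancers))) {
        if (enhancers$chrom[j] == ch &&
            max(s, enhancers$start[j]) < min(e, enhancers$end[j])) {
          in_enh <- TRUE; break
        }
      }
    }
    if (in_prom && in_enh) "Promoter_Enhancer"
    else if (in_prom) "Promoter_only"
    else if (in_enh) "Enhancer_only"
    else "Other"
  }, character(1))
}

# Random classification instance on a single chromosome
random_classify_instance <- function(seed, n_peaks = 200, n_tss = 100,
                                     n_enh = 60, span = 2e5) {
  set.seed(seed)
  s <- floor(runif(n_peaks) * (span - 5000))
  peaks <- data.frame(chrom = "chrI", start = s,
                      end = s + floor(runif(n_peaks, 200, 4000)),
                      signalValue = runif(n_peaks, 1, 10),
                      qValue_neglog10 = runif(n_peaks, 0, 8),
                      mark = sample(c("me1", "me2", "me3"), n_peaks, TRUE),
                      stringsAsFactors = FALSE)
  tss <- data.frame(name = sprintf("t%d", seq_len(n_tss)), chrom = "chrI",
                    pos = floor(runif(n_tss, 2000, span - 2000)),
                    strand = "+", stringsAsFactors = FALSE)
  es <- floor(runif(n_enh, 0, span - 1000))
  enhancers <- data.frame(name = sprintf("e%d", seq_len(n_enh)),
                          chrom = "chrI", start = es,
                          end = es + floor(runif(n_enh, 150, 900)),
                          stringsAsFactors = FALSE)
  list(peaks = peaks, tss = tss, enhancers = enhancers)
}

# Per-base brute-force oracle for signal-matrix extraction
oracle_matrix <- function(track, anchors, flank, bin_size) {
  ncol <- 2 * flank / bin_size
  out <- matrix(NA_real_, nrow(anchors), ncol,
                dimnames = list(anchors$name, NULL))
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    extent <- length(v) * track$bin_size
    for (j in seq_len(ncol)) {
      a <- anchors$pos[i] - flank + (j - 1) * bin_size
      b <- a + bin_size
      if (a < 0 || b > extent) next
      bases <- a:(b - 1)
      out[i, j] <- mean(v[floor(bases / track$bin_size) + 1])
    }
    strand <- if ("strand" %in% names(anchors)) anchors$strand[i] else "+"
    if (strand == "-") out[i, ] <- rev(out[i, ])
  }
  out
}

# Minimal differential-expression table builder for rule tests
deg_row <- function(gene_id, lfc, padj, baseA = 100, baseB = NULL,
                    chrom = "chrI") {
  if (is.null(baseB)) baseB <- baseA * 2^lfc
  data.frame(gene_id = gene_id, chrom = chrom,
             baseMean = (baseA + baseB) / 2,
             baseMeanA = baseA, baseMeanB = baseB,
             log2FoldChange = lfc, padj = padj, stringsAsFactors = FALSE)
}
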