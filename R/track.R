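#' Binned coverage track
#'
#' A `coverage_track` stores per-chromosome signal in fixed-width bins,
#' together with the bin size and a normalisation tag. The bin grid starts
#' at coordinate 0 on every chromosome; the last bin may be partial.
#'
#' @param values Named list, one non-negative numeric vector per chromosome.
#' @param bin_size Bin width in bp.
#' @param normalisation One of `"raw"`, `"cpm"`, `"spike_normalised"`.
#' @param genome Optional `genome_model`; if supplied, vector lengths are
#'   checked against `ceiling(length / bin_size)`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, bin_size,
                           normalisation = c("raw", "cpm", "spike_normalised"),
                           genome = NULL) {
  normalisation <- match.arg(normalisation)
  stopifnot(is.list(values), !is.null(names(values)),
            all(nzchar(names(values))),
            is.numeric(bin_size), length(bin_size) == 1L, bin_size >= 1)
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (!is.numeric(v)) stop("values for ", chrom, " must be numeric")
    if (any(!is.finite(v)) || any(v < 0))
      stop("negative or non-finite values on ", chrom)
  }
  if (!is.null(genome)) {
    want <- ceiling(chrom_lengths(genome) / bin_size)
    for (chrom in chrom_names(genome)) {
      if (is.null(values[[chrom]]))
        stop("track is missing chromosome ", chrom)
      if (length(values[[chrom]]) != want[[chrom]])
        stop("track on ", chrom, " has ", length(values[[chrom]]),
             " bins, expected ", want[[chrom]])
    }
  }
  structure(list(values = values, bin_size = as.numeric(bin_size),
                 normalisation = normalisation),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track: bin", x$bin_size, "bp,", length(x$values),
      "chromosomes,", x$normalisation, "normalisation\n")
  invisible(x)
}

#' Total signal in a track
#' @param track A `coverage_track`.
#' @return Sum of all bin values across chromosomes.
#' @export
track_total <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  sum(vapply(track$values, sum, numeric(1)))
}

# Value of the track at 0-based base positions `pos` on `chrom`
# (piecewise-constant on the bin grid). Out-of-range positions give NA.
track_value_at <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("track has no chromosome ", chrom)
  idx <- floor(pos / track$bin_size) + 1
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

# Convert a track to a GRanges with run-length-collapsed bins, for export.
track_to_granges <- function(track, genome) {
  stopifnot(inherits(track, "coverage_track"), inherits(genome, "genome_model"))
  lens <- chrom_lengths(genome)
  pieces <- lapply(chrom_names(genome), function(chrom) {
    v <- track$values[[chrom]]
    if (is.null(v)) stop("track is missing chromosome ", chrom)
    r <- rle(v)
    n <- length(r$lengths)
    ends0 <- cumsum(r$lengths) * track$bin_size
    starts0 <- c(0, ends0[-n])
    ends0[n] <- min(ends0[n], lens[[chrom]])
    data.frame(chrom = chrom, start0 = starts0, end0 = ends0,
               score = r$values)
  })
  df <- do.call(rbind, pieces)
  gr <- GenomicRanges::GRanges(
    factor(df$chrom, levels = chrom_names(genome)),
    IRanges::IRanges(start = df$start0 + 1, end = df$end0),
    score = df$score,
    seqlengths = lens)
  gr
}

# Inverse of track_to_granges: paint interval scores onto the bin grid.
# Intervals are assumed bin-aligned except possibly at chromosome ends.
granges_to_track <- function(gr, genome, bin_size, normalisation = "raw") {
  lens <- chrom_lengths(genome)
  values <- lapply(chrom_names(genome), function(chrom) {
    nb <- ceiling(lens[[chrom]] / bin_size)
    v <- numeric(nb)
    sel <- gr[GenomeInfoDb::seqnames(gr) == chrom]
    if (length(sel)) {
      s0 <- GenomicRanges::start(sel) - 1
      e0 <- GenomicRanges::end(sel)
      from <- floor(s0 / bin_size) + 1
      to <- pmin(ceiling(e0 / bin_size), nb)
      sc <- sel$score
      for (i in seq_along(sel)) v[from[i]:to[i]] <- sc[i]
    }
    v
  })
  coverage_track(setNames(values, chrom_names(genome)), bin_size,
                 normalisation)
}
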