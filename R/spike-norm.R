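#' Derive spike-in scaling factors
#'
#' Within each antibody (mark) group, every sample is scaled *down* to the
#' sample with the fewest spike-in reads:
#' `factor_s = min_t(spike_reads_t) / spike_reads_s`, so the reference sample
#' gets factor 1 and all factors lie in (0, 1]. IP efficiency is
#' antibody-specific, so factors are never compared across marks.
#'
#' @param table Spike-in count table with columns `sample_id`,
#'   `spike_reads`, and (when `group_by` is `"mark"`) a `mark` column.
#' @param group_by `"mark"` to derive factors within each mark, or `NULL`
#'   to treat the whole table as one group.
#' @return Data frame `sample_id`, `factor` (plus the grouping column).
#' @examples
#' tab <- data.frame(sample_id = c("A", "B", "C"), mark = "me3",
#'                   spike_reads = c(1e6, 2e6, 5e5))
#' compute_scaling_factors(tab)
#' @export
compute_scaling_factors <- function(table, group_by = "mark") {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "spike_reads") %in% names(table)))
  if (anyDuplicated(table$sample_id))
    stop("sample_ids must be unique")
  if (any(table$spike_reads <= 0))
    stop("zero spike reads for sample(s): ",
         paste(table$sample_id[table$spike_reads <= 0], collapse = ", "))
  grp <- if (is.null(group_by)) rep("all", nrow(table)) else {
    if (!group_by %in% names(table))
      stop("grouping column not present: ", group_by)
    as.character(table[[group_by]])
  }
  factor <- numeric(nrow(table))
  for (g in unique(grp)) {
    i <- grp == g
    factor[i] <- min(table$spike_reads[i]) / table$spike_reads[i]
  }
  out <- data.frame(sample_id = table$sample_id, factor = factor,
                    stringsAsFactors = FALSE)
  if (!is.null(group_by)) out[[group_by]] <- table[[group_by]]
  out
}

#' Binomially downsample integer counts
#'
#' Each count is thinned binomially with retention probability `factor`,
#' the in-silico analogue of read downsampling: the expected total is
#' `factor` times the original total and count statistics are preserved.
#'
#' @param x An integer-valued numeric vector or a raw-count
#'   `coverage_track`.
#' @param factor Retention probability in (0, 1].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Same type as `x`.
#' @export
downsample_counts <- function(x, factor, seed = 1L) {
  if (!is.numeric(factor) || length(factor) != 1L ||
      factor <= 0 || factor > 1)
    stop("downsampling factor must lie in (0, 1]")
  thin <- function(v) {
    if (any(v != round(v))) stop("downsampling needs integer counts")
    if (factor == 1) return(v)
    as.numeric(rbinom(length(v), size = round(v), prob = factor))
  }
  if (inherits(x, "coverage_track")) {
    with_stream(seed, "downsample", {
      coverage_track(lapply(x$values, thin), x$bin_size, x$normalisation)
    })
  } else if (is.numeric(x)) {
    with_stream(seed, "downsample", thin(x))
  } else stop("x must be a numeric vector or a coverage_track")
}

#' Counts-per-million normalisation of a track
#'
#' Scales every bin by `1e6 / total`, the per-sample CPM convention of
#' coverage-track generation.
#'
#' @param track A `coverage_track` of counts.
#' @param total Library size used as the denominator; defaults to the
#'   track's own total. Passing a common total across samples yields
#'   comparable tracks (used by [normalise_experiment()]).
#' @param tag Normalisation tag for the result.
#' @return A `coverage_track` tagged `cpm` (or `tag`).
#' @export
cpm_normalise <- function(track, total = NULL, tag = "cpm") {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(total)) total <- track_total(track)
  if (total <= 0) stop("cannot CPM-normalise an all-zero track")
  coverage_track(lapply(track$values, function(v) v * 1e6 / total),
                 track$bin_size, tag)
}

#' Spike-in normalise a set of coverage tracks
#'
#' Composes the normalisation contract: each sample's raw count track is
#' binomially downsampled by its spike-in scaling factor, then expressed in
#' CPM units of the reference library (the factor-1 sample of its mark
#' group), preserving the between-sample scaling the spike-in encodes. A
#' per-sample CPM denominator would cancel the factors and is exactly the
#' naive normalisation the spike-in exists to correct.
#'
#' @param tracks Named list of raw-count `coverage_track`s, one per
#'   `sample_id` in `spike_table`.
#' @param spike_table Spike-in count table (see
#'   [compute_scaling_factors()]).
#' @param seed Integer master seed (per-sample streams derived internally).
#' @param factors Optional precomputed factor table (`sample_id`,
#'   `factor`); must contain a factor-1 reference per group.
#' @param group_by Grouping column for factor derivation.
#' @return Named list of `coverage_track`s tagged `spike_normalised`.
#' @export
normalise_experiment <- function(tracks, spike_table, seed = 1L,
                                 factors = NULL, group_by = "mark") {
  stopifnot(is.data.frame(spike_table))
  if (is.null(factors))
    factors <- compute_scaling_factors(spike_table, group_by = group_by)
  stopifnot(all(c("sample_id", "factor") %in% names(factors)))
  grp <- if (!is.null(group_by) && group_by %in% names(factors))
    as.character(factors[[group_by]]) else rep("all", nrow(factors))
  for (g in unique(grp)) {
    if (max(factors$factor[grp == g]) < 1)
      stop("factor table violates the reference convention ",
           "(no factor-1 sample) in group ", g)
    if (any(factors$factor[grp == g] <= 0))
      stop("factors must be positive")
  }
  missing_trk <- setdiff(factors$sample_id, names(tracks))
  if (length(missing_trk))
    stop("missing track for sample(s): ", paste(missing_trk, collapse = ", "))
  down <- list()
  for (i in seq_len(nrow(factors))) {
    s <- factors$sample_id[i]
    down[[s]] <- downsample_counts(tracks[[s]], factors$factor[i],
                                   seed = stream_seed(seed,
                                                      paste0("norm/", s)))
  }
  out <- list()
  for (g in unique(grp)) {
    ids <- factors$sample_id[grp == g]
    ref <- ids[which.max(factors$factor[grp == g])]
    ref_total <- track_total(down[[ref]])
    for (s in ids)
      out[[s]] <- cpm_normalise(down[[s]], total = ref_total,
                                tag = "spike_normalised")
  }
  out[names(tracks)[names(tracks) %in% factors$sample_id]]
}

#' Mean track signal over feature windows
#'
#' Convenience used to compare normalised signal between samples: the mean
#' bin value over windows of `halfwidth` bp around each anchor.
#'
#' @param track A `coverage_track`.
#' @param anchors Anchor table (`chrom`, `pos`).
#' @param halfwidth Window half-width in bp.
#' @return Mean signal (single number).
#' @export
feature_signal <- function(track, anchors, halfwidth = 500) {
  stopifnot(inherits(track, "coverage_track"), nrow(anchors) > 0)
  bs <- track$bin_size
  vals <- unlist(lapply(seq_len(nrow(anchors)), function(i) {
    v <- track$values[[anchors$chrom[i]]]
    lo <- max(1L, floor((anchors$pos[i] - halfwidth) / bs) + 1L)
    hi <- min(length(v), ceiling((anchors$pos[i] + halfwidth) / bs))
    v[lo:hi]
  }))
  mean(vals)
}

#' Simulated recovery of a known global depletion
#'
#' End-to-end check of the normalisation contract on synthetic data with
#' known truth: a wild-type and a globally depleted sample (mark retention
#' `d`) are simulated with a sequencing-depth imbalance, spike-in counts
#' are drawn from the composition model, and the mutant/wild-type feature
#' signal ratio is measured after (a) spike-in normalisation and (b) naive
#' per-sample CPM. A working spike-in pipeline returns (a) close to `d`;
#' the naive control returns a ratio near 1 regardless of `d`.
#'
#' @param d True global retention factor in (0, 1].
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @param genome A `genome_model`.
#' @param n_tss,n_enh Feature counts for the simulated annotation.
#' @param depth Wild-type sequencing depth (reads).
#' @param depth_imbalance Mutant depth as a multiple of `depth`.
#' @return List `spike_ratio`, `naive_ratio`, `factors`.
#' @export
spikein_recovery_experiment <- function(d, seed = 1L,
                                        config = sim_config(),
                                        genome = default_genome(),
                                        n_tss = 100, n_enh = 50,
                                        depth = 2e5,
                                        depth_imbalance = 2) {
  stopifnot(d > 0, d <= 1)
  feats <- simulate_features(genome, n_tss, n_enh, seed = seed,
                             enhancer_width = config$enhancer_width)
  depths <- c(wt = depth, mut = depth_imbalance * depth)
  spike <- simulate_spikein_counts(c(wt = 1, mut = d), depths,
                                   config$spike_fraction, seed = seed)
  spike$mark <- "mark"
  tracks <- list(
    wt = simulate_coverage(genome, feats$tss, feats$enhancers, "me3", "wt",
                           config,
                           depth = spike$target_reads[
                             spike$sample_id == "wt"],
                           seed = stream_seed(seed, "sample/wt")),
    # global depletion scales the whole mark; the track shape is unchanged
    mut = simulate_coverage(genome, feats$tss, feats$enhancers, "me3", "wt",
                            config,
                            depth = spike$target_reads[
                              spike$sample_id == "mut"],
                            seed = stream_seed(seed, "sample/mut")))
  normed <- normalise_experiment(tracks, spike, seed = seed)
  sig <- function(trk) feature_signal(trk, feats$tss, halfwidth = 500)
  list(spike_ratio = sig(normed$mut) / sig(normed$wt),
       naive_ratio = sig(cpm_normalise(tracks$mut)) /
         sig(cpm_normalise(tracks$wt)),
       factors = compute_scaling_factors(spike))
}
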