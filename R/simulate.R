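#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. The defaults encode
#' the study conditions the generator emulates: 10-bp coverage bins, a 5%
#' spike-in chromatin fraction, genotype effects in which loss of RBBP-5
#' abolishes all three H3K4 methylation states while loss of WDR-5 strongly
#' reduces H3K4me3, redistributes H3K4me2 from TSS to enhancers, and
#' increases H3K4me1, and a differential-expression structure with more up-
#' than down-regulated genes but down-regulated genes drawn at higher
#' baseline expression.
#'
#' @param seed Master seed; every stage derives its own named stream from it
#'   via [stream_seed()].
#' @param bin_size Coverage bin width in bp.
#' @param depth Expected reads per simulated ChIP sample.
#' @param spike_fraction Fraction of spike-in chromatin in (0, 1).
#' @param background Background coverage intensity (arbitrary units) relative
#'   to the unit feature amplitudes.
#' @param enhancer_width Simulated enhancer interval width in bp.
#' @param mark_effects Nested list `genotype -> mark -> c(tss=, enhancer=)`
#'   of multiplicative factors applied to feature enrichment.
#' @param deg_params List of differential-expression generator parameters:
#'   `n_genes`, `frac_up`, `frac_down`, `lfc_mean`, `lfc_sd`,
#'   `basemean_log_mean`, `basemean_log_sd`, `x_gene_fraction`,
#'   `down_log_shift` (added to `basemean_log_mean` for down-regulated genes).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       bin_size = 10L,
                       depth = 1e6,
                       spike_fraction = 0.05,
                       background = 1,
                       enhancer_width = 400L,
                       mark_effects = default_mark_effects(),
                       deg_params = list()) {
  dp <- utils::modifyList(list(
    n_genes = 15000L, frac_up = 0.15, frac_down = 0.07,
    lfc_mean = 2, lfc_sd = 0.8,
    basemean_log_mean = log(200), basemean_log_sd = 1.2,
    x_gene_fraction = 0.15, down_log_shift = 3), deg_params)
  stopifnot(spike_fraction > 0, spike_fraction < 1,
            depth > 0, bin_size >= 1, background >= 0,
            dp$frac_up >= 0, dp$frac_down >= 0)
  if (dp$frac_up + dp$frac_down > 1)
    stop("frac_up + frac_down must not exceed 1")
  for (g in names(mark_effects))
    for (m in names(mark_effects[[g]]))
      if (any(mark_effects[[g]][[m]] < 0))
        stop("mark_effects factors must be >= 0 (", g, "/", m, ")")
  structure(list(seed = seed, bin_size = as.integer(bin_size), depth = depth,
                 spike_fraction = spike_fraction, background = background,
                 enhancer_width = as.integer(enhancer_width),
                 mark_effects = mark_effects, deg_params = dp),
            class = "sim_config")
}

#' Default genotype effects on H3K4 methylation enrichment
#'
#' Wild type is the unit reference. The `rbbp5` genotype sets every factor
#' to 0 (loss of all H3K4 methylation); `wdr5` reduces H3K4me3 everywhere,
#' shifts H3K4me2 from TSS toward enhancers, and elevates H3K4me1.
#'
#' @return Nested list `genotype -> mark -> c(tss, enhancer)`.
#' @export
default_mark_effects <- function() {
  list(
    wt    = list(me1 = c(tss = 1, enhancer = 1),
                 me2 = c(tss = 1, enhancer = 1),
                 me3 = c(tss = 1, enhancer = 1)),
    wdr5  = list(me1 = c(tss = 1.6, enhancer = 1.5),
                 me2 = c(tss = 0.5, enhancer = 1.8),
                 me3 = c(tss = 0.2, enhancer = 0.2)),
    rbbp5 = list(me1 = c(tss = 0, enhancer = 0),
                 me2 = c(tss = 0, enhancer = 0),
                 me3 = c(tss = 0, enhancer = 0))
  )
}

.check_mark <- function(mark) {
  if (!is.character(mark) || length(mark) != 1L ||
      !mark %in% c("me1", "me2", "me3"))
    stop("unknown mark: ", paste(mark, collapse = ", "),
         " (expected me1, me2 or me3)")
  mark
}

#' Simulate TSS anchors and enhancer intervals
#'
#' Stands in for external TSS and active-enhancer annotation sets. TSS are
#' single-base anchors with strand; enhancers are intervals of fixed width.
#' No anchor is placed within `edge_margin` bp of a chromosome edge, so
#' downstream flanking windows (up to +/- 5 kb) never leave the chromosome.
#'
#' @param genome A `genome_model`.
#' @param n_tss,n_enh Numbers of TSS and enhancers to place.
#' @param seed Integer seed (stream-derived internally).
#' @param edge_margin Minimum distance of any anchor from a chromosome edge.
#' @param enhancer_width Enhancer interval width in bp.
#' @return List with `tss` (data frame `name`, `chrom`, `pos`, `strand`;
#'   `pos` 0-based) and `enhancers` (data frame `name`, `chrom`, `start`,
#'   `end`; 0-based half-open).
#' @export
simulate_features <- function(genome, n_tss, n_enh, seed = 1L,
                              edge_margin = 6000L, enhancer_width = 400L) {
  stopifnot(inherits(genome, "genome_model"), n_tss >= 0, n_enh >= 0)
  lens <- chrom_lengths(genome)
  avail <- pmax(lens - 2 * edge_margin, 0)
  if (n_tss > sum(avail) || n_enh > sum(pmax(avail - enhancer_width, 0)))
    stop("genome too small for the requested feature counts")
  place <- function(n, width, what) {
    if (n == 0L)
      return(data.frame(name = character(), chrom = character(),
                        pos = numeric(), stringsAsFactors = FALSE))
    room <- pmax(avail - width, 0)
    chrom <- sample(names(lens), n, replace = TRUE, prob = room / sum(room))
    pos <- edge_margin + floor(runif(n) * room[chrom])
    data.frame(name = sprintf("%s_%d", what, seq_len(n)), chrom = chrom,
               pos = pos, stringsAsFactors = FALSE)
  }
  with_stream(seed, "features", {
    tss <- place(n_tss, 0L, "tss")
    tss$strand <- if (n_tss) sample(c("+", "-"), n_tss, replace = TRUE)
                  else character()
    enh <- place(n_enh, enhancer_width, "enh")
    enhancers <- data.frame(name = enh$name, chrom = enh$chrom,
                            start = enh$pos, end = enh$pos + enhancer_width,
                            stringsAsFactors = FALSE)
    list(tss = tss[, c("name", "chrom", "pos", "strand")],
         enhancers = enhancers)
  })
}

# Unit (wild-type) enrichment shapes per mark: mixture-of-Gaussian bumps
# relative to the anchor. me3 shows a double peak flanking the TSS, me1 a
# TSS valley with flanking enrichment and a strong central enhancer peak.
.shape_params <- list(
  tss = list(
    me3 = list(centers = c(-150, 150), sds = c(100, 100), amps = c(8, 8)),
    me2 = list(centers = 0, sds = 400, amps = 5),
    me1 = list(centers = c(-450, 450), sds = c(150, 150), amps = c(4, 4))),
  enhancer = list(
    me3 = list(centers = 0, sds = 200, amps = 1),
    me2 = list(centers = 0, sds = 200, amps = 3),
    me1 = list(centers = 0, sds = 150, amps = 6)))

#' Simulate a binned ChIP coverage track
#'
#' Background Poisson noise plus shaped enrichment at TSS and enhancers,
#' with feature-class enrichment scaled by the genotype's `mark_effects`
#' factors. Read counts are drawn as Poisson with total expectation `depth`,
#' so the returned track is a raw count track on the 0-anchored bin grid.
#'
#' @param genome A `genome_model`.
#' @param tss,enhancers Feature tables as returned by [simulate_features()].
#' @param mark One of `"me1"`, `"me2"`, `"me3"`.
#' @param genotype A genotype named in `config$mark_effects`.
#' @param config A [sim_config()].
#' @param depth Expected total read count (defaults to `config$depth`).
#' @param seed Seed (defaults to `config$seed`); the RNG stream is named by
#'   genotype and mark, so tracks for different samples are independent.
#' @return A raw-count [coverage_track()].
#' @export
simulate_coverage <- function(genome, tss, enhancers, mark, genotype, config,
                              depth = config$depth, seed = config$seed) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  .check_mark(mark)
  eff <- config$mark_effects[[genotype]]
  if (is.null(eff)) stop("unknown genotype: ", genotype)
  if (is.null(eff[[mark]])) stop("no effect entry for mark ", mark,
                                 " in genotype ", genotype)
  fct <- eff[[mark]]
  bs <- config$bin_size
  lens <- chrom_lengths(genome)
  mu <- lapply(names(lens), function(chrom) {
    rep(config$background, ceiling(lens[[chrom]] / bs))
  })
  names(mu) <- names(lens)
  add_bumps <- function(mu, chrom, anchor, shape, factor) {
    v <- mu[[chrom]]
    for (k in seq_along(shape$centers)) {
      c0 <- anchor + shape$centers[k]
      sdk <- shape$sds[k]
      lo <- max(1L, floor((c0 - 4 * sdk) / bs) + 1L)
      hi <- min(length(v), ceiling((c0 + 4 * sdk) / bs))
      if (lo > hi) next
      centers <- (seq(lo, hi) - 0.5) * bs
      v[lo:hi] <- v[lo:hi] +
        factor * shape$amps[k] * exp(-(centers - c0)^2 / (2 * sdk^2))
    }
    mu[[chrom]] <- v
    mu
  }
  if (nrow(tss))
    for (i in seq_len(nrow(tss)))
      mu <- add_bumps(mu, tss$chrom[i], tss$pos[i],
                      .shape_params$tss[[mark]], fct[["tss"]])
  if (nrow(enhancers))
    for (i in seq_len(nrow(enhancers)))
      mu <- add_bumps(mu, enhancers$chrom[i],
                      (enhancers$start[i] + enhancers$end[i]) / 2,
                      .shape_params$enhancer[[mark]], fct[["enhancer"]])
  total_mu <- sum(vapply(mu, sum, numeric(1)))
  with_stream(seed, paste("coverage", genotype, mark, sep = "/"), {
    values <- lapply(mu, function(v) as.numeric(rpois(length(v),
                                                      depth * v / total_mu)))
    coverage_track(values, bs, "raw", genome = genome)
  })
}

#' Simulate spike-in read-count tables
#'
#' Models the immunoprecipitated material as target-marked worm chromatin
#' (proportional to the genotype's true mark retention) plus a constant
#' spike-in pulldown from the foreign-histone antibody. Sequenced reads are
#' split binomially by that composition, so samples with depleted target
#' marks yield proportionally more spike reads at equal depth.
#'
#' @param true_depletion Named numeric vector, one retention factor in
#'   `[0, 1]` per sample (1 = wild-type abundance, 0 = complete loss).
#' @param depths Named numeric vector of total reads per sample (same names).
#' @param spike_fraction Spike-in chromatin fraction in (0, 1).
#' @param seed Integer seed.
#' @return Data frame `sample_id`, `target_reads`, `spike_reads`.
#' @examples
#' simulate_spikein_counts(c(wt = 1, mut = 0.5),
#'                         c(wt = 1e6, mut = 1e6), seed = 1)
#' @export
simulate_spikein_counts <- function(true_depletion, depths,
                                    spike_fraction = 0.05, seed = 1L) {
  stopifnot(!is.null(names(true_depletion)), !is.null(names(depths)),
            setequal(names(true_depletion), names(depths)),
            spike_fraction > 0, spike_fraction < 1)
  if (any(true_depletion < 0 | true_depletion > 1))
    stop("true_depletion factors must lie in [0, 1]")
  if (any(depths <= 0)) stop("sample depths must be positive")
  ids <- names(depths)
  s <- spike_fraction
  with_stream(seed, "spikein", {
    spike_share <- s / ((1 - s) * true_depletion[ids] + s)
    spike <- rbinom(length(ids), size = round(depths[ids]),
                    prob = spike_share)
    data.frame(sample_id = ids,
               target_reads = round(depths[ids]) - spike,
               spike_reads = spike,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

# Expected spike-read share for a retention factor, under the composition
# model above; exported for use as an analytic reference in simulations.
#' @rdname simulate_spikein_counts
#' @export
expected_spike_share <- function(true_depletion, spike_fraction = 0.05) {
  spike_fraction / ((1 - spike_fraction) * true_depletion + spike_fraction)
}

#' Simulate a differential-expression result table
#'
#' Emulates a per-gene result table from a negative-binomial differential
#' test: lognormal baseline expression, designated up/down genes with
#' |log2 fold change| beyond 1 and adjusted p below 0.05, null genes with
#' fold changes near zero and adjusted p uniform on (0.05, 1]. Down-regulated
#' genes are drawn at higher baseline expression than up-regulated genes
#' (by `down_log_shift` on the log scale), reproducing the observation that
#' highly expressed genes are the ones lost. Per-condition means satisfy
#' `baseMeanB = baseMeanA * 2^log2FoldChange` and
#' `baseMean = (baseMeanA + baseMeanB) / 2` exactly.
#'
#' @param config A [sim_config()]; `config$deg_params` drives the draw.
#' @param genome A `genome_model`; chromosomes are assigned with probability
#'   `x_gene_fraction` for the X and uniformly among autosomes otherwise.
#' @param seed Seed (defaults to `config$seed`).
#' @param label Stream label, so several tables (genotypes) can be drawn
#'   independently from one master seed.
#' @param cooks_replicates Optional character vector; for each name a
#'   `cooks_<name>` column of synthetic Cook's distances is added.
#' @return Data frame with columns `gene_id`, `chrom`, `baseMean`,
#'   `baseMeanA`, `baseMeanB`, `log2FoldChange`, `padj` and `status`
#'   (the ground-truth label `up`/`down`/`null`).
#' @export
simulate_deg_table <- function(config, genome, seed = config$seed,
                               label = "deg", cooks_replicates = character()) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_model"))
  dp <- config$deg_params
  n <- dp$n_genes
  if (dp$frac_up + dp$frac_down > 1)
    stop("frac_up + frac_down must not exceed 1")
  n_up <- round(n * dp$frac_up)
  n_down <- round(n * dp$frac_down)
  with_stream(seed, paste("degtable", label, sep = "/"), {
    status <- rep("null", n)
    idx <- sample.int(n)
    status[idx[seq_len(n_up)]] <- "up"
    if (n_down) status[idx[n_up + seq_len(n_down)]] <- "down"
    is_x <- runif(n) < dp$x_gene_fraction
    chrom <- ifelse(is_x, genome$x_name,
                    sample(autosome_names(genome), n, replace = TRUE))
    meanlog <- rep(dp$basemean_log_mean, n)
    meanlog[status == "down"] <- meanlog[status == "down"] + dp$down_log_shift
    baseA <- rlnorm(n, meanlog, dp$basemean_log_sd)
    # |log2FC| for DEG: normal truncated below at 1
    rtrunc_above1 <- function(k) {
      if (!k) return(numeric())
      u <- runif(k, pnorm(1, dp$lfc_mean, dp$lfc_sd), 1)
      qnorm(u, dp$lfc_mean, dp$lfc_sd)
    }
    lfc <- rnorm(n, 0, 0.25)
    lfc <- pmax(pmin(lfc, 0.99), -0.99)
    lfc[status == "up"] <- rtrunc_above1(sum(status == "up"))
    lfc[status == "down"] <- -rtrunc_above1(sum(status == "down"))
    padj <- runif(n, 0.0500001, 1)
    padj[status != "null"] <- runif(sum(status != "null"), 0, 0.0499)
    baseB <- baseA * 2^lfc
    out <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n)),
                      chrom = chrom,
                      baseMean = (baseA + baseB) / 2,
                      baseMeanA = baseA, baseMeanB = baseB,
                      log2FoldChange = lfc, padj = padj, status = status,
                      stringsAsFactors = FALSE)
    for (rep_name in cooks_replicates)
      out[[paste0("cooks_", rep_name)]] <- rlnorm(n, -2.5, 1.2)
    out
  })
}

#' Simulate broad-peak calls for a mark and genotype
#'
#' Emits one candidate peak per feature with probability equal to the
#' genotype's (capped) enrichment factor, plus a small set of weak
#' background peaks away from features, in ENCODE broadPeak geometry:
#' H3K4me1/me2 peaks broad (>= ~2 kb), H3K4me3 peaks narrower.
#'
#' @inheritParams simulate_coverage
#' @return Data frame of broadPeak fields (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signalValue`, `pValue_neglog10`, `qValue_neglog10`)
#'   plus `mark` and `genotype` labels.
#' @export
simulate_peaks <- function(genome, tss, enhancers, mark, genotype, config,
                           seed = config$seed) {
  .check_mark(mark)
  eff <- config$mark_effects[[genotype]]
  if (is.null(eff)) stop("unknown genotype: ", genotype)
  fct <- eff[[mark]]
  lens <- chrom_lengths(genome)
  with_stream(seed, paste("peaks", genotype, mark, sep = "/"), {
    mk <- function(chrom, center, factor) {
      keep <- runif(length(center)) < pmin(1, factor)
      chrom <- chrom[keep]; center <- center[keep]
      k <- length(center)
      if (!k) return(NULL)
      width <- if (mark == "me3") runif(k, 600, 1500) else runif(k, 2200, 4000)
      start <- pmax(0, round(center - width / 2))
      end <- pmin(lens[chrom], round(center + width / 2))
      signal <- (3.5 + 2 * min(factor, 2)) * rlnorm(k, 0, 0.15)
      data.frame(chrom = chrom, start = start, end = end,
                 signalValue = signal,
                 pValue_neglog10 = runif(k, 4, 12),
                 qValue_neglog10 = runif(k, 3, 10),
                 stringsAsFactors = FALSE)
    }
    parts <- list()
    if (nrow(tss)) parts$tss <- mk(tss$chrom, tss$pos, fct[["tss"]])
    if (nrow(enhancers))
      parts$enh <- mk(enhancers$chrom,
                      (enhancers$start + enhancers$end) / 2,
                      fct[["enhancer"]])
    # weak background calls; most fail the signal >= 3 post-filter
    n_bg <- max(1L, round(0.2 * (nrow(tss) + nrow(enhancers))))
    bg_chrom <- sample(names(lens), n_bg, replace = TRUE,
                       prob = lens / sum(lens))
    bg <- mk(bg_chrom, 6000 + floor(runif(n_bg) * (lens[bg_chrom] - 12000)),
             factor = 1)
    if (!is.null(bg)) {
      bg$signalValue <- runif(nrow(bg), 1, 4)
      bg$qValue_neglog10 <- runif(nrow(bg), 1.5, 4)
      parts$bg <- bg
    }
    out <- do.call(rbind, parts)
    if (is.null(out))
      out <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), signalValue = numeric(),
                        pValue_neglog10 = numeric(),
                        qValue_neglog10 = numeric(),
                        stringsAsFactors = FALSE)
    out$name <- sprintf("%s_%s_peak_%d", genotype, mark, seq_len(nrow(out)))
    out$score <- pmin(1000L, as.integer(round(100 * out$signalValue)))
    out$strand <- rep(".", nrow(out))
    out$mark <- rep(mark, nrow(out))
    out$genotype <- rep(genotype, nrow(out))
    rownames(out) <- NULL
    out[, c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue_neglog10", "qValue_neglog10",
            "mark", "genotype")]
  })
}

#' Simulate a minimal gene-model table
#'
#' Each gene carries a `gene` span row plus 5' UTR exon, CDS, intron, CDS
#' and 3' UTR exon rows, strand-aware, for use with
#' [annotate_six_features()].
#'
#' @param genome A `genome_model`.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param edge_margin Minimum distance from chromosome edges.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`, `type`
#'   with `type` in `gene`, `UTR_exon`, `CDS`, `intron` (0-based half-open).
#' @export
simulate_gene_models <- function(genome, n_genes, seed = 1L,
                                 edge_margin = 6000L) {
  lens <- chrom_lengths(genome)
  avail <- pmax(lens - 2 * edge_margin - 6000, 0)
  if (n_genes > 0 && sum(avail) <= 0) stop("genome too small for gene models")
  with_stream(seed, "gene_models", {
    chrom <- sample(names(lens), n_genes, replace = TRUE,
                    prob = avail / sum(avail))
    glen <- round(runif(n_genes, 2000, 6000))
    start <- edge_margin + floor(runif(n_genes) * (avail[chrom]))
    end <- start + glen
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    rows <- lapply(seq_len(n_genes), function(i) {
      utr <- 200
      body <- glen[i] - 2 * utr
      cds1 <- round(0.3 * body); intr <- round(0.4 * body)
      cds2 <- body - cds1 - intr
      b <- start[i] + cumsum(c(0, utr, cds1, intr, cds2, utr))
      data.frame(gene_id = sprintf("gm_%04d", i), chrom = chrom[i],
                 start = c(start[i], b[1], b[2], b[3], b[4], b[5]),
                 end = c(end[i], b[2], b[3], b[4], b[5], b[6]),
                 strand = strand[i],
                 type = c("gene", "UTR_exon", "CDS", "intron", "CDS",
                          "UTR_exon"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
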