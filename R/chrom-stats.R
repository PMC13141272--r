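#' Per-chromosome coverage summary
#'
#' Exact mean and total bin signal per chromosome, with genome totals.
#'
#' @param track A `coverage_track` covering every genome chromosome.
#' @param genome A `genome_model`.
#' @return A list of class `chrom_coverage_summary` with `per_chrom`
#'   (data frame `name`, `length`, `n_bins`, `mean_signal`,
#'   `total_signal`), `grand_total` and `genome`.
#' @export
per_chrom_summary <- function(track, genome) {
  stopifnot(inherits(track, "coverage_track"),
            inherits(genome, "genome_model"))
  missing <- setdiff(chrom_names(genome), names(track$values))
  if (length(missing))
    stop("track is missing chromosome(s): ", paste(missing, collapse = ", "))
  per <- do.call(rbind, lapply(chrom_names(genome), function(chrom) {
    v <- track$values[[chrom]]
    data.frame(name = chrom,
               length = chrom_lengths(genome)[[chrom]],
               n_bins = length(v),
               mean_signal = mean(v),
               total_signal = sum(v),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_chrom = per, grand_total = sum(per$total_signal),
                 genome = genome),
            class = "chrom_coverage_summary")
}

#' Per-chromosome log2(observed/expected) coverage
#'
#' Observed share = chromosome signal / genome signal; expected share =
#' chromosome length / genome length. Chromosomes with zero signal give
#' `-Inf` (flagged with a warning), never an error.
#'
#' @param summary A [per_chrom_summary()] result.
#' @return Data frame `name`, `observed`, `expected`, `log2_obs_exp`.
#' @export
log2_obs_exp <- function(summary) {
  stopifnot(inherits(summary, "chrom_coverage_summary"))
  if (summary$grand_total <= 0) stop("total signal must be positive")
  per <- summary$per_chrom
  obs <- per$total_signal / summary$grand_total
  expd <- per$length / sum(per$length)
  if (any(obs == 0))
    warning("zero signal on: ", paste(per$name[obs == 0], collapse = ", "),
            " (log2 ratio is -Inf)")
  data.frame(name = per$name, observed = obs, expected = expd,
             log2_obs_exp = log2(obs / expd), stringsAsFactors = FALSE)
}

#' Chromosome-size-weighted chi-squared uniformity test
#'
#' Goodness-of-fit of the per-chromosome totals against expected counts
#' proportional to chromosome length: `E_i = total * length_i / genome`,
#' statistic `sum((O_i - E_i)^2 / E_i)`, upper-tail p on `n - 1` degrees of
#' freedom. The totals must be on a counts scale; real-valued coverage
#' (e.g. RPGC) is converted by dividing by `value_scale` (the per-read bin
#' value), and the conversion is reported in the result.
#'
#' @param summary A [per_chrom_summary()] result.
#' @param value_scale Counts-conversion divisor (1 for raw count tracks).
#' @return A list of class `uniformity_result`: `per_chrom` (observed,
#'   expected, log2_obs_exp), `chisq_stat`, `df`, `p_value`,
#'   `x_autosome_log2`, `value_scale`.
#' @examples
#' g <- build_genome(c(chrA = 100, chrX = 100), "chrX")
#' tr <- coverage_track(list(chrA = rep(6, 10), chrX = rep(4, 10)), 10)
#' weighted_chisq_uniformity(per_chrom_summary(tr, g))$chisq_stat  # 4
#' @export
weighted_chisq_uniformity <- function(summary, value_scale = 1) {
  stopifnot(inherits(summary, "chrom_coverage_summary"), value_scale > 0)
  per <- summary$per_chrom
  if (nrow(per) < 2) stop("need at least two chromosomes")
  if (any(per$total_signal < 0)) stop("totals must be non-negative")
  O <- per$total_signal / value_scale
  total <- sum(O)
  if (total <= 0) stop("grand total must be positive")
  E <- total * per$length / sum(per$length)
  stat <- sum((O - E)^2 / E)
  df <- nrow(per) - 1L
  res <- list(per_chrom = data.frame(
                name = per$name, observed = O, expected = E,
                log2_obs_exp = log2((O / total) / (per$length /
                                                     sum(per$length))),
                stringsAsFactors = FALSE),
              chisq_stat = stat, df = df,
              p_value = pchisq(stat, df, lower.tail = FALSE),
              x_autosome_log2 = x_autosome_log2(summary),
              value_scale = value_scale)
  class(res) <- "uniformity_result"
  res
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("chi-squared uniformity: stat = %.4g, df = %d, p = %.4g\n",
              x$chisq_stat, x$df, x$p_value))
  cat(sprintf("chrX / autosome log2 ratio: %.4g\n", x$x_autosome_log2))
  invisible(x)
}

#' chrX versus autosome log2 signal ratio
#'
#' `log2(mean_signal(X) / weighted_mean_signal(autosomes))`, where the
#' autosomal mean is weighted by chromosome length.
#'
#' @param summary A [per_chrom_summary()] result.
#' @return A single number.
#' @export
x_autosome_log2 <- function(summary) {
  stopifnot(inherits(summary, "chrom_coverage_summary"))
  per <- summary$per_chrom
  xn <- summary$genome$x_name
  auto <- per[per$name != xn, ]
  auto_mean <- sum(auto$mean_signal * auto$length) / sum(auto$length)
  if (auto_mean <= 0) stop("autosome signal must be positive")
  log2(per$mean_signal[per$name == xn] / auto_mean)
}
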