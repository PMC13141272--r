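test_that("genome construction validates its inputs and preserves order", {
  g <- build_genome(setNames(rep(1e6, 6), c("I", "II", "III", "IV", "V",
                                            "X")), "X")
  expect_equal(chrom_names(g), c("I", "II", "III", "IV", "V", "X"))
  expect_equal(genome_length(g), 6e6)
  expect_equal(autosome_names(g), c("I", "II", "III", "IV", "V"))
  expect_error(build_genome(c(a = 100, a = 200), "a"), "duplicate")
  expect_error(build_genome(c(a = 0, b = 100), "a"), "positive")
  expect_error(build_genome(c(a = 100), "chrX"), "x_name")
})

test_that("feature simulation is deterministic and respects bounds", {
  g <- tiny_genome()
  f1 <- simulate_features(g, 100, 50, seed = 1)
  f2 <- simulate_features(g, 100, 50, seed = 1)
  expect_identical(f1, f2)
  expect_false(identical(f1, simulate_features(g, 100, 50, seed = 2)))
  lens <- chrom_lengths(g)
  expect_true(all(f1$tss$pos >= 6000 & f1$tss$pos < lens[f1$tss$chrom] -
                    6000))
  expect_true(all(f1$enhancers$end <= lens[f1$enhancers$chrom] - 6000))
  f0 <- simulate_features(g, 0, 5, seed = 1)
  expect_equal(nrow(f0$tss), 0)
  expect_equal(nrow(f0$enhancers), 5)
  small <- build_genome(c(c1 = 10000), "c1")
  expect_error(simulate_features(small, 10, 0, seed = 1), "too small")
})

test_that("zeroed genotype effects reduce feature signal to background", {
  g <- tiny_genome()
  f <- simulate_features(g, 40, 20, seed = 3)
  # pick a background probe position on chrII away from every feature
  feat_pos <- c(f$tss$pos[f$tss$chrom == "chrII"],
                f$enhancers$start[f$enhancers$chrom == "chrII"])
  cand <- seq(10000, 190000, by = 1000)
  bg_pos <- cand[which.max(vapply(cand, function(p)
    min(abs(p - feat_pos)), numeric(1)))]
  stopifnot(min(abs(bg_pos - feat_pos)) > 7000)
  bg_anchor <- data.frame(name = "bg", chrom = "chrII", pos = bg_pos)
  ratios <- sapply(1:20, function(s) {
    cfg <- fast_config(seed = s)
    trk <- simulate_coverage(g, f$tss, f$enhancers, "me3", "rbbp5", cfg)
    feature_signal(trk, f$tss, 300) / feature_signal(trk, bg_anchor, 3000)
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("unit factors are statistically indistinguishable from wild type", {
  g <- tiny_genome()
  f <- simulate_features(g, 40, 20, seed = 3)
  eff <- default_mark_effects()
  eff$clone <- eff$wt
  sig <- sapply(1:20, function(s) {
    cfg <- fast_config(seed = s, mark_effects = eff)
    c(wt = feature_signal(simulate_coverage(g, f$tss, f$enhancers, "me3",
                                            "wt", cfg), f$tss, 300),
      clone = feature_signal(simulate_coverage(g, f$tss, f$enhancers, "me3",
                                               "clone", cfg), f$tss, 300))
  })
  expect_lt(abs(mean(sig["clone", ]) / mean(sig["wt", ]) - 1), 0.02)
})

test_that("coverage simulation rejects unknown marks and genotypes", {
  g <- tiny_genome()
  f <- simulate_features(g, 5, 5, seed = 1)
  cfg <- fast_config()
  expect_error(simulate_coverage(g, f$tss, f$enhancers, "me4", "wt", cfg),
               "unknown mark")
  expect_error(simulate_coverage(g, f$tss, f$enhancers, "me3", "nope", cfg),
               "unknown genotype")
  trk <- simulate_coverage(g, f$tss, f$enhancers, "me1", "wdr5", cfg)
  expect_true(all(unlist(trk$values) >= 0))
  expect_equal(length(trk$values$chrI), ceiling(2e5 / 10))
})

test_that("spike-in counts follow the IP composition model", {
  # equal retention, equal depth: equal spike reads in expectation
  eq <- sapply(1:25, function(s)
    simulate_spikein_counts(c(a = 1, b = 1), c(a = 1e5, b = 1e5),
                            seed = s)$spike_reads)
  expect_lt(abs(mean(eq[1, ]) / mean(eq[2, ]) - 1), 0.05)
  # retention 0.5 vs 1.0: spike share doubles after composition
  # renormalisation, s/((1-s)d + s) -> ratio 1.905 at s = 0.05
  an <- expected_spike_share(0.5) / expected_spike_share(1)
  mc <- sapply(1:50, function(s)
    simulate_spikein_counts(c(dep = 0.5, full = 1), c(dep = 1e5, full = 1e5),
                            seed = s)$spike_reads)
  expect_lt(abs(mean(mc[1, ]) / mean(mc[2, ]) - an), 0.05 * an)
  expect_gt(an, 1.85)
  expect_error(simulate_spikein_counts(c(a = -0.1), c(a = 100)), "\\[0, 1\\]")
  expect_error(simulate_spikein_counts(c(a = 1), c(a = 0)), "positive")
})

test_that("spike read shares converge to equality as retention -> 1", {
  for (d in c(0.9, 0.99)) {
    mc <- sapply(1:50, function(s)
      simulate_spikein_counts(c(a = d, b = 1), c(a = 1e5, b = 1e5),
                              seed = s)$spike_reads)
    rel <- abs(mean(mc[1, ]) / mean(mc[2, ]) - 1)
    expect_lt(rel, (1 - d) + 0.05)
  }
})

test_that("differential-expression tables are internally consistent", {
  g <- tiny_genome()
  cfg <- fast_config(seed = 7,
                     deg_params = list(n_genes = 1000, frac_up = 0.1,
                                       frac_down = 0.05))
  deg <- simulate_deg_table(cfg, g)
  expect_equal(sum(deg$status == "up"), 100)
  expect_equal(sum(deg$status == "down"), 50)
  expect_equal(deg$baseMean, (deg$baseMeanA + deg$baseMeanB) / 2)
  expect_equal(deg$log2FoldChange, log2(deg$baseMeanB / deg$baseMeanA))
  expect_true(all(abs(deg$log2FoldChange[deg$status != "null"]) > 1))
  expect_true(all(deg$padj[deg$status != "null"] < 0.05))
  expect_true(all(deg$padj[deg$status == "null"] > 0.05))
})

test_that("a null table yields no calls at the study thresholds", {
  g <- tiny_genome()
  cfg <- fast_config(seed = 2,
                     deg_params = list(n_genes = 2000, frac_up = 0,
                                       frac_down = 0))
  deg <- simulate_deg_table(cfg, g)
  call <- call_deg(deg)
  expect_equal(length(deg_genes(call)), 0)
})

test_that("chrX gene share matches the configured fraction", {
  g <- tiny_genome()
  cfg <- fast_config(seed = 11,
                     deg_params = list(n_genes = 10000,
                                       x_gene_fraction = 0.2))
  deg <- simulate_deg_table(cfg, g)
  share <- mean(deg$chrom == "chrX")
  expect_lt(abs(share - 0.2), 0.02)  # ~5 sd of binomial(10000, 0.2)/n
  expect_error(sim_config(deg_params = list(frac_up = 0.7, frac_down = 0.4)),
               "exceed 1")
})

test_that("fixtures round-trip through their on-disk formats", {
  out <- withr::local_tempdir()
  g <- tiny_genome()
  cfg <- fast_config(seed = 5, depth = 2e4)
  manifest <- write_fixtures(out, cfg, g, n_tss = 30, n_enh = 15)
  expect_gte(length(manifest), 6)
  expect_true(all(file.exists(manifest)))
  g2 <- read_chrom_sizes(manifest[["chrom_sizes"]])
  expect_equal(chrom_lengths(g2), chrom_lengths(g))
  tss <- read_tss_bed(manifest[["tss"]])
  expect_equal(nrow(tss), 30)
  enh <- read_intervals_bed(manifest[["enhancers"]])
  expect_equal(nrow(enh), 15)
  spike <- read_tsv(manifest[["spike_counts"]])
  expect_true(all(c("sample_id", "genotype", "mark", "target_reads",
                    "spike_reads") %in% names(spike)))
  pk <- read_broadpeak(manifest[["peaks_wt"]], mark = "me3",
                       genotype = "wt")
  expect_true(all(pk$end > pk$start))
  deg <- read_deg_table(manifest[["deg_wdr5"]])
  expect_gt(nrow(deg), 0)
  # bedGraph round trip is exact for count tracks
  trk <- simulate_coverage(g, read_tss_bed(manifest[["tss"]]), enh,
                           "me3", "wt", cfg)
  p <- file.path(out, "rt.bedgraph")
  write_bedgraph(trk, g, p)
  trk2 <- read_bedgraph(p, g, cfg$bin_size)
  expect_equal(trk2$values, trk$values)
})

test_that("identical seeds give byte-identical fixtures", {
  g <- tiny_genome()
  cfg <- fast_config(seed = 9, depth = 1e4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_fixtures(d1, cfg, g, n_tss = 10, n_enh = 5)
  m2 <- write_fixtures(d2, cfg, g, n_tss = 10, n_enh = 5)
  for (k in names(m1))
    expect_identical(unname(tools::md5sum(m1[[k]])),
                     unname(tools::md5sum(m2[[k]])), label = k)
})

test_that("empty feature sets write valid, readable BED files", {
  out <- withr::local_tempdir()
  p <- file.path(out, "empty.bed")
  write_tss_bed(data.frame(name = character(), chrom = character(),
                           pos = numeric(), strand = character()), p)
  expect_true(file.exists(p))
  expect_equal(nrow(read_tss_bed(p)), 0)
})
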