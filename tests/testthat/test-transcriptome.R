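test_that("DEG calling applies strict thresholds and the count floor", {
  tab <- rbind(
    deg_row("up1", 1.5, 0.01, baseA = 100),
    deg_row("edge_lfc", 1.0, 0.001, baseA = 100),
    deg_row("edge_p", 1.5, 0.05, baseA = 100),
    deg_row("low", 2, 1e-5, baseA = 10, baseB = 30),
    deg_row("dn1", -2, 0.001, baseA = 500),
    deg_row("na_p", 3, NA, baseA = 100))
  call <- call_deg(tab)
  expect_false("low" %in% call$universe)  # both condition means < 50
  st <- call$status
  expect_equal(as.character(st[["up1"]]), "up")
  expect_equal(as.character(st[["edge_lfc"]]), "unchanged")  # strict >
  expect_equal(as.character(st[["edge_p"]]), "unchanged")    # strict <
  expect_equal(as.character(st[["dn1"]]), "down")
  expect_equal(as.character(st[["na_p"]]), "unchanged")
  # baseMeanB alone can admit a gene to the universe
  only_b <- call_deg(deg_row("b", 3, 0.01, baseA = 10, baseB = 90))
  expect_equal(length(only_b$universe), 1)
})

test_that("net transcriptome change matches forced arithmetic", {
  tab <- rbind(deg_row("A", 1, 0.01, baseA = 100 * 2 / (1 + 2)),
               deg_row("B", -1, 0.01, baseA = 300 * 2 / (1 + 0.5)))
  # constructed so baseMean is exactly 100 and 300
  expect_equal(tab$baseMean, c(100, 300))
  call <- call_deg(tab, lfc_abs_min = 0.5, count_cutoff = 10)
  expect_equal(net_transcriptome_change(call, tab), -50)
  single <- deg_row("S", 2, 0.01, baseA = 100)
  expect_equal(net_transcriptome_change(call_deg(single), single), 200)
  # mirror pairs cancel exactly
  sym <- rbind(deg_row("u", 2, 0.01, baseA = 400 * 2 / (1 + 4)),
               deg_row("d", -2, 0.01, baseA = 400 * 2 / (1 + 0.25)))
  expect_equal(net_transcriptome_change(call_deg(sym), sym), 0)
  # invariant to row order and to rescaling all baseMeans
  tab2 <- tab[2:1, ]
  expect_equal(net_transcriptome_change(
    call_deg(tab2, lfc_abs_min = 0.5, count_cutoff = 10), tab2), -50)
  tab3 <- tab
  for (cl in c("baseMean", "baseMeanA", "baseMeanB"))
    tab3[[cl]] <- tab3[[cl]] * 13
  expect_equal(net_transcriptome_change(
    call_deg(tab3, lfc_abs_min = 0.5, count_cutoff = 10), tab3), -50)
  none <- deg_row("x", 0.2, 0.8)
  expect_error(net_transcriptome_change(call_deg(none), none), "undefined")
})

test_that("exact Mann-Whitney reproduces the enumeration example", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "exact")
  same <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)
})

test_that("exact mode agrees with the rank-sum oracle for all n, m <= 6", {
  set.seed(17)
  for (n in 2:6) for (m in 2:6) {
    x <- rnorm(n); y <- rnorm(m)  # continuous: no ties
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mine$U, unname(ref$statistic), label = paste(n, m))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12,
                 label = paste(n, m))
  }
})

test_that("the normal approximation tracks the exact tail for n = m = 8", {
  set.seed(23)
  diffs <- replicate(100, {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    exact <- mann_whitney_u(x, y, exact_max = 8)$p_value
    approx <- mann_whitney_u(x, y, exact_max = 0)$p_value
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("baseline-stratified rank tests run over all three contrasts", {
  g <- tiny_genome()
  cfg <- fast_config(seed = 21, deg_params = list(n_genes = 2000))
  tab <- simulate_deg_table(cfg, g)
  call <- call_deg(tab)
  res <- baseline_stratified_test(call, tab)
  expect_equal(res$contrast,
               c("down_vs_up", "down_vs_unchanged", "up_vs_unchanged"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # the generator draws down genes at higher baseline: strongly significant
  expect_lt(res$p_value[res$contrast == "down_vs_up"], 0.01)
  empty_call <- call_deg(deg_row("only", 2, 0.01))
  expect_error(baseline_stratified_test(empty_call,
                                        deg_row("only", 2, 0.01)),
               "empty category")
})

test_that("chromosome enrichment matches forced arithmetic", {
  g <- tiny_genome()
  # universe of 1000 genes, 200 on chrX; 100 up-genes, 40 of them on chrX
  n <- 1000
  chrom <- rep(autosome_names(g), length.out = n)
  chrom[1:200] <- "chrX"
  lfc <- rep(0, n); padj <- rep(0.9, n)
  up_idx <- c(1:40, 201:260)
  lfc[up_idx] <- 2; padj[up_idx] <- 0.001
  tab <- data.frame(gene_id = sprintf("g%d", 1:n), chrom = chrom,
                    baseMean = 100, baseMeanA = 100, baseMeanB = 100,
                    log2FoldChange = lfc, padj = padj)
  enr <- chromosome_enrichment(call_deg(tab), tab, g, "up")
  x <- enr[enr$chrom == "chrX", ]
  expect_equal(x$observed, 40)
  expect_equal(x$expected, 100 * 0.2)
  expect_equal(x$log2_obs_exp, 1)
  expect_equal(x$p, binom.test(40, 100, 0.2)$p.value)
  expect_true(x$ci_low < 1 && x$ci_high > 1)
  expect_equal(nrow(enr), 6)
})

test_that("enrichment flags require both FDR and effect-size criteria", {
  g <- tiny_genome()
  n <- 600
  chrom <- rep(chrom_names(g), each = 100)
  lfc <- rep(0, n); padj <- rep(0.9, n)
  # mild, non-significant excess on chrI
  up_idx <- which(chrom == "chrI")[1:12]
  up_idx <- c(up_idx, which(chrom != "chrI")[1:50])
  lfc[up_idx] <- 2; padj[up_idx] <- 0.001
  tab <- data.frame(gene_id = sprintf("g%d", 1:n), chrom = chrom,
                    baseMean = 100, baseMeanA = 100, baseMeanB = 100,
                    log2FoldChange = lfc, padj = padj)
  enr <- chromosome_enrichment(call_deg(tab), tab, g, "up")
  expect_true(all(enr$flagged == (enr$fdr <= 0.01 &
                                    abs(enr$log2_obs_exp) >= log2(1.2))))
})

test_that("overlap significance equals the exact hypergeometric tail", {
  univ <- sprintf("g%d", 1:1000)
  mkcall <- function(deg) {
    tab <- data.frame(gene_id = univ, chrom = "chrI", baseMean = 100,
                      baseMeanA = 100, baseMeanB = 100,
                      log2FoldChange = ifelse(univ %in% deg, 2, 0),
                      padj = ifelse(univ %in% deg, 0.001, 0.9))
    call_deg(tab)
  }
  a <- mkcall(univ[1:50]); b <- mkcall(univ[41:90])
  ov <- overlap_sets(list(A = a, B = b))
  expect_equal(ov$pairwise$overlap, 10)
  # oracle: direct tail sum of the hypergeometric mass function
  oracle_p <- sum(dhyper(10:50, 50, 950, 50))
  expect_equal(ov$pairwise$p_value, oracle_p, tolerance = 1e-12)
  disj <- overlap_sets(list(A = mkcall(univ[1:20]),
                            B = mkcall(univ[21:40])))
  expect_equal(disj$pairwise$overlap, 0)
  expect_equal(disj$pairwise$p_value, 1)
  ident <- overlap_sets(list(A = a, B = a))
  expect_equal(ident$pairwise$overlap, 50)
  expect_equal(ident$pairwise$p_value, dhyper(50, 50, 950, 50))
  three <- overlap_sets(list(A = a, B = b, C = a))
  expect_equal(three$triple, 10)
  expect_error(overlap_sets(list(A = a, B = call_deg(deg_row("z", 2,
                                                             0.01)))),
               "universe")
})

test_that("restored-gene logic counts single-mutant DEG lost in the
           double", {
  univ <- sprintf("g%d", 1:100)
  mkcall <- function(deg) {
    tab <- data.frame(gene_id = univ, chrom = "chrI", baseMean = 100,
                      baseMeanA = 100, baseMeanB = 100,
                      log2FoldChange = ifelse(univ %in% deg, 2, 0),
                      padj = ifelse(univ %in% deg, 0.001, 0.9))
    call_deg(tab)
  }
  single <- mkcall(c("g1", "g2", "g3"))
  double <- mkcall(c("g1", "g2"))
  r <- restored_genes(single, double)
  expect_equal(r$genes, "g3")
  expect_equal(r$fraction, 1 / 3)
  expect_equal(restored_genes(single, single)$fraction, 0)
  superset <- mkcall(c("g1", "g2", "g3", "g4"))
  expect_equal(restored_genes(single, superset)$fraction, 0)
})

test_that("Cook's-distance sensitivity counts nest correctly", {
  tab <- rbind(deg_row("a", 1.2, 0.01, baseA = 100),
               deg_row("b", 0.9, 0.02, baseA = 100),
               deg_row("c", 0.5, 0.5, baseA = 100),
               deg_row("d", 2.0, 0.001, baseA = 20, baseB = 30),
               deg_row("e", -1.5, 0.001, baseA = 200))
  tab$cooks_rep1 <- c(1.5, 1.5, 0.2, 5, 0.9)
  r <- cooks_sensitivity(tab, "rep1")
  # gene d fails the both-conditions expression filter
  expect_equal(r$n_sensitive, 2)
  expect_equal(sort(r$genes), c("a", "b"))
  expect_equal(r$n_standard, 1)   # only a: |lfc| > 1 & padj < 0.05
  expect_equal(r$n_relaxed, 2)    # b enters at |lfc| > 0.75 & padj < 0.1
  expect_gte(r$n_relaxed, r$n_standard)
  tab$cooks_rep1 <- 0
  r0 <- cooks_sensitivity(tab, "rep1")
  expect_equal(r0$n_sensitive + r0$n_standard + r0$n_relaxed, 0)
  expect_error(cooks_sensitivity(tab, "nope"), "replicate")
})

test_that("relaxed criteria never select fewer genes than standard", {
  g <- tiny_genome()
  cfg <- fast_config(seed = 31, deg_params = list(n_genes = 3000))
  tab <- simulate_deg_table(cfg, g, cooks_replicates = "r1")
  r <- cooks_sensitivity(tab, "r1")
  expect_gte(r$n_relaxed, r$n_standard)
})

test_that("delta-delta-Ct matches the worked examples", {
  ct <- data.frame(gene = rep(c("tgt", "act-1"), each = 2),
                   condition = rep(c("control", "mutant"), 2),
                   replicate = 1,
                   ct = c(20, 18, 15, 15))
  r <- ddct(ct, control_condition = "control")
  expect_equal(r$fold[r$condition == "mutant"], 4)
  expect_equal(r$fold[r$condition == "control"], 1)
  same <- ct; same$ct <- c(20, 20, 15, 15)
  expect_equal(ddct(same, control_condition = "control")$fold, c(1, 1))
  up1 <- ct; up1$ct <- c(20, 21, 15, 15)   # one cycle later = half the RNA
  r2 <- ddct(up1, control_condition = "control")
  expect_equal(r2$fold[r2$condition == "mutant"], 0.5)
  noref <- ct[ct$gene != "act-1", ]
  expect_error(ddct(noref, control_condition = "control"), "reference")
})

test_that("replicate SEMs propagate into the fold interval", {
  ct <- expand.grid(gene = c("tgt", "act-1"),
                    condition = c("control", "mutant"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  set.seed(4)
  base <- ifelse(ct$gene == "act-1", 15, 20) -
    2 * (ct$gene == "tgt" & ct$condition == "mutant")
  ct$ct <- base + rnorm(nrow(ct), 0, 0.1)
  r <- ddct(ct, control_condition = "control")
  mut <- r[r$condition == "mutant", ]
  expect_gt(mut$sem_ddct, 0)
  expect_true(mut$fold_low < mut$fold && mut$fold < mut$fold_high)
  expect_equal(mut$fold, 4, tolerance = 0.3)
})
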