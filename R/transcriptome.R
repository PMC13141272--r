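#' Call differentially expressed genes from a result table
#'
#' The detected universe is genes with `baseMeanA >= count_cutoff` OR
#' `baseMeanB >= count_cutoff` (an expression floor of 50 in either
#' condition by default). Within the universe, `up` requires
#' `log2FoldChange > lfc_abs_min` and `padj < padj_max` (both strict, so
#' boundary genes are excluded); `down` is the mirror; everything else,
#' including genes with missing `padj`, is `unchanged`.
#'
#' @param table Data frame with `gene_id`, `baseMeanA`, `baseMeanB`,
#'   `log2FoldChange`, `padj`.
#' @param lfc_abs_min Strict |log2 fold change| threshold (1 = two-fold).
#' @param padj_max Strict adjusted-p threshold.
#' @param count_cutoff Expression floor for universe membership.
#' @return A list of class `deg_call`: `status` (named factor `up`, `down`,
#'   `unchanged` over the universe genes), `universe` (gene ids),
#'   `thresholds`.
#' @export
call_deg <- function(table, lfc_abs_min = 1, padj_max = 0.05,
                     count_cutoff = 50) {
  stopifnot(is.data.frame(table), nrow(table) >= 1,
            all(c("gene_id", "baseMeanA", "baseMeanB", "log2FoldChange",
                  "padj") %in% names(table)))
  in_univ <- table$baseMeanA >= count_cutoff | table$baseMeanB >= count_cutoff
  if (!any(in_univ)) warning("empty universe at this count cutoff")
  tab <- table[in_univ, ]
  sig <- !is.na(tab$padj) & tab$padj < padj_max
  status <- rep("unchanged", nrow(tab))
  status[sig & tab$log2FoldChange > lfc_abs_min] <- "up"
  status[sig & tab$log2FoldChange < -lfc_abs_min] <- "down"
  structure(list(status = setNames(factor(status,
                                          levels = c("up", "down",
                                                     "unchanged")),
                                   tab$gene_id),
                 universe = tab$gene_id,
                 thresholds = list(lfc_abs_min = lfc_abs_min,
                                   padj_max = padj_max,
                                   count_cutoff = count_cutoff)),
            class = "deg_call")
}

#' @export
print.deg_call <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf("deg_call: %d up, %d down, %d unchanged (universe %d)\n",
              tab[["up"]], tab[["down"]], tab[["unchanged"]],
              length(x$universe)))
  invisible(x)
}

#' Genes called differentially expressed (up and down)
#' @param call A `deg_call`.
#' @return Character vector of gene ids.
#' @export
deg_genes <- function(call) names(call$status)[call$status != "unchanged"]

#' Net transcriptome change percent
#'
#' A baseMean-weighted directional summary of transcriptome disruption:
#' `100 * sum(baseMean * log2FC) / sum(baseMean)` over the differentially
#' expressed genes. Negative values indicate net down-regulation. The
#' statistic is a weighted mean of log2 fold changes (times 100) and is
#' not bounded by +/-100.
#'
#' @param call A [call_deg()] result.
#' @param table The result table the call was made from (needs `gene_id`,
#'   `baseMean`, `log2FoldChange`).
#' @return The net change percent (single number).
#' @examples
#' tab <- data.frame(gene_id = c("A", "B"), chrom = "chrI",
#'                   baseMean = c(100, 300), baseMeanA = c(100, 600),
#'                   baseMeanB = c(200, 300),
#'                   log2FoldChange = c(1, -1), padj = c(0.01, 0.01))
#' net_transcriptome_change(call_deg(tab), tab)  # -50
#' @export
net_transcriptome_change <- function(call, table) {
  stopifnot(inherits(call, "deg_call"))
  deg <- deg_genes(call)
  if (length(deg) == 0L)
    stop("no differentially expressed genes; net change is undefined")
  sel <- table[match(deg, table$gene_id), ]
  100 * sum(sel$baseMean * sel$log2FoldChange) / sum(sel$baseMean)
}

#' Rank tests of wild-type baseline expression across DEG categories
#'
#' Mann-Whitney U tests on log2-transformed wild-type mean expression
#' (`baseMeanA`, pseudocount 1) between the down/up/unchanged categories
#' of a call: down vs up, down vs unchanged, up vs unchanged.
#'
#' @param call A [call_deg()] result.
#' @param table The underlying result table (needs `gene_id`, `baseMeanA`).
#' @param pseudocount Added before the log2 transform.
#' @return Data frame `contrast`, `U`, `p_value`, `method`, `n1`, `n2`.
#' @export
baseline_stratified_test <- function(call, table, pseudocount = 1) {
  stopifnot(inherits(call, "deg_call"))
  lv <- log2(table$baseMeanA[match(names(call$status), table$gene_id)] +
               pseudocount)
  groups <- split(lv, call$status)
  contrasts <- list(c("down", "up"), c("down", "unchanged"),
                    c("up", "unchanged"))
  out <- do.call(rbind, lapply(contrasts, function(ct) {
    a <- groups[[ct[1]]]; b <- groups[[ct[2]]]
    if (length(a) == 0L || length(b) == 0L)
      stop("empty category: ", ct[which(c(length(a), length(b)) == 0)[1]])
    r <- mann_whitney_u(a, b)
    data.frame(contrast = paste(ct, collapse = "_vs_"), U = r$U,
               p_value = r$p_value, method = r$method,
               n1 = r$n, n2 = r$m, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Wilson score 95% interval for a binomial proportion
.wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Chromosome-level enrichment of differentially expressed genes
#'
#' For one direction (`up` or `down`): per chromosome, the observed DEG
#' count is compared with the expectation under the universe's chromosome
#' composition. Reports log2(observed/expected), the Wilson 95% CI of the
#' observed proportion mapped onto the log2 scale, a two-sided exact
#' binomial p per chromosome, Benjamini-Hochberg FDR across chromosomes,
#' and a flag requiring both FDR <= `fdr_max` and
#' |log2(obs/exp)| >= log2(`min_enrichment`) (the +/-20% biological
#' threshold by default).
#'
#' @param call A [call_deg()] result.
#' @param table The underlying result table (needs `gene_id`, `chrom`).
#' @param genome A `genome_model`.
#' @param direction `"up"` or `"down"`.
#' @param fdr_max,min_enrichment The dual flagging criteria.
#' @return Data frame per chromosome: `chrom`, `n_universe`, `observed`,
#'   `expected`, `log2_obs_exp`, `ci_low`, `ci_high` (log2 scale), `p`,
#'   `fdr`, `flagged`.
#' @export
chromosome_enrichment <- function(call, table, genome,
                                  direction = c("up", "down"),
                                  fdr_max = 0.01, min_enrichment = 1.2) {
  direction <- match.arg(direction)
  stopifnot(inherits(call, "deg_call"), inherits(genome, "genome_model"))
  chrom <- table$chrom[match(names(call$status), table$gene_id)]
  bad <- setdiff(unique(chrom), chrom_names(genome))
  if (length(bad))
    stop("universe genes on chromosomes absent from the genome: ",
         paste(bad, collapse = ", "))
  deg <- names(call$status)[call$status == direction]
  n_deg <- length(deg)
  if (n_deg == 0L) stop("no genes in direction ", direction)
  deg_chrom <- chrom[match(deg, names(call$status))]
  out <- do.call(rbind, lapply(chrom_names(genome), function(cn) {
    n_univ <- sum(chrom == cn)
    if (n_univ == 0L) {
      warning("no universe genes on ", cn, "; excluded")
      return(NULL)
    }
    share <- n_univ / length(call$universe)
    obs <- sum(deg_chrom == cn)
    expd <- n_deg * share
    ci <- .wilson_ci(obs, n_deg)
    data.frame(chrom = cn, n_universe = n_univ, observed = obs,
               expected = expd,
               log2_obs_exp = log2((obs / n_deg) / share),
               ci_low = log2(ci[["low"]] / share),
               ci_high = log2(ci[["high"]] / share),
               p = binom.test(obs, n_deg, share)$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$fdr <- p.adjust(out$p, method = "BH")
  out$flagged <- out$fdr <= fdr_max &
    abs(out$log2_obs_exp) >= log2(min_enrichment)
  out
}

#' Overlap of DEG sets with hypergeometric significance
#'
#' Pairwise (and, for three calls, triple) intersection counts of the
#' differentially expressed gene sets, with upper-tail hypergeometric
#' p-values on the shared universe for each pair.
#'
#' @param calls Named list of 2 or 3 [call_deg()] results sharing one
#'   universe.
#' @return List with `sizes`, `pairwise` (data frame `set1`, `set2`,
#'   `overlap`, `p_value`) and, for three calls, `triple` (count).
#' @export
overlap_sets <- function(calls) {
  stopifnot(is.list(calls), length(calls) %in% c(2L, 3L),
            !is.null(names(calls)))
  u <- calls[[1]]$universe
  for (k in calls) if (!setequal(k$universe, u))
    stop("calls must share one universe")
  sets <- lapply(calls, deg_genes)
  nU <- length(u)
  pairs <- combn(names(calls), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1, j]]]; b <- sets[[pairs[2, j]]]
    ov <- length(intersect(a, b))
    data.frame(set1 = pairs[1, j], set2 = pairs[2, j], overlap = ov,
               p_value = phyper(ov - 1, length(a), nU - length(a),
                                length(b), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out <- list(sizes = vapply(sets, length, integer(1)), pairwise = pairwise)
  if (length(calls) == 3L)
    out$triple <- length(Reduce(intersect, sets))
  out
}

#' Genes restored to wild-type expression in a double mutant
#'
#' Genes differentially expressed in the single mutant but unchanged in the
#' double mutant; their misregulation therefore required the second factor.
#'
#' @param single_call,double_call [call_deg()] results on a shared
#'   universe.
#' @return List `genes` (character), `fraction` (restored / single-mutant
#'   DEG count; 0 when the single mutant has no DEG).
#' @export
restored_genes <- function(single_call, double_call) {
  stopifnot(inherits(single_call, "deg_call"),
            inherits(double_call, "deg_call"))
  single <- deg_genes(single_call)
  double <- deg_genes(double_call)
  restored <- setdiff(single, double)
  list(genes = restored,
       fraction = if (length(single)) length(restored) / length(single)
                  else 0)
}

#' Cook's-distance sensitivity of the differential-expression results
#'
#' Applies the expression filter of the replicate-influence analysis
#' (baseMean above the cutoff in BOTH conditions), selects genes whose
#' Cook's distance for the named replicate exceeds `cooks_min`, and counts
#' how many meet the standard and relaxed differential-expression criteria.
#'
#' @param table Result table with a `cooks_<replicate>` column.
#' @param replicate Replicate name (e.g. `"rbbp5_1"`).
#' @param cooks_min Cook's distance threshold.
#' @param standard,relaxed `c(lfc, padj)` threshold pairs; defaults
#'   `(1, 0.05)` and `(0.75, 0.1)`.
#' @param count_cutoff Expression floor, required in both conditions.
#' @return List `n_sensitive`, `n_standard`, `n_relaxed`, `genes`
#'   (the Cook's-sensitive gene ids).
#' @export
cooks_sensitivity <- function(table, replicate, cooks_min = 1,
                              standard = c(1, 0.05),
                              relaxed = c(0.75, 0.1),
                              count_cutoff = 50) {
  col <- paste0("cooks_", replicate)
  if (!col %in% names(table))
    stop("no Cook's distance column for replicate ", replicate)
  keep <- table$baseMeanA > count_cutoff & table$baseMeanB > count_cutoff
  tab <- table[keep, ]
  sens <- tab[!is.na(tab[[col]]) & tab[[col]] > cooks_min, ]
  meets <- function(th) {
    sum(abs(sens$log2FoldChange) > th[1] &
          !is.na(sens$padj) & sens$padj < th[2])
  }
  list(n_sensitive = nrow(sens),
       n_standard = meets(standard),
       n_relaxed = meets(relaxed),
       genes = sens$gene_id)
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Per gene and condition: `dCt = mean Ct(target) - mean Ct(reference)`;
#' `ddCt = dCt(condition) - dCt(control)`; fold change `2^(-ddCt)`.
#' Per-replicate SEMs of the mean Ct are propagated in quadrature through
#' both subtractions and reported as a fold-change interval.
#'
#' @param ct_table Data frame `gene`, `condition`, `replicate`, `ct`.
#' @param reference_gene Internal reference gene (default `act-1`).
#' @param control_condition The control (calibrator) condition.
#' @return Data frame `gene`, `condition`, `ddct`, `fold`, `sem_ddct`,
#'   `fold_low`, `fold_high`.
#' @examples
#' ct <- data.frame(gene = rep(c("g", "act-1"), each = 2),
#'                  condition = rep(c("control", "mutant"), 2),
#'                  replicate = 1,
#'                  ct = c(20, 18, 15, 15))
#' ddct(ct, control_condition = "control")  # fold 4 for gene g
#' @export
ddct <- function(ct_table, reference_gene = "act-1", control_condition) {
  stopifnot(is.data.frame(ct_table),
            all(c("gene", "condition", "replicate", "ct") %in%
                  names(ct_table)))
  conds <- unique(ct_table$condition)
  if (!control_condition %in% conds)
    stop("control condition not present: ", control_condition)
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (!all(conds %in% unique(ref$condition)))
    stop("reference gene ", reference_gene,
         " missing in condition(s): ",
         paste(setdiff(conds, unique(ref$condition)), collapse = ", "))
  mstat <- function(v) c(mean = mean(v),
                         sem = if (length(v) > 1)
                           sd(v) / sqrt(length(v)) else 0)
  ref_stats <- lapply(split(ref$ct, ref$condition), mstat)
  targets <- setdiff(unique(ct_table$gene), reference_gene)
  out <- do.call(rbind, lapply(targets, function(g) {
    sub <- ct_table[ct_table$gene == g, ]
    dct <- lapply(split(sub$ct, sub$condition), mstat)
    if (!control_condition %in% names(dct))
      stop("gene ", g, " has no measurements in the control condition")
    d0 <- dct[[control_condition]][["mean"]] -
      ref_stats[[control_condition]][["mean"]]
    s0 <- sqrt(dct[[control_condition]][["sem"]]^2 +
                 ref_stats[[control_condition]][["sem"]]^2)
    do.call(rbind, lapply(names(dct), function(cn) {
      d <- dct[[cn]][["mean"]] - ref_stats[[cn]][["mean"]]
      s <- sqrt(dct[[cn]][["sem"]]^2 + ref_stats[[cn]][["sem"]]^2)
      dd <- d - d0
      sem_dd <- if (cn == control_condition) s else sqrt(s^2 + s0^2)
      data.frame(gene = g, condition = cn, ddct = dd, fold = 2^(-dd),
                 sem_ddct = sem_dd,
                 fold_low = 2^(-(dd + sem_dd)),
                 fold_high = 2^(-(dd - sem_dd)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
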