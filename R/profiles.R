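# Integral of a piecewise-constant binned track from 0 to x (bp), on one
# chromosome. Vectorised over x; NA outside [0, n_bins * bin_size].
.track_integral <- function(values, bin_size, x) {
  extent <- length(values) * bin_size
  cum <- c(0, cumsum(values)) * bin_size
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= extent
  full <- pmin(floor(x[ok] / bin_size), length(values) - 1)
  out[ok] <- cum[full + 1] + values[full + 1] * (x[ok] - full * bin_size)
  out
}

#' Extract an anchor-centred signal matrix
#'
#' Row r, column j holds the mean track value over the j-th `bin_size` bin
#' of `[anchor - flank, anchor + flank)`. The matrix bin grid is anchored
#' at the region, not at the genome grid: where matrix bins straddle track
#' bins, the overlap-weighted mean is used (exact for the piecewise-constant
#' track). Rows for minus-strand anchors are reversed so downstream is
#' always to the right. Bins extending beyond the track are `NA`, never 0.
#'
#' @param track A `coverage_track`.
#' @param anchors Anchor table (`name`, `chrom`, `pos`, optional `strand`;
#'   `pos` 0-based).
#' @param flank Flank in bp on each side; must be a multiple of `bin_size`.
#' @param bin_size Matrix bin width in bp (defaults to the track's).
#' @param anchor_kind Label stored with the matrix (`"TSS"`,
#'   `"enhancer_midpoint"`, `"peak_summit"`, ...).
#' @return A numeric matrix (rows = anchors, in input order) with
#'   attributes `anchor_kind`, `flank`, `bin_size`.
#' @export
extract_matrix <- function(track, anchors, flank, bin_size = track$bin_size,
                           anchor_kind = "TSS") {
  stopifnot(inherits(track, "coverage_track"), nrow(anchors) >= 1,
            flank > 0)
  if (flank %% bin_size != 0)
    stop("flank must be a multiple of bin_size")
  unknown <- !anchors$chrom %in% names(track$values)
  if (any(unknown))
    stop("anchor(s) on chromosomes absent from the track: ",
         paste(anchors$name[unknown], collapse = ", "))
  ncol <- as.integer(2 * flank / bin_size)
  strand <- if ("strand" %in% names(anchors)) anchors$strand
            else rep("+", nrow(anchors))
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = ncol,
                dimnames = list(anchors$name, NULL))
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    bounds <- anchors$pos[i] - flank + (0:ncol) * bin_size
    s <- .track_integral(v, track$bin_size, bounds)
    row <- diff(s) / bin_size
    if (strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  attr(mat, "anchor_kind") <- anchor_kind
  attr(mat, "flank") <- flank
  attr(mat, "bin_size") <- bin_size
  mat
}

#' Split regions into me3 High / me3 Low by k-means
#'
#' k = 2 clustering of the row vectors (standard within-cluster
#' sum-of-squares objective, best of `n_restarts` starts); the cluster with
#' the larger mean row sum is labelled `me3_High`. Missing cells are imputed
#' with the row-local mean before clustering. Deterministic given `seed`.
#'
#' @param mat A signal matrix from [extract_matrix()] (typically H3K4me3).
#' @param seed Integer seed.
#' @param n_restarts Number of k-means restarts.
#' @param on_rows If `"vectors"` (default) cluster the full binned rows;
#'   if `"mean"` cluster the per-row mean signal only.
#' @return Factor (levels `me3_Low`, `me3_High`) named by row, with
#'   attribute `degenerate = TRUE` (and all rows `me3_Low`, plus a warning)
#'   when all rows are identical.
#' @export
kmeans_high_low <- function(mat, seed = 1L, n_restarts = 10L,
                            on_rows = c("vectors", "mean")) {
  on_rows <- match.arg(on_rows)
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  imp <- mat
  rm_ <- rowMeans(imp, na.rm = TRUE)
  rm_[!is.finite(rm_)] <- 0
  for (i in seq_len(nrow(imp)))
    imp[i, is.na(imp[i, ])] <- rm_[i]
  x <- if (on_rows == "mean") matrix(rowMeans(imp), ncol = 1) else imp
  if (all(apply(x, 2, function(col) max(col) - min(col) == 0))) {
    warning("all rows identical; returning a single me3_Low cluster")
    out <- factor(rep("me3_Low", nrow(mat)),
                  levels = c("me3_Low", "me3_High"))
    names(out) <- rownames(mat)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cluster <- if (nrow(x) == 2L) c(1L, 2L)  # each row its own cluster
  else with_stream(seed, "kmeans",
                   kmeans(x, centers = 2, nstart = n_restarts))$cluster
  high_cluster <- which.max(tapply(rowSums(imp), cluster, mean))
  out <- factor(ifelse(cluster == high_cluster, "me3_High", "me3_Low"),
                levels = c("me3_Low", "me3_High"))
  names(out) <- rownames(mat)
  attr(out, "degenerate") <- FALSE
  out
}

#' Aggregate a signal matrix into per-group mean/sd profiles
#'
#' Column-wise, missing-aware mean and standard deviation per group of
#' rows (e.g. the High/Low clusters, or a chromosome map).
#'
#' @param mat A signal matrix.
#' @param group Optional vector/factor of length `nrow(mat)` partitioning
#'   the rows; `NULL` treats all rows as one group.
#' @return Data frame `group`, `bin` (bp offset of the bin centre from the
#'   anchor when the matrix carries its attributes, else the column index),
#'   `mean`, `sd`, `n` (group size).
#' @export
aggregate_profile <- function(mat, group = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(group)) group <- rep("all", nrow(mat))
  stopifnot(length(group) == nrow(mat))
  bs <- attr(mat, "bin_size"); fl <- attr(mat, "flank")
  bin <- if (!is.null(bs) && !is.null(fl))
    (seq_len(ncol(mat)) - 0.5) * bs - fl else seq_len(ncol(mat))
  lv <- if (is.factor(group)) levels(group)
        else sort(unique(as.character(group)))
  out <- do.call(rbind, lapply(lv, function(g) {
    rows <- mat[group == g, , drop = FALSE]
    n <- nrow(rows)
    data.frame(group = g, bin = bin,
               mean = if (n) colMeans(rows, na.rm = TRUE)
                      else rep(NA_real_, ncol(mat)),
               sd = if (n) apply(rows, 2, sd, na.rm = TRUE)
                    else rep(NA_real_, ncol(mat)),
               n = n, row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Serialise a signal matrix as gzipped TSV with a JSON header
#'
#' @param mat A signal matrix from [extract_matrix()].
#' @param path Output path (a `.tsv.gz` is written).
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(mat, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  meta <- list(anchor_kind = attr(mat, "anchor_kind"),
               flank = attr(mat, "flank"),
               bin_size = attr(mat, "bin_size"))
  writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  write.table(mat, con, sep = "\t", quote = FALSE,
              col.names = FALSE, row.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  header <- readLines(con, n = 1)
  meta <- jsonlite::fromJSON(sub("^#", "", header))
  df <- read.table(con, sep = "\t", header = FALSE, row.names = 1,
                   na.strings = "NA")
  mat <- as.matrix(df)
  dimnames(mat)[[2]] <- NULL
  attr(mat, "anchor_kind") <- meta$anchor_kind
  attr(mat, "flank") <- meta$flank
  attr(mat, "bin_size") <- meta$bin_size
  mat
}
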