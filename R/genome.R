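#' Build a genome model
#'
#' A `genome_model` holds an ordered chromosome set with lengths and
#' designates which chromosome is treated as the X, defining the
#' autosome/X partition used by the chromosome-level statistics.
#'
#' @param chromosomes Either a data frame with columns `name` and `length`,
#'   or a named numeric vector of chromosome lengths (bp). Order is preserved.
#' @param x_name Name of the chromosome treated as X.
#' @return An object of class `genome_model` with elements `chromosomes`
#'   (data frame `name`, `length`) and `x_name`.
#' @examples
#' g <- build_genome(c(chrI = 1e6, chrX = 1e6), x_name = "chrX")
#' genome_length(g)
#' @export
build_genome <- function(chromosomes, x_name) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.numeric(unname(chromosomes)),
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L)
    stop("genome must contain at least one chromosome")
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome name: ",
         paste(unique(chromosomes$name[duplicated(chromosomes$name)]),
               collapse = ", "))
  if (any(!is.finite(chromosomes$length) | chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  if (!is.character(x_name) || length(x_name) != 1L ||
      !x_name %in% chromosomes$name)
    stop("x_name must be one of the chromosome names")
  structure(list(chromosomes = chromosomes[, c("name", "length")],
                 x_name = x_name),
            class = "genome_model")
}

#' Default toy genome: six 1-Mb chromosomes (I--V, X)
#'
#' Mirrors the chromosome count of the *C. elegans* karyotype at a size
#' small enough for fast simulation while leaving room for +/- 5 kb windows.
#'
#' @param chrom_length Length of every chromosome in bp.
#' @return A [build_genome()] object.
#' @export
default_genome <- function(chrom_length = 1e6) {
  nm <- c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrX")
  build_genome(setNames(rep(chrom_length, 6L), nm), x_name = "chrX")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      format(genome_length(x), big.mark = ","), "bp total; X =",
      x$x_name, "\n")
  invisible(x)
}

#' @rdname build_genome
#' @param genome A `genome_model`.
#' @export
chrom_names <- function(genome) genome$chromosomes$name

#' @rdname build_genome
#' @export
chrom_lengths <- function(genome)
  setNames(genome$chromosomes$length, genome$chromosomes$name)

#' @rdname build_genome
#' @export
genome_length <- function(genome) sum(genome$chromosomes$length)

#' @rdname build_genome
#' @export
autosome_names <- function(genome)
  setdiff(chrom_names(genome), genome$x_name)
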