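# Expected recovery of a single-copy fungal gene (e.g. the cytochrome
# P450 nitric oxide reductase, P450nor) from a shotgun metagenome.

#' Expected fungal gene reads in a metagenome
#'
#' Under the simplest possible model — one fungal species carrying
#' `copies_per_genome` copies of the gene — a fungal read hits the gene
#' with probability `gene_length_bp / genome_size_bp` (or, when the read
#' length is supplied, `(gene_length_bp + read_length_bp - 1) /
#' genome_size_bp`, counting any overlap). The expected number of gene
#' reads is then
#' \deqn{\lambda = N_{reads} \times f_{fungal} \times c \times p_{hit}}
#' and the chance of recovering at least one read is the Poisson
#' complement \eqn{P(\ge 1) = 1 - e^{-\lambda}}. With the ~0.02% fungal
#' read fractions typical of oxygen-minimum-zone metagenomes, \eqn{\lambda}
#' falls well below 1 at ordinary sequencing depths, i.e. absence of the
#' gene is expected even if the fungus is there.
#'
#' @param total_reads Number of classifiable reads in the metagenome.
#' @param fungal_fraction Fraction of reads that are fungal (0-1).
#' @param genome_size_bp Fungal genome size (default 3e7, a typical
#'   fungal genome).
#' @param gene_length_bp Gene length (default 1500, a typical cytochrome
#'   P450 ORF).
#' @param copies_per_genome Gene copies per genome (default 1).
#' @param read_length_bp Optional read length; when given, the hit
#'   probability counts reads overlapping the gene by at least one base.
#' @return List of class `gene_detectability` with `lambda` and
#'   `p_detect`.
#' @examples
#' expected_gene_reads(1e7, 2e-4) # lambda = 0.1
#' @export
expected_gene_reads <- function(total_reads, fungal_fraction,
                                genome_size_bp = 3e7, gene_length_bp = 1500,
                                copies_per_genome = 1,
                                read_length_bp = NULL) {
  if (!is.finite(total_reads) || total_reads <= 0) {
    stop_validation("`total_reads` must be positive")
  }
  if (any(!is.finite(fungal_fraction)) || any(fungal_fraction < 0) ||
      any(fungal_fraction > 1)) {
    stop_validation("`fungal_fraction` must lie in [0, 1]")
  }
  if (!is.finite(genome_size_bp) || genome_size_bp <= 0) {
    stop_validation("`genome_size_bp` must be positive")
  }
  if (!is.finite(gene_length_bp) || gene_length_bp <= 0 ||
      gene_length_bp > genome_size_bp) {
    stop_validation("`gene_length_bp` must be in (0, genome_size_bp]")
  }
  if (!is.finite(copies_per_genome) || copies_per_genome <= 0) {
    stop_validation("`copies_per_genome` must be positive")
  }
  target_bp <- if (is.null(read_length_bp)) {
    gene_length_bp
  } else {
    if (!is.finite(read_length_bp) || read_length_bp <= 0) {
      stop_validation("`read_length_bp` must be positive")
    }
    gene_length_bp + read_length_bp - 1
  }
  lambda <- total_reads * fungal_fraction * copies_per_genome *
    target_bp / genome_size_bp
  structure(list(
    lambda = lambda,
    p_detect = 1 - exp(-lambda),
    total_reads = total_reads,
    fungal_fraction = fungal_fraction,
    genome_size_bp = genome_size_bp,
    gene_length_bp = gene_length_bp,
    copies_per_genome = copies_per_genome,
    read_length_bp = read_length_bp
  ), class = "gene_detectability")
}

#' @export
print.gene_detectability <- function(x, ...) {
  cat(sprintf(
    "Gene detectability: %.4g expected reads (lambda), P(>=1 read) = %.4g\n  (%g reads, fungal fraction %.3g, gene %g bp / genome %g bp)\n",
    x$lambda, x$p_detect, x$total_reads, x$fungal_fraction,
    x$gene_length_bp, x$genome_size_bp))
  invisible(x)
}

#' @export
as.data.frame.gene_detectability <- function(x, ...) {
  data.frame(total_reads = x$total_reads, fungal_fraction = x$fungal_fraction,
             genome_size_bp = x$genome_size_bp,
             gene_length_bp = x$gene_length_bp,
             copies_per_genome = x$copies_per_genome,
             lambda = x$lambda, p_detect = x$p_detect,
             stringsAsFactors = FALSE)
}
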