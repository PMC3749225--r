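#' Generate a random reference genome
#'
#' Draws each chromosome as i.i.d. bases with a fixed GC content. The result
#' stands in for a real reference so that the full integration-site pipeline
#' can be exercised without any external download.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Integer vector of chromosome lengths in bp (recycled if a
#'   single value). Every length must be at least 10 kb, so that 100-kb
#'   TSS-centred window analyses remain meaningful.
#' @param gc Target GC fraction, strictly between 0 and 1. Default 0.41
#'   (approximately the human genome average).
#' @param seed Integer seed; the genome is a pure function of the arguments.
#'
#' @return A [Biostrings::DNAStringSet] named `chr1`, `chr2`, ... with
#'   alphabet restricted to A/C/G/T.
#' @examples
#' g <- generate_genome(2, c(50000, 60000), gc = 0.4, seed = 7)
#' Biostrings::width(g)
#' @export
generate_genome <- function(n_chrom, lengths, gc = 0.41, seed) {
  stopifnot(n_chrom >= 1)
  if (length(lengths) == 1L) lengths <- rep(lengths, n_chrom)
  if (length(lengths) != n_chrom)
    stop("`lengths` must have one entry per chromosome", call. = FALSE)
  lengths <- as.integer(lengths)
  if (any(lengths < 10000L))
    stop("every chromosome must be at least 10 kb (10000 bp): shorter ",
         "sequences cannot host the 100-kb TSS-window analyses downstream",
         call. = FALSE)
  if (!(gc > 0 && gc < 1))
    stop("`gc` must lie strictly between 0 and 1", call. = FALSE)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- .with_seed(seed, lapply(lengths, function(L) {
    paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
  }))
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  Biostrings::DNAStringSet(unlist(chroms))
}

#' Write / read a reference genome as FASTA
#'
#' Thin wrappers around [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()]; sequences are wrapped at 60 columns.
#'
#' @param genome A `DNAStringSet` (or named character vector of chromosomes).
#' @param path Path of the FASTA file.
#' @return `write_genome_fasta` returns `path` invisibly; `read_genome_fasta`
#'   returns a `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  gchr <- .as_genome_chr(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gchr), path,
                              width = 60L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first token as the name
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
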