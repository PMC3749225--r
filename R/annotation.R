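#' Construct a genome annotation
#'
#' Bundles a gene table with named label sets (for example a cancer-related
#' gene list). Coordinates are 0-based half-open: a gene occupies
#' `[tx_start, tx_end)` and its transcription start site (TSS) is `tx_start`
#' on the `+` strand and `tx_end - 1` on the `-` strand.
#'
#' @param genes A data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tx_start`, `tx_end`.
#' @param label_sets Named list of character vectors of gene ids; every id
#'   must exist in `genes`.
#' @return An object of class `GenomeAnnotation` (a list with elements
#'   `genes` and `label_sets`).
#' @export
genome_annotation <- function(genes, label_sets = list()) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("`genes` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  genes <- genes[need]
  genes$tx_start <- as.integer(genes$tx_start)
  genes$tx_end <- as.integer(genes$tx_end)
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique", call. = FALSE)
    if (!all(genes$strand %in% c("+", "-")))
      stop("`strand` must be '+' or '-'", call. = FALSE)
    if (any(genes$tx_start < 0L) || any(genes$tx_start >= genes$tx_end))
      stop("need 0 <= tx_start < tx_end for every gene", call. = FALSE)
  }
  if (length(label_sets)) {
    if (is.null(names(label_sets)) || any(!nzchar(names(label_sets))))
      stop("`label_sets` must be a named list", call. = FALSE)
    for (lab in names(label_sets)) {
      unknown <- setdiff(label_sets[[lab]], genes$gene_id)
      if (length(unknown))
        stop("label '", lab, "' refers to unknown gene id(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(genes = genes, label_sets = label_sets),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  for (lab in names(x$label_sets))
    cat("  label '", lab, "': ", length(x$label_sets[[lab]]), " genes\n",
        sep = "")
  invisible(x)
}

#' Generate a random non-overlapping gene annotation
#'
#' Places `n_genes` genes uniformly on the genome (chromosomes weighted by
#' length) with lengths uniform in `gene_len`, rejecting placements that
#' would overlap an existing gene. Strands are assigned uniformly and
#' `round(cancer_frac * n_genes)` genes are labelled `"cancer"`.
#'
#' @param genome Reference genome (`DNAStringSet` or named character vector).
#' @param n_genes Number of genes to place.
#' @param gene_len Length-2 vector, min and max gene length in bp.
#' @param cancer_frac Fraction of genes to label `"cancer"`, in `[0, 1]`.
#' @param seed Integer seed.
#' @param min_gap Minimum gap in bp enforced between gene intervals and
#'   from chromosome ends (default 0, i.e. plain disjointness). Setting it
#'   to at least twice a window half-width guarantees non-overlapping,
#'   unclipped TSS windows, which makes uniform-background density
#'   profiles exactly flat in expectation.
#' @param max_attempts Total placement attempts before giving up.
#' @return A [genome_annotation()] object with pairwise disjoint gene
#'   intervals.
#' @export
generate_annotation <- function(genome, n_genes, gene_len = c(5000, 20000),
                                cancer_frac = 0.25, seed, min_gap = 0L,
                                max_attempts = 200L * max(n_genes, 1L)) {
  gchr <- .as_genome_chr(genome)
  lens <- nchar(gchr)
  stopifnot(length(gene_len) == 2L, gene_len[1] >= 1, gene_len[1] <= gene_len[2])
  if (!(cancer_frac >= 0 && cancer_frac <= 1))
    stop("`cancer_frac` must lie in [0, 1]", call. = FALSE)
  if (max(gene_len) > max(lens))
    stop("gene length range exceeds the longest chromosome", call. = FALSE)

  res <- .with_seed(seed, {
    placed <- vector("list", n_genes)
    starts <- lapply(gchr, function(x) integer(0))  # per-chrom occupied starts
    ends <- lapply(gchr, function(x) integer(0))
    k <- 0L; attempts <- 0L
    while (k < n_genes) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n_genes, " non-overlapping genes of ",
             gene_len[1], "-", gene_len[2], " bp in ", sum(lens),
             " bp of genome after ", max_attempts,
             " attempts; reduce n_genes or gene_len", call. = FALSE)
      chrom <- sample(names(gchr), 1L, prob = lens)
      L <- lens[[chrom]]
      glen <- sample(gene_len[1]:gene_len[2], 1L)
      if (glen > L) next
      s <- sample.int(L - glen + 1L, 1L) - 1L   # 0-based start
      e <- s + glen                             # 0-based exclusive end
      if (s < min_gap || e > L - min_gap) next
      if (any(s - min_gap < ends[[chrom]] & e + min_gap > starts[[chrom]]))
        next
      k <- k + 1L
      starts[[chrom]] <- c(starts[[chrom]], s)
      ends[[chrom]] <- c(ends[[chrom]], e)
      placed[[k]] <- data.frame(chrom = chrom, tx_start = s, tx_end = e,
                                stringsAsFactors = FALSE)
    }
    genes <- if (n_genes > 0) do.call(rbind, placed) else
      data.frame(chrom = character(0), tx_start = integer(0),
                 tx_end = integer(0))
    genes$strand <- if (n_genes > 0)
      sample(c("+", "-"), n_genes, replace = TRUE) else character(0)
    genes$gene_id <- sprintf("gene%03d", seq_len(n_genes))
    n_cancer <- round(cancer_frac * n_genes)
    cancer <- if (n_cancer > 0) sort(sample(genes$gene_id, n_cancer)) else
      character(0)
    list(genes = genes, cancer = cancer)
  })
  label_sets <- if (n_genes > 0) list(cancer = res$cancer) else list()
  genome_annotation(res$genes[c("gene_id", "chrom", "strand", "tx_start",
                                "tx_end")],
                    label_sets = label_sets)
}

#' Transcription start site positions
#'
#' @param ann A `GenomeAnnotation` or its `genes` data.frame.
#' @return Integer vector of 0-based TSS positions, one per gene:
#'   `tx_start` for `+` strand genes, `tx_end - 1` for `-` strand genes.
#' @export
tss_positions <- function(ann) {
  genes <- if (inherits(ann, "GenomeAnnotation")) ann$genes else ann
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

#' Write / read a gene annotation as BED6
#'
#' Six tab-separated columns (chrom, tx_start, tx_end, gene_id, score = 0,
#' strand), 0-based half-open, no header. Label sets are written as separate
#' one-gene-id-per-line files via [write_label_set()].
#'
#' @param ann A `GenomeAnnotation`.
#' @param path File path.
#' @export
write_annotation_bed <- function(ann, path) {
  g <- ann$genes
  out <- data.frame(g$chrom, g$tx_start, g$tx_end, g$gene_id, 0L, g$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @param label_paths Named character vector of label-list file paths, e.g.
#'   `c(cancer = "cancer_genes.txt")`.
#' @export
read_annotation_bed <- function(path, label_paths = character(0)) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "tx_start", "tx_end",
                                         "gene_id", "score", "strand"))
  labels <- lapply(label_paths, read_label_set)
  genome_annotation(bed[c("gene_id", "chrom", "strand", "tx_start", "tx_end")],
                    label_sets = as.list(labels))
}

#' Write / read a gene-label list (one gene id per line)
#'
#' @param ids Character vector of gene ids.
#' @param path File path.
#' @export
write_label_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' @rdname write_label_set
#' @export
read_label_set <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}
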