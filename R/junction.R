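# Junction-read parsing: recover the genomic flank between the nested LTR
# primer (read prefix) and the reverse complement of the nested linker
# primer (read suffix).

#' Parse junction reads into genomic flanks
#'
#' A read is expected to be
#' `[nested LTR primer][genomic flank][revcomp(nested linker primer)]`.
#' Matching is anchored: the LTR primer must be a prefix and the
#' reverse-complemented linker primer a suffix, each within
#' `max_primer_mismatch` substitutions. Checks run in order, and the first
#' failure sets the status: `no_ltr_primer`, then `no_linker`, then
#' `flank_too_short`; otherwise `ok` and the interior substring is the flank.
#' Parsing is total: every read yields exactly one call.
#'
#' @param read A single read: a character string, or a list/one-row
#'   data.frame with `read_id` and `seq`.
#' @param reads A data.frame with columns `read_id` and `seq`.
#' @param protocol An [lmpcr_protocol()]; supplies the primers and
#'   `min_flank_bp`.
#' @param max_primer_mismatch Substitutions tolerated in each primer match
#'   (default 1).
#' @return `parse_junction_read`: a one-row data.frame; `parse_junction_reads`:
#'   a data.frame with one row per read, columns `read_id`, `flank_seq`
#'   (`NA` unless `ok`) and `status`.
#' @export
parse_junction_read <- function(read, protocol, max_primer_mismatch = 1L) {
  if (is.character(read)) read <- list(read_id = "read", seq = read)
  parse_junction_reads(data.frame(read_id = read$read_id, seq = read$seq,
                                  stringsAsFactors = FALSE),
                       protocol, max_primer_mismatch)
}

#' @rdname parse_junction_read
#' @export
parse_junction_reads <- function(reads, protocol, max_primer_mismatch = 1L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)),
            inherits(protocol, "LmPcrProtocol"), max_primer_mismatch >= 0)
  if (nrow(reads) && any(!nzchar(reads$seq)))
    stop("empty read sequence (read ",
         paste(reads$read_id[!nzchar(reads$seq)], collapse = ", "),
         "): reads must be non-empty", call. = FALSE)
  prefix <- protocol$ltr_primer_nested
  suffix <- .revcomp(protocol$linker_primer_nested)
  np <- nchar(prefix); ns <- nchar(suffix)
  min_flank <- protocol$min_flank_bp

  n <- nrow(reads)
  status <- character(n); flank <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- reads$seq[i]; L <- nchar(s)
    if (L < np || .hamming(substr(s, 1L, np), prefix) > max_primer_mismatch) {
      status[i] <- "no_ltr_primer"; next
    }
    if (L - np < ns ||
        .hamming(substr(s, L - ns + 1L, L), suffix) > max_primer_mismatch) {
      status[i] <- "no_linker"; next
    }
    fl <- substr(s, np + 1L, L - ns)
    if (nchar(fl) < min_flank) { status[i] <- "flank_too_short"; next }
    status[i] <- "ok"; flank[i] <- fl
  }
  data.frame(read_id = reads$read_id, flank_seq = flank, status = status,
             stringsAsFactors = FALSE)
}

#' Collapse mapped reads to independent integration sites
#'
#' Reads mapping within `merge_bp` of each other on the same chromosome and
#' orientation are treated as clones of one integration event
#' (single-linkage chaining); the representative position is the smallest in
#' the cluster and the multiplicity counts its reads.
#'
#' @param mapped A data.frame with columns `chrom`, `pos`, `orient` (e.g.
#'   mapped rows of [map_flanks()] output).
#' @param merge_bp Maximum gap merged into one site (default 3, absorbing
#'   junction-trimming slippage; use 0 for exact deduplication).
#' @return A data.frame `chrom`, `pos`, `orient`, `multiplicity`, sorted by
#'   `(chrom, pos)`.
#' @export
collapse_to_independent_sites <- function(mapped, merge_bp = 3L) {
  mapped <- .as_sites_df(mapped)
  stopifnot(merge_bp >= 0)
  if (nrow(mapped) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      orient = character(0), multiplicity = integer(0)))
  out <- list()
  for (key in split(seq_len(nrow(mapped)),
                    paste(mapped$chrom, mapped$orient, sep = "\r"))) {
    p <- sort(mapped$pos[key])
    new_cluster <- c(TRUE, diff(p) > merge_bp)
    cl <- cumsum(new_cluster)
    out[[length(out) + 1L]] <- data.frame(
      chrom = mapped$chrom[key[1]],
      pos = as.integer(tapply(p, cl, min)),
      orient = mapped$orient[key[1]],
      multiplicity = as.integer(tapply(p, cl, length)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$orient), , drop = FALSE]
  rownames(res) <- NULL
  res
}
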