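# Independent oracles used to check the package's own implementations.

# Exhaustive every-offset, both-strand placement search via
# Biostrings::matchPattern, followed by the same unique-best-hit decision
# rule as map_flanks(). Independent of the package's seed-and-extend search.
bf_map_flank <- function(flank, genome, max_mismatches = 2L,
                         uniqueness_margin = 2L) {
  gset <- if (inherits(genome, "DNAStringSet")) genome else
    Biostrings::DNAStringSet(genome)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- Biostrings::DNAString(flank)
    if (strand == "-") pat <- Biostrings::reverseComplement(pat)
    for (ch in names(gset)) {
      subj <- gset[[ch]]
      v <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches)
      if (length(v)) {
        st <- BiocGenerics::start(v)
        mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                          with.indels = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, strand = strand, start = st, mm = as.integer(mm),
          stringsAsFactors = FALSE)
      }
    }
  }
  L <- nchar(flank)
  out <- data.frame(status = NA_character_, chrom = NA_character_,
                    pos = NA_integer_, orient = NA_character_,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)
  if (!length(hits)) { out$status <- "unmapped"; return(out) }
  h <- do.call(rbind, hits)
  h <- h[h$mm <= max_mismatches, , drop = FALSE]
  if (!nrow(h)) { out$status <- "unmapped"; return(out) }
  best <- min(h$mm)
  runner <- if (nrow(h) > 1L) sort(h$mm)[2L] else Inf
  if (sum(h$mm == best) > 1L || runner - best < uniqueness_margin) {
    out$status <- "ambiguous"; return(out)
  }
  b <- which.min(h$mm)
  out$status <- "mapped"
  out$chrom <- h$chrom[b]
  out$orient <- h$strand[b]
  out$pos <- if (h$strand[b] == "+") h$start[b] - 1L else
    h$start[b] - 1L + L - 1L
  out$mismatches <- h$mm[b]
  out
}

# All-pairs nearest-TSS minimisation with the package's sign and
# tie-break conventions.
bf_nearest_tss <- function(chrom, pos, ann) {
  genes <- ann$genes[ann$genes$chrom == chrom, , drop = FALSE]
  if (!nrow(genes))
    return(list(gene_id = NA_character_, distance = NA_integer_))
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  d <- abs(pos - tss)
  cand <- which(d == min(d))
  pick <- cand[order(genes$gene_id[cand])][1]
  signed <- if (genes$strand[pick] == "+") pos - tss[pick] else
    tss[pick] - pos
  list(gene_id = genes$gene_id[pick], distance = as.integer(signed))
}

# Exact two-sided Fisher p by enumerating all tables with the observed
# margins and summing probabilities <= that of the observed table.
bf_fisher_p <- function(k_a, n_a, k_b, n_b) {
  k <- k_a + k_b
  xs <- max(0, k - n_b):min(k, n_a)
  probs <- stats::dhyper(xs, n_a, n_b, k)
  p_obs <- stats::dhyper(k_a, n_a, n_b, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Substitute k random bases of a DNA string.
mutate_seq <- function(s, k) {
  if (k == 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in sample(length(ch), k))
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Extract the expected genomic flank of a simulated site from the genome.
truth_flank <- function(genome, chrom, pos, orient, len) {
  s <- as.character(genome)[[chrom]]
  if (orient == "+") substr(s, pos + 1L, pos + len) else
    revcomp_chr(substr(s, pos - len + 2L, pos + 1L))
}

site_key <- function(df) sort(paste(df$chrom, df$pos, df$orient))
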